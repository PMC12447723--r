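#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Global spliced-alignment DP with affine gaps and an intron state.
//
// States per cell (i consumed ref bases, j consumed query bases):
//   H: best ending in a match/mismatch or just after closing a gap/intron
//   E: deletion run (ref consumed, gap in query), affine q + e*len
//   F: insertion run (query consumed), affine q + e*len
//   Etilde: intron state; opened from H[i'][j] at cost dcost[i'] + q~ where
//     i' is the local offset of the first intronic base, closed into H[i][j]
//     at cost acost[i] (i = one past the intron end), no per-base cost.
// A minimum intron length is enforced by delaying when an opened intron
// becomes closable; an optional maximum length expires old opens.
//
// Tie preference when filling H: M (diag) > Etilde > E > F, and among tied
// intron openings the leftmost start. Traceback follows the stored choices,
// giving a deterministic single optimal path.

static const double NEG = -1e18;

// [[Rcpp::export]]
List dp_align_cpp(std::string ref, std::string query,
                  double match, double mismatch,
                  double gap_open, double gap_ext, double intron_open,
                  NumericVector dcost, NumericVector acost,
                  int min_intron, double max_intron) {
  const int n = (int) ref.size(), m = (int) query.size();
  if ((int) dcost.size() != n + 1 || (int) acost.size() != n + 1)
    stop("dcost/acost must have length nchar(ref) + 1");
  const size_t ncell = (size_t)(n + 1) * (m + 1);
  std::vector<double> H(ncell, NEG);
  std::vector<uint8_t> choice(ncell, 0);
  std::vector<int> eentry(ncell, -1);
  std::vector<double> Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  std::vector<double> open_val(n + 1, NEG);

  for (int j = 0; j <= m; j++) {
    double Ecur = NEG;
    double best_open = NEG; int best_arg = -1;
    for (int i = 0; i <= n; i++) {
      const size_t c = (size_t) i * (m + 1) + j;
      // E: deletion run ending with ref base i (same j)
      double Ev = NEG; bool Eopen = false;
      if (i > 0) {
        const double ho = H[c - (m + 1)];
        const double eo = (ho > NEG / 2) ? ho - gap_open : NEG;
        if (eo >= Ecur) { Ev = eo; Eopen = true; } else Ev = Ecur;
        Ev = (Ev > NEG / 2) ? Ev - gap_ext : NEG;
      }
      // F: insertion run ending with query base j (same i)
      double Fv = NEG; bool Fopen = false;
      if (j > 0) {
        const double ho = H[c - 1];
        const double fo = (ho > NEG / 2) ? ho - gap_open : NEG;
        if (fo >= Fprev[i]) { Fv = fo; Fopen = true; } else Fv = Fprev[i];
        Fv = (Fv > NEG / 2) ? Fv - gap_ext : NEG;
      }
      // Etilde: admit the open that is now min_intron old; expire too-old opens
      if (i - min_intron >= 0) {
        const int cand = i - min_intron;
        if (open_val[cand] > best_open) { best_open = open_val[cand]; best_arg = cand; }
      }
      if (R_finite(max_intron) && best_arg >= 0 && i - best_arg > max_intron) {
        best_open = NEG; best_arg = -1;
        const int lo = i - (int) max_intron, hi = i - min_intron;
        for (int t = (lo > 0 ? lo : 0); t <= hi; t++)
          if (open_val[t] > best_open) { best_open = open_val[t]; best_arg = t; }
      }
      // H
      double hv = NEG; int src = -1;
      if (i == 0 && j == 0) { hv = 0.0; src = 0; }
      if (i > 0 && j > 0) {
        const double hd = H[c - (m + 1) - 1];
        if (hd > NEG / 2) {
          const char a = ref[i - 1], b = query[j - 1];
          const double sub = (a == b && a != 'N') ? match : mismatch;
          if (hd + sub > hv) { hv = hd + sub; src = 0; }
        }
      }
      if (best_arg >= 0 && best_open > NEG / 2) {
        const double ev = best_open - acost[i];
        if (ev > hv) { hv = ev; src = 3; }
      }
      if (Ev > hv) { hv = Ev; src = 1; }
      if (Fv > hv) { hv = Fv; src = 2; }
      H[c] = hv;
      uint8_t ch = (uint8_t) (src < 0 ? 0 : src);
      if (Eopen) ch |= 4;
      if (Fopen) ch |= 8;
      choice[c] = ch;
      eentry[c] = best_arg;
      Ecur = Ev;
      Fcur[i] = Fv;
      // record this cell's intron opening for later columns of this row
      open_val[i] = (hv > NEG / 2) ? hv - dcost[i] - intron_open : NEG;
    }
    std::swap(Fprev, Fcur);
    std::fill(open_val.begin(), open_val.end(), NEG);
    // opens are per-row (intron consumes ref only); rebuild for next j is
    // handled implicitly because open_val was just cleared and refilled as
    // the next row is swept. But the next row needs opens from ITS OWN H
    // values, which are written during its sweep, so clearing is correct.
  }

  const double score = H[ncell - 1];
  if (score < NEG / 2) stop("no valid global alignment (should not happen)");

  // traceback
  std::string ops;
  int i = n, j = m, n_match = 0;
  std::vector<int> jst, jen;
  while (i > 0 || j > 0) {
    const size_t c = (size_t) i * (m + 1) + j;
    const uint8_t ch = choice[c];
    const int src = ch & 3;
    if (src == 0) {
      const char a = ref[i - 1], b = query[j - 1];
      if (a == b && a != 'N') n_match++;
      ops.push_back('M'); i--; j--;
    } else if (src == 1) {
      // walk the deletion run
      while (true) {
        const size_t cc = (size_t) i * (m + 1) + j;
        const bool wasopen = (choice[cc] & 4) != 0;
        ops.push_back('D'); i--;
        if (wasopen) break;
      }
    } else if (src == 2) {
      while (true) {
        const size_t cc = (size_t) i * (m + 1) + j;
        const bool wasopen = (choice[cc] & 8) != 0;
        ops.push_back('I'); j--;
        if (wasopen) break;
      }
    } else {
      const int start = eentry[c];
      if (start < 0) stop("traceback error: intron close without entry");
      jst.push_back(start); jen.push_back(i);
      for (int t = 0; t < i - start; t++) ops.push_back('N');
      i = start;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode to CIGAR
  std::string cigar;
  size_t p = 0;
  int n_aligned_cols = 0;
  while (p < ops.size()) {
    size_t q2 = p;
    while (q2 < ops.size() && ops[q2] == ops[p]) q2++;
    cigar += std::to_string(q2 - p);
    cigar.push_back(ops[p]);
    if (ops[p] == 'M' || ops[p] == 'I' || ops[p] == 'D')
      n_aligned_cols += (int)(q2 - p);
    p = q2;
  }
  std::reverse(jst.begin(), jst.end());
  std::reverse(jen.begin(), jen.end());
  IntegerMatrix junc(jst.size(), 2);
  for (size_t k = 0; k < jst.size(); k++) { junc(k, 0) = jst[k]; junc(k, 1) = jen[k]; }
  return List::create(_["score"] = score, _["cigar"] = cigar,
                      _["junctions"] = junc, _["n_match"] = n_match,
                      _["n_aligned_cols"] = n_aligned_cols);
}

// Exhaustive run-decomposition oracle: enumerates alignments as sequences of
// runs (diagonal step, deletion run, insertion run, intron run >= min length)
// with per-run costs, memoized on (i, j). Independent of the H/E/F/Etilde
// recurrence above.
static double oracle_rec(int i, int j, int n, int m,
                         const std::string &ref, const std::string &query,
                         double match, double mismatch, double gap_open,
                         double gap_ext, double intron_open,
                         const NumericVector &dcost, const NumericVector &acost,
                         int min_intron,
                         std::vector<double> &memo, std::vector<char> &seen) {
  const int c = i * (m + 1) + j;
  if (seen[c]) return memo[c];
  double best = NEG;
  if (i == n && j == m) best = 0.0;
  if (i < n && j < m) {
    const char a = ref[i], b = query[j];
    const double sub = (a == b && a != 'N') ? match : mismatch;
    const double v = sub + oracle_rec(i + 1, j + 1, n, m, ref, query, match,
                                      mismatch, gap_open, gap_ext, intron_open,
                                      dcost, acost, min_intron, memo, seen);
    if (v > best) best = v;
  }
  for (int l = 1; i + l <= n; l++) {
    const double v = -(gap_open + gap_ext * l) +
      oracle_rec(i + l, j, n, m, ref, query, match, mismatch, gap_open,
                 gap_ext, intron_open, dcost, acost, min_intron, memo, seen);
    if (v > best) best = v;
  }
  for (int l = 1; j + l <= m; l++) {
    const double v = -(gap_open + gap_ext * l) +
      oracle_rec(i, j + l, n, m, ref, query, match, mismatch, gap_open,
                 gap_ext, intron_open, dcost, acost, min_intron, memo, seen);
    if (v > best) best = v;
  }
  for (int l = min_intron; i + l <= n; l++) {
    const double v = -(intron_open + dcost[i] + acost[i + l]) +
      oracle_rec(i + l, j, n, m, ref, query, match, mismatch, gap_open,
                 gap_ext, intron_open, dcost, acost, min_intron, memo, seen);
    if (v > best) best = v;
  }
  seen[c] = 1;
  memo[c] = best;
  return best;
}

// [[Rcpp::export]]
double dp_oracle_cpp(std::string ref, std::string query,
                     double match, double mismatch,
                     double gap_open, double gap_ext, double intron_open,
                     NumericVector dcost, NumericVector acost, int min_intron) {
  const int n = (int) ref.size(), m = (int) query.size();
  if ((int) dcost.size() != n + 1 || (int) acost.size() != n + 1)
    stop("dcost/acost must have length nchar(ref) + 1");
  std::vector<double> memo((n + 1) * (m + 1), NEG);
  std::vector<char> seen((n + 1) * (m + 1), 0);
  return oracle_rec(0, 0, n, m, ref, query, match, mismatch, gap_open,
                    gap_ext, intron_open, dcost, acost, min_intron, memo, seen);
}
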