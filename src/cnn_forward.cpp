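#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Inference-only forward pass of the two-layer 1D-CNN. Mirrors the R
// training-path implementation exactly (same layer order, ReLU, pair-wise
// max-pooling with ties to the first element, dense softmax head); the test
// suite asserts numerical agreement between the two paths.
// x: one-hot windows, a C x W x B array flattened column-major.
// [[Rcpp::export]]
List cnn_forward_infer_cpp(NumericVector x, int C, int W, int B,
                           NumericMatrix W1, NumericVector b1, int k1,
                           NumericMatrix W2, NumericVector b2, int k2,
                           NumericMatrix Wh, NumericVector bh, int nhidden,
                           NumericMatrix Wd, NumericVector bd,
                           bool want_embed) {
  const int F1 = W1.nrow(), F2 = W2.nrow();
  const int L1 = W - k1 + 1, L1p = L1 / 2;
  const int L2 = L1p - k2 + 1, L2p = L2 / 2;
  const int flat = F2 * L2p;
  const int ncls = Wd.nrow();
  NumericVector prob(B);
  NumericMatrix embed(want_embed ? B : 1, want_embed ? flat : 1);

  // contiguous copies of the weights (NumericMatrix is column-major:
  // column t of W1/W2 holds all F output features for im2col row t)
  const std::vector<double> W1d(W1.begin(), W1.end());
  const std::vector<double> W2d(W2.begin(), W2.end());
  std::vector<double> r1(F1 * L1), p1(F1 * L1p), r2(F2 * L2), p2(flat);
  std::vector<double> acc(std::max(F1, F2));
  std::vector<double> logits(ncls);
  for (int b = 0; b < B; b++) {
    const double *xb = &x[(size_t) b * C * W];
    // conv1 + ReLU; the one-hot input is sparse, so only nonzero entries
    // contribute and their value is 1
    for (int p = 0; p < L1; p++) {
      const double *xc = xb + (size_t) p * C;
      for (int f = 0; f < F1; f++) acc[f] = b1[f];
      for (int t = 0; t < C * k1; t++) {
        const double xv = xc[t];
        if (xv != 0.0) {
          const double *wcol = &W1d[(size_t) t * F1];
          for (int f = 0; f < F1; f++) acc[f] += wcol[f] * xv;
        }
      }
      for (int f = 0; f < F1; f++)
        r1[(size_t) p * F1 + f] = acc[f] > 0 ? acc[f] : 0;
    }
    for (int p = 0; p < L1p; p++)
      for (int f = 0; f < F1; f++) {
        const double a = r1[(size_t)(2 * p) * F1 + f];
        const double c = r1[(size_t)(2 * p + 1) * F1 + f];
        p1[(size_t) p * F1 + f] = a >= c ? a : c;
      }
    for (int p = 0; p < L2; p++) {
      const double *pc = &p1[(size_t) p * F1];
      for (int f = 0; f < F2; f++) acc[f] = b2[f];
      for (int t = 0; t < F1 * k2; t++) {
        const double xv = pc[t];
        if (xv != 0.0) {
          const double *wcol = &W2d[(size_t) t * F2];
          for (int f = 0; f < F2; f++) acc[f] += wcol[f] * xv;
        }
      }
      for (int f = 0; f < F2; f++)
        r2[(size_t) p * F2 + f] = acc[f] > 0 ? acc[f] : 0;
    }
    for (int p = 0; p < L2p; p++)
      for (int f = 0; f < F2; f++) {
        const double a = r2[(size_t)(2 * p) * F2 + f];
        const double c = r2[(size_t)(2 * p + 1) * F2 + f];
        p2[(size_t) p * F2 + f] = a >= c ? a : c;
      }
    if (want_embed)
      for (int t = 0; t < flat; t++) embed(b, t) = p2[t];
    const double *head = &p2[0];
    std::vector<double> hid(nhidden > 0 ? nhidden : 1);
    if (nhidden > 0) {
      for (int h = 0; h < nhidden; h++) {
        double acc = bh[h];
        for (int t = 0; t < flat; t++) acc += Wh(h, t) * p2[t];
        hid[h] = acc > 0 ? acc : 0;
      }
      head = &hid[0];
    }
    const int head_len = nhidden > 0 ? nhidden : flat;
    double zmax = -1e300;
    for (int cl = 0; cl < ncls; cl++) {
      double acc = bd[cl];
      for (int t = 0; t < head_len; t++) acc += Wd(cl, t) * head[t];
      logits[cl] = acc;
      if (acc > zmax) zmax = acc;
    }
    double denom = 0;
    for (int cl = 0; cl < ncls; cl++) denom += std::exp(logits[cl] - zmax);
    prob[b] = std::exp(logits[1] - zmax) / denom;
  }
  if (want_embed) return List::create(_["prob"] = prob, _["embed"] = embed);
  return List::create(_["prob"] = prob);
}
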