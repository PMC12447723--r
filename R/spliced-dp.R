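#' Parameters of the spliced-alignment dynamic program
#'
#' The recurrence scores a global alignment of a query (mRNA-like) sequence
#' against a reference span with four states: match/mismatch, affine
#' deletion, affine insertion, and an intron state that lets the reference
#' advance at no per-base cost between a donor and an acceptor boundary.
#' Opening an intron at reference offset i costs `d(i) + intron_open` and
#' closing it at offset i' costs `a(i')`, where d and a are *costs*: the
#' calibrated splice scores are log-odds in which higher is better, so
#' `d(i) = -s_donor(i)` and `a(i) = -s_acceptor(i)` (a well-supported
#' junction is a bonus), and boundaries without a score cost
#' `noncanonical_cost` each.
#'
#' @param match,mismatch Substitution scores (defaults +2 / -4).
#' @param gap_open,gap_ext Affine gap penalties q and e (cost of a length-l
#'   gap is q + e*l).
#' @param intron_open Intron-open penalty q-tilde. The default (30) exceeds
#'   the largest donor+acceptor bonus a calibrated score file can deliver
#'   (about 2 * 2*log2((P+N)/P)), so well-scored decoy boundaries inside a
#'   real intron can never make splitting it into two introns profitable.
#' @param noncanonical_cost Donor/acceptor cost D_max at boundaries with no
#'   splice score.
#' @param min_intron Minimum intron length (default 4 = GT + AG).
#' @param max_intron Optional maximum intron length (default unlimited).
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -4, gap_open = 4, gap_ext = 2,
                         intron_open = 30, noncanonical_cost = 30,
                         min_intron = 4L, max_intron = Inf) {
  stopifnot(gap_open >= 0, gap_ext >= 0, intron_open >= 0,
            noncanonical_cost >= 0, min_intron >= 1L)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, intron_open = intron_open,
                 noncanonical_cost = noncanonical_cost,
                 min_intron = as.integer(min_intron), max_intron = max_intron),
            class = "align_params")
}

#' Donor/acceptor cost vectors for a reference span
#'
#' Converts splice-score records into the per-offset cost vectors consumed
#' by [align_spliced()]. Offsets are local to the span (`0 .. nchar(span)`);
#' positions without a record cost `params$noncanonical_cost`. For a
#' minus-strand span (aligning against the reverse complement of the
#' forward locus), genomic offsets map to `(start + len) - offset` and the
#' minus-strand records are used.
#'
#' @param scores A `splice_scores` tibble.
#' @param chrom Chromosome of the span.
#' @param start 0-based forward start of the span.
#' @param len Span length.
#' @param strand `"+"` to align against the forward span, `"-"` against its
#'   reverse complement.
#' @param params An [align_params()].
#' @return List with numeric `dcost` and `acost`, each of length `len + 1`.
#' @export
locus_costs <- function(scores, chrom, start, len, strand = "+",
                        params = align_params()) {
  dcost <- rep(params$noncanonical_cost, len + 1L)
  acost <- rep(params$noncanonical_cost, len + 1L)
  sel <- scores[scores$chrom == chrom & scores$strand == strand &
                  scores$offset >= start & scores$offset <= start + len, ,
                drop = FALSE]
  loc <- if (strand == "+") sel$offset - start else (start + len) - sel$offset
  ok <- loc >= 0L & loc <= len
  isD <- sel$site_type == "D" & ok
  isA <- sel$site_type == "A" & ok
  dcost[loc[isD] + 1L] <- -sel$score[isD]
  acost[loc[isA] + 1L] <- -sel$score[isA]
  list(dcost = dcost, acost = acost)
}

#' Uniform GT..AG-only cost vectors for a reference span
#'
#' Baseline splice model: every GT (donor) and AG (acceptor) on the span's
#' forward reading gets cost 0, everything else `noncanonical_cost`. This is
#' the minimal canonical-dinucleotide model with no learned signal.
#'
#' @param span Character scalar: the (already oriented) reference span.
#' @param params An [align_params()].
#' @return List with `dcost` and `acost` of length `nchar(span) + 1`.
#' @export
gtag_costs <- function(span, params = align_params()) {
  len <- nchar(span)
  dcost <- rep(params$noncanonical_cost, len + 1L)
  acost <- rep(params$noncanonical_cost, len + 1L)
  dcost[find_dinuc(span, "GT") + 1L] <- 0
  acost[find_dinuc(span, "AG") + 2L + 1L] <- 0
  list(dcost = dcost, acost = acost)
}

#' Spliced global alignment of a query against a reference span
#'
#' Fills the four-state recurrence (match, affine deletion, affine
#' insertion, intron) and returns one optimal global alignment under the
#' documented tie-breaking (match > intron > deletion > insertion, then
#' leftmost intron starts).
#'
#' @param ref Reference span (character scalar, plus-sense).
#' @param query Query sequence (character scalar).
#' @param params An [align_params()].
#' @param costs Optional list with `dcost`/`acost` from [locus_costs()] or
#'   [gtag_costs()]; defaults to no scored boundaries (every junction costs
#'   `2 * noncanonical_cost + intron_open`).
#' @return A list of class `spliced_alignment`: `score`, `cigar` (ops M, I,
#'   D, N), `junctions` (tibble of local 0-based half-open intron
#'   intervals), `identity` (matches / aligned M+I+D columns), `n_match`.
#' @export
align_spliced <- function(ref, query, params = align_params(), costs = NULL) {
  stopifnot(nchar(ref) > 0L, nchar(query) > 0L)
  if (is.null(costs)) {
    costs <- list(dcost = rep(params$noncanonical_cost, nchar(ref) + 1L),
                  acost = rep(params$noncanonical_cost, nchar(ref) + 1L))
  }
  res <- dp_align_cpp(ref, query, params$match, params$mismatch,
                      params$gap_open, params$gap_ext, params$intron_open,
                      costs$dcost, costs$acost, params$min_intron,
                      params$max_intron)
  junc <- res$junctions
  structure(list(
    score = res$score,
    cigar = res$cigar,
    junctions = tibble(start = as.integer(junc[, 1]), end = as.integer(junc[, 2])),
    n_match = res$n_match,
    identity = if (res$n_aligned_cols > 0) res$n_match / res$n_aligned_cols else NA_real_,
    ref_length = nchar(ref), query_length = nchar(query),
    params = params
  ), class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat("Spliced alignment: score", x$score, "\n")
  cat("  cigar:", x$cigar, "\n")
  cat(sprintf("  identity: %.3f, junctions: %d\n", x$identity, nrow(x$junctions)))
  invisible(x)
}

#' Exhaustive-enumeration alignment oracle
#'
#' Enumerates alignments as run decompositions (diagonal steps, deletion
#' runs, insertion runs, intron runs of at least the minimum length) and
#' returns the maximum score. Intended for verifying [align_spliced()] on
#' tiny instances only.
#'
#' @inheritParams align_spliced
#' @return The optimal score (numeric scalar).
#' @export
oracle_align <- function(ref, query, params = align_params(), costs = NULL) {
  if (nchar(ref) > 12L || nchar(query) > 8L) {
    abort("oracle_align enumerates exhaustively: nchar(ref) <= 12 and nchar(query) <= 8 required")
  }
  if (is.null(costs)) {
    costs <- list(dcost = rep(params$noncanonical_cost, nchar(ref) + 1L),
                  acost = rep(params$noncanonical_cost, nchar(ref) + 1L))
  }
  dp_oracle_cpp(ref, query, params$match, params$mismatch, params$gap_open,
                params$gap_ext, params$intron_open, costs$dcost, costs$acost,
                params$min_intron)
}

#' Which junction placement does the aligner choose?
#'
#' Demonstrates consensus preference: when a reference offers several
#' residue-equivalent placements of the same intron, the alignment picks the
#' one whose donor + acceptor splice scores total highest (ties broken by
#' the leftmost intron start).
#'
#' @inheritParams align_spliced
#' @return The `junctions` tibble of the optimal alignment.
#' @export
consensus_preference_demo <- function(ref, query, params = align_params(),
                                      costs = NULL) {
  align_spliced(ref, query, params = params, costs = costs)$junctions
}
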