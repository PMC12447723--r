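#' Build the empirical log-odds calibration table
#'
#' Raw model scores t in \[0, 1\] are divided evenly into `b` bins
#' (`i = floor(t*b)`, with t = 1 clipped into the top bin). For each bin the
#' table counts annotated sites (P_i) and unannotated GT/AG (N_i); the
#' empirical probability of a bin-i candidate being real is P_i/(P_i+N_i).
#' The calibrated score is the log odds of that probability against the null
#' model in which every GT/AG is equally likely to be real:
#'
#'   s(t) = 2*log2( P_i/(P_i+N_i) * (P+N)/P )
#'
#' The 2*log2 scale keeps the scores interoperable with BLOSUM-scaled
#' aligner scoring. Degenerate bins are handled as follows: an empty bin
#' borrows the counts of the nearest non-empty bin (ties to the lower bin),
#' and a bin with P_i = 0 (empirical probability zero, log odds negative
#' infinity) maps to `floor_score`. A bin with N_i = 0 needs no special
#' rule: the formula is finite there, topping out at 2*log2((P+N)/P).
#'
#' @param t Raw scores in \[0, 1\].
#' @param is_annotated Logical; whether each scored site is annotated.
#' @param b Number of bins (default 50).
#' @param floor_score,cap_score Integer clamp bounds for quantized scores.
#' @return A list of class `calibration_table` with a per-bin tibble `bins`
#'   (`bin`, `P_i`, `N_i`, `s`), totals `P`, `N`, and the clamp bounds.
#' @export
build_calibration <- function(t, is_annotated, b = 50L,
                              floor_score = -64L, cap_score = 64L) {
  if (length(t) == 0L) abort("cannot build a calibration table from empty input")
  stopifnot(length(t) == length(is_annotated), all(t >= 0 & t <= 1))
  bin <- pmin(floor(t * b), b - 1L)
  P_i <- tabulate(bin[is_annotated] + 1L, nbins = b)
  N_i <- tabulate(bin[!is_annotated] + 1L, nbins = b)
  P <- sum(P_i); N <- sum(N_i)
  if (P == 0L) abort("no annotated sites in calibration input")
  eP <- P_i; eN <- N_i
  nonempty <- which(P_i + N_i > 0L)
  for (i in seq_len(b)) {
    if (P_i[i] + N_i[i] == 0L) {
      j <- nonempty[which.min(abs(nonempty - i))]  # which.min ties -> lower bin
      eP[i] <- P_i[j]; eN[i] <- N_i[j]
    }
  }
  s <- ifelse(eP == 0L, floor_score,
              2 * log2(eP / (eP + eN) * (P + N) / P))
  structure(list(
    bins = tibble(bin = seq_len(b) - 1L, P_i = P_i, N_i = N_i, s = as.numeric(s)),
    b = as.integer(b), P = P, N = N,
    floor_score = as.integer(floor_score), cap_score = as.integer(cap_score)
  ), class = "calibration_table")
}

#' Transform raw scores through a calibration table
#'
#' @param table A [build_calibration()] table.
#' @param t Raw scores in \[0, 1\].
#' @return Numeric calibrated scores (real-valued 2*log2 odds, not yet
#'   clamped except through degenerate-bin handling).
#' @export
calibrate_score <- function(table, t) {
  stopifnot(inherits(table, "calibration_table"), all(t >= 0 & t <= 1))
  bin <- pmin(floor(t * table$b), table$b - 1L)
  table$bins$s[bin + 1L]
}

#' Quantize a calibrated score to an integer
#'
#' Rounds half away from zero and clamps to the table's bounds, producing
#' the integer score written to the splice-score file.
#'
#' @param s Real-valued calibrated scores.
#' @param floor_score,cap_score Clamp bounds (default \[-64, 64\]).
#' @return Integer vector.
#' @export
quantize_score <- function(s, floor_score = -64L, cap_score = 64L) {
  q <- sign(s) * floor(abs(s) + 0.5)
  as.integer(pmax(floor_score, pmin(cap_score, q)))
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("Splice-score calibration table:", x$b, "bins,",
      x$P, "annotated /", x$N, "unannotated sites\n")
  print(x$bins, ...)
  invisible(x)
}

#' Calibrate a trained model against held-out chromosomes
#'
#' Scores every GT/AG on the genome's even-index (held-out) chromosomes with
#' the raw model, labels each candidate by the annotation, and builds the
#' calibration table from those counts.
#'
#' @param fit A `cnn_fit` or `cnn_model`.
#' @param genome Genome tibble.
#' @param genes Gene-model tibble (the annotation providing labels).
#' @param flank Window flank matching the model input.
#' @param b Number of bins.
#' @param floor_score,cap_score Clamp bounds.
#' @return A `calibration_table`.
#' @export
calibrate_on_heldout <- function(fit, genome, genes, flank = 100L, b = 50L,
                                 floor_score = -64L, cap_score = 64L) {
  even <- genome[genome$index_in_file %% 2L == 0L, , drop = FALSE]
  if (nrow(even) == 0L) abort("genome has no even-index chromosomes to calibrate on")
  cands <- enumerate_candidates(even)
  t <- score_candidates(fit, even, cands, flank = flank)
  ann <- extract_annotated_sites(genes[genes$chrom %in% even$name, , drop = FALSE],
                                 even)
  key <- paste(ann$chrom, ann$pos, ann$strand, ann$site_type)
  lab <- paste(cands$chrom, cands$offset, cands$strand, cands$site_type) %in% key
  build_calibration(t, lab, b = b, floor_score = floor_score,
                    cap_score = cap_score)
}
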