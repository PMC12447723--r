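#' ROC curve of splice-site scores
#'
#' Standard receiver operating characteristic over all score thresholds:
#' true positive rate against false positive rate, both nondecreasing along
#' the curve, starting at (0, 0) and ending at (1, 1).
#'
#' @param scores Numeric scores (higher = more site-like).
#' @param labels Logical or 0/1; TRUE/1 = positive (annotated site).
#' @return Tibble of class `splice_roc` with `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (all(labels) || !any(labels)) {
    abort("ROC needs both classes present")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  P <- sum(l); N <- sum(!l)
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct threshold
  out <- tibble(
    fpr = c(0, fp[last] / N),
    tpr = c(0, tp[last] / P),
    threshold = c(Inf, s[last])
  )
  class(out) <- c("splice_roc", class(out))
  out
}

#' Restricted, rescaled area under the ROC curve (rAUC)
#'
#' Area of the region under the ROC curve intersected with the rectangle
#' FPR in \[0, `max_fpr`\] and TPR in \[`min_tpr`, 1\], divided by the
#' rectangle's area `max_fpr * (1 - min_tpr)`, so rAUC is always in
#' \[0, 1\]. This focuses the comparison on the regime that matters for
#' spliced alignment: sensitivity above 50% at a false positive rate below
#' 10%. Trapezoidal integration with exact handling of segments crossing
#' the rectangle edges.
#'
#' @param roc A `splice_roc` tibble from [roc_points()].
#' @param min_tpr,max_fpr Rectangle bounds (defaults 0.5 and 0.1).
#' @return Numeric scalar in \[0, 1\].
#' @export
rauc <- function(roc, min_tpr = 0.5, max_fpr = 0.1) {
  x <- roc$fpr; y <- roc$tpr
  stopifnot(length(x) >= 2L, !is.unsorted(x), !is.unsorted(y))
  area <- 0
  for (k in seq_len(length(x) - 1L)) {
    x0 <- x[k]; x1 <- x[k + 1L]; y0 <- y[k]; y1 <- y[k + 1L]
    # clip segment to the fpr window
    if (x1 <= 0 || x0 >= max_fpr) next
    if (x1 > x0) {
      t0 <- max(x0, 0); t1 <- min(x1, max_fpr)
      yy0 <- y0 + (y1 - y0) * (t0 - x0) / (x1 - x0)
      yy1 <- y0 + (y1 - y0) * (t1 - x0) / (x1 - x0)
      area <- area + clipped_trapezoid(t0, t1, yy0, yy1, min_tpr)
    }
  }
  area / (max_fpr * (1 - min_tpr))
}

# Area between min_tpr and the segment (t0,y0)-(t1,y1), clipped below at
# min_tpr and above at 1, over [t0, t1].
clipped_trapezoid <- function(t0, t1, y0, y1, min_tpr) {
  f <- function(y) max(0, min(y, 1) - min_tpr)
  # integrate piecewise-linearly; split at crossings of min_tpr and 1
  ts <- c(t0, t1)
  if (y1 != y0) {
    for (lev in c(min_tpr, 1)) {
      tc <- t0 + (lev - y0) * (t1 - t0) / (y1 - y0)
      if (tc > t0 && tc < t1) ts <- c(ts, tc)
    }
  }
  ts <- sort(unique(ts))
  yat <- function(t) if (t1 == t0) y0 else y0 + (y1 - y0) * (t - t0) / (t1 - t0)
  a <- 0
  for (k in seq_len(length(ts) - 1L)) {
    a <- a + (ts[k + 1L] - ts[k]) * (f(yat(ts[k])) + f(yat(ts[k + 1L]))) / 2
  }
  a
}

#' Junction accuracy against an annotation
#'
#' Compares predicted intron junctions with annotated ones under exact
#' boundary-and-strand matching and reports the percentage of predicted
#' junctions that are unannotated (the junction error proxy
#' `%unannotated = 100 * (1 - hits/predicted)`). Junctions are counted per
#' alignment; deduplicated counts are reported alongside.
#'
#' @param predicted Tibble of junctions: `chrom`, `start`, `end` (0-based
#'   half-open intron interval), `strand`.
#' @param annotated Tibble of annotated junctions, same columns.
#' @return One-row tibble: `n_predicted`, `n_annotated_hits`,
#'   `pct_unannotated` (rounded to 2 decimals; `NA` when nothing was
#'   predicted), plus `n_predicted_distinct`, `pct_unannotated_distinct`.
#' @export
junction_accuracy <- function(predicted, annotated) {
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  ann <- unique(key(annotated))
  n_pred <- nrow(predicted)
  if (n_pred == 0L) {
    return(tibble(n_predicted = 0L, n_annotated_hits = 0L,
                  pct_unannotated = NA_real_, n_predicted_distinct = 0L,
                  pct_unannotated_distinct = NA_real_))
  }
  hit <- key(predicted) %in% ann
  dk <- unique(key(predicted))
  tibble(
    n_predicted = n_pred,
    n_annotated_hits = sum(hit),
    pct_unannotated = pct_unannotated(n_pred, sum(hit)),
    n_predicted_distinct = length(dk),
    pct_unannotated_distinct = pct_unannotated(length(dk), sum(dk %in% ann))
  )
}

#' The junction-error formula, \%unannotated = 100 * (1 - hits/predicted)
#'
#' @param n_predicted Number of predicted junctions.
#' @param n_annotated_hits Number of those that match the annotation exactly.
#' @return Percentage rounded to two decimals; `NA` when `n_predicted` is 0.
#' @export
pct_unannotated <- function(n_predicted, n_annotated_hits) {
  ifelse(n_predicted == 0, NA_real_,
         round(100 * (1 - n_annotated_hits / n_predicted), 2))
}

#' Base-level sensitivity and specificity of aligned intervals
#'
#' Sn = 100 * |pred intersect annot| / |annot|;
#' Sp = 100 * |pred intersect annot| / |pred|, with interval arithmetic per
#' chromosome over 0-based half-open intervals.
#'
#' @param predicted,annotated Tibbles with `chrom`, `start`, `end`.
#' @return One-row tibble with `sensitivity` and `specificity` (percent).
#' @export
base_sn_sp <- function(predicted, annotated) {
  if (nrow(annotated) == 0L) abort("empty annotation")
  to_ir <- function(d, chrom) {
    dd <- d[d$chrom == chrom, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(start = dd$start + 1L, end = dd$end))
  }
  chroms <- union(unique(predicted$chrom), unique(annotated$chrom))
  inter <- 0; n_ann <- 0; n_pred <- 0
  for (ch in chroms) {
    p <- to_ir(predicted, ch); a <- to_ir(annotated, ch)
    inter <- inter + sum(IRanges::width(BiocGenerics::intersect(p, a)))
    n_ann <- n_ann + sum(IRanges::width(a))
    n_pred <- n_pred + sum(IRanges::width(p))
  }
  tibble(
    sensitivity = 100 * inter / n_ann,
    specificity = if (n_pred == 0) NA_real_ else 100 * inter / n_pred
  )
}

#' Stratify alignments by identity and report per-bin junction error
#'
#' @param alignments Tibble with `identity` (in \[0, 1\]), `n_junctions`
#'   and `n_annotated_hits` per alignment.
#' @param bin_width Identity bin width (default 0.02).
#' @return Tibble with one row per occupied bin: `bin_lo`, `bin_hi`,
#'   `n_alignments`, `n_junctions`, `n_annotated_hits`, `pct_unannotated`.
#' @export
identity_binning <- function(alignments, bin_width = 0.02) {
  stopifnot(bin_width > 0)
  alignments %>%
    dplyr::mutate(bin_lo = floor(.data$identity / bin_width) * bin_width) %>%
    dplyr::group_by(.data$bin_lo) %>%
    dplyr::summarise(
      bin_hi = .data$bin_lo[1L] + bin_width,
      n_alignments = dplyr::n(),
      n_junctions = sum(.data$n_junctions),
      n_annotated_hits = sum(.data$n_annotated_hits),
      .groups = "drop"
    ) %>%
    dplyr::mutate(pct_unannotated = pct_unannotated(.data$n_junctions,
                                                    .data$n_annotated_hits)) %>%
    dplyr::arrange(.data$bin_lo)
}

#' Expected number of false splice-site calls genome-wide
#'
#' At a given false positive rate, a genome of size G with a candidate
#' dinucleotide frequency f carries G * f * FPR expected false calls --
#' e.g. 3e9 * 2/16 * 1% = 3.75 million false donors, an order of magnitude
#' more than real donor sites, which is why calibrated scores (not hard
#' calls) feed the aligner.
#'
#' @param genome_size Genome length in bp.
#' @param dinucleotide_freq Frequency of the candidate dinucleotide
#'   (e.g. 2/16 for GT on both strands under a uniform base model).
#' @param fpr False positive rate in \[0, 1\].
#' @return Expected count (numeric scalar).
#' @export
expected_false_sites <- function(genome_size, dinucleotide_freq, fpr) {
  stopifnot(genome_size > 0, dinucleotide_freq > 0, fpr >= 0)
  genome_size * dinucleotide_freq * fpr
}
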