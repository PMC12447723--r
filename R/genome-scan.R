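#' Enumerate every candidate splice site in a genome
#'
#' Lists every GT and AG on both strands: a `+` donor at every forward
#' `GT`, a `+` acceptor at every forward `AG`, a `-` donor at every forward
#' `AC` (GT on the reverse strand) and a `-` acceptor at every forward `CT`.
#' Offsets follow the boundary convention of [write_score_file()].
#'
#' @param genome Genome tibble.
#' @return Tibble (`chrom`, `offset`, `strand`, `site_type`) sorted by
#'   (chrom, offset, strand, site_type).
#' @export
enumerate_candidates <- function(genome) {
  pats <- tibble(
    strand = c("+", "+", "-", "-"),
    site_type = c("D", "A", "D", "A"),
    pat = c("GT", "AG", "AC", "CT")
  )
  out <- purrr::pmap(list(rep(genome$name, each = 4L),
                          rep(genome$seq, each = 4L),
                          rep(pats$strand, nrow(genome)),
                          rep(pats$site_type, nrow(genome)),
                          rep(pats$pat, nrow(genome))),
    function(chrom, seq, strand, ty, pat) {
      p <- find_dinuc(seq, pat)
      if (length(p) == 0L) return(NULL)
      tibble(chrom = chrom, offset = as.integer(site_offset(p, strand, ty)),
             strand = strand, site_type = ty)
    })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), offset = integer(),
                  strand = character(), site_type = character()))
  }
  dplyr::arrange(out, .data$chrom, .data$offset, .data$strand, .data$site_type)
}

# Raw model scores for a candidate tibble; windows running past sequence
# ends are zero-padded so every candidate gets a score.
score_candidates <- function(fit, genome, candidates, flank = 100L,
                             chunk = 2048L) {
  model <- as_cnn_model(fit)
  if (model$config$window != 2L * flank + 2L) {
    abort(paste0("model window (", model$config$window,
                 ") does not match flank ", flank))
  }
  sites <- tibble(chrom = candidates$chrom, pos = candidates$offset,
                  strand = candidates$strand, site_type = candidates$site_type)
  n <- nrow(sites)
  if (n == 0L) return(numeric(0))
  t <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    w <- build_windows(sites[s:e, , drop = FALSE], genome, flank = flank,
                       pad = TRUE)
    t[s:e] <- predict_raw(model, w$x)
  }
  t
}

#' Score every GT/AG in a genome and emit splice-score records
#'
#' The prediction step of the workflow: every candidate from
#' [enumerate_candidates()] is one-hot encoded (zero-padded at sequence
#' ends), scored by the trained model, calibrated to 2*log2 empirical
#' log-odds and quantized to an integer. Two scans of the same genome and
#' model are identical.
#'
#' @param genome Genome tibble.
#' @param fit A `cnn_fit` or `cnn_model`.
#' @param table A `calibration_table`.
#' @param flank Window flank matching the model.
#' @param skip_N Drop candidates whose window contains any N (default keeps
#'   them, scored over zero columns, so aligner lookups never miss a key).
#' @return A `splice_scores` tibble (`chrom`, `offset`, `strand`,
#'   `site_type`, `score`), sorted by (chrom, offset).
#' @export
scan_genome <- function(genome, fit, table, flank = 100L, skip_N = FALSE) {
  cands <- enumerate_candidates(genome)
  if (skip_N && nrow(cands) > 0L) {
    sites <- tibble(chrom = cands$chrom, pos = cands$offset,
                    strand = cands$strand, site_type = cands$site_type)
    keep <- !window_has_N(sites, genome, flank)
    cands <- cands[keep, , drop = FALSE]
  }
  t <- score_candidates(fit, genome, cands, flank = flank)
  records <- cands %>%
    dplyr::mutate(score = quantize_score(calibrate_score(table, t),
                                         table$floor_score, table$cap_score)) %>%
    dplyr::arrange(.data$chrom, .data$offset, .data$strand, .data$site_type)
  class(records) <- c("splice_scores", class(records))
  records
}

# TRUE where a site's window (including out-of-bounds padding) contains N.
window_has_N <- function(sites, genome, flank) {
  seqs <- setNames(genome$seq, genome$name)
  lens <- setNames(nchar(genome$seq), genome$name)
  core_start <- ifelse(
    (sites$strand == "+" & sites$site_type == "D") |
      (sites$strand == "-" & sites$site_type == "A"),
    sites$pos, sites$pos - 2L)
  from <- core_start - flank
  to <- core_start + 2L + flank
  oob <- from < 0L | to > lens[sites$chrom]
  f <- pmax(from, 0L)
  t <- pmin(to, lens[sites$chrom])
  has_n <- grepl("N", substring(seqs[sites$chrom], f + 1L, t), fixed = TRUE)
  unname(has_n | oob)
}
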