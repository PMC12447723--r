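#' Tidy the per-epoch training history of a CNN fit
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_cost`, `validation_cost`.
#' @export
tidy.cnn_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a CNN fit
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs run, best epoch and costs.
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble(
    n_parameters = parameter_count(x$model),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    stopped_epoch = x$stopped_epoch,
    train_cost = x$history$train_cost[x$best_epoch],
    validation_cost = min(x$history$validation_cost)
  )
}

#' Tidy a calibration table
#'
#' @param x A `calibration_table`.
#' @param ... Unused.
#' @return The per-bin tibble (`bin`, `P_i`, `N_i`, `s`).
#' @export
tidy.calibration_table <- function(x, ...) {
  x$bins
}

#' One-row summary of a calibration table
#'
#' @param x A `calibration_table`.
#' @param ... Unused.
#' @return Tibble with bin count, totals and clamp bounds.
#' @export
glance.calibration_table <- function(x, ...) {
  tibble(b = x$b, P = x$P, N = x$N,
         positive_fraction = x$P / (x$P + x$N),
         floor_score = x$floor_score, cap_score = x$cap_score)
}

#' Tidy a spliced alignment into its junctions
#'
#' @param x A `spliced_alignment`.
#' @param ... Unused.
#' @return Tibble of local 0-based half-open intron intervals.
#' @export
tidy.spliced_alignment <- function(x, ...) {
  x$junctions
}

#' One-row summary of a spliced alignment
#'
#' @param x A `spliced_alignment`.
#' @param ... Unused.
#' @return Tibble with score, cigar, identity and junction count.
#' @export
glance.spliced_alignment <- function(x, ...) {
  tibble(score = x$score, cigar = x$cigar, identity = x$identity,
         n_junctions = nrow(x$junctions), n_match = x$n_match,
         ref_length = x$ref_length, query_length = x$query_length)
}
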