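#' Write a model checkpoint
#'
#' Serializes the network configuration, all weight arrays, optional
#' training history and optional calibration table to a single JSON file
#' (text, portable, diffable).
#'
#' @param fit A `cnn_fit` or `cnn_model`.
#' @param path Output path (conventionally `.json`).
#' @param calibration Optional `calibration_table` stored alongside.
#' @return `path`, invisibly.
#' @export
write_cnn_model <- function(fit, path, calibration = NULL) {
  model <- as_cnn_model(fit)
  cfg <- model$config
  obj <- list(
    format = "splicescore-model-1",
    config = list(
      window = cfg$window, in_channels = cfg$in_channels,
      conv_features = cfg$conv_features, kernel_sizes = cfg$kernel_sizes,
      pool_sizes = cfg$pool_sizes, dense_hidden = cfg$dense_hidden,
      n_classes = cfg$n_classes
    ),
    weights = purrr::map(model$weights, function(w) {
      list(dim = if (is.matrix(w)) dim(w) else length(w), data = as.numeric(w))
    })
  )
  if (inherits(fit, "cnn_fit")) {
    obj$history <- as.list(fit$history)
    obj$best_epoch <- fit$best_epoch
  }
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "calibration_table"))
    obj$calibration <- list(
      b = calibration$b, P_i = calibration$bins$P_i,
      N_i = calibration$bins$N_i, s = calibration$bins$s,
      floor_score = calibration$floor_score, cap_score = calibration$cap_score
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path Path written by [write_cnn_model()].
#' @return List with `model` (a `cnn_model`) and `calibration` (a
#'   `calibration_table` or `NULL`).
#' @export
read_cnn_model <- function(path) {
  if (!file.exists(path)) abort(paste0("model file not found: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "splicescore-model-1")) {
    abort(paste0("unrecognized model format in ", path))
  }
  cfg <- cnn_config(window = obj$config$window,
                    in_channels = obj$config$in_channels,
                    conv_features = obj$config$conv_features,
                    kernel_sizes = obj$config$kernel_sizes,
                    pool_sizes = obj$config$pool_sizes,
                    dense_hidden = obj$config$dense_hidden %||% 0L,
                    n_classes = obj$config$n_classes)
  weights <- purrr::imap(obj$weights, function(w, nm) {
    if (length(w$dim) == 2L) matrix(w$data, nrow = w$dim[1L]) else as.numeric(w$data)
  })
  model <- structure(list(config = cfg, weights = weights), class = "cnn_model")
  calib <- NULL
  if (!is.null(obj$calibration)) {
    cc <- obj$calibration
    P <- sum(cc$P_i); N <- sum(cc$N_i)
    calib <- structure(list(
      bins = tibble(bin = seq_len(cc$b) - 1L, P_i = as.integer(cc$P_i),
                    N_i = as.integer(cc$N_i), s = as.numeric(cc$s)),
      b = as.integer(cc$b), P = P, N = N,
      floor_score = as.integer(cc$floor_score),
      cap_score = as.integer(cc$cap_score)
    ), class = "calibration_table")
  }
  list(model = model, calibration = calib)
}
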