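#' Configuration of the two-layer 1D-CNN splice-site classifier
#'
#' The default architecture is conv(16 features, kernel 5) -> ReLU ->
#' maxpool(2) -> conv(16, kernel 5) -> ReLU -> maxpool(2) -> flatten ->
#' dense(8) -> ReLU -> dense(2) -> softmax, over a 4 x W one-hot window with
#' the invariant GT/AG at the center. One joint model handles donors and
#' acceptors: the central dinucleotide tells the two apart, and the small
#' hidden dense layer lets the readout gate donor-style against
#' acceptor-style evidence nonlinearly. For the default 202-bp window this
#' network has 7,674 trainable parameters (see [parameter_count()]).
#'
#' @param window Window length W in bp (default 202 = 2*100 + 2).
#' @param in_channels Input channels (4: one per base).
#' @param conv_features Features of the two convolution layers.
#' @param kernel_sizes Kernel widths of the two convolution layers.
#' @param pool_sizes Max-pooling widths (= strides) after each convolution.
#' @param dense_hidden Width of the hidden dense layer (0 = none, a direct
#'   linear softmax readout).
#' @param n_classes Output classes (2: site vs non-site).
#' @return A list of class `cnn_config` including the derived per-layer
#'   output lengths (`shape`).
#' @export
cnn_config <- function(window = 202L, in_channels = 4L,
                       conv_features = c(16L, 16L), kernel_sizes = c(5L, 5L),
                       pool_sizes = c(2L, 2L), dense_hidden = 8L,
                       n_classes = 2L) {
  stopifnot(window > 0L, in_channels > 0L, all(conv_features > 0L),
            all(kernel_sizes > 0L), all(pool_sizes > 0L), dense_hidden >= 0L,
            n_classes >= 2L)
  L1 <- window - kernel_sizes[1L] + 1L
  L1p <- L1 %/% pool_sizes[1L]
  L2 <- L1p - kernel_sizes[2L] + 1L
  L2p <- L2 %/% pool_sizes[2L]
  if (L1 <= 0L || L1p <= 0L || L2 <= 0L || L2p <= 0L) {
    abort("inconsistent architecture: a layer output length is not positive")
  }
  structure(list(
    window = as.integer(window), in_channels = as.integer(in_channels),
    conv_features = as.integer(conv_features),
    kernel_sizes = as.integer(kernel_sizes),
    pool_sizes = as.integer(pool_sizes),
    dense_hidden = as.integer(dense_hidden), n_classes = as.integer(n_classes),
    shape = c(conv1 = L1, pool1 = L1p, conv2 = L2, pool2 = L2p,
              flat = conv_features[2L] * L2p)
  ), class = "cnn_config")
}

#' Initialize an untrained CNN model
#'
#' Convolution kernels get He-scaled Gaussian initialization; the dense head
#' is zero-initialized, so an untrained model outputs exactly 0.5 for every
#' window (softmax of equal logits).
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for the kernel initialization.
#' @return A list of class `cnn_model` with `config` and `weights`.
#' @export
cnn_init <- function(config = cnn_config(), seed = 1L) {
  set.seed(derive_seed(seed, "init"))
  C <- config$in_channels
  k <- config$kernel_sizes
  Fm <- config$conv_features
  fan1 <- C * k[1L]
  fan2 <- Fm[1L] * k[2L]
  weights <- list(
    W1 = matrix(rnorm(Fm[1L] * fan1, sd = sqrt(2 / fan1)), nrow = Fm[1L]),
    b1 = numeric(Fm[1L]),
    W2 = matrix(rnorm(Fm[2L] * fan2, sd = sqrt(2 / fan2)), nrow = Fm[2L]),
    b2 = numeric(Fm[2L])
  )
  nh <- config$dense_hidden
  flat <- config$shape[["flat"]]
  if (nh > 0L) {
    weights$Wh <- matrix(rnorm(nh * flat, sd = sqrt(2 / flat)), nrow = nh)
    weights$bh <- numeric(nh)
    weights$Wd <- matrix(0, nrow = config$n_classes, ncol = nh)
  } else {
    weights$Wd <- matrix(0, nrow = config$n_classes, ncol = flat)
  }
  weights$bd <- numeric(config$n_classes)
  structure(list(config = config, weights = weights), class = "cnn_model")
}

#' Count trainable parameters
#'
#' Sum of `out*in*k + out` over convolution layers plus `in*out + out` for
#' the dense head.
#'
#' @param x A `cnn_model` or `cnn_config`.
#' @return Integer count of trainable scalars.
#' @export
parameter_count <- function(x) {
  cfg <- if (inherits(x, "cnn_model")) x$config else x
  stopifnot(inherits(cfg, "cnn_config"))
  C <- cfg$in_channels
  Fm <- cfg$conv_features
  k <- cfg$kernel_sizes
  conv <- Fm[1L] * C * k[1L] + Fm[1L] + Fm[2L] * Fm[1L] * k[2L] + Fm[2L]
  flat <- cfg$shape[["flat"]]
  dense <- if (cfg$dense_hidden > 0L) {
    flat * cfg$dense_hidden + cfg$dense_hidden +
      cfg$dense_hidden * cfg$n_classes + cfg$n_classes
  } else {
    flat * cfg$n_classes + cfg$n_classes
  }
  as.integer(conv + dense)
}

# Gather-index matrix for im2col over a (C x L) input with kernel k:
# entry (r, p) is the column-major flat index of channel c = (r-1) %% C + 1
# at position p + (r-1) %/% C.
im2col_index <- function(C, L, k) {
  Lout <- L - k + 1L
  r <- seq_len(C * k)
  c_of_r <- (r - 1L) %% C + 1L
  dk <- (r - 1L) %/% C
  I <- outer(r, seq_len(Lout), function(rr, pp) {
    (pp + ((rr - 1L) %/% C) - 1L) * C + ((rr - 1L) %% C + 1L)
  })
  storage.mode(I) <- "integer"
  I
}

# Sparse scatter matrix: maps im2col-space gradients back to input space.
scatter_matrix <- function(I, C, L) {
  Matrix::sparseMatrix(i = as.vector(I), j = seq_along(I), x = 1,
                       dims = c(C * L, length(I)))
}

# Cached layer geometry (index + scatter matrices) keyed by config shape.
layer_plan <- function(config) {
  key <- paste(config$window, config$in_channels,
               paste(config$conv_features, collapse = ","),
               paste(config$kernel_sizes, collapse = ","), sep = "|")
  if (is.null(.plan_cache[[key]])) {
    C <- config$in_channels
    W <- config$window
    k <- config$kernel_sizes
    Fm <- config$conv_features
    L1p <- config$shape[["pool1"]]
    I1 <- im2col_index(C, W, k[1L])
    I2 <- im2col_index(Fm[1L], L1p, k[2L])
    .plan_cache[[key]] <- list(
      I1 = I1, I2 = I2,
      S1 = scatter_matrix(I1, C, W),
      S2 = scatter_matrix(I2, Fm[1L], L1p)
    )
  }
  .plan_cache[[key]]
}
.plan_cache <- new.env(parent = emptyenv())

# im2col gather for a batch array (C x L x B) -> matrix (C*k x Lout*B),
# columns in batch-major blocks. Batch-expanded index vectors are cached.
gather_batch <- function(x, I, C, L) {
  B <- dim(x)[3L]
  key <- paste(C, L, nrow(I), ncol(I), B, sep = "_")
  idx <- .gather_cache[[key]]
  if (is.null(idx)) {
    idx <- rep.int(as.vector(I), B) +
      rep(as.integer(C * L) * (seq_len(B) - 1L), each = length(I))
    storage.mode(idx) <- "integer"
    .gather_cache[[key]] <- idx
  }
  matrix(x[idx], nrow = nrow(I))
}
.gather_cache <- new.env(parent = emptyenv())

# Max-pool pairs of a (F x L x B) array; returns pooled array, the argmax
# mask (TRUE = first of the pair, ties to the first), and the pooled length.
pool2_forward <- function(a) {
  L <- dim(a)[2L]
  Lp <- L %/% 2L
  a1 <- a[, seq(1L, 2L * Lp, by = 2L), , drop = FALSE]
  a2 <- a[, seq(2L, 2L * Lp, by = 2L), , drop = FALSE]
  mask <- a1 >= a2
  list(p = a1 * mask + a2 * !mask, mask = mask, Lp = Lp)
}

# Full forward pass with caches for backprop. x: (4 x W x B) array.
cnn_forward_full <- function(model, x) {
  cfg <- model$config
  wt <- model$weights
  plan <- layer_plan(cfg)
  B <- dim(x)[3L]
  Fm <- cfg$conv_features
  M1 <- gather_batch(x, plan$I1, cfg$in_channels, cfg$window)
  Z1 <- wt$W1 %*% M1 + wt$b1
  R1 <- array(Z1 * (Z1 > 0), dim = c(Fm[1L], cfg$shape[["conv1"]], B))
  pl1 <- pool2_forward(R1)
  M2 <- gather_batch(pl1$p, plan$I2, Fm[1L], cfg$shape[["pool1"]])
  Z2 <- wt$W2 %*% M2 + wt$b2
  R2 <- array(Z2 * (Z2 > 0), dim = c(Fm[2L], cfg$shape[["conv2"]], B))
  pl2 <- pool2_forward(R2)
  Hf <- matrix(pl2$p, nrow = cfg$shape[["flat"]])
  if (cfg$dense_hidden > 0L) {
    Zh <- wt$Wh %*% Hf + wt$bh
    Rh <- Zh * (Zh > 0)
    Z <- wt$Wd %*% Rh + wt$bd
  } else {
    Zh <- NULL; Rh <- NULL
    Z <- wt$Wd %*% Hf + wt$bd
  }
  Zs <- sweep(Z, 2L, apply(Z, 2L, max))
  ez <- exp(Zs)
  probs <- sweep(ez, 2L, colSums(ez), "/")
  list(M1 = M1, Z1 = Z1, pl1 = pl1, M2 = M2, Z2 = Z2, pl2 = pl2,
       Hf = Hf, Zh = Zh, Rh = Rh, probs = probs, B = B)
}

#' Raw splice score of one-hot windows
#'
#' Runs the network forward and returns the softmax probability of the
#' "site" class, a raw score t in \[0, 1\] (higher means more splice-like).
#'
#' @param model A `cnn_model` (or `cnn_fit`).
#' @param x A single 4 x W matrix or a 4 x W x n array.
#' @param chunk Internal batching size.
#' @return Numeric vector of length n.
#' @export
predict_raw <- function(model, x, chunk = 1024L) {
  model <- as_cnn_model(model)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[1L] != model$config$in_channels || dim(x)[2L] != model$config$window) {
    abort(paste0("window shape ", dim(x)[1L], "x", dim(x)[2L],
                 " does not match model input ", model$config$in_channels,
                 "x", model$config$window))
  }
  cnn_infer(model, x)$prob
}

# Compiled inference path (numerically identical to the R training path).
cnn_infer <- function(model, x, want_embed = FALSE) {
  cfg <- model$config
  wt <- model$weights
  nh <- cfg$dense_hidden
  Wh <- if (nh > 0L) wt$Wh else matrix(0, 0L, 0L)
  bh <- if (nh > 0L) wt$bh else numeric(0)
  cnn_forward_infer_cpp(as.numeric(x), cfg$in_channels, cfg$window,
                        dim(x)[3L], wt$W1, wt$b1, cfg$kernel_sizes[1L],
                        wt$W2, wt$b2, cfg$kernel_sizes[2L], Wh, bh, nh,
                        wt$Wd, wt$bd, want_embed)
}

as_cnn_model <- function(x) {
  if (inherits(x, "cnn_fit")) x$model else {
    stopifnot(inherits(x, "cnn_model"))
    x
  }
}

# Cross-entropy loss and parameter gradients for a labeled batch.
# y: 0/1 vector (1 = site). Returns list(loss, grads).
cnn_loss_grads <- function(model, x, y) {
  cfg <- model$config
  wt <- model$weights
  plan <- layer_plan(cfg)
  fw <- cnn_forward_full(model, x)
  B <- fw$B
  Fm <- cfg$conv_features
  Y <- rbind(1 - y, y)
  loss <- -mean(log(pmax(fw$probs[cbind(y + 1L, seq_len(B))], 1e-12)))
  dZ <- (fw$probs - Y) / B
  if (cfg$dense_hidden > 0L) {
    gWd <- dZ %*% t(fw$Rh)
    gbd <- rowSums(dZ)
    dZh <- (t(wt$Wd) %*% dZ) * (fw$Zh > 0)
    gWh <- dZh %*% t(fw$Hf)
    gbh <- rowSums(dZh)
    dHf <- t(wt$Wh) %*% dZh
  } else {
    gWd <- dZ %*% t(fw$Hf)
    gbd <- rowSums(dZ)
    gWh <- NULL; gbh <- NULL
    dHf <- t(wt$Wd) %*% dZ
  }
  dH <- array(dHf, dim = c(Fm[2L], cfg$shape[["pool2"]], B))
  dR2 <- array(0, dim = c(Fm[2L], cfg$shape[["conv2"]], B))
  Lp2 <- cfg$shape[["pool2"]]
  dR2[, seq(1L, 2L * Lp2, by = 2L), ] <- dH * fw$pl2$mask
  dR2[, seq(2L, 2L * Lp2, by = 2L), ] <- dH * !fw$pl2$mask
  dZ2 <- matrix(dR2, nrow = Fm[2L]) * (fw$Z2 > 0)
  gW2 <- dZ2 %*% t(fw$M2)
  gb2 <- rowSums(dZ2)
  dM2 <- t(wt$W2) %*% dZ2
  ncol2 <- nrow(plan$I2) * ncol(plan$I2)
  dP1 <- array(as.matrix(plan$S2 %*% matrix(array(dM2,
           dim = c(nrow(plan$I2), ncol(plan$I2), B)), nrow = ncol2)),
         dim = c(Fm[1L], cfg$shape[["pool1"]], B))
  dR1 <- array(0, dim = c(Fm[1L], cfg$shape[["conv1"]], B))
  Lp1 <- cfg$shape[["pool1"]]
  dR1[, seq(1L, 2L * Lp1, by = 2L), ] <- dP1 * fw$pl1$mask
  dR1[, seq(2L, 2L * Lp1, by = 2L), ] <- dP1 * !fw$pl1$mask
  dZ1 <- matrix(dR1, nrow = Fm[1L]) * (fw$Z1 > 0)
  gW1 <- dZ1 %*% t(fw$M1)
  gb1 <- rowSums(dZ1)
  grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  if (cfg$dense_hidden > 0L) {
    grads$Wh <- gWh; grads$bh <- gbh
  }
  grads$Wd <- gWd; grads$bd <- gbd
  list(loss = loss, grads = grads)
}

# Mean cross-entropy of a labeled set (no gradients), chunked.
cnn_cost <- function(model, x, y, chunk = 1024L) {
  n <- dim(x)[3L]
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    fw <- cnn_forward_full(model, x[, , s:e, drop = FALSE])
    idx <- cbind(y[s:e] + 1L, seq_len(e - s + 1L))
    tot <- tot + sum(-log(pmax(fw$probs[idx], 1e-12)))
  }
  tot / n
}

#' Epoch at which early stopping halts training
#'
#' Pure helper encoding the stopping rule: training halts at the first epoch
#' `e` such that the `patience` epochs after the best-validation epoch have
#' all failed to improve, i.e. `e = best + patience + 1`; the best-epoch
#' weights are restored.
#'
#' @param val_costs Numeric vector of per-epoch validation costs so far.
#' @param patience Number of non-improving epochs tolerated.
#' @return The stopping epoch, or `NA` if training should continue.
#' @export
early_stop_epoch <- function(val_costs, patience = 3L) {
  if (length(val_costs) == 0L) return(NA_integer_)
  best <- which.min(val_costs)
  if (length(val_costs) - best >= patience) best + patience + 1L else NA_integer_
}

#' Train the CNN with Adam and early stopping
#'
#' Minimizes mean cross-entropy over mixed donor/acceptor examples. Training
#' is fully deterministic for a fixed seed (initialization and per-epoch
#' shuffling both derive from it). After each epoch the validation cost is
#' measured; when it has not improved for `patience` consecutive epochs the
#' loop stops and the best-validation weights are returned.
#'
#' @param x_train,y_train Training windows (4 x W x n array) and 0/1 labels
#'   (1 = annotated site).
#' @param x_val,y_val Validation windows and labels.
#' @param config A [cnn_config()].
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled (AdamW-style) L2 weight decay per step;
#'   biases are not decayed. The network is small but so are desk-scale
#'   training sets, and a little shrinkage on the dense head helps
#'   genome-wide generalization.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Hard epoch cap.
#' @param seed Integer seed.
#' @param verbose Print per-epoch costs.
#' @return A list of class `cnn_fit`: `model` (best weights), `history`
#'   (tibble of per-epoch train/validation cost), `best_epoch`,
#'   `stopped_epoch`.
#' @export
train_cnn <- function(x_train, y_train, x_val, y_val, config = cnn_config(),
                      lr = 1e-3, weight_decay = 1e-4, batch_size = 64L,
                      patience = 3L, max_epochs = 100L, seed = 1L,
                      verbose = FALSE) {
  stopifnot(dim(x_train)[3L] == length(y_train), dim(x_val)[3L] == length(y_val),
            length(y_train) > 0L, length(y_val) > 0L)
  model <- cnn_init(config, seed = seed)
  mstate <- purrr::map(model$weights, ~ .x * 0)
  vstate <- purrr::map(model$weights, ~ .x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(y_train)
  history <- list()
  best_cost <- Inf
  best_weights <- model$weights
  best_epoch <- 0L
  stopped_epoch <- NA_integer_
  for (epoch in seq_len(max_epochs)) {
    set.seed(derive_seed(seed, "shuffle") + epoch)
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      e <- min(s + batch_size - 1L, n)
      idx <- ord[s:e]
      lg <- cnn_loss_grads(model, x_train[, , idx, drop = FALSE], y_train[idx])
      if (!is.finite(lg$loss)) {
        abort(paste0("training diverged (non-finite cost) at epoch ", epoch))
      }
      step <- step + 1L
      for (nm in names(model$weights)) {
        g <- lg$grads[[nm]]
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        decay <- if (nm %in% c("W1", "W2", "Wh", "Wd")) weight_decay else 0
        model$weights[[nm]] <- model$weights[[nm]] * (1 - lr * decay) -
          lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
    }
    val_cost <- cnn_cost(model, x_val, y_val)
    history[[epoch]] <- tibble(epoch = epoch, train_cost = ep_loss / nb,
                               validation_cost = val_cost)
    if (verbose) {
      inform(sprintf("epoch %d: train %.4f validation %.4f", epoch,
                     ep_loss / nb, val_cost))
    }
    if (val_cost < best_cost) {
      best_cost <- val_cost
      best_weights <- model$weights
      best_epoch <- epoch
    }
    stop_at <- early_stop_epoch(
      purrr::map_dbl(history, "validation_cost"), patience)
    if (!is.na(stop_at)) {
      stopped_epoch <- stop_at
      break
    }
  }
  model$weights <- best_weights
  structure(list(
    model = model,
    history = dplyr::bind_rows(history),
    best_epoch = best_epoch,
    stopped_epoch = if (is.na(stopped_epoch)) max_epochs else stopped_epoch
  ), class = "cnn_fit")
}

#' Fit the splice-site CNN from a genome and annotation
#'
#' Convenience wrapper: builds the labeled dataset with
#' [prepare_training_data()], one-hot encodes the train/validation windows
#' (sites too close to a contig end are skipped), and trains the joint
#' donor/acceptor model.
#'
#' @param genome Genome tibble.
#' @param genes Gene-model tibble.
#' @param flank Window flank (default 100 -> 202-bp windows).
#' @param neg_ratio Negatives per positive (default 3).
#' @param seed Integer seed driving every stochastic stage.
#' @param ... Passed on to [train_cnn()].
#' @return A `cnn_fit` with the `splice_dataset` attached as `$data`.
#' @export
fit_splice_cnn <- function(genome, genes, flank = 100L, neg_ratio = 3,
                           seed = 1L, ...) {
  ds <- prepare_training_data(genome, genes, flank = flank,
                              neg_ratio = neg_ratio, seed = seed)
  cfg <- cnn_config(window = 2L * flank + 2L)
  tr <- build_windows(ds$split$train, genome, flank = flank, pad = FALSE)
  va <- build_windows(ds$split$validation, genome, flank = flank, pad = FALSE)
  fit <- train_cnn(
    tr$x, as.integer(ds$split$train$label[tr$kept] == "positive"),
    va$x, as.integer(ds$split$validation$label[va$kept] == "positive"),
    config = cfg, seed = seed, ...)
  fit$data <- ds
  fit
}

#' Activation-rate difference at the last max-pooling layer
#'
#' For each cell of the final max-pooling layer (feature x position), the
#' activation rate over a window set is the frequency of that cell being
#' strictly positive after ReLU. The returned matrix is the rate over the
#' positive set minus the rate over the negative set, each entry in
#' \[-1, 1\]: persistent positive entries mark cells that fire preferentially
#' on real sites (splice-signal or exon-composition detectors).
#'
#' @param model A `cnn_model` or `cnn_fit`.
#' @param positives,negatives Window arrays (4 x W x n).
#' @return A features x positions matrix of class `activation_diff`.
#' @export
activation_rate_diff <- function(model, positives, negatives) {
  model <- as_cnn_model(model)
  stopifnot(dim(positives)[3L] > 0L, dim(negatives)[3L] > 0L)
  rate <- function(x) {
    acts <- cnn_embed(model, x)  # n x (F*L)
    matrix(colMeans(acts > 0), nrow = model$config$conv_features[2L])
  }
  out <- rate(positives) - rate(negatives)
  class(out) <- c("activation_diff", class(out))
  out
}

#' Last max-pooling-layer embedding of windows
#'
#' Returns the raw (non-negative) activations of the final max-pooling
#' layer, one row per window, for external dimensionality reduction.
#'
#' @param model A `cnn_model` or `cnn_fit`.
#' @param x Window array (4 x W x n) or single 4 x W matrix.
#' @param chunk Internal batching size.
#' @return An n x (features * positions) numeric matrix.
#' @export
cnn_embed <- function(model, x, chunk = 1024L) {
  model <- as_cnn_model(model)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  cnn_infer(model, x, want_embed = TRUE)$embed
}
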