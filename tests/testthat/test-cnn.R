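test_that("parameter count follows the layer arithmetic", {
  # single conv layer: 16 filters x 4 channels x kernel 5, plus biases
  expect_equal(16 * 4 * 5 + 16, 336)
  cfg <- cnn_config()
  # conv1 336 + conv2 16*16*5+16 + dense 752*8+8 + 8*2+2
  expect_equal(parameter_count(cfg),
               336L + (16L * 16L * 5L + 16L) +
                 (752L * 8L + 8L) + (8L * 2L + 2L))
  expect_equal(parameter_count(cfg), 7674L)
  # direct linear head: dense layer 10 -> 2 with bias has 22 parameters
  cfg2 <- cnn_config(window = 22, dense_hidden = 0)
  flat <- cfg2$shape[["flat"]]
  expect_equal(parameter_count(cfg2),
               336L + (16L * 16L * 5L + 16L) + flat * 2L + 2L)
  expect_equal(parameter_count(cnn_init(cfg, seed = 1)), parameter_count(cfg))
})

test_that("an inconsistent shape chain is rejected", {
  expect_error(cnn_config(window = 8), "not positive")
})

test_that("untrained models output exactly 0.5 and valid probabilities", {
  m <- cnn_init(cnn_config(window = 42), seed = 1)
  x <- splicescore:::one_hot(c(random_dna(42), random_dna(42)), 42L)
  expect_equal(predict_raw(m, x), c(0.5, 0.5))
  # all-N window: finite, in (0, 1)
  xN <- splicescore:::one_hot(strrep("N", 42), 42L)
  t <- predict_raw(m, xN)
  expect_true(is.finite(t) && t > 0 && t < 1)
})

test_that("batched forward equals per-example forward and the R reference path", {
  m <- cnn_init(cnn_config(window = 42), seed = 2)
  m$weights$Wd <- matrix(stats::rnorm(length(m$weights$Wd), sd = 0.2), nrow = 2)
  x <- splicescore:::one_hot(replicate(7, random_dna(42)), 42L)
  batch <- predict_raw(m, x)
  single <- vapply(1:7, function(i) predict_raw(m, x[, , i]), numeric(1))
  expect_equal(batch, single)
  fw <- splicescore:::cnn_forward_full(m, x)
  expect_equal(as.numeric(fw$probs[2, ]), batch, tolerance = 1e-12)
  expect_equal(colSums(fw$probs), rep(1, 7))  # softmax over 2 classes
  expect_error(predict_raw(m, x[, 1:30, ]), "does not match")
})

test_that("analytic gradients match finite differences", {
  set.seed(79)
  cfg <- cnn_config(window = 22)
  m <- cnn_init(cfg, seed = 3)
  m$weights$Wd <- matrix(stats::rnorm(length(m$weights$Wd), sd = 0.1), nrow = 2)
  x <- splicescore:::one_hot(replicate(6, random_dna(22)), 22L)
  y <- c(1L, 0L, 1L, 1L, 0L, 0L)
  lg <- splicescore:::cnn_loss_grads(m, x, y)
  eps <- 1e-5
  for (nm in names(m$weights)) {
    idx <- sample(length(m$weights[[nm]]), min(5, length(m$weights[[nm]])))
    for (i in idx) {
      mp <- m; mp$weights[[nm]][i] <- m$weights[[nm]][i] + eps
      mm <- m; mm$weights[[nm]][i] <- m$weights[[nm]][i] - eps
      fd <- (splicescore:::cnn_cost(mp, x, y) -
               splicescore:::cnn_cost(mm, x, y)) / (2 * eps)
      an <- lg$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("the trainer fits linearly separable toy windows", {
  # fixed motif vs uniform background
  set.seed(83)
  W <- 22L
  mk <- function(n, planted) {
    seqs <- replicate(n, {
      s <- random_dna(W)
      if (planted) paste0(substr(s, 1, 8), "GTAAGTCC", substr(s, 17, W)) else s
    })
    splicescore:::one_hot(seqs, W)
  }
  x_tr <- array(c(mk(120, TRUE), mk(120, FALSE)), dim = c(4, W, 240))
  y_tr <- rep(c(1L, 0L), each = 120)
  x_va <- array(c(mk(30, TRUE), mk(30, FALSE)), dim = c(4, W, 60))
  y_va <- rep(c(1L, 0L), each = 30)
  fit <- train_cnn(x_tr, y_tr, x_va, y_va, cnn_config(window = W),
                   max_epochs = 20, patience = 20, seed = 5)
  acc <- mean((predict_raw(fit$model, x_tr) > 0.5) == (y_tr == 1))
  expect_gte(acc, 0.99)
})

test_that("training is deterministic for a fixed seed", {
  set.seed(89)
  W <- 22L
  x <- splicescore:::one_hot(replicate(80, random_dna(W)), W)
  y <- rep(c(1L, 0L), 40)
  f1 <- train_cnn(x, y, x[, , 1:20], y[1:20], cnn_config(window = W),
                  max_epochs = 3, seed = 11)
  f2 <- train_cnn(x, y, x[, , 1:20], y[1:20], cnn_config(window = W),
                  max_epochs = 3, seed = 11)
  expect_identical(f1$model$weights, f2$model$weights)
  f3 <- train_cnn(x, y, x[, , 1:20], y[1:20], cnn_config(window = W),
                  max_epochs = 3, seed = 12)
  expect_false(identical(f3$model$weights, f1$model$weights))
})

test_that("early stopping halts after patience epochs past the best", {
  # pure stopping-rule contract
  expect_equal(early_stop_epoch(c(1.0, 1.1, 1.2, 1.3), patience = 3), 5L)
  expect_true(is.na(early_stop_epoch(c(1.0, 1.1, 1.2), patience = 3)))
  expect_true(is.na(early_stop_epoch(c(1.0, 1.1, 0.9, 1.2, 1.3), patience = 3)))
  expect_equal(early_stop_epoch(c(1.0, 1.1, 0.9, 1.2, 1.3, 1.2), patience = 3), 7L)
  expect_true(is.na(early_stop_epoch(numeric(0))))
})

test_that("the train loop applies the stopping rule and restores best weights", {
  set.seed(97)
  W <- 22L
  # tiny training set, big lr: validation cost rises quickly after epoch 1
  x <- splicescore:::one_hot(replicate(40, random_dna(W)), W)
  y <- rep(c(1L, 0L), 20)
  xv <- splicescore:::one_hot(replicate(30, random_dna(W)), W)
  yv <- rep(c(0L, 1L, 0L), 10)
  fit <- train_cnn(x, y, xv, yv, cnn_config(window = W), lr = 0.05,
                   max_epochs = 50, patience = 3, seed = 13)
  expect_lt(nrow(fit$history), 50L)  # stopped early
  expect_equal(fit$stopped_epoch, fit$best_epoch + 3L + 1L)
  expect_equal(min(fit$history$validation_cost),
               fit$history$validation_cost[fit$best_epoch])
  # returned weights reproduce the best epoch's validation cost
  expect_equal(splicescore:::cnn_cost(fit$model, xv, yv),
               min(fit$history$validation_cost))
})

test_that("activation-rate differences are bounded and vanish on identical sets", {
  m <- cnn_init(cnn_config(window = 42), seed = 4)
  x <- splicescore:::one_hot(replicate(12, random_dna(42)), 42L)
  d0 <- activation_rate_diff(m, x, x)
  expect_true(all(d0 == 0))
  y <- splicescore:::one_hot(replicate(15, random_dna(42)), 42L)
  d <- activation_rate_diff(m, x, y)
  expect_equal(dim(d), c(16L, m$config$shape[["pool2"]]))
  expect_true(all(abs(d) <= 1))
})

test_that("embeddings equal the internal pooled activations row by row", {
  m <- cnn_init(cnn_config(window = 42), seed = 6)
  x <- splicescore:::one_hot(replicate(5, random_dna(42)), 42L)
  em <- cnn_embed(m, x)
  expect_equal(dim(em), c(5L, m$config$shape[["flat"]]))
  fw <- splicescore:::cnn_forward_full(m, x)
  expect_equal(em, t(matrix(fw$pl2$p, nrow = m$config$shape[["flat"]])),
               tolerance = 1e-12)
  expect_identical(em, cnn_embed(m, x))  # deterministic given weights
  expect_equal(nrow(cnn_embed(m, x[, , 1])), 1L)
})

test_that("model checkpoints survive the JSON round trip", {
  m <- cnn_init(cnn_config(window = 42), seed = 7)
  m$weights$Wd <- matrix(stats::rnorm(length(m$weights$Wd)), nrow = 2)
  tab <- build_calibration(c(0.1, 0.6, 0.9), c(FALSE, TRUE, TRUE), b = 10)
  f <- withr::local_tempfile(fileext = ".json")
  write_cnn_model(m, f, calibration = tab)
  back <- read_cnn_model(f)
  expect_equal(back$model$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$model$config$window, 42L)
  expect_equal(back$calibration$bins$s, tab$bins$s, tolerance = 1e-12)
  x <- splicescore:::one_hot(random_dna(42), 42L)
  expect_equal(predict_raw(back$model, x), predict_raw(m, x), tolerance = 1e-12)
})
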