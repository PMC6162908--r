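test_that("initialization is seeded Gaussian with zero biases", {
  cfg <- rnn_config(cell = "lstm", tau = 10, hidden = 50, seed = 17)
  m1 <- init_model(cfg, 40, 4)
  m2 <- init_model(cfg, 40, 4)
  expect_identical(m1$params, m2$params)
  w <- unlist(m1$params[c("Wi", "Ui", "Wf", "Uf", "Wo", "Uo", "Wg", "Ug")])
  expect_gt(length(w), 1e4)
  expect_gt(sd(w), 0.19)
  expect_lt(sd(w), 0.21)
  expect_lt(abs(mean(w)), 0.01)
  expect_true(all(m1$params$bi == 0) && all(m1$params$by == 0))
  expect_error(rnn_config(cell = "elman"), "unknown cell")
})

test_that("forward scoring returns simplex vectors; zero model is uniform", {
  cfg <- rnn_config(cell = "gru", tau = 5, hidden = 6, seed = 2)
  m <- init_model(cfg, 3, 4)
  withr::with_seed(3, x <- matrix(rnorm(15), 3, 5))
  p <- forward(m, x)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  z <- m
  for (nm in names(z$params)) z$params[[nm]] <- z$params[[nm]] * 0
  expect_equal(unname(forward(z, x)), rep(0.25, 4))
  expect_error(forward(m, matrix(0, 2, 5)), "rows")
  expect_error(forward(m, matrix(0, 3, 4)), "length")
})

test_that("a hand-computed 1-unit GRU matches the implementation", {
  # scalar GRU, all weights 1, biases 0, sigmoid gates, tanh candidate;
  # head weights +1 / -1 so class probabilities are informative
  cfg <- rnn_config(cell = "gru", tau = 2, hidden = 1, seed = 1,
                    gate_activation_mode = "conventional_sigmoid")
  m <- init_model(cfg, 1, 2)
  for (nm in c("Wz", "Uz", "Wr", "Ur", "Wc", "Uc"))
    m$params[[nm]] <- matrix(1, 1, 1)
  m$params$bz <- m$params$br <- m$params$bc <- 0
  m$params$Wy <- matrix(c(1, -1), 2, 1)
  m$params$by <- c(0, 0)
  # independent scalar arithmetic, step by step
  sg <- function(v) 1 / (1 + exp(-v))
  h <- 0
  for (x in c(1, 1)) {
    z <- sg(x + h); r <- sg(x + h)
    cand <- tanh(x + r * h)
    h <- (1 - z) * h + z * cand
  }
  expected <- exp(c(h, -h)) / sum(exp(c(h, -h)))
  got <- forward(m, matrix(c(1, 1), 1, 2))
  expect_equal(unname(got), expected, tolerance = 1e-12)
})

test_that("cross-entropy follows the logarithmic loss with batch averaging", {
  expect_equal(cross_entropy(c(1, 0), 1L), 0, tolerance = 1e-10)
  expect_equal(cross_entropy(c(0.5, 0.5), 1L), log(2), tolerance = 1e-12)
  # batch of two averages the per-example losses
  p <- cbind(c(0.9, 0.1), c(0.2, 0.8))
  a <- -log(0.9); b <- -log(0.8)
  expect_equal(cross_entropy(p, c(1L, 2L)), (a + b) / 2)
  # clipping keeps impossible predictions finite
  expect_lt(cross_entropy(c(0, 1), 1L), 28)
})

test_that("BPTT gradients match central finite differences on a toy", {
  # one cell/mode pair here as a fast regression guard; the full sweep over
  # cells and gate modes runs in the acceptance suite
  cfg <- rnn_config(cell = "gru", tau = 4, hidden = 5, dropout = 0,
                    seed = 7)
  model <- init_model(cfg, 3, 2)
  withr::with_seed(8, {
    X <- array(rnorm(3 * 4 * 3, sd = 0.8), dim = c(3, 4, 3))
    y <- sample(1:2, 3, replace = TRUE)
  })
  lg <- fbcsprnn:::rnn_loss_grad(model, X, y)
  eps <- 1e-4
  worst <- 0
  for (nm in names(model$params)) {
    w <- model$params[[nm]]
    idx <- if (length(w) > 5) withr::with_seed(9, sample(length(w), 5))
           else seq_along(w)
    for (i in idx) {
      mp <- model; mp$params[[nm]][i] <- w[i] + eps
      mm <- model; mm$params[[nm]][i] <- w[i] - eps
      fd <- (fbcsprnn:::rnn_loss_grad(mp, X, y)$loss -
               fbcsprnn:::rnn_loss_grad(mm, X, y)$loss) / (2 * eps)
      worst <- max(worst, abs(fd - lg$grads[[nm]][i]) /
                     max(abs(fd), abs(lg$grads[[nm]][i]), 1e-6))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training runs the exact iteration count, deterministically", {
  slices <- make_separable_slices(n_per_class = 10, tau = 6)
  cfg <- quick_rnn_cfg(cell = "gru", tau = 6L)
  m <- init_model(cfg, 4, 2)
  fit1 <- train_rnn(m, slices, cfg = cfg)
  fit2 <- train_rnn(init_model(cfg, 4, 2), slices, cfg = cfg)
  expect_equal(nrow(fit1$trace), cfg$max_iterations)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$trace, fit2$trace)
  expect_true(all(fit1$trace$train_loss >= 0))
  expect_error(train_rnn(m, list(x = array(0, c(4, 6, 0)), y = integer(0)),
                         cfg = cfg), "empty")
  # validation columns filled when validation slices are supplied
  cfg_long <- quick_rnn_cfg(cell = "gru", tau = 6L, max_iterations = 30L)
  fit3 <- train_rnn(init_model(cfg_long, 4, 2), slices, slices, cfg_long)
  expect_true(all(is.finite(fit3$trace$val_loss)))
  # easy separable problem is learned quickly
  expect_gt(tail(fit3$trace$val_acc, 1), 0.9)
})

test_that("trial prediction averages slice probabilities with low-index ties", {
  probs <- rbind(c(0.6, 0.4), c(0.4, 0.6), c(0.8, 0.2))
  expect_equal(colMeans(probs), c(0.6, 0.4))
  # decision rule via the exported function on a crafted model: a zero
  # model yields an exact tie, broken toward the lowest class index
  cfg <- rnn_config(cell = "vanilla", tau = 3, hidden = 2, seed = 1)
  z <- init_model(cfg, 2, 2)
  for (nm in names(z$params)) z$params[[nm]] <- z$params[[nm]] * 0
  Z <- feature_series(matrix(rnorm(20), 2), label = 1L)
  agg <- predict_trial(z, Z, tau = 3)
  expect_equal(unname(agg$mean_probs), c(0.5, 0.5))
  expect_equal(agg$final_label, 1L)
  expect_equal(nrow(agg$slice_probs), 10 - 3)
  expect_equal(rowSums(agg$slice_probs), rep(1, 7), tolerance = 1e-9)
  expect_error(predict_trial(z, feature_series(matrix(0, 2, 3)), tau = 3),
               "exceed")
})

test_that("autoregressive mode continues signals and rejects classifiers", {
  cfg <- rnn_config(cell = "gru", tau = 4, hidden = 3, head = "linear",
                    seed = 5)
  m <- init_model(cfg, 2, 2)
  seedseq <- matrix(rnorm(8), 2, 4)
  expect_equal(dim(autoregressive_predict(m, seedseq, 0)), c(2, 0))
  z <- m
  for (nm in names(z$params)) z$params[[nm]] <- z$params[[nm]] * 0
  expect_true(all(autoregressive_predict(z, seedseq, 5) == 0))
  clf <- init_model(rnn_config(cell = "gru", tau = 4, hidden = 3), 2, 2)
  expect_error(autoregressive_predict(clf, seedseq, 3), "linear")
})

test_that("a trained signal model continues a 10 Hz rhythm at 10 Hz", {
  rate <- 250
  x <- matrix(sin(2 * pi * 10 * (0:599) / rate), nrow = 1)
  cfg <- rnn_config(cell = "gru", tau = 25, hidden = 16, dropout = 0,
                    max_iterations = 120, head = "linear", seed = 3,
                    learning_rate = 3e-3)
  fit <- train_signal_model(x, cfg, stride = 2)
  pred <- autoregressive_predict(fit$model, x[, 1:50, drop = FALSE], 400)
  sp <- stats::spec.pgram(as.numeric(pred), plot = FALSE, taper = 0)
  peak_hz <- sp$freq[which.max(sp$spec)] * rate
  expect_lt(abs(peak_hz - 10), 1)
})

test_that("depth sweep picks the accuracy-maximizing tau deterministically", {
  feats <- lapply(1:8, function(i) {
    shift <- if (i %% 2) 1 else -1
    withr::with_seed(i, feature_series(matrix(rnorm(3 * 30, mean = shift),
                                              3, 30),
                                       label = (i %% 2) + 1L, trial_id = i))
  })
  cfg <- quick_rnn_cfg(max_iterations = 3L)
  sw1 <- sweep_depth(feats[1:4], feats[5:8], c(5L), cfg, cells = "gru",
                     stride = 5)
  expect_equal(unname(sw1$onhl["gru"]), 5L)
  sw2 <- sweep_depth(feats[1:4], feats[5:8], c(5L, 8L), cfg, cells = "gru",
                     stride = 5)
  sw3 <- sweep_depth(feats[1:4], feats[5:8], c(5L, 8L), cfg, cells = "gru",
                     stride = 5)
  expect_identical(sw2$onhl, sw3$onhl)
  expect_equal(nrow(sw2$curves), 2)
})

test_that("models round-trip through serialization", {
  cfg <- rnn_config(cell = "lstm", tau = 4, hidden = 3, seed = 6)
  m <- init_model(cfg, 2, 2, layout = data.frame(band = 1, ovr_class = NA,
                                                 component = 1:2))
  path <- withr::local_tempfile(fileext = ".rnn")
  save_rnn_model(m, path)
  back <- load_rnn_model(path)
  expect_identical(back$params, m$params)
  expect_identical(back$layout, m$layout)
  expect_error(load_rnn_model(file.path(tempdir(), "no.rnn")), "no such")
})
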