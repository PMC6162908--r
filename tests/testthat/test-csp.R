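test_that("class covariance averages trace-normalized per-trial covariances", {
  # long white-noise trial: expect ~identity/N with small off-diagonals
  withr::with_seed(8, {
    trs <- lapply(1:4, function(i)
      trial(matrix(rnorm(4 * 20000), 4, 20000), 1L))
  })
  ce <- class_covariance(trs, 1L)
  expect_equal(diag(ce$matrix), rep(0.25, 4), tolerance = 0.02)
  offd <- ce$matrix[row(ce$matrix) != col(ce$matrix)]
  expect_lt(max(abs(offd)), 0.02)

  # hand computation: second row is constant -> centered to zero
  tr <- trial(rbind(c(1, -1, 1, -1), c(1, 1, 1, 1)), 2L)
  ce2 <- class_covariance(list(tr), 2L)
  expect_equal(ce2$matrix, diag(c(1, 0)), tolerance = 1e-12)

  expect_error(class_covariance(trs, 9L), "no trials")
})

test_that("class covariances are symmetric positive semi-definite", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      trs <- lapply(1:3, function(i)
        trial(matrix(rnorm(5 * 40), 5, 40), 1L))
    })
    m <- class_covariance(trs, 1L)$matrix
    expect_equal(m, t(m))
    expect_gt(min(eigen(m, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("CSP solves the Rayleigh quotient: axis-aligned case and grid oracle", {
  C1 <- diag(c(4, 1)) / 5
  C2 <- diag(c(1, 4)) / 5
  fs <- fit_csp(C1, C2, 1, gamma = 0)
  expect_equal(fs$eigenvalues, c(0.8, 0.2), tolerance = 1e-10)
  cos1 <- abs(fs$projection[1, ] %*% c(1, 0)) /
    sqrt(sum(fs$projection[1, ]^2))
  cos2 <- abs(fs$projection[2, ] %*% c(0, 1)) /
    sqrt(sum(fs$projection[2, ]^2))
  expect_gt(cos1, 0.999)
  expect_gt(cos2, 0.999)
  # independent oracle: brute-force maximization of the power ratio over a
  # 0.1-degree grid of unit vectors
  theta <- seq(0, pi, by = 0.1 * pi / 180)
  ratio <- vapply(theta, function(a) {
    w <- c(cos(a), sin(a))
    (w %*% C1 %*% w) / (w %*% (C1 + C2) %*% w)
  }, numeric(1))
  expect_equal(max(ratio), fs$eigenvalues[1], tolerance = 1e-6)
  # normalization contract: w' (C1+C2) w = 1 per filter row
  for (i in 1:2)
    expect_equal(as.numeric(fs$projection[i, ] %*% (C1 + C2) %*%
                              fs$projection[i, ]), 1, tolerance = 1e-10)
})

test_that("identical class covariances give eigenvalues 1/2; views pair up", {
  C <- diag(c(4, 1)) / 5
  expect_equal(fit_csp(C, C, 1)$eigenvalues, c(0.5, 0.5), tolerance = 1e-10)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- crossprod(matrix(rnorm(16), 4)); A <- A / sum(diag(A))
      B <- crossprod(matrix(rnorm(16), 4)); B <- B / sum(diag(B))
    })
    l1 <- fit_csp(A, B, 2)$eigenvalues
    l2 <- fit_csp(B, A, 2)$eigenvalues
    expect_equal(l1, 1 - rev(l2), tolerance = 1e-10)
  }
  expect_error(fit_csp(diag(2), diag(2), 2), "exceeds")
})

test_that("filter-bank CSP produces the documented set counts and shapes", {
  bank <- default_filter_bank(250)
  ts2 <- make_noise_trialset(n_channels = 3, n_per_class = 3, T = 150)
  sets2 <- fit_fbcsp(ts2, bank, m = 1)
  expect_length(sets2, 10)                       # 2 classes: one per band
  expect_true(all(vapply(sets2, function(s) nrow(s$projection), integer(1))
                  == 2))                          # m = 1 -> M = 2
  expect_true(all(is.na(vapply(sets2, `[[`, integer(1), "ovr_class"))))

  ts4 <- make_noise_trialset(n_channels = 4, n_per_class = 3, T = 150,
                             n_classes = 4)
  sets4 <- fit_fbcsp(ts4, bank, m = 2)
  expect_length(sets4, 40)                       # 10 bands x 4 OVR classes
  expect_true(all(vapply(sets4, function(s) nrow(s$projection), integer(1))
                  == 4))                          # m = 2 -> M = 4
  # deterministic band-major-then-class ordering
  expect_equal(vapply(sets4[1:4], `[[`, integer(1), "band_index"),
               rep(1L, 4))
  expect_equal(vapply(sets4[1:4], `[[`, integer(1), "ovr_class"), 1:4)
})

test_that("projection stacks rows per the layout and preserves shape", {
  ts <- make_noise_trialset(n_channels = 3, n_per_class = 3, T = 150)
  bank <- default_filter_bank(250)
  sets <- fit_fbcsp(ts, bank, m = 1)
  feats <- fbcsp_features(ts, bank, sets)
  expect_equal(nrow(feats[[1]]$values), 20)      # 10 bands x M=2
  expect_equal(ncol(feats[[1]]$values), 150)
  expect_equal(feats[[1]]$label, ts$trials[[1]]$label)
  expect_equal(nrow(feats[[1]]$layout), 20)

  # identity projection returns the input channels
  id_set <- structure(list(projection = diag(3), eigenvalues = rep(0.5, 3),
                           m = 1L, band_index = 1L, ovr_class = NA_integer_),
                      class = "csp_filters")
  bt <- list(ts$trials[[1]])
  z <- project_features(bt, list(id_set))
  expect_equal(z$values, ts$trials[[1]]$data)
  z0 <- project_features(list(trial(matrix(0, 3, 10), 1L)), list(id_set))
  expect_true(all(z0$values == 0))
  expect_error(project_features(list(trial(matrix(0, 2, 10), 1L)),
                                list(id_set)), "channels")
})

test_that("log band-power features: closed form, scale invariance, flooring", {
  t <- seq(0, 2, by = 1 / 250)[-1]               # whole periods of 10 Hz
  Z <- feature_series(rbind(sin(2 * pi * 10 * t),
                            2 * cos(2 * pi * 14 * t)), label = 1L)
  raw <- logvar_features(Z, normalize = FALSE)
  expect_equal(exp(raw[1]), 0.5, tolerance = 1e-2)   # A^2/2 for A = 1
  norm1 <- logvar_features(Z)
  Zs <- Z; Zs$values <- 7 * Zs$values
  expect_equal(logvar_features(Zs), norm1, tolerance = 1e-12)
  Z0 <- feature_series(rbind(rep(0, 10), rnorm(10)), label = 1L)
  expect_warning(out <- logvar_features(Z0), "floored")
  expect_true(all(is.finite(out)))
})
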