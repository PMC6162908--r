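test_that("the generator balances labels and is seed-deterministic", {
  cfg <- synth_config(n_trials_per_class = 5L, trial_length_s = 2,
                      imagery_window_s = c(0.5, 1.5), seed = 4)
  ts1 <- simulate_trialset(cfg)
  expect_length(ts1$trials, 10)
  expect_equal(as.integer(table(trial_labels(ts1))), c(5L, 5L))
  expect_equal(ncol(ts1$trials[[1]]$data), 500)
  ts2 <- simulate_trialset(cfg)
  expect_identical(ts1$trials[[7]]$data, ts2$trials[[7]]$data)
  expect_error(synth_config(class_spec = list(list(list(
    source = 1, rhythm = "gamma", erd_depth = 0.5)))), "rhythm")
  expect_error(synth_config(class_spec = list(list(list(
    source = 1, rhythm = "mu", erd_depth = 1.5)))), "erd_depth")
  expect_error(synth_config(mixing = matrix(1, 2, 3), n_channels = 3),
               "rows")
})

test_that("ERD depth 0.6 suppresses mu power by about (1-0.6)^2", {
  ts <- simulate_trialset(synth_config(seed = 11))
  ep <- epoch_trials(ts, c(4, 6))
  labs <- trial_labels(ep)
  p1 <- mean(vapply(ep$trials[labs == 1],
                    function(tr) band_power(tr$data[1, ], 250, c(8, 12)),
                    numeric(1)))
  p2 <- mean(vapply(ep$trials[labs == 2],
                    function(tr) band_power(tr$data[1, ], 250, c(8, 12)),
                    numeric(1)))
  ratio <- p1 / p2
  expect_gt(ratio, 0.16 * 0.5)
  expect_lt(ratio, 0.16 * 1.5)
})

test_that("with no ERD the class band powers are indistinguishable", {
  flat <- list(
    list(list(source = 1L, rhythm = "mu", erd_depth = 0)),
    list(list(source = 3L, rhythm = "mu", erd_depth = 0)))
  rejections <- vapply(1:20, function(s) {
    ts <- simulate_trialset(synth_config(class_spec = flat,
                                         n_trials_per_class = 15L,
                                         trial_length_s = 3,
                                         imagery_window_s = c(0.5, 2.5),
                                         seed = 100 + s))
    ep <- epoch_trials(ts, c(0.5, 2.5))
    labs <- trial_labels(ep)
    bp <- vapply(ep$trials,
                 function(tr) band_power(tr$data[1, ], 250, c(8, 12)),
                 numeric(1))
    stats::t.test(bp[labs == 1], bp[labs == 2])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
})

test_that("CSP concentrates weight on the ERD-modulated channel", {
  one_sided <- list(
    list(list(source = 1L, rhythm = "mu", erd_depth = 0.7)),
    list())                                     # class 2 modulates nothing
  ts <- simulate_trialset(synth_config(class_spec = one_sided,
                                       n_trials_per_class = 30L, seed = 13))
  ep <- epoch_trials(ts, c(4, 6))
  bank <- filter_bank(list(c(8, 12)), 250)
  sets <- fit_fbcsp(ep, bank, m = 1)
  fs <- sets[[1]]
  # the filter whose eigenvalue is farthest from 1/2 is the discriminative
  # one; its squared weight should concentrate on channel 1
  ev <- fs$eigenvalues[c(1, length(fs$eigenvalues))]
  row <- if (abs(ev[1] - 0.5) >= abs(ev[2] - 0.5)) fs$projection[1, ]
         else fs$projection[nrow(fs$projection), ]
  expect_gte(row[1]^2 / sum(row^2), 0.5)
})

test_that("synthetic configurations round-trip through YAML", {
  cfg <- synth_config(n_trials_per_class = 3L, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back$n_trials_per_class, 3L)
  expect_equal(back$class_spec[[1]][[1]]$erd_depth, 0.6)
  expect_identical(simulate_trialset(back)$trials[[1]]$data,
                   simulate_trialset(cfg)$trials[[1]]$data)
})
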