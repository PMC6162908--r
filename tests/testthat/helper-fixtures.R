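# Fixtures built in code: tiny trials, trial sets and feature series used
# across the suite.

make_noise_trialset <- function(n_channels = 3, n_per_class = 4, T = 200,
                                n_classes = 2, rate = 250, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(seq_len(n_classes), each = n_per_class)
    trials <- lapply(labels, function(cl)
      trial(matrix(rnorm(n_channels * T), n_channels, T), cl,
            subject_id = "fix", session_id = as.character(1 + (cl %% 2))))
    trial_set(trials, seq_len(n_classes), rate)
  })
}

make_feature_series <- function(d = 3, T = 100, label = 1, seed = 2) {
  withr::with_seed(seed,
    feature_series(matrix(rnorm(d * T), d, T), label = label, trial_id = 1))
}

# small strongly-separable slice set: class differs by a mean offset
make_separable_slices <- function(n_per_class = 20, d = 4, tau = 8,
                                  seed = 3) {
  withr::with_seed(seed, {
    mk <- function(cl) lapply(seq_len(n_per_class), function(i) {
      shift <- if (cl == 1) 1.2 else -1.2
      time_slice(matrix(rnorm(d * tau, mean = shift), d, tau), cl, i)
    })
    c(mk(1L), mk(2L))
  })
}

quick_rnn_cfg <- function(...) {
  args <- utils::modifyList(list(hidden = 8L, max_iterations = 5L,
                                 dropout = 0, batch_size = 16L, seed = 11L),
                            list(...))
  do.call(rnn_config, args)
}

# band power of one channel via the smoothed periodogram, in a Hz band
band_power <- function(x, rate, band) {
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = TRUE)
  f <- sp$freq * rate
  sum(sp$spec[f >= band[1] & f <= band[2]])
}
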