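# Synthetic motor-imagery EEG with class-dependent ERD band-power
# modulation of mu and beta rhythms, so every pipeline stage can be
# exercised without external recordings.

RHYTHM_BANDS <- list(mu = c(8, 12), beta = c(18, 25))

#' Synthetic ERD/ERS generator configuration
#'
#' Each "source" carries narrowband mu (8-12 Hz) and beta (18-25 Hz)
#' rhythms built by band-pass filtering white noise (realistic
#' non-sinusoidal rhythms). During the imagery interval of a trial, the
#' (source, rhythm) pairs listed for the trial's class are attenuated by
#' `1 - erd_depth` — the event-related desynchronization. Sources are
#' mixed to channels by `mixing` and 1/f background noise is added per
#' channel.
#'
#' The default emulates a two-class left/right-hand montage with three
#' channels (C3-like, Cz-like, C4-like): class 1 desynchronizes both
#' rhythms at channel 1, class 2 at channel 3. The trial timeline follows
#' the standard cue paradigm — cue at 2 s, imagery through 6 s — so
#' epoching at `[4, 6]` s captures modulated signal.
#'
#' @param n_channels number of channels (= sources for identity mixing).
#' @param class_spec list, one element per class, each a list of
#'   `list(source =, rhythm = "mu"|"beta", erd_depth =)` entries;
#'   `erd_depth` in `[0, 1]` is the fractional amplitude suppression.
#' @param trial_length_s trial duration in seconds.
#' @param sample_rate_hz sampling rate (250 Hz standard).
#' @param background_noise_sigma standard deviation of the 1/f noise.
#' @param mixing `"identity"` or an `n_channels x n_sources` matrix.
#' @param n_trials_per_class trials generated per class.
#' @param imagery_window_s `c(start, stop)` seconds of the imagery
#'   interval within each trial.
#' @param rhythm_sigma standard deviation of each rhythm source.
#' @param seed RNG seed; same seed, identical trial set.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 3L,
                         class_spec = NULL,
                         trial_length_s = 7,
                         sample_rate_hz = 250,
                         background_noise_sigma = 0.5,
                         mixing = "identity",
                         n_trials_per_class = 100L,
                         imagery_window_s = c(2, 6),
                         rhythm_sigma = 1,
                         seed = 1L) {
  if (is.null(class_spec))
    class_spec <- list(
      list(list(source = 1L, rhythm = "mu", erd_depth = 0.6),
           list(source = 1L, rhythm = "beta", erd_depth = 0.6)),
      list(list(source = n_channels, rhythm = "mu", erd_depth = 0.6),
           list(source = n_channels, rhythm = "beta", erd_depth = 0.6)))
  for (cls in class_spec)
    for (mod in cls) {
      if (!mod$rhythm %in% names(RHYTHM_BANDS))
        stop_arg("unknown rhythm '%s'", mod$rhythm)
      if (mod$erd_depth < 0 || mod$erd_depth > 1)
        stop_arg("erd_depth must be in [0, 1]")
    }
  if (trial_length_s <= 0 || sample_rate_hz <= 0)
    stop_arg("lengths and rates must be positive")
  n_sources <- if (is.matrix(mixing)) ncol(mixing) else n_channels
  if (is.matrix(mixing) && nrow(mixing) != n_channels)
    stop_arg("mixing must have n_channels = %d rows", n_channels)
  for (cls in class_spec)
    for (mod in cls)
      if (mod$source < 1 || mod$source > n_sources)
        stop_arg("class_spec source %d outside 1..%d", mod$source, n_sources)
  structure(list(n_channels = as.integer(n_channels),
                 class_spec = class_spec,
                 trial_length_s = trial_length_s,
                 sample_rate_hz = sample_rate_hz,
                 background_noise_sigma = background_noise_sigma,
                 mixing = mixing,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 imagery_window_s = imagery_window_s,
                 rhythm_sigma = rhythm_sigma,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# narrowband noise: white noise band-passed to `band`, rescaled to unit sd
narrowband_noise <- function(n, band, rate) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf$b, bf$a, stats::rnorm(n))
  x / stats::sd(x)
}

# 1/f (power slope -1) background noise with standard deviation sigma
pink_noise <- function(n, sigma) {
  w <- stats::fft(stats::rnorm(n))
  f <- 0:(n - 1)
  fm <- pmin(f, n - f)                           # symmetric frequency index
  fm[1] <- 1                                     # DC zeroed below
  shaped <- w / sqrt(fm)
  shaped[1] <- 0
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  if (sigma == 0 || stats::sd(x) == 0) return(numeric(n))
  x / stats::sd(x) * sigma
}

#' Simulate a labelled motor-imagery trial set
#'
#' Generates `n_trials_per_class` trials per class according to the
#' configuration (see [synth_config()]). Deterministic for a given seed.
#'
#' @param cfg a [synth_config()].
#' @return A [trial_set()] with balanced labels `1..n_classes`.
#' @export
simulate_trialset <- function(cfg) {
  rate <- cfg$sample_rate_hz
  n <- round(cfg$trial_length_s * rate)
  n_classes <- length(cfg$class_spec)
  n_sources <- if (is.matrix(cfg$mixing)) ncol(cfg$mixing) else cfg$n_channels
  mix <- if (is.matrix(cfg$mixing)) cfg$mixing else diag(cfg$n_channels)
  im0 <- round(cfg$imagery_window_s[1] * rate) + 1L
  im1 <- min(round(cfg$imagery_window_s[2] * rate), n)
  labels <- rep(seq_len(n_classes), each = cfg$n_trials_per_class)
  trials <- withr::with_seed(cfg$seed, {
    lapply(seq_along(labels), function(i) {
      cls <- labels[i]
      mods <- cfg$class_spec[[cls]]
      src <- matrix(0, n_sources, n)
      for (s in seq_len(n_sources)) {
        for (rh in names(RHYTHM_BANDS)) {
          osc <- cfg$rhythm_sigma *
            narrowband_noise(n, RHYTHM_BANDS[[rh]], rate)
          depth <- 0
          for (mod in mods)
            if (mod$source == s && mod$rhythm == rh) depth <- mod$erd_depth
          if (depth > 0)
            osc[im0:im1] <- osc[im0:im1] * (1 - depth)
          src[s, ] <- src[s, ] + osc
        }
      }
      x <- mix %*% src
      for (ch in seq_len(cfg$n_channels))
        x[ch, ] <- x[ch, ] + pink_noise(n, cfg$background_noise_sigma)
      trial(x, cls, subject_id = "synthetic", session_id = "1")
    })
  })
  trial_set(trials, seq_len(n_classes), rate)
}

#' Write a synthetic configuration to YAML / read it back
#'
#' @param cfg a [synth_config()].
#' @param path YAML file path.
#' @export
write_synth_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: '%s'", path)
  v <- yaml::read_yaml(path)
  do.call(synth_config, v[names(v) %in% names(formals(synth_config))])
}
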