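# Broadband preprocessing (notch + band-pass) and the multi-band
# Butterworth filter bank used for spatial-frequency feature extraction.

#' Band specification
#'
#' @param low_hz,high_hz band edges in Hz, `0 < low < high`.
#' @param order Butterworth order (applied forward-backward, so the
#'   effective magnitude response is squared).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_hz, high_hz, order = 4L) {
  if (low_hz <= 0 || high_hz <= low_hz)
    stop_arg("need 0 < low_hz < high_hz (got [%g, %g])", low_hz, high_hz)
  if (order < 1) stop_arg("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "band_spec")
}

#' Build a Butterworth band-pass filter bank
#'
#' Realizes zero-phase Butterworth band-pass filters for a list of bands at a
#' given sample rate. Every band edge must lie strictly below Nyquist.
#'
#' @param bands list of [band_spec()] objects (or `list(low, high)` pairs).
#' @param sample_rate_hz design sample rate in Hz.
#' @param order default order for bands given as bare pairs.
#' @return An object of class `filter_bank` with realized coefficients.
#' @export
filter_bank <- function(bands, sample_rate_hz, order = 4L) {
  if (length(bands) == 0L) stop_arg("bands must be non-empty")
  bands <- lapply(bands, function(b) {
    if (inherits(b, "band_spec")) b
    else band_spec(b[[1]], b[[2]], order)
  })
  nyq <- sample_rate_hz / 2
  coef <- lapply(bands, function(b) {
    if (b$high_hz >= nyq)
      stop_arg("band [%g, %g] Hz reaches Nyquist (%g Hz)",
               b$low_hz, b$high_hz, nyq)
    signal::butter(b$order, c(b$low_hz, b$high_hz) / nyq, type = "pass")
  })
  structure(list(bands = bands, coef = coef,
                 sample_rate_hz = sample_rate_hz),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  rng <- vapply(x$bands, function(b) sprintf("[%g,%g]", b$low_hz, b$high_hz),
                character(1))
  cat(sprintf("<filter_bank> %d bands @ %g Hz: %s\n", length(x$bands),
              x$sample_rate_hz, paste(rng, collapse = " ")))
  invisible(x)
}

#' The standard 10-band division of the 8-30 Hz range
#'
#' Ten 4-Hz-wide bands covering the mu and beta rhythms, each overlapping the
#' next by 2 Hz: `[8,12]`, `[10,14]`, ..., `[26,30]` Hz. This fixed division
#' is subject-independent.
#'
#' @param sample_rate_hz design sample rate in Hz; must exceed 60 Hz so the
#'   30 Hz upper edge stays below Nyquist.
#' @param order Butterworth order per band.
#' @return A [filter_bank()] with 10 bands.
#' @export
default_filter_bank <- function(sample_rate_hz, order = 4L) {
  lows <- seq(8, 26, by = 2)
  bands <- lapply(lows, function(lo) band_spec(lo, lo + 4, order))
  filter_bank(bands, sample_rate_hz, order)
}

# second-order IIR notch (biquad), standard constant-Q design
notch_coef <- function(freq_hz, sample_rate_hz, q = 30) {
  w0 <- 2 * pi * freq_hz / sample_rate_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# forward-backward filtering of every row of a matrix
filtfilt_rows <- function(x, b, a) {
  t(apply(x, 1, function(row) signal::filtfilt(b, a, row)))
}

#' Broadband preprocessing of a raw recording
#'
#' Applies a 50 Hz notch (second-order IIR, quality factor 30) followed by a
#' 0.1-100 Hz Butterworth band-pass, both zero-phase (forward-backward), to
#' every channel. When the sample rate is too low for a 100 Hz upper edge,
#' the edge is clipped just below Nyquist. The band-pass is realized as a
#' high-pass / low-pass cascade so the very low 0.1 Hz edge stays numerically
#' well conditioned.
#'
#' @param recording a [raw_recording()].
#' @param notch_hz notch frequency (default 50 Hz mains).
#' @param band_hz broadband pass band (default `c(0.1, 100)` Hz).
#' @param notch_q notch quality factor.
#' @return A [raw_recording()] of identical shape.
#' @export
preprocess <- function(recording, notch_hz = 50, band_hz = c(0.1, 100),
                       notch_q = 30) {
  rate <- recording$sample_rate_hz
  nyq <- rate / 2
  x <- recording$signal
  if (notch_hz < nyq) {
    nc <- notch_coef(notch_hz, rate, notch_q)
    x <- filtfilt_rows(x, nc$b, nc$a)
  }
  hi <- min(band_hz[2], 0.95 * nyq)
  hp <- signal::butter(2, band_hz[1] / nyq, type = "high")
  lp <- signal::butter(4, hi / nyq, type = "low")
  x <- filtfilt_rows(x, hp$b, hp$a)
  x <- filtfilt_rows(x, lp$b, lp$a)
  raw_recording(x, rate, recording$channel_labels, recording$events)
}

#' Apply every band of a filter bank to one trial
#'
#' @param tr a [trial()] (or a [raw_recording()]: filtering a continuous
#'   recording before epoching avoids epoch-edge transients).
#' @param bank a [filter_bank()]; its design rate must match `sample_rate_hz`.
#' @param sample_rate_hz the trial's sample rate.
#' @return A list with one band-filtered copy of the input per band, same
#'   shape, same label and metadata, ordered as the bank's bands.
#' @export
apply_filter_bank <- function(tr, bank, sample_rate_hz) {
  if (!isTRUE(all.equal(sample_rate_hz, bank$sample_rate_hz)))
    stop_arg("trial sample rate (%g) does not match bank design rate (%g)",
             sample_rate_hz, bank$sample_rate_hz)
  x <- if (inherits(tr, "trial")) tr$data else tr$signal
  lapply(bank$coef, function(cf) {
    y <- filtfilt_rows(x, cf$b, cf$a)
    if (inherits(tr, "trial"))
      trial(y, tr$label, tr$subject_id, tr$session_id)
    else raw_recording(y, sample_rate_hz, tr$channel_labels, tr$events)
  })
}

#' Band-filter every trial of a set
#'
#' @param ts a [trial_set()].
#' @param bank a [filter_bank()].
#' @return A list of length `n_bands`; element `b` is the list of all trials
#'   filtered to band `b` (band-major layout).
#' @export
filter_bank_trials <- function(ts, bank) {
  per_trial <- lapply(ts$trials, apply_filter_bank, bank = bank,
                      sample_rate_hz = ts$sample_rate_hz)
  lapply(seq_along(bank$bands), function(b)
    lapply(per_trial, `[[`, b))
}
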