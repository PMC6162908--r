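# ---- validation helpers ------------------------------------------------

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

assert_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_arg("%s must be a numeric matrix", what)
  if (any(!is.finite(x)))
    stop_arg("%s contains non-finite values", what)
  invisible(x)
}

# ---- RawRecording ------------------------------------------------------

#' Construct a raw multi-channel recording
#'
#' A continuous (un-epoched) recording: a channels-by-samples signal matrix in
#' microvolts, its sample rate, channel labels, and a list of stimulus events
#' (`onset_sample`, 0-based, and a class `label`).
#'
#' @param signal numeric matrix, channels x samples (microvolts).
#' @param sample_rate_hz positive sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param events list of `list(onset_sample =, label =)` entries; onsets are
#'   0-based sample indices into `signal`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sample_rate_hz, channel_labels = NULL,
                          events = list()) {
  assert_finite_matrix(signal, "signal")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop_arg("sample_rate_hz must be a positive scalar")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    stop_arg("channel_labels length (%d) != channel count (%d)",
             length(channel_labels), nrow(signal))
  for (ev in events) {
    if (is.null(ev$onset_sample) || is.null(ev$label))
      stop_arg("each event needs onset_sample and label")
    if (ev$onset_sample < 0 || ev$onset_sample >= ncol(signal))
      stop_arg("event onset %d outside recording [0, %d)",
               ev$onset_sample, ncol(signal))
  }
  structure(list(signal = signal, sample_rate_hz = sample_rate_hz,
                 channel_labels = as.character(channel_labels),
                 events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$sample_rate_hz,
              length(x$events)))
  invisible(x)
}

# ---- Trial / TrialSet --------------------------------------------------

#' Construct a single epoched trial
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param label integer class id.
#' @param subject_id,session_id character metadata.
#' @return An object of class `trial`.
#' @export
trial <- function(data, label, subject_id = "", session_id = "") {
  assert_finite_matrix(data, "trial data")
  if (ncol(data) < 1L) stop_arg("trial must have at least one sample")
  if (length(label) != 1L || is.na(label)) stop_arg("label must be a scalar")
  structure(list(data = data, label = as.integer(label),
                 subject_id = as.character(subject_id),
                 session_id = as.character(session_id)),
            class = "trial")
}

#' Construct a set of epoched trials
#'
#' All trials must share channel and sample counts, and every label must be a
#' member of `class_set`. The order of `class_set` is meaningful: it fixes the
#' one-versus-rest class index and the order of classifier output units.
#'
#' @param trials list of [trial()] objects.
#' @param class_set ordered integer vector of class ids.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trials, class_set, sample_rate_hz) {
  if (!is.list(trials) || length(trials) < 1L)
    stop_arg("trials must be a non-empty list")
  if (!all(vapply(trials, inherits, logical(1), "trial")))
    stop_arg("all elements of trials must be trial objects")
  class_set <- as.integer(class_set)
  if (anyDuplicated(class_set)) stop_arg("class_set has duplicates")
  dims <- vapply(trials, function(tr) dim(tr$data), integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
    stop_arg("all trials must share channel and sample counts")
  labs <- vapply(trials, `[[`, integer(1), "label")
  if (!all(labs %in% class_set))
    stop_arg("trial labels outside declared class_set")
  if (sample_rate_hz <= 0) stop_arg("sample_rate_hz must be positive")
  structure(list(trials = trials, class_set = class_set,
                 sample_rate_hz = as.numeric(sample_rate_hz)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  labs <- trial_labels(x)
  cat(sprintf("<trial_set> L=%d trials, %d channels x %d samples @ %g Hz\n",
              length(x$trials), nrow(x$trials[[1]]$data),
              ncol(x$trials[[1]]$data), x$sample_rate_hz))
  cat("  classes:", paste(sprintf("%d (n=%d)", x$class_set,
                                  tabulate(match(labs, x$class_set),
                                           length(x$class_set))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Labels of all trials in a set
#' @param ts a [trial_set()].
#' @return Integer vector of length L.
#' @export
trial_labels <- function(ts) {
  vapply(ts$trials, `[[`, integer(1), "label")
}

# ---- Epoch extraction --------------------------------------------------

#' Extract an epoch around an event
#'
#' Cuts the window `[start, stop)` seconds, relative to the event onset, out
#' of a continuous recording. Sample indexing is 0-based and the epoch is
#' half-open in samples, so a `[4, 6]` s window at 250 Hz yields exactly
#' `round(2 * 250) = 500` samples. The epoch length depends only on the
#' window and the sample rate, never on the onset.
#'
#' @param recording a [raw_recording()].
#' @param event one element of `recording$events` (or any list with
#'   `onset_sample` and `label`).
#' @param window_s numeric length-2 vector `c(start, stop)` in seconds.
#' @param subject_id,session_id metadata copied onto the trial.
#' @return A [trial()] with `T = round((stop - start) * rate)` samples.
#' @export
extract_epoch <- function(recording, event, window_s,
                          subject_id = "", session_id = "") {
  if (length(window_s) != 2L || window_s[2] <= window_s[1])
    stop_arg("window_s must be c(start, stop) with stop > start")
  rate <- recording$sample_rate_hz
  first <- event$onset_sample + round(window_s[1] * rate)   # 0-based
  n <- round((window_s[2] - window_s[1]) * rate)
  if (first < 0 || first + n > ncol(recording$signal))
    stop_arg("epoch [%d, %d) outside recording of %d samples",
             first, first + n, ncol(recording$signal))
  trial(recording$signal[, (first + 1):(first + n), drop = FALSE],
        label = event$label, subject_id = subject_id,
        session_id = session_id)
}

#' Re-epoch every trial of a set to a sub-window
#'
#' Convenience for trial sets whose trials all start at the protocol origin
#' (t = 0 s): applies the same half-open `[start, stop)` second window to
#' each trial.
#'
#' @param ts a [trial_set()].
#' @param window_s numeric `c(start, stop)` in seconds relative to trial start.
#' @return A new [trial_set()] with shorter trials.
#' @export
epoch_trials <- function(ts, window_s) {
  rate <- ts$sample_rate_hz
  trials <- lapply(ts$trials, function(tr) {
    rec <- raw_recording(tr$data, rate)
    extract_epoch(rec, list(onset_sample = 0L, label = tr$label), window_s,
                  subject_id = tr$subject_id, session_id = tr$session_id)
  })
  trial_set(trials, ts$class_set, rate)
}

# ---- Trial container I/O ----------------------------------------------

CONTAINER_FORMAT <- "fbcsprnn-trialset"
CONTAINER_VERSION <- 1L

#' Write a trial set to a portable container file
#'
#' The container is a single self-describing file holding, for each trial,
#' its data matrix and label/subject/session attributes, plus the root
#' attributes `class_set` and `sample_rate_hz`. [read_trialset()] inverts it
#' bit-exactly.
#'
#' @param ts a [trial_set()] satisfying its invariants.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_trialset <- function(ts, path) {
  if (!inherits(ts, "trial_set")) stop_arg("ts must be a trial_set")
  # revalidate: the constructor's invariants must hold at write time
  ts <- trial_set(ts$trials, ts$class_set, ts$sample_rate_hz)
  obj <- list(format = CONTAINER_FORMAT, version = CONTAINER_VERSION,
              class_set = ts$class_set, sample_rate_hz = ts$sample_rate_hz,
              trials = lapply(ts$trials, function(tr)
                list(data = tr$data, label = tr$label,
                     subject_id = tr$subject_id, session_id = tr$session_id)))
  ok <- tryCatch({ saveRDS(obj, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_arg("cannot write trial container to '%s'", path)
  invisible(path)
}

#' Read a trial set container
#'
#' @param path a file written by [write_trialset()].
#' @return The stored [trial_set()], field-by-field identical to what was
#'   written.
#' @export
read_trialset <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: '%s'", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_arg("'%s' is not a readable trial container: %s", path,
             conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, CONTAINER_FORMAT))
    stop_arg("'%s' is not a %s container", path, CONTAINER_FORMAT)
  if (is.null(obj$class_set) || is.null(obj$sample_rate_hz) ||
      is.null(obj$trials))
    stop_arg("container '%s' is missing required attributes", path)
  trials <- lapply(obj$trials, function(rec)
    trial(rec$data, rec$label, rec$subject_id, rec$session_id))
  trial_set(trials, obj$class_set, obj$sample_rate_hz)
}

# ---- GDF import --------------------------------------------------------

#' Import a GDF biosignal recording
#'
#' Bridges to the Python `mne` library (if available on the PATH) to read a
#' GDF file, the container used by the BCI Competition IV recordings, and
#' returns it as a [raw_recording()]. Event onsets are converted to 0-based
#' sample indices. With `eeg_channels_only = TRUE`, channels whose type is
#' EOG are dropped (they are excluded from all analysis by default).
#'
#' @param path a GDF file.
#' @param eeg_channels_only drop non-EEG channels (default `TRUE`).
#' @param python name/path of the python interpreter.
#' @return A [raw_recording()].
#' @export
import_gdf <- function(path, eeg_channels_only = TRUE, python = "python") {
  if (!file.exists(path)) stop_arg("no such file: '%s'", path)
  if (Sys.which(python) == "")
    stop_arg("python interpreter '%s' not found; GDF import unavailable",
             python)
  out_dir <- tempfile("gdf")
  dir.create(out_dir)
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  script <- file.path(out_dir, "convert.py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "import mne",
    "path, out_dir, eeg_only = sys.argv[1], sys.argv[2], sys.argv[3] == '1'",
    "raw = mne.io.read_raw_gdf(path, preload=True, verbose='error')",
    "if eeg_only:",
    "    raw.pick(picks='eeg', verbose='error')",
    "sig = raw.get_data(units='uV').astype('float64')",
    "events, event_id = mne.events_from_annotations(raw, verbose='error')",
    "hdr = {'sample_rate_hz': float(raw.info['sfreq']),",
    "       'channel_labels': list(raw.ch_names),",
    "       'n_channels': int(sig.shape[0]),",
    "       'n_samples': int(sig.shape[1]),",
    "       'events': [{'onset_sample': int(e[0]), 'label': int(e[2])}",
    "                  for e in events]}",
    "sig.T.tofile(out_dir + '/signal.bin')",  # column-major channels-fast
    "with open(out_dir + '/header.json', 'w') as fh:",
    "    json.dump(hdr, fh)"
  ), script)
  res <- suppressWarnings(system2(python, c(script, shQuote(path), out_dir,
                                            if (eeg_channels_only) "1" else "0"),
                                  stdout = TRUE, stderr = TRUE))
  hdr_path <- file.path(out_dir, "header.json")
  if (!file.exists(hdr_path))
    stop_arg("GDF import of '%s' failed: %s", path,
             paste(res, collapse = " | "))
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  sig <- readBin(file.path(out_dir, "signal.bin"), what = "double",
                 n = hdr$n_channels * hdr$n_samples)
  sig <- matrix(sig, nrow = hdr$n_channels, ncol = hdr$n_samples)
  events <- list()
  if (length(hdr$events) && nrow(as.data.frame(hdr$events)) > 0) {
    ev <- as.data.frame(hdr$events)
    events <- lapply(seq_len(nrow(ev)), function(i)
      list(onset_sample = ev$onset_sample[i], label = ev$label[i]))
    events <- Filter(function(e) e$onset_sample < hdr$n_samples, events)
  }
  raw_recording(sig, hdr$sample_rate_hz, hdr$channel_labels, events)
}
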