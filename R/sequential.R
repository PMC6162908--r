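# Smoothing time windows on spatial-frequency features and the
# sliding-window cropping strategy that turns one labelled trial into many
# labelled time slices.

#' Causal moving-average smoothing of a feature series
#'
#' Each output sample is the mean of the current and previous `omega`
#' samples (`omega + 1` terms). At the left edge, where fewer samples exist,
#' the divisor shrinks to the number of available terms, so constants are
#' fixed points and there is no onset attenuation. `omega = 0` is the
#' identity.
#'
#' `literal = TRUE` keeps the full `omega + 1`-term sum but divides by
#' `omega` instead — a historical variant retained for comparison; it
#' rescales constants by `(omega + 1) / omega` and requires `omega >= 1`.
#'
#' @param Z a [feature_series()] (or bare D x T matrix).
#' @param omega non-negative integer smoothing window size, in samples.
#' @param literal use the divisor-`omega` variant.
#' @return The smoothed object, same type and shape as the input.
#' @export
smooth_features <- function(Z, omega, literal = FALSE) {
  if (omega < 0) stop_arg("omega must be >= 0")
  omega <- as.integer(omega)
  x <- if (inherits(Z, "feature_series")) Z$values else Z
  if (omega == 0L && !literal) return(Z)
  if (literal && omega == 0L)
    stop_arg("the literal divisor-omega form is undefined for omega = 0")
  tt <- ncol(x)
  w <- min(omega + 1L, tt)
  # running sums of the trailing (omega+1)-sample window, per row
  cs <- t(apply(x, 1, cumsum))
  if (tt == 1L) cs <- matrix(cs, nrow = nrow(x))
  out <- cs
  if (w < tt)
    out[, (w + 1L):tt] <- cs[, (w + 1L):tt, drop = FALSE] -
      cs[, 1:(tt - w), drop = FALSE]
  div <- if (literal) rep(omega, tt) else pmin(seq_len(tt), omega + 1L)
  if (literal) div[seq_len(min(omega, tt))] <- omega  # same divisor at edge
  out <- sweep(out, 2, div, "/")
  if (inherits(Z, "feature_series"))
    feature_series(out, Z$label, Z$trial_id, Z$layout)
  else out
}

#' Construct a time slice
#'
#' @param values D x tau numeric matrix of contiguous feature columns.
#' @param label class id inherited from the source trial.
#' @param trial_id source trial identifier.
#' @param offset 0-based start sample of the slice within the trial.
#' @return An object of class `time_slice`.
#' @export
time_slice <- function(values, label, trial_id = NA, offset = 0L) {
  assert_finite_matrix(values, "slice values")
  structure(list(values = values, label = as.integer(label),
                 trial_id = trial_id, offset = as.integer(offset)),
            class = "time_slice")
}

#' Crop a feature series into sliding-window time slices
#'
#' Cuts `tau`-column windows starting at offsets `0, stride, 2 stride, ...`
#' up to `T - tau - 1`, each inheriting the trial's label. With stride 1
#' this produces exactly `T - tau` slices — a 500-sample trial cropped at
#' `tau = 20` yields 480 slices — multiplying the number of labelled
#' training samples by `T - tau`.
#'
#' @param Z a [feature_series()].
#' @param tau slice length in samples, `1 <= tau < T`.
#' @param stride offset increment between consecutive slices.
#' @return A list of [time_slice()] objects.
#' @export
crop_slices <- function(Z, tau, stride = 1L) {
  x <- Z$values
  tt <- ncol(x)
  if (tau < 1L || tau >= tt)
    stop_arg("need 1 <= tau < T (tau = %d, T = %d)", tau, tt)
  if (stride < 1L) stop_arg("stride must be >= 1")
  offsets <- seq(0L, tt - tau - 1L, by = as.integer(stride))
  lapply(offsets, function(o)
    time_slice(x[, (o + 1L):(o + tau), drop = FALSE], Z$label,
               Z$trial_id, o))
}

#' Crop many feature series and stack the slices into one array
#'
#' Training-oriented bulk form of [crop_slices()]: crops every series and
#' returns the slices as a single D x tau x B array with aligned labels.
#'
#' @param feature_list list of [feature_series()].
#' @param tau,stride as in [crop_slices()].
#' @return List with `x` (D x tau x B array), `y` (length-B integer labels),
#'   `trial_id`, `offset` vectors.
#' @export
crop_slices_array <- function(feature_list, tau, stride = 1L) {
  slices <- unlist(lapply(feature_list, crop_slices, tau = tau,
                          stride = stride),
                   recursive = FALSE)
  slices_to_array(slices)
}

#' Stack a list of time slices into an array
#'
#' @param slices list of [time_slice()] objects sharing D and tau.
#' @return List with `x` (D x tau x B), `y`, `trial_id`, `offset`.
#' @export
slices_to_array <- function(slices) {
  if (length(slices) == 0L) stop_arg("no slices")
  d <- nrow(slices[[1]]$values); tau <- ncol(slices[[1]]$values)
  x <- array(0, dim = c(d, tau, length(slices)))
  for (i in seq_along(slices)) x[, , i] <- slices[[i]]$values
  list(x = x,
       y = vapply(slices, `[[`, integer(1), "label"),
       trial_id = lapply(slices, `[[`, "trial_id"),
       offset = vapply(slices, `[[`, integer(1), "offset"))
}
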