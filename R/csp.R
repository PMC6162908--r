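# Common spatial patterns per band, one-versus-rest multi-class extension,
# projection to spatial-frequency feature series, and log band-power features.

#' Average normalized class covariance
#'
#' Each trial is mean-centered per channel, its covariance `X X'` is
#' normalized by its trace (removing trial-amplitude confounds), and the
#' normalized covariances are averaged over all trials of the class.
#'
#' @param trials list of band-filtered [trial()] objects.
#' @param class_id class whose trials enter the average.
#' @return An object of class `covariance_estimate` with fields `matrix`
#'   (symmetric positive semi-definite N x N), `class_id`, `n_trials`.
#' @export
class_covariance <- function(trials, class_id) {
  sel <- Filter(function(tr) tr$label == class_id, trials)
  if (length(sel) == 0L)
    stop_arg("no trials of class %s", as.character(class_id))
  n <- nrow(sel[[1]]$data)
  acc <- matrix(0, n, n)
  for (tr in sel) {
    x <- tr$data - rowMeans(tr$data)
    cm <- tcrossprod(x)
    tr_cm <- sum(diag(cm))
    if (tr_cm > 0) cm <- cm / tr_cm
    acc <- acc + cm
  }
  m <- acc / length(sel)
  m <- (m + t(m)) / 2
  structure(list(matrix = m, class_id = class_id, n_trials = length(sel)),
            class = "covariance_estimate")
}

cov_matrix <- function(x) if (inherits(x, "covariance_estimate")) x$matrix else x

shrink_cov <- function(C, gamma) {
  n <- nrow(C)
  (1 - gamma) * C + gamma * (sum(diag(C)) / n) * diag(n)
}

#' Fit a binary CSP spatial filter set
#'
#' Maximizes the Rayleigh quotient `w' C1 w / w' C2 w` over spatial filters
#' `w`, equivalently solving the generalized eigenproblem
#' `C1 w = lambda (C1 + C2) w` by whitening the composite covariance. The
#' eigenvalues lie in `[0, 1]` and are returned sorted descending; the
#' projection keeps the eigenvectors of the `m` largest and `m` smallest
#' eigenvalues (most discriminative in either direction). Every filter row
#' satisfies `w' (C1 + C2) w = 1`, and each row's sign is fixed so its
#' largest-magnitude coefficient is positive.
#'
#' @param C1,C2 [class_covariance()] estimates (or plain symmetric matrices)
#'   of the two classes, same dimension.
#' @param m filters kept per extreme; `2 m <= N`.
#' @param gamma shrinkage weight toward the scaled identity applied to each
#'   covariance before solving (guards near-singular composites).
#' @param band_index,ovr_class bookkeeping copied onto the result.
#' @return An object of class `csp_filters` with fields `projection`
#'   (`2m x N`, rows = spatial filters), `eigenvalues` (length N,
#'   descending), `m`, `band_index`, `ovr_class`.
#' @export
fit_csp <- function(C1, C2, m, gamma = 1e-6, band_index = NA_integer_,
                    ovr_class = NA_integer_) {
  A <- shrink_cov(cov_matrix(C1), gamma)
  B <- shrink_cov(cov_matrix(C2), gamma)
  n <- nrow(A)
  if (!all(dim(A) == dim(B))) stop_arg("C1 and C2 must have the same dimension")
  if (2 * m > n) stop_arg("2m = %d exceeds channel count N = %d", 2 * m, n)
  comp <- A + B
  ec <- eigen(comp, symmetric = TRUE)
  tol <- max(ec$values) * 1e-12
  if (any(ec$values <= tol))
    stop_arg("composite covariance is singular after regularization")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitening: P comp P' = I
  S1 <- P %*% A %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  es <- eigen(S1, symmetric = TRUE)                  # values descending
  lambda <- pmin(pmax(es$values, 0), 1)
  W <- t(P) %*% es$vectors                           # columns: w with w'comp w = 1
  keep <- c(seq_len(m), seq(n - m + 1, n))
  proj <- t(W[, keep, drop = FALSE])
  # deterministic sign: largest-|coefficient| positive
  for (i in seq_len(nrow(proj))) {
    j <- which.max(abs(proj[i, ]))
    if (proj[i, j] < 0) proj[i, ] <- -proj[i, ]
  }
  structure(list(projection = proj, eigenvalues = lambda, m = as.integer(m),
                 band_index = band_index, ovr_class = ovr_class),
            class = "csp_filters")
}

#' @export
print.csp_filters <- function(x, ...) {
  cat(sprintf("<csp_filters> %d x %d (m=%d), band=%s, ovr_class=%s\n",
              nrow(x$projection), ncol(x$projection), x$m,
              as.character(x$band_index), as.character(x$ovr_class)))
  invisible(x)
}

# pooled covariance of all classes except `class_id`, weighted by trial counts
pooled_rest_covariance <- function(cov_by_class, class_id) {
  rest <- Filter(function(ce) ce$class_id != class_id, cov_by_class)
  w <- vapply(rest, `[[`, integer(1), "n_trials")
  acc <- Reduce(`+`, Map(function(ce, wi) wi * ce$matrix, rest, w))
  structure(list(matrix = acc / sum(w), class_id = NA_integer_,
                 n_trials = sum(w)),
            class = "covariance_estimate")
}

#' Fit filter-bank CSP on a trial set
#'
#' Band-filters all trials, then fits CSP within each band. With two classes
#' one binary filter set per band is fitted (first class vs second, in
#' `class_set` order). With more classes the one-versus-rest extension fits
#' one set per (band, class): the class covariance against the pooled
#' covariance of all remaining classes (weighted by their trial counts).
#' Filter sets are ordered band-major, then by class.
#'
#' @param ts a [trial_set()] with at least two classes, none empty.
#' @param bank a [filter_bank()].
#' @param m filters per extreme (2 for 22-channel montages, 1 for 3-channel
#'   bipolar montages are the conventional choices).
#' @param gamma shrinkage passed to [fit_csp()].
#' @return A list of [fit_csp()] results (`n_bands` for two classes,
#'   `n_bands * n_classes` otherwise).
#' @export
fit_fbcsp <- function(ts, bank, m, gamma = 1e-6) {
  classes <- ts$class_set
  if (length(classes) < 2L) stop_arg("need at least 2 classes")
  labs <- trial_labels(ts)
  for (cl in classes)
    if (!any(labs == cl)) stop_arg("no trials of class %d", cl)
  by_band <- filter_bank_trials(ts, bank)
  sets <- list()
  for (b in seq_along(by_band)) {
    cov_by_class <- lapply(classes, function(cl)
      class_covariance(by_band[[b]], cl))
    if (length(classes) == 2L) {
      sets[[length(sets) + 1L]] <-
        fit_csp(cov_by_class[[1]], cov_by_class[[2]], m, gamma,
                band_index = b, ovr_class = NA_integer_)
    } else {
      for (k in seq_along(classes)) {
        rest <- pooled_rest_covariance(cov_by_class, classes[k])
        sets[[length(sets) + 1L]] <-
          fit_csp(cov_by_class[[k]], rest, m, gamma,
                  band_index = b, ovr_class = classes[k])
      }
    }
  }
  sets
}

#' Project band-filtered trials through CSP filter sets
#'
#' Applies `Z = W X` for every filter set and stacks all sets' rows in the
#' deterministic band-major (then class) layout. The row layout is recorded
#' on the result so feature rows stay self-describing.
#'
#' @param band_trials list over bands; element `b` holds the band-`b`
#'   filtered [trial()] (as produced by [apply_filter_bank()]).
#' @param filter_sets list of [fit_csp()] results whose `band_index` fields
#'   index into `band_trials`.
#' @return An object of class `feature_series`: `values` (D x T), `label`,
#'   `trial_id`, and a `layout` data frame (band, ovr_class, component).
#' @export
project_features <- function(band_trials, filter_sets) {
  first <- band_trials[[1]]
  lab <- if (inherits(first, "trial")) first$label else NA_integer_
  rows <- list(); layout <- list()
  for (fs in filter_sets) {
    b <- fs$band_index
    if (is.na(b) || b > length(band_trials))
      stop_arg("filter set band_index %s out of range", as.character(b))
    x <- band_trials[[b]]
    x <- if (inherits(x, "trial")) x$data else x
    if (ncol(fs$projection) != nrow(x))
      stop_arg("filter set expects %d channels, trial has %d",
               ncol(fs$projection), nrow(x))
    rows[[length(rows) + 1L]] <- fs$projection %*% x
    layout[[length(layout) + 1L]] <-
      data.frame(band = b, ovr_class = fs$ovr_class,
                 component = seq_len(nrow(fs$projection)))
  }
  feature_series(do.call(rbind, rows), label = lab,
                 layout = do.call(rbind, layout))
}

#' Construct a feature series
#'
#' @param values D x T numeric matrix of per-time-step feature vectors.
#' @param label class id inherited from the source trial (NA if unlabeled).
#' @param trial_id identifier of the source trial.
#' @param layout data frame naming each row (band, ovr_class, component).
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, label = NA_integer_, trial_id = NA,
                           layout = NULL) {
  assert_finite_matrix(values, "feature values")
  if (is.null(layout))
    layout <- data.frame(band = NA_integer_, ovr_class = NA_integer_,
                         component = seq_len(nrow(values)))
  if (nrow(layout) != nrow(values))
    stop_arg("layout rows (%d) != feature rows (%d)", nrow(layout),
             nrow(values))
  structure(list(values = values, label = as.integer(label),
                 trial_id = trial_id, layout = layout),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> D=%d rows x T=%d, label=%s\n",
              nrow(x$values), ncol(x$values), as.character(x$label)))
  invisible(x)
}

#' Extract spatial-frequency feature series for every trial of a set
#'
#' @param ts a [trial_set()].
#' @param bank the [filter_bank()] used to fit `filter_sets`.
#' @param filter_sets output of [fit_fbcsp()].
#' @return A list of [feature_series()], one per trial, in trial order.
#' @export
fbcsp_features <- function(ts, bank, filter_sets) {
  lapply(seq_along(ts$trials), function(i) {
    bands <- apply_filter_bank(ts$trials[[i]], bank, ts$sample_rate_hz)
    fs <- project_features(bands, filter_sets)
    fs$trial_id <- i
    fs
  })
}

#' Log band-power features of a feature series
#'
#' The classical CSP feature vector: per row, the variance over time,
#' normalized by the sum of variances within the row's filter set, then
#' log-transformed. Zero variances are floored at machine epsilon (with a
#' warning) so the log stays finite. With `normalize = FALSE` the raw log
#' variances are returned.
#'
#' @param Z a [feature_series()] whose layout groups rows into filter sets
#'   (one set per distinct band/ovr_class pair).
#' @param normalize normalize variances within each filter set (default).
#' @return Numeric feature vector of length D.
#' @export
logvar_features <- function(Z, normalize = TRUE) {
  x <- Z$values
  if (ncol(x) < 2L) stop_arg("need at least 2 samples to form variances")
  v <- apply(x, 1, stats::var)
  if (any(v <= 0)) {
    warning("zero-variance feature row(s) floored at machine epsilon")
    v <- pmax(v, .Machine$double.eps)
  }
  if (normalize) {
    ovr <- Z$layout$ovr_class
    ovr[is.na(ovr)] <- 0L
    band <- Z$layout$band
    band[is.na(band)] <- 0L
    grp <- interaction(band, ovr, drop = TRUE, lex.order = TRUE)
    sums <- tapply(v, grp, sum)[grp]
    v <- v / as.numeric(sums)
  }
  log(v)
}
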