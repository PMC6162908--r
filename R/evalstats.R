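# SVM band-power baseline, misclassification metrics, and the paired
# t-test protocol used to compare classification methods across subjects.

#' Cross-validated SVM baseline on band-power features
#'
#' A kernel support-vector classifier on log band-power feature vectors,
#' evaluated by stratified k-fold cross-validation (multi-class problems
#' are handled one-versus-rest-consistently by the underlying SVM). With
#' `folds < 2` the training error is reported instead.
#'
#' Hyperparameters follow common defaults: cost 1, RBF
#' `gamma = 1 / (D * var(features))`, polynomial degree 3; they are
#' recorded on the result.
#'
#' @param features numeric matrix, one row per trial.
#' @param labels class ids, one per row.
#' @param kernel one of `"linear"`, `"polynomial"`, `"rbf"`.
#' @param folds number of CV folds (default 5).
#' @param cost,gamma,degree SVM hyperparameters (`gamma = NULL` uses the
#'   default above).
#' @param seed seed for the fold assignment.
#' @return List with `error_rate` (%), `fold_rates`, `variance` (sample
#'   variance of per-fold rates), and `params`.
#' @export
svm_baseline <- function(features, labels, kernel = "rbf", folds = 5L,
                         cost = 1, gamma = NULL, degree = 3, seed = 1L) {
  if (!kernel %in% c("linear", "polynomial", "rbf"))
    stop_arg("unknown kernel '%s' (use linear, polynomial or rbf)", kernel)
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop_arg("need at least 2 classes")
  if (min(table(labels)) < 2L) stop_arg("need >= 2 samples per class")
  if (is.null(gamma)) {
    v <- stats::var(as.numeric(features))
    gamma <- 1 / (ncol(features) * max(v, .Machine$double.eps))
  }
  e1071_kernel <- c(linear = "linear", polynomial = "polynomial",
                    rbf = "radial")[[kernel]]
  fit_pred <- function(tr_idx, te_idx) {
    fit <- e1071::svm(features[tr_idx, , drop = FALSE], labels[tr_idx],
                      kernel = e1071_kernel, cost = cost, gamma = gamma,
                      degree = degree, scale = FALSE)
    pred <- stats::predict(fit, features[te_idx, , drop = FALSE])
    100 * mean(pred != labels[te_idx])
  }
  if (folds < 2L) {
    rate <- fit_pred(seq_len(nrow(features)), seq_len(nrow(features)))
    return(list(error_rate = rate, fold_rates = rate, variance = 0,
                params = list(kernel = kernel, cost = cost, gamma = gamma,
                              degree = degree, folds = folds)))
  }
  fold_of <- withr::with_seed(seed, {
    f <- integer(length(labels))
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  fold_rates <- vapply(seq_len(folds), function(k)
    fit_pred(which(fold_of != k), which(fold_of == k)), numeric(1))
  list(error_rate = mean(fold_rates), fold_rates = fold_rates,
       variance = stats::var(fold_rates),
       params = list(kernel = kernel, cost = cost, gamma = gamma,
                     degree = degree, folds = folds))
}

#' Misclassification rate (and its variance across folds)
#'
#' @param predicted,true equal-length label vectors.
#' @param folds optional fold/session assignment; when given, per-fold
#'   rates and their sample variance are reported.
#' @return List with `rate` (percent), and with folds also `fold_rates`
#'   and `variance`.
#' @export
misclassification_rate <- function(predicted, true, folds = NULL) {
  if (length(predicted) != length(true))
    stop_arg("predicted and true differ in length (%d vs %d)",
             length(predicted), length(true))
  rate <- 100 * mean(predicted != true)
  out <- list(rate = rate)
  if (!is.null(folds)) {
    if (length(folds) != length(true))
      stop_arg("folds length mismatch")
    fr <- vapply(split(seq_along(true), folds), function(ix)
      100 * mean(predicted[ix] != true[ix]), numeric(1))
    out$fold_rates <- fr
    out$variance <- if (length(fr) > 1L) stats::var(fr) else 0
  }
  out
}

#' Two-sided paired t-test on per-subject error rates
#'
#' Classical paired t statistic on the differences, with `n - 1` degrees
#' of freedom. Degenerate zero-variance differences are handled explicitly:
#' identical rates give `p = 1`, a constant non-zero difference is flagged
#' degenerate with `p = 0`.
#'
#' @param rates_a,rates_b equal-length (>= 2) per-subject rate vectors.
#' @return List with `statistic` (t), `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_ttest <- function(rates_a, rates_b) {
  if (length(rates_a) != length(rates_b))
    stop_arg("rate vectors differ in length (%d vs %d)", length(rates_a),
             length(rates_b))
  if (length(rates_a) < 2L) stop_arg("need at least 2 paired observations")
  d <- rates_a - rates_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = 0, df = length(d) - 1L, p_value = 1,
                  mean_diff = 0, degenerate = TRUE))
    return(list(statistic = Inf * sign(mean(d)), df = length(d) - 1L,
                p_value = 0, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(rates_a, rates_b, paired = TRUE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Build an evaluation report
#'
#' @param per_subject data frame with columns `subject`, `method`,
#'   `error_rate`, `variance`, and optionally `onhl`.
#' @param comparisons optional data frame of method pairs and p-values
#'   (from [compare_methods()]).
#' @param meta optional provenance list.
#' @return Object of class `eval_report`.
#' @export
eval_report <- function(per_subject, comparisons = NULL, meta = list()) {
  stopifnot(all(c("subject", "method", "error_rate") %in%
                  colnames(per_subject)))
  if (any(per_subject$error_rate < 0 | per_subject$error_rate > 100))
    stop_arg("error rates must lie in [0, 100]")
  structure(list(per_subject = per_subject, comparisons = comparisons,
                 meta = meta),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  agg <- stats::aggregate(error_rate ~ method, data = x$per_subject, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s: mean error %.2f%%\n", agg$method[i],
                agg$error_rate[i]))
  if (!is.null(x$comparisons) && nrow(x$comparisons))
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("  %s vs %s: p = %.4g\n", x$comparisons$method_a[i],
                  x$comparisons$method_b[i], x$comparisons$p_value[i]))
  invisible(x)
}

#' Pairwise paired t-tests between methods in a rate table
#'
#' @param rates data frame with columns `subject`, `method`, `error_rate`
#'   (one row per subject x method).
#' @return Data frame `method_a`, `method_b`, `t`, `df`, `p_value`.
#' @export
compare_methods <- function(rates) {
  methods <- unique(rates$method)
  out <- data.frame()
  if (length(methods) < 2L) return(out)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  for (pr in pairs) {
    a <- rates[rates$method == pr[1], ]
    b <- rates[rates$method == pr[2], ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    common <- intersect(a$subject, b$subject)
    tt <- paired_ttest(a$error_rate[a$subject %in% common],
                       b$error_rate[b$subject %in% common])
    out <- rbind(out, data.frame(method_a = pr[1], method_b = pr[2],
                                 t = tt$statistic, df = tt$df,
                                 p_value = tt$p_value))
  }
  out
}

#' Serialize an evaluation report to CSV (per-subject rows) and JSON
#' (summary + comparisons)
#'
#' @param report an [eval_report()].
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_subject, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    agg <- stats::aggregate(error_rate ~ method, data = report$per_subject,
                            mean)
    obj <- list(summary = agg, comparisons = report$comparisons,
                meta = report$meta)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
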