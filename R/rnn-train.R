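# Training (BPTT + Adam + dropout), trial-level prediction by slice
# averaging, autoregressive signal prediction, and the hidden-depth sweep
# that selects the cropping size.

#' Logarithmic cross-entropy loss
#'
#' Categorical cross-entropy `-log p[target]`, averaged over the batch.
#' With two classes this coincides with the binary form
#' `-(c log p + (1 - c) log(1 - p))` because the two probabilities sum to
#' one. Probabilities are clipped to `[1e-12, 1 - 1e-12]` before the log.
#'
#' @param pred_probs probability vector (one example), matrix with one
#'   column per example, or matrix with one row per example when targets
#'   have matching length.
#' @param target integer class indices (1-based into the probability rows).
#' @return Mean loss, a non-negative scalar.
#' @export
cross_entropy <- function(pred_probs, target) {
  if (is.null(dim(pred_probs)))
    pred_probs <- matrix(pred_probs, ncol = 1)
  if (ncol(pred_probs) != length(target) && nrow(pred_probs) == length(target))
    pred_probs <- t(pred_probs)
  p <- pred_probs[cbind(target, seq_along(target))]
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  mean(-log(p))
}

# ---- loss + gradient on one batch -------------------------------------

# X: D x tau x B; y: class indices (softmax) or K x B target matrix
# (linear head, mean squared error). Returns loss and parameter grads.
rnn_loss_grad <- function(model, X, y, masks = NULL, head_mask = NULL) {
  fwd <- rnn_forward(model, X, masks = masks, head_mask = head_mask,
                     cache = TRUE)
  b <- dim(X)[3]
  if (model$head == "softmax") {
    loss <- cross_entropy(fwd$out, y)
    d_logits <- fwd$out
    d_logits[cbind(y, seq_len(b))] <- d_logits[cbind(y, seq_len(b))] - 1
    d_logits <- d_logits / b
  } else {
    err <- fwd$out - y
    loss <- mean(err^2)
    d_logits <- 2 * err / length(err)
  }
  list(loss = loss, grads = rnn_backward(model, fwd, d_logits), out = fwd$out)
}

adam_init <- function(params)
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0), t = 0L)

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] +
      (1 - cfg$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + cfg$epsilon)
  }
  list(params = params, state = state)
}

slice_input <- function(slices) {
  if (is.list(slices) && !is.null(slices$x)) slices
  else slices_to_array(slices)
}

make_dropout_masks <- function(d, tau, b, h, rate) {
  if (rate <= 0) return(list(masks = NULL, head_mask = NULL))
  keep <- 1 - rate
  masks <- lapply(seq_len(tau), function(t)
    matrix(stats::rbinom(d * b, 1, keep), d, b) / keep)
  head_mask <- matrix(stats::rbinom(h * b, 1, keep), h, b) / keep
  list(masks = masks, head_mask = head_mask)
}

#' Train a recurrent model on labelled time slices
#'
#' Mini-batch backpropagation through time with the Adam optimizer.
#' Dropout is applied to the non-recurrent connections (slice inputs and
#' the head input) during training only. Training runs exactly
#' `cfg$max_iterations` epochs over the slices — no early stopping — and a
#' per-epoch trace of training/validation loss and accuracy is recorded.
#' The run is deterministic given `cfg$seed`.
#'
#' For signal-prediction mode (`cfg$head == "linear"`), pass targets as a
#' `K x B` matrix in `y` (and in `val$y`); the loss is the mean squared
#' error.
#'
#' @param model an [init_model()] result (trained in place, functionally).
#' @param slices training slices: a list of [time_slice()] objects or the
#'   array form from [slices_to_array()].
#' @param val_slices optional validation slices, same forms.
#' @param cfg the [rnn_config()] used for training.
#' @return List with `model` (trained) and `trace` (class
#'   `training_trace`: data frame with one row per epoch).
#' @export
train_rnn <- function(model, slices, val_slices = NULL, cfg = model$config) {
  tr <- slice_input(slices)
  if (dim(tr$x)[3] == 0L) stop_arg("empty training set")
  if (model$head == "softmax") {
    y <- match(tr$y, model$class_order)
    if (any(is.na(y))) stop_arg("training labels outside model class order")
  } else y <- tr$y
  val <- NULL
  if (!is.null(val_slices)) {
    va <- slice_input(val_slices)
    vy <- if (model$head == "softmax") match(va$y, model$class_order)
          else va$y
    val <- list(x = va$x, y = vy)
  }
  n <- dim(tr$x)[3]
  d <- dim(tr$x)[1]
  state <- adam_init(model$params)
  trace <- data.frame(epoch = seq_len(cfg$max_iterations),
                      train_loss = NA_real_, train_acc = NA_real_,
                      val_loss = NA_real_, val_acc = NA_real_)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$max_iterations)) {
      idx <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- tr$x[, , bi, drop = FALSE]
        yb <- if (model$head == "softmax") y[bi] else y[, bi, drop = FALSE]
        dm <- make_dropout_masks(d, model$tau, length(bi), model$hidden,
                                 cfg$dropout)
        lg <- rnn_loss_grad(model, Xb, yb, dm$masks, dm$head_mask)
        upd <- adam_step(model$params, lg$grads, state, cfg)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(bi)
        if (model$head == "softmax")
          ep_correct <- ep_correct + sum(apply(lg$out, 2, which.max) == yb)
      }
      trace$train_loss[ep] <- ep_loss / n
      trace$train_acc[ep] <- if (model$head == "softmax") ep_correct / n
                             else NA_real_
      if (!is.null(val)) {
        ev <- evaluate_slices(model, val$x, val$y)
        trace$val_loss[ep] <- ev$loss
        trace$val_acc[ep] <- ev$acc
      }
    }
  })
  class(trace) <- c("training_trace", "data.frame")
  list(model = model, trace = trace)
}

# loss/accuracy of a model on a slice array (no dropout)
evaluate_slices <- function(model, X, y) {
  out <- rnn_forward(model, X)$out
  if (model$head == "softmax") {
    list(loss = cross_entropy(out, y),
         acc = mean(apply(out, 2, which.max) == y))
  } else {
    list(loss = mean((out - y)^2), acc = NA_real_)
  }
}

#' Write a training trace to CSV
#' @param trace a `training_trace` from [train_rnn()].
#' @param path output CSV path.
#' @export
write_training_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

# ---- trial-level prediction -------------------------------------------

#' Classify a whole trial by averaging its slice predictions
#'
#' Crops the feature series into sliding-window slices, scores every slice,
#' averages the probability vectors, and returns the class with the
#' highest mean probability (ties broken toward the lowest class index).
#'
#' @param model a trained softmax-head [init_model()].
#' @param Z a [feature_series()] with `T > tau` columns.
#' @param tau slice length (defaults to the model's unroll depth).
#' @param stride slice offset increment.
#' @return An object of class `prediction_aggregate`: `slice_probs`
#'   (slices x classes), `mean_probs`, `final_label`.
#' @export
predict_trial <- function(model, Z, tau = model$tau, stride = 1L) {
  if (model$head != "softmax")
    stop_arg("predict_trial needs a classification (softmax) model")
  if (ncol(Z$values) <= tau)
    stop_arg("trial length %d must exceed tau = %d", ncol(Z$values), tau)
  arr <- crop_slices_array(list(Z), tau, stride)
  out <- rnn_forward(model, arr$x)$out           # K x B
  slice_probs <- t(out)
  colnames(slice_probs) <- as.character(model$class_order)
  mean_probs <- colMeans(slice_probs)
  final <- model$class_order[which.max(mean_probs)]
  structure(list(slice_probs = slice_probs, mean_probs = mean_probs,
                 final_label = final),
            class = "prediction_aggregate")
}

#' @export
print.prediction_aggregate <- function(x, ...) {
  cat(sprintf("<prediction_aggregate> %d slices, mean probs [%s] -> class %d\n",
              nrow(x$slice_probs),
              paste(sprintf("%.3f", x$mean_probs), collapse = ", "),
              x$final_label))
  invisible(x)
}

#' Classify every trial of a feature list
#'
#' @param model trained softmax model.
#' @param feature_list list of [feature_series()].
#' @param tau,stride as in [predict_trial()].
#' @return Integer vector of predicted class ids.
#' @export
predict_trials <- function(model, feature_list, tau = model$tau,
                           stride = 1L) {
  vapply(feature_list, function(Z)
    predict_trial(model, Z, tau, stride)$final_label, integer(1))
}

# ---- autoregressive signal prediction ---------------------------------

#' Autoregressive continuation of a signal
#'
#' For a model trained in signal-prediction mode (linear head whose output
#' dimension equals the input row count), repeatedly feeds the last `tau`
#' samples through the network, appends the one-step prediction, and feeds
#' it back — the free-running generative use of the network.
#'
#' @param model linear-head [init_model()] with `n_classes == input_rows`.
#' @param seed_sequence D x L matrix, `L >= tau`, priming the recursion.
#' @param n_steps number of samples to predict.
#' @return D x `n_steps` matrix of predicted samples.
#' @export
autoregressive_predict <- function(model, seed_sequence, n_steps) {
  if (model$head != "linear")
    stop_arg("autoregressive prediction needs a linear-head (signal) model")
  if (model$n_classes != model$input_rows)
    stop_arg("signal model must predict all %d input rows", model$input_rows)
  if (is.null(dim(seed_sequence)))
    seed_sequence <- matrix(seed_sequence, nrow = 1)
  if (ncol(seed_sequence) < model$tau)
    stop_arg("seed sequence needs >= tau = %d samples", model$tau)
  d <- model$input_rows
  buf <- seed_sequence
  out <- matrix(0, d, n_steps)
  if (n_steps == 0L) return(out)
  for (s in seq_len(n_steps)) {
    win <- buf[, (ncol(buf) - model$tau + 1L):ncol(buf), drop = FALSE]
    yhat <- rnn_forward(model, array(win, dim = c(d, model$tau, 1L)))$out
    out[, s] <- yhat
    buf <- cbind(buf, yhat)
  }
  out
}

#' Train a signal-prediction model on a continuous sequence
#'
#' Builds (window, next-sample) pairs from a D x T sequence and trains a
#' linear-head network to predict sample `t + 1` from samples
#' `t - tau + 1 .. t`.
#'
#' @param seq_mat D x T numeric matrix.
#' @param cfg an [rnn_config()] with `head = "linear"`.
#' @param stride window stride when building training pairs.
#' @return List with `model` and `trace`, as [train_rnn()].
#' @export
train_signal_model <- function(seq_mat, cfg, stride = 1L) {
  if (is.null(dim(seq_mat))) seq_mat <- matrix(seq_mat, nrow = 1)
  d <- nrow(seq_mat); tt <- ncol(seq_mat); tau <- cfg$tau
  if (tt <= tau) stop_arg("sequence must be longer than tau")
  starts <- seq(1L, tt - tau, by = as.integer(stride))
  x <- array(0, dim = c(d, tau, length(starts)))
  y <- matrix(0, d, length(starts))
  for (i in seq_along(starts)) {
    o <- starts[i]
    x[, , i] <- seq_mat[, o:(o + tau - 1L), drop = FALSE]
    y[, i] <- seq_mat[, o + tau]
  }
  model <- init_model(cfg, d, d)
  train_rnn(model, list(x = x, y = y), cfg = cfg)
}

# ---- hidden-depth sweep ------------------------------------------------

#' Sweep the unroll depth to find the optimal number of hidden layers
#'
#' Trains one model per (cell type, tau) on training slices cropped at that
#' tau, records validation accuracy and cross-entropy, and returns per cell
#' the tau maximizing validation accuracy (ties broken toward the smaller
#' tau). That tau is the cropping size used downstream, since slice length
#' and unroll depth are the same quantity.
#'
#' @param train_features,val_features lists of [feature_series()].
#' @param tau_grid integer vector of unroll depths to try.
#' @param cfg base [rnn_config()]; its `tau` is overridden per grid point.
#' @param cells cell types to sweep.
#' @param class_order class id vector (defaults to sorted labels present).
#' @param stride cropping stride for the sweep's training slices.
#' @return List with `onhl` (named integer per cell) and `curves` (data
#'   frame: cell, tau, val_acc, val_loss).
#' @export
sweep_depth <- function(train_features, val_features, tau_grid, cfg,
                        cells = c("lstm", "gru"), class_order = NULL,
                        stride = 1L) {
  if (length(tau_grid) == 0L) stop_arg("tau_grid must be non-empty")
  if (is.null(class_order))
    class_order <- sort(unique(vapply(train_features, `[[`, integer(1),
                                      "label")))
  d <- nrow(train_features[[1]]$values)
  curves <- data.frame()
  onhl <- stats::setNames(integer(length(cells)), cells)
  for (cell in cells) {
    for (tau in sort(as.integer(tau_grid))) {
      cfg_t <- cfg
      cfg_t$cell <- cell
      cfg_t$tau <- as.integer(tau)
      tr <- crop_slices_array(train_features, tau, stride)
      va <- crop_slices_array(val_features, tau, stride)
      model <- init_model(cfg_t, d, length(class_order),
                          class_order = class_order)
      fit <- train_rnn(model, tr, va, cfg_t)
      last <- fit$trace[nrow(fit$trace), ]
      curves <- rbind(curves, data.frame(cell = cell, tau = tau,
                                         val_acc = last$val_acc,
                                         val_loss = last$val_loss))
    }
    cc <- curves[curves$cell == cell, ]
    best <- cc$tau[order(-cc$val_acc, cc$tau)][1]
    onhl[cell] <- best
  }
  list(onhl = onhl, curves = curves)
}

# ---- model serialization ----------------------------------------------

MODEL_FORMAT <- "fbcsprnn-model"

#' Save a recurrent model (weights, configuration, feature layout, class
#' order) to a single file
#' @param model an [init_model()] result.
#' @param path output path.
#' @export
save_rnn_model <- function(model, path) {
  obj <- list(format = MODEL_FORMAT, version = 1L, model = unclass(model))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model written by [save_rnn_model()]
#' @param path model file.
#' @return The stored `rnn_model`.
#' @export
load_rnn_model <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: '%s'", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop_arg("'%s' is not a %s file", path, MODEL_FORMAT)
  structure(obj$model, class = "rnn_model")
}
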