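# Gated recurrent cells (vanilla / LSTM with peepholes / GRU) unrolled over
# time slices, with hand-derived backpropagation through time. The unroll
# depth equals the slice length tau, so "network depth" and cropping size
# are the same quantity.

# ---- activations -------------------------------------------------------

act_apply <- function(name, z) {
  switch(name,
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         relu = pmax(z, 0),
         identity = z,
         stop_arg("unknown activation '%s'", name))
}

# derivative wrt preactivation, given preactivation z and output a
act_deriv <- function(name, z, a) {
  switch(name,
         tanh = 1 - a * a,
         sigmoid = a * (1 - a),
         relu = (z > 0) * 1,
         identity = array(1, dim = dim(z)),
         stop_arg("unknown activation '%s'", name))
}

# ---- configuration -----------------------------------------------------

#' Recurrent network configuration
#'
#' @param cell one of `"vanilla"`, `"lstm"`, `"gru"`.
#' @param tau unroll depth = time-slice length in samples. The network is
#'   unrolled once per slice sample, so tau doubles as the "number of
#'   hidden layers".
#' @param hidden hidden state width H.
#' @param init_sigma standard deviation of the Gaussian N(0, sigma) weight
#'   initialization (biases start at zero).
#' @param dropout dropout rate in `[0, 1)` applied to non-recurrent
#'   connections (inputs and the classifier head input) during training.
#' @param max_iterations training epochs; training always runs exactly this
#'   many (no early stopping).
#' @param learning_rate,beta1,beta2,epsilon Adam optimizer parameters.
#' @param batch_size mini-batch size in slices.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param gate_activation_mode `"conventional_sigmoid"` (default; bounded
#'   gates, stable) or `"paper_relu"` (ReLU gate activations intended to
#'   keep the error flow from vanishing).
#' @param cell_input_activation activation of the cell input / candidate
#'   (default tanh).
#' @param cell_output_activation LSTM cell-output activation applied to the
#'   cell state before gating the hidden state (default sigmoid).
#' @param head `"softmax"` classification head on the final unrolled step,
#'   or `"linear"` regression head for signal-prediction mode.
#' @return An object of class `rnn_config`.
#' @export
rnn_config <- function(cell = "gru", tau = 20L, hidden = 32L,
                       init_sigma = 0.2, dropout = 0.2,
                       max_iterations = 200L, learning_rate = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       batch_size = 64L, seed = 42L,
                       gate_activation_mode = "conventional_sigmoid",
                       cell_input_activation = "tanh",
                       cell_output_activation = "sigmoid",
                       head = "softmax") {
  if (!cell %in% c("vanilla", "lstm", "gru"))
    stop_arg("unknown cell '%s' (use vanilla, lstm or gru)", cell)
  if (!gate_activation_mode %in% c("conventional_sigmoid", "paper_relu"))
    stop_arg("unknown gate_activation_mode '%s'", gate_activation_mode)
  if (tau < 1L || hidden < 1L) stop_arg("tau and hidden must be >= 1")
  if (dropout < 0 || dropout >= 1) stop_arg("dropout must be in [0, 1)")
  structure(list(cell = cell, tau = as.integer(tau),
                 hidden = as.integer(hidden), init_sigma = init_sigma,
                 dropout = dropout, max_iterations = as.integer(max_iterations),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 gate_activation_mode = gate_activation_mode,
                 cell_input_activation = cell_input_activation,
                 cell_output_activation = cell_output_activation,
                 head = head),
            class = "rnn_config")
}

gate_activation <- function(cfg) {
  if (cfg$gate_activation_mode == "paper_relu") "relu" else "sigmoid"
}

# ---- initialization ----------------------------------------------------

#' Initialize a recurrent model
#'
#' All weight matrices (input, recurrent, peephole, output) are drawn
#' i.i.d. Gaussian with mean 0 and standard deviation `cfg$init_sigma`;
#' biases start at zero. Deterministic given `cfg$seed`.
#'
#' @param cfg an [rnn_config()].
#' @param input_rows number of feature rows D the model consumes.
#' @param n_classes number of classes (softmax head) or output dimension
#'   (linear head).
#' @param layout optional feature-row layout recorded for provenance.
#' @param class_order optional class id vector fixing output unit order.
#' @return An object of class `rnn_model`.
#' @export
init_model <- function(cfg, input_rows, n_classes, layout = NULL,
                       class_order = NULL) {
  d <- as.integer(input_rows); h <- cfg$hidden; k <- as.integer(n_classes)
  gmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, cfg$init_sigma),
                                  nr, nc)
  params <- withr::with_seed(cfg$seed, {
    p <- switch(cfg$cell,
      vanilla = list(Wx = gmat(h, d), Wh = gmat(h, h), b = numeric(h)),
      gru = list(Wz = gmat(h, d), Uz = gmat(h, h), bz = numeric(h),
                 Wr = gmat(h, d), Ur = gmat(h, h), br = numeric(h),
                 Wc = gmat(h, d), Uc = gmat(h, h), bc = numeric(h)),
      lstm = list(Wi = gmat(h, d), Ui = gmat(h, h), bi = numeric(h),
                  Wf = gmat(h, d), Uf = gmat(h, h), bf = numeric(h),
                  Wo = gmat(h, d), Uo = gmat(h, h), bo = numeric(h),
                  Wg = gmat(h, d), Ug = gmat(h, h), bg = numeric(h),
                  pi_ = gmat(h, 1)[, 1], pf_ = gmat(h, 1)[, 1],
                  po_ = gmat(h, 1)[, 1]))
    p$Wy <- gmat(k, h)
    p$by <- numeric(k)
    p
  })
  structure(list(cell = cfg$cell, tau = cfg$tau, hidden = h, input_rows = d,
                 n_classes = k, head = cfg$head, params = params,
                 activations = list(cell_input = cfg$cell_input_activation,
                                    cell_output = cfg$cell_output_activation,
                                    gate = gate_activation(cfg)),
                 layout = layout,
                 class_order = if (is.null(class_order)) seq_len(k)
                               else as.integer(class_order),
                 config = cfg),
            class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("<rnn_model> %s cell, tau=%d, H=%d, D=%d, %s head (%d units)\n",
              x$cell, x$tau, x$hidden, x$input_rows, x$head, x$n_classes))
  invisible(x)
}

# ---- forward pass ------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# X: D x tau x B array. masks: optional list of D x B dropout masks per
# step (already scaled by 1/(1-p)); head_mask: H x B. Returns output and,
# with cache = TRUE, everything the backward pass needs.
rnn_forward <- function(model, X, masks = NULL, head_mask = NULL,
                        cache = FALSE) {
  p <- model$params
  tau <- dim(X)[2]; b <- dim(X)[3]; h <- model$hidden
  g_act <- model$activations$gate
  in_act <- model$activations$cell_input
  out_act <- model$activations$cell_output
  hs <- matrix(0, h, b); cs <- matrix(0, h, b)
  steps <- if (cache) vector("list", tau) else NULL
  for (t in seq_len(tau)) {
    x <- matrix(X[, t, ], nrow = dim(X)[1], ncol = b)
    if (!is.null(masks)) x <- x * masks[[t]]
    h_prev <- hs
    if (model$cell == "vanilla") {
      az <- p$Wx %*% x + p$Wh %*% hs + p$b
      hs <- act_apply(in_act, az)
      if (cache) steps[[t]] <- list(x = x, h_prev = h_prev, az = az, h = hs)
    } else if (model$cell == "gru") {
      az <- p$Wz %*% x + p$Uz %*% hs + p$bz
      ar <- p$Wr %*% x + p$Ur %*% hs + p$br
      z <- act_apply(g_act, az)
      r <- act_apply(g_act, ar)
      ac <- p$Wc %*% x + p$Uc %*% (r * hs) + p$bc
      cc <- act_apply(in_act, ac)
      hs <- (1 - z) * h_prev + z * cc
      if (cache) steps[[t]] <- list(x = x, h_prev = h_prev, az = az, ar = ar,
                                    ac = ac, z = z, r = r, cc = cc, h = hs)
    } else { # lstm with peepholes on input/forget (from c_{t-1}) and output
             # (from c_t)
      c_prev <- cs
      ai <- p$Wi %*% x + p$Ui %*% hs + p$pi_ * c_prev + p$bi
      af <- p$Wf %*% x + p$Uf %*% hs + p$pf_ * c_prev + p$bf
      ag <- p$Wg %*% x + p$Ug %*% hs + p$bg
      i <- act_apply(g_act, ai)
      f <- act_apply(g_act, af)
      g <- act_apply(in_act, ag)
      cs <- f * c_prev + i * g
      ao <- p$Wo %*% x + p$Uo %*% hs + p$po_ * cs + p$bo
      o <- act_apply(g_act, ao)
      cout <- act_apply(out_act, cs)
      hs <- o * cout
      if (cache) steps[[t]] <- list(x = x, h_prev = h_prev, c_prev = c_prev,
                                    ai = ai, af = af, ag = ag, ao = ao,
                                    i = i, f = f, g = g, o = o, c = cs,
                                    cout = cout, h = hs)
    }
  }
  h_head <- hs
  if (!is.null(head_mask)) h_head <- h_head * head_mask
  logits <- p$Wy %*% h_head + p$by
  out <- if (model$head == "softmax") softmax_cols(logits) else logits
  list(out = out, logits = logits, h_final = hs, h_head = h_head,
       steps = steps, head_mask = head_mask, masks = masks)
}

#' Score one time slice
#'
#' Runs the recurrent cell over the `tau` slice columns and applies the
#' classifier head (softmax over classes) to the final step's hidden state.
#'
#' @param model an [init_model()] result (softmax head).
#' @param slice a [time_slice()] (or bare D x tau matrix) whose row count
#'   and length match the model.
#' @return Class probability vector on the simplex, named by class order.
#' @export
forward <- function(model, slice) {
  x <- if (inherits(slice, "time_slice")) slice$values else slice
  if (nrow(x) != model$input_rows)
    stop_arg("slice has %d rows, model expects %d", nrow(x),
             model$input_rows)
  if (ncol(x) != model$tau)
    stop_arg("slice length %d != model tau %d", ncol(x), model$tau)
  out <- rnn_forward(model, array(x, dim = c(nrow(x), ncol(x), 1L)))$out
  p <- as.numeric(out)
  names(p) <- model$class_order
  p
}

# ---- backward pass (BPTT) ---------------------------------------------

# d_out: gradient of the loss wrt the head output pre-softmax logits
# (softmax head) or wrt the linear outputs. Returns gradients for every
# parameter, in the same shapes.
rnn_backward <- function(model, fwd, d_logits) {
  p <- model$params
  grads <- lapply(p, function(w) if (is.matrix(w)) w * 0 else numeric(length(w)))
  h_head <- fwd$h_head
  grads$Wy <- d_logits %*% t(h_head)
  grads$by <- rowSums(d_logits)
  dh <- t(p$Wy) %*% d_logits
  if (!is.null(fwd$head_mask)) dh <- dh * fwd$head_mask
  g_act <- model$activations$gate
  in_act <- model$activations$cell_input
  out_act <- model$activations$cell_output
  tau <- length(fwd$steps)
  dc_carry <- NULL
  for (t in rev(seq_len(tau))) {
    s <- fwd$steps[[t]]
    if (model$cell == "vanilla") {
      dz <- dh * act_deriv(in_act, s$az, s$h)
      grads$Wx <- grads$Wx + dz %*% t(s$x)
      grads$Wh <- grads$Wh + dz %*% t(s$h_prev)
      grads$b <- grads$b + rowSums(dz)
      dh <- t(p$Wh) %*% dz
    } else if (model$cell == "gru") {
      dz_gate <- dh * (s$cc - s$h_prev)
      dcc <- dh * s$z
      dh_prev <- dh * (1 - s$z)
      da_c <- dcc * act_deriv(in_act, s$ac, s$cc)
      grads$Wc <- grads$Wc + da_c %*% t(s$x)
      grads$Uc <- grads$Uc + da_c %*% t(s$r * s$h_prev)
      grads$bc <- grads$bc + rowSums(da_c)
      drh <- t(p$Uc) %*% da_c
      dr <- drh * s$h_prev
      dh_prev <- dh_prev + drh * s$r
      da_z <- dz_gate * act_deriv(g_act, s$az, s$z)
      grads$Wz <- grads$Wz + da_z %*% t(s$x)
      grads$Uz <- grads$Uz + da_z %*% t(s$h_prev)
      grads$bz <- grads$bz + rowSums(da_z)
      dh_prev <- dh_prev + t(p$Uz) %*% da_z
      da_r <- dr * act_deriv(g_act, s$ar, s$r)
      grads$Wr <- grads$Wr + da_r %*% t(s$x)
      grads$Ur <- grads$Ur + da_r %*% t(s$h_prev)
      grads$br <- grads$br + rowSums(da_r)
      dh_prev <- dh_prev + t(p$Ur) %*% da_r
      dh <- dh_prev
    } else { # lstm
      if (is.null(dc_carry)) dc_carry <- s$c * 0
      do_ <- dh * s$cout
      da_o <- do_ * act_deriv(g_act, s$ao, s$o)
      dc <- dh * s$o * act_deriv(out_act, s$c, s$cout) + dc_carry +
        p$po_ * da_o
      di <- dc * s$g
      df <- dc * s$c_prev
      dg <- dc * s$i
      da_i <- di * act_deriv(g_act, s$ai, s$i)
      da_f <- df * act_deriv(g_act, s$af, s$f)
      da_g <- dg * act_deriv(in_act, s$ag, s$g)
      grads$Wi <- grads$Wi + da_i %*% t(s$x)
      grads$Ui <- grads$Ui + da_i %*% t(s$h_prev)
      grads$bi <- grads$bi + rowSums(da_i)
      grads$Wf <- grads$Wf + da_f %*% t(s$x)
      grads$Uf <- grads$Uf + da_f %*% t(s$h_prev)
      grads$bf <- grads$bf + rowSums(da_f)
      grads$Wo <- grads$Wo + da_o %*% t(s$x)
      grads$Uo <- grads$Uo + da_o %*% t(s$h_prev)
      grads$bo <- grads$bo + rowSums(da_o)
      grads$Wg <- grads$Wg + da_g %*% t(s$x)
      grads$Ug <- grads$Ug + da_g %*% t(s$h_prev)
      grads$bg <- grads$bg + rowSums(da_g)
      grads$pi_ <- grads$pi_ + rowSums(da_i * s$c_prev)
      grads$pf_ <- grads$pf_ + rowSums(da_f * s$c_prev)
      grads$po_ <- grads$po_ + rowSums(da_o * s$c)
      dh <- t(p$Ui) %*% da_i + t(p$Uf) %*% da_f + t(p$Uo) %*% da_o +
        t(p$Ug) %*% da_g
      dc_carry <- dc * s$f + p$pi_ * da_i + p$pf_ * da_f
    }
  }
  grads
}
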