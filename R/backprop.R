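# Full forward pass with caches, and the matching analytic backward pass.
# Shapes: x (N, T, C); top hidden sequence (N, T, h); predictions (N, H).

model_forward <- function(x, params, config, mode = "eval") {
  enc <- encoder_forward(x, params, config, mode)
  H_top <- enc$h_top
  N <- dim(x)[1]
  T <- config$T
  hT <- slice_t(H_top, T)
  if (config$attention == "softmax") {
    Q <- hT %*% t(params$W_a)
    logits <- vapply(
      seq_len(T), function(t) rowSums(slice_t(H_top, t) * Q), numeric(N)
    )
    logits <- matrix(logits, N, T)
    logits <- logits - apply(logits, 1, max)
    e <- exp(logits)
    alpha <- e / rowSums(e)
    ctx <- matrix(0, N, config$hidden_size)
    for (t in seq_len(T)) ctx <- ctx + alpha[, t] * slice_t(H_top, t)
  } else {
    alpha <- matrix(0, N, T)
    alpha[, T] <- 1
    Q <- NULL
    ctx <- hT
  }
  a_out <- ctx %*% params$W_out +
    matrix(params$b_out, N, config$H, byrow = TRUE)
  y_hat <- if (config$output_activation == "scaled_sigmoid") {
    sigmoid(a_out)
  } else {
    a_out
  }
  list(
    y_hat = y_hat, alpha = alpha, ctx = ctx, a_out = a_out, enc = enc,
    Q = Q, hT = hT
  )
}

model_backward <- function(fwd, d_y, params, config) {
  N <- nrow(d_y)
  T <- config$T
  h_sz <- config$hidden_size
  H_top <- fwd$enc$h_top

  d_a <- if (config$output_activation == "scaled_sigmoid") {
    d_y * fwd$y_hat * (1 - fwd$y_hat)
  } else {
    d_y
  }
  dW_out <- t(fwd$ctx) %*% d_a
  db_out <- colSums(d_a)
  d_ctx <- d_a %*% t(params$W_out)

  dH_top <- array(0, c(N, T, h_sz))
  if (config$attention == "softmax") {
    alpha <- fwd$alpha
    d_alpha <- matrix(0, N, T)
    for (t in seq_len(T)) {
      Ht <- slice_t(H_top, t)
      d_alpha[, t] <- rowSums(d_ctx * Ht)
      dH_top[, t, ] <- dH_top[, t, ] + alpha[, t] * d_ctx
    }
    d_logit <- alpha * (d_alpha - rowSums(alpha * d_alpha))
    M <- matrix(0, N, h_sz) # sum_t d_logit_t h_t
    dhT_q <- matrix(0, N, h_sz) # query-side gradient
    for (t in seq_len(T)) {
      Ht <- slice_t(H_top, t)
      M <- M + d_logit[, t] * Ht
      dH_top[, t, ] <- dH_top[, t, ] + d_logit[, t] * fwd$Q
      dhT_q <- dhT_q + d_logit[, t] * (Ht %*% params$W_a)
    }
    dW_a <- t(M) %*% fwd$hT
    dH_top[, T, ] <- dH_top[, T, ] + dhT_q
  } else {
    dW_a <- matrix(0, h_sz, h_sz)
    dH_top[, T, ] <- dH_top[, T, ] + d_ctx
  }

  L <- config$n_layers
  d_layers <- vector("list", L)
  d_above <- dH_top
  for (l in rev(seq_len(L))) {
    cache <- fwd$enc$layers[[l]]
    if (!is.null(cache$do_mask)) {
      d_above <- d_above * cache$do_mask / (1 - config$dropout_rate)
    }
    n_in <- dim(cache$input)[3]
    dW_x <- matrix(0, n_in, 4 * h_sz)
    dW_h_eff <- matrix(0, h_sz, 4 * h_sz)
    db <- rep(0, 4 * h_sz)
    d_below <- array(0, c(N, T, n_in))
    dh_rec <- matrix(0, N, h_sz)
    dc_rec <- matrix(0, N, h_sz)
    for (t in rev(seq_len(T))) {
      i_g <- slice_t(cache$i, t)
      f_g <- slice_t(cache$f, t)
      g_g <- slice_t(cache$g, t)
      o_g <- slice_t(cache$o, t)
      tanh_c <- slice_t(cache$tanh_c, t)
      c_prev <- if (t > 1) slice_t(cache$c, t - 1) else matrix(0, N, h_sz)
      h_prev <- if (t > 1) slice_t(cache$h, t - 1) else matrix(0, N, h_sz)
      dh <- matrix(d_above[, t, ], N, h_sz) + dh_rec
      d_o <- dh * tanh_c
      dc <- dc_rec + dh * o_g * (1 - tanh_c^2)
      d_i <- dc * g_g
      d_g <- dc * i_g
      d_f <- dc * c_prev
      dc_rec <- dc * f_g
      dZ <- cbind(
        d_i * i_g * (1 - i_g),
        d_f * f_g * (1 - f_g),
        d_g * (1 - g_g^2),
        d_o * o_g * (1 - o_g)
      )
      xt <- slice_t(cache$input, t)
      dW_x <- dW_x + t(xt) %*% dZ
      dW_h_eff <- dW_h_eff + t(h_prev) %*% dZ
      db <- db + colSums(dZ)
      dh_rec <- dZ %*% t(cache$W_h_eff)
      d_below[, t, ] <- dZ %*% t(params$layers[[l]]$W_x)
    }
    dW_h <- if (!is.null(cache$dc_mask)) {
      dW_h_eff * cache$dc_mask / (1 - config$dropconnect_rate)
    } else {
      dW_h_eff
    }
    d_layers[[l]] <- list(W_x = dW_x, W_h = dW_h, b = db)
    d_above <- d_below
  }
  list(layers = d_layers, W_a = dW_a, W_out = dW_out, b_out = db_out)
}

# Loss + gradients for one batch; the entry point the optimizer uses.
model_loss_grad <- function(x, y, params, config, mode = "train",
                            groups = NULL) {
  fwd <- model_forward(x, params, config, mode)
  loss <- composite_loss(y, fwd$y_hat, config$lambda, groups)
  d_y <- composite_loss_grad(y, fwd$y_hat, config$lambda, groups)
  grads <- model_backward(fwd, d_y, params, config)
  list(loss = loss, grads = grads, y_hat = fwd$y_hat, alpha = fwd$alpha)
}

#' Predict HIS for windows
#'
#' Deterministic eval-mode forward pass through the encoder, attention and
#' head, returning predictions on the normalized scale together with each
#' window's attention profile.
#'
#' @param windows A `his_windows` object (or a bare `(N, T, C)` array /
#'   `T x C` matrix).
#' @param params Model parameters.
#' @param config The matching [model_config()].
#' @return A list of class `his_prediction`: `y_hat` (`N x H`, normalized
#'   scale), `alpha` (`N x T` attention weights, rows summing to 1), and
#'   `index` when the input carries one.
#' @export
predict_windows <- function(windows, params, config) {
  index <- NULL
  if (inherits(windows, "his_windows")) {
    index <- windows$index
    x <- windows$x
  } else if (is.matrix(windows)) {
    x <- array(windows, c(1, dim(windows)))
  } else {
    x <- windows
  }
  fwd <- model_forward(x, params, config, mode = "eval")
  structure(
    list(y_hat = fwd$y_hat, alpha = fwd$alpha, index = index),
    class = "his_prediction"
  )
}
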