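#' Model configuration
#'
#' Architecture and regularization settings for the HIS forecaster: a
#' stack of `n_layers` LSTM layers (default 5), temporal attention over
#' the top-layer hidden sequence, and a dense head mapping the context
#' vector to an `H`-step HIS prediction. Defaults follow the tuned
#' configuration (5 layers, 128 hidden units, dropout 0.2); tests and
#' examples use smaller stacks.
#'
#' @param n_channels Number of input channels per day.
#' @param n_layers Number of stacked LSTM layers (>= 1).
#' @param hidden_size Hidden units per layer.
#' @param dropout_rate Inter-layer dropout probability in `[0, 1)`.
#' @param dropconnect_rate DropConnect probability on recurrent weight
#'   matrices in `[0, 1)`.
#' @param lambda Weight of the temporal-smoothness loss term (>= 0).
#' @param output_activation `"identity"` (default, standard for regression
#'   on normalized targets) or `"scaled_sigmoid"` (logistic, keeps
#'   predictions in `[0, 1]`).
#' @param attention `"softmax"` (default) or `"last"`, which ablates
#'   attention and takes the final hidden state as the context — the
#'   plain-LSTM baseline configuration.
#' @param T Window length the model expects.
#' @param H Prediction horizon (steps emitted by the head).
#' @return A list of class `his_model_config`.
#' @export
model_config <- function(n_channels, n_layers = 5, hidden_size = 128,
                         dropout_rate = 0.2, dropconnect_rate = 0.2,
                         lambda = 0.1,
                         output_activation = c("identity", "scaled_sigmoid"),
                         attention = c("softmax", "last"),
                         T = 7, H = 1) {
  check_count(n_channels, "n_channels", min = 1L)
  check_count(n_layers, "n_layers", min = 1L)
  check_count(hidden_size, "hidden_size", min = 1L)
  check_fraction(dropout_rate, "dropout_rate")
  check_fraction(dropconnect_rate, "dropconnect_rate")
  if (!is.numeric(lambda) || lambda < 0) {
    stop("`lambda` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      n_channels = as.integer(n_channels), n_layers = as.integer(n_layers),
      hidden_size = as.integer(hidden_size), dropout_rate = dropout_rate,
      dropconnect_rate = dropconnect_rate, lambda = lambda,
      output_activation = match.arg(output_activation),
      attention = match.arg(attention),
      T = check_count(T, "T", 1L), H = check_count(H, "H", 1L)
    ),
    class = "his_model_config"
  )
}

# Orthogonal matrix via QR of a standard normal draw, sign-fixed.
orthogonal_init <- function(n) {
  qr_d <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_d)
  q * rep(sign(diag(qr.R(qr_d)) + (diag(qr.R(qr_d)) == 0)), each = n)
}

#' Initialize model parameters
#'
#' Standard LSTM initialization: uniform fan-in input weights, orthogonal
#' recurrent blocks (one per gate), zero biases with the forget-gate bias
#' at 1, small-normal attention matrix, uniform fan-in head. Deterministic
#' in `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A `his_model_params` list: `layers` (per layer `W_x`
#'   `(in x 4h)`, `W_h` `(h x 4h)`, `b` `(4h)`; gate column order input,
#'   forget, candidate, output), attention matrix `W_a` `(h x h)`, head
#'   `W_out` `(h x H)` and `b_out`.
#' @export
init_params <- function(config, seed = 1) {
  h <- config$hidden_size
  with_seed(seed, {
    layers <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      n_in <- if (l == 1L) config$n_channels else h
      lim <- 1 / sqrt(n_in)
      W_x <- matrix(stats::runif(n_in * 4 * h, -lim, lim), n_in, 4 * h)
      W_h <- do.call(cbind, lapply(1:4, function(g) orthogonal_init(h)))
      b <- rep(0, 4 * h)
      b[(h + 1):(2 * h)] <- 1 # forget gate
      layers[[l]] <- list(W_x = W_x, W_h = W_h, b = b)
    }
    # identity start = plain dot-product attention, perturbed to break ties
    W_a <- diag(h) + matrix(stats::rnorm(h * h, 0, 0.1 / sqrt(h)), h, h)
    lim <- 1 / sqrt(h)
    W_out <- matrix(stats::runif(h * config$H, -lim, lim), h, config$H)
    b_out <- rep(0, config$H)
    structure(
      list(layers = layers, W_a = W_a, W_out = W_out, b_out = b_out),
      class = "his_model_params"
    )
  })
}

n_params <- function(params) length(unlist(params, use.names = FALSE))

sigmoid <- function(x) 1 / (1 + exp(-x))

# N x T x k slice at time t as an N x k matrix (drop-safe).
slice_t <- function(a, t) {
  d <- dim(a)
  matrix(a[, t, ], nrow = d[1], ncol = d[3])
}

#' Apply DropConnect to a weight matrix
#'
#' In train mode, each weight is independently zeroed with probability
#' `rate` and survivors are rescaled by `1 / (1 - rate)` so the expected
#' pre-activation is unchanged; eval mode (and `rate = 0`) is the
#' identity.
#'
#' @param W A weight matrix.
#' @param rate Drop probability in `[0, 1)`.
#' @param mode `"train"` or `"eval"`.
#' @param seed Optional seed for the mask.
#' @return The (possibly masked) weight matrix.
#' @export
apply_dropconnect <- function(W, rate, mode = c("train", "eval"), seed = NULL) {
  mode <- match.arg(mode)
  check_fraction(rate, "rate")
  if (mode == "eval" || rate == 0) {
    return(W)
  }
  with_seed(seed, {
    mask <- matrix(stats::runif(length(W)) >= rate, nrow(W), ncol(W))
    W * mask / (1 - rate)
  })
}

#' Stacked-LSTM encoder forward pass
#'
#' Runs the gate recurrence `h_t = LSTM(x_t, h_{t-1}, c_{t-1})` through
#' every layer; layer `l > 1` consumes layer `l - 1`'s hidden sequence.
#' In train mode, DropConnect masks the recurrent matrices and dropout
#' masks inter-layer activations; eval mode is deterministic. States are
#' initialized to zero.
#'
#' @param window A `T x n_channels` matrix (one window) or an
#'   `(N, T, n_channels)` array.
#' @param params A `his_model_params` list.
#' @param config The matching [model_config()].
#' @param mode `"eval"` (default) or `"train"`.
#' @param seed Optional seed for the train-mode masks.
#' @return An `encoder_state` list: `h_top` — the top-layer hidden
#'   sequence (`T x hidden` matrix for a single window, else an
#'   `(N, T, hidden)` array) — plus per-layer hidden/cell state arrays in
#'   `$layers`.
#' @export
lstm_stack_forward <- function(window, params, config,
                               mode = c("eval", "train"), seed = NULL) {
  mode <- match.arg(mode)
  single <- is.matrix(window)
  x <- if (single) array(window, c(1, dim(window))) else window
  d <- dim(x)
  if (length(d) != 3 || d[2] != config$T || d[3] != config$n_channels) {
    stop(
      "input shape mismatch: expected (N, ", config$T, ", ",
      config$n_channels, "), got (", paste(d, collapse = ", "), ")",
      call. = FALSE
    )
  }
  fwd <- with_seed(seed, encoder_forward(x, params, config, mode))
  h_top <- fwd$h_top
  state <- structure(
    list(
      h_top = if (single) matrix(h_top[1, , ], config$T, config$hidden_size) else h_top,
      layers = lapply(fwd$layers, function(l) list(h = l$h, c = l$c))
    ),
    class = "encoder_state"
  )
  state
}

# Internal batched encoder; returns full caches for backprop.
encoder_forward <- function(x, params, config, mode) {
  N <- dim(x)[1]
  T <- config$T
  h_sz <- config$hidden_size
  L <- config$n_layers
  train <- mode == "train"
  inp <- x
  layer_caches <- vector("list", L)
  for (l in seq_len(L)) {
    p <- params$layers[[l]]
    W_h_eff <- p$W_h
    dc_mask <- NULL
    if (train && config$dropconnect_rate > 0) {
      dc_mask <- matrix(
        stats::runif(length(p$W_h)) >= config$dropconnect_rate,
        nrow(p$W_h), ncol(p$W_h)
      )
      W_h_eff <- p$W_h * dc_mask / (1 - config$dropconnect_rate)
    }
    n_in <- dim(inp)[3]
    gi <- array(0, c(N, T, h_sz))
    gf <- gi
    gg <- gi
    go <- gi
    cc <- gi
    tc <- gi
    hh <- gi
    h_prev <- matrix(0, N, h_sz)
    c_prev <- matrix(0, N, h_sz)
    b_row <- matrix(p$b, N, 4 * h_sz, byrow = TRUE)
    for (t in seq_len(T)) {
      xt <- slice_t(inp, t)
      Z <- xt %*% p$W_x + h_prev %*% W_h_eff + b_row
      i_g <- sigmoid(Z[, 1:h_sz, drop = FALSE])
      f_g <- sigmoid(Z[, (h_sz + 1):(2 * h_sz), drop = FALSE])
      g_g <- tanh(Z[, (2 * h_sz + 1):(3 * h_sz), drop = FALSE])
      o_g <- sigmoid(Z[, (3 * h_sz + 1):(4 * h_sz), drop = FALSE])
      c_new <- f_g * c_prev + i_g * g_g
      tanh_c <- tanh(c_new)
      h_new <- o_g * tanh_c
      gi[, t, ] <- i_g
      gf[, t, ] <- f_g
      gg[, t, ] <- g_g
      go[, t, ] <- o_g
      cc[, t, ] <- c_new
      tc[, t, ] <- tanh_c
      hh[, t, ] <- h_new
      h_prev <- h_new
      c_prev <- c_new
    }
    out <- hh
    do_mask <- NULL
    if (l < L && train && config$dropout_rate > 0) {
      do_mask <- array(
        stats::runif(N * T * h_sz) >= config$dropout_rate, c(N, T, h_sz)
      )
      out <- hh * do_mask / (1 - config$dropout_rate)
    }
    layer_caches[[l]] <- list(
      input = inp, i = gi, f = gf, g = gg, o = go, c = cc, tanh_c = tc,
      h = hh, W_h_eff = W_h_eff, dc_mask = dc_mask, do_mask = do_mask
    )
    inp <- out
  }
  list(h_top = inp, layers = layer_caches)
}

#' Temporal attention weights
#'
#' Softmax over time steps of the bilinear scores
#' `h_t' W_a h_T`, where `h_T` — the final top-layer state — is the
#' query. Computed with max-subtraction for overflow safety. All `T`
#' steps, including the query step itself, compete in the softmax.
#'
#' @param H Top-layer hidden sequence: `T x hidden` matrix or
#'   `(N, T, hidden)` array (or an `encoder_state`).
#' @param W_a Attention weight matrix (`hidden x hidden`).
#' @return Attention weights summing to 1 per window: length-`T` vector
#'   for a single window, else an `N x T` matrix.
#' @examples
#' H <- rbind(c(1, 0), c(0, 1))
#' attention_weights(H, diag(2)) # logits (0, 1) -> c(0.2689, 0.7311)
#' @export
attention_weights <- function(H, W_a) {
  if (inherits(H, "encoder_state")) H <- H$h_top
  single <- is.matrix(H)
  if (single) H <- array(H, c(1, dim(H)))
  if (!all(is.finite(H))) {
    stop("non-finite hidden states passed to attention", call. = FALSE)
  }
  T <- dim(H)[2]
  hT <- slice_t(H, T)
  Q <- hT %*% t(W_a) # row n: W_a h_T
  logits <- vapply(
    seq_len(T), function(t) rowSums(slice_t(H, t) * Q),
    numeric(dim(H)[1])
  )
  logits <- matrix(logits, nrow = dim(H)[1], ncol = T)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  alpha <- e / rowSums(e)
  if (single) alpha[1, ] else alpha
}

#' Attention context vector
#'
#' The convex combination `c = sum_t alpha_t h_t` of top-layer hidden
#' states (distinct from the LSTM cell state).
#'
#' @param H Hidden sequence as in [attention_weights()].
#' @param alpha Attention weights from [attention_weights()].
#' @return Length-`hidden` vector for a single window, else an
#'   `N x hidden` matrix.
#' @export
context_vector <- function(H, alpha) {
  if (inherits(H, "encoder_state")) H <- H$h_top
  single <- is.matrix(H)
  if (single) {
    H <- array(H, c(1, dim(H)))
    alpha <- matrix(alpha, 1)
  }
  if (ncol(alpha) != dim(H)[2]) {
    stop(
      "length mismatch: ", ncol(alpha), " weights for ", dim(H)[2],
      " time steps",
      call. = FALSE
    )
  }
  ctx <- matrix(0, dim(H)[1], dim(H)[3])
  for (t in seq_len(dim(H)[2])) {
    ctx <- ctx + alpha[, t] * slice_t(H, t)
  }
  if (single) ctx[1, ] else ctx
}

#' Dense output head
#'
#' The affine map `sigma(W c + b)` from the context vector to the
#' `H`-step prediction. `identity` returns the affine value;
#' `scaled_sigmoid` applies the logistic function (targets are
#' pre-normalized to `[0, 1]`).
#'
#' @param ctx Context vector (length `hidden`) or `N x hidden` matrix.
#' @param W Head weight matrix (`hidden x H`).
#' @param b Head bias (length `H`).
#' @param activation `"identity"` or `"scaled_sigmoid"`.
#' @return Prediction(s) on the normalized scale.
#' @export
output_head <- function(ctx, W, b, activation = c("identity", "scaled_sigmoid")) {
  activation <- match.arg(activation)
  single <- is.null(dim(ctx))
  if (single) ctx <- matrix(ctx, 1)
  if (ncol(ctx) != nrow(W)) {
    stop(
      "shape mismatch: context has ", ncol(ctx), " units, head expects ",
      nrow(W),
      call. = FALSE
    )
  }
  a <- ctx %*% W + matrix(b, nrow(ctx), length(b), byrow = TRUE)
  y <- if (activation == "scaled_sigmoid") sigmoid(a) else a
  if (single) y[1, ] else y
}
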