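# Shared fixtures and independent oracles used across test files.

# Brute-force metric suite written directly from the formula definitions,
# kept independent of compute_metrics().
oracle_metrics <- function(y, yhat) {
  e <- yhat - y
  n <- length(y)
  sstot <- sum((y - sum(y) / n)^2)
  list(
    mae = sum(abs(e)) / n,
    rmse = sqrt(sum(e^2) / n),
    r2 = 1 - sum(e^2) / sstot,
    evs = 1 - sum((e - sum(e) / n)^2) / sstot,
    mbe = sum(e) / n
  )
}

# Scalar LSTM cell executed gate by gate, independent of the package's
# vectorized recurrence. Weights are length-4 vectors in gate order
# (input, forget, candidate, output).
oracle_lstm_scalar <- function(x_seq, w_x, w_h, b) {
  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0
  c <- 0
  for (x in x_seq) {
    i <- sig(w_x[1] * x + w_h[1] * h + b[1])
    f <- sig(w_x[2] * x + w_h[2] * h + b[2])
    g <- tanh(w_x[3] * x + w_h[3] * h + b[3])
    o <- sig(w_x[4] * x + w_h[4] * h + b[4])
    c <- f * c + i * g
    h <- o * tanh(c)
  }
  list(h = h, c = c)
}

# Central finite-difference gradient of f at theta.
numeric_gradient <- function(f, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(i) {
    tp <- theta
    tp[i] <- tp[i] + eps
    tm <- theta
    tm[i] <- tm[i] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}

# Scalar model params (hidden size 1, one channel) with every weight set
# by hand, for end-to-end forward oracles.
scalar_params <- function(w_x, w_h, b, w_a, w_out, b_out) {
  structure(
    list(
      layers = list(list(
        W_x = matrix(w_x, 1, 4), W_h = matrix(w_h, 1, 4), b = b
      )),
      W_a = matrix(w_a, 1, 1),
      W_out = matrix(w_out, 1, 1), b_out = b_out
    ),
    class = "his_model_params"
  )
}

# Minimal hand-built cohort: given per-participant HIS vectors and two
# channels of arbitrary values, returns a his_cohort-compatible tibble.
tiny_cohort <- function(his_list, hr = NULL, steps = NULL) {
  rows <- lapply(seq_along(his_list), function(p) {
    his <- his_list[[p]]
    nd <- length(his)
    tibble::tibble(
      participant_id = p, day = 0:(nd - 1),
      hr_rest = if (is.null(hr)) rep(60, nd) else hr[[p]],
      steps = if (is.null(steps)) rep(7000, nd) else steps[[p]],
      his = his
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("his_cohort", class(tibble::tibble()))
  out
}

# Small windowed dataset with known targets and a known index, built
# directly (bypassing make_windows) for evaluation fixtures.
manual_windows <- function(y, pid, T = 3, n_channels = 2, his_lags = NULL) {
  n <- length(y)
  hisforecast:::new_his_windows(
    x = array(0.5, c(n, T, n_channels)),
    y = matrix(y, ncol = 1),
    index = tibble::tibble(participant_id = pid, start_day = seq_len(n)),
    channels = paste0("ch", seq_len(n_channels)),
    T = T, H = 1L, stride = 1L,
    his_lags = if (is.null(his_lags)) matrix(y, n, T) else his_lags
  )
}
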