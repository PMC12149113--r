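tiny_config <- function(...) {
  model_config(
    n_channels = 1, n_layers = 1, hidden_size = 1, dropout_rate = 0,
    dropconnect_rate = 0, T = 2, H = 1, ...
  )
}

test_that("the encoder fixes zero inputs with zero weights at zero", {
  cfg <- model_config(
    n_channels = 2, n_layers = 2, hidden_size = 3,
    dropout_rate = 0, dropconnect_rate = 0, T = 4
  )
  params <- init_params(cfg, seed = 1)
  for (l in seq_along(params$layers)) {
    params$layers[[l]]$W_x[] <- 0
    params$layers[[l]]$W_h[] <- 0
    params$layers[[l]]$b[] <- 0
  }
  state <- lstm_stack_forward(matrix(0, 4, 2), params, cfg)
  expect_equal(state$h_top, matrix(0, 4, 3))
})

test_that("eval-mode encoding is a pure function of input and parameters", {
  cfg <- model_config(
    n_channels = 3, n_layers = 2, hidden_size = 4,
    dropout_rate = 0.3, dropconnect_rate = 0.3, T = 5
  )
  params <- init_params(cfg, seed = 2)
  x <- matrix(runif(15), 5, 3)
  expect_identical(
    lstm_stack_forward(x, params, cfg, mode = "eval"),
    lstm_stack_forward(x, params, cfg, mode = "eval")
  )
  expect_error(
    lstm_stack_forward(matrix(0, 4, 3), params, cfg),
    "expected \\(N, 5, 3\\)"
  )
})

test_that("a scalar-width forward pass matches the hand-executed gate trace", {
  w_x <- c(0.5, -0.3, 0.8, 0.2)
  w_h <- c(0.1, 0.4, -0.2, 0.3)
  b <- c(0.05, 1.0, -0.1, 0.2)
  x_seq <- c(0.7, -1.2)
  oracle <- oracle_lstm_scalar(x_seq, w_x, w_h, b)

  cfg <- tiny_config()
  params <- scalar_params(w_x, w_h, b, w_a = 0.5, w_out = 1, b_out = 0)
  state <- lstm_stack_forward(matrix(x_seq, 2, 1), params, cfg)
  expect_equal(state$h_top[2, 1], oracle$h, tolerance = 1e-10)
  expect_equal(state$layers[[1]]$c[1, 2, 1], oracle$c, tolerance = 1e-10)
})

test_that("attention weights reproduce the hand softmax and its edge cases", {
  expect_equal(attention_weights(matrix(2.5, 1, 1), matrix(1)), 1.0)

  H4 <- matrix(rnorm(12), 4, 3)
  expect_equal(
    attention_weights(H4, matrix(0, 3, 3)), rep(0.25, 4),
    tolerance = 1e-12
  )

  H <- rbind(c(1, 0), c(0, 1))
  alpha <- attention_weights(H, diag(2)) # logits (0, 1)
  expect_equal(alpha, c(0.2689, 0.7311), tolerance = 1e-4)

  bad <- H
  bad[1, 1] <- NaN
  expect_error(attention_weights(bad, diag(2)), "non-finite")
})

test_that("the context vector is the attention-weighted state average", {
  H <- matrix(rnorm(10), 5, 2)
  one_hot <- c(0, 0, 1, 0, 0)
  expect_equal(context_vector(H, one_hot), H[3, ])
  expect_equal(context_vector(H, rep(0.2, 5)), colMeans(H))
  expect_equal(context_vector(matrix(c(4, 8), 2, 1), c(0.25, 0.75)), 7)
  expect_error(context_vector(H, c(0.5, 0.5)), "mismatch")
})

test_that("the output head applies the affine map and activation", {
  expect_equal(output_head(c(1, 2), matrix(0, 2, 1), 0), 0)
  expect_equal(output_head(c(1, 2), matrix(c(1, 1), 2, 1), 0.5), 3.5)
  expect_equal(
    output_head(c(0, 0), matrix(c(1, 1), 2, 1), 0, "scaled_sigmoid"), 0.5
  )
  expect_error(output_head(c(1, 2, 3), matrix(0, 2, 1), 0), "mismatch")
})

test_that("the composite loss matches hand arithmetic and decomposes in lambda", {
  y <- c(1, 2)
  yhat <- c(1.5, 2.5)
  expect_equal(composite_loss(y, yhat, lambda = 0), 0.25) # plain MSE
  expect_equal(composite_loss(y, yhat, lambda = 0.1), 0.35) # + 0.1 * 1

  expect_equal(
    composite_loss(c(1, 5, 2), rep(3, 3), lambda = 10),
    mean((c(1, 5, 2) - 3)^2) # constant predictions zero the smoothness term
  )
  expect_error(composite_loss(y, yhat, lambda = -1), "lambda")

  set.seed(3)
  yt <- matrix(runif(12), 3, 4)
  yp <- matrix(runif(12), 3, 4)
  s <- hisforecast:::smoothness_term(yp)
  for (l in c(0, 0.1, 1)) {
    expect_equal(composite_loss(yt, yp, l), composite_loss(yt, yp, 0) + l * s)
  }
  # grouped (cross-window) form: only within-participant pairs count
  yt1 <- runif(5)
  yp1 <- runif(5)
  groups <- c(1, 1, 2, 2, 2)
  s_manual <- mean(c(
    (yp1[2] - yp1[1])^2, (yp1[4] - yp1[3])^2, (yp1[5] - yp1[4])^2
  ))
  expect_equal(
    composite_loss(yt1, yp1, 0.7, groups),
    mean((yt1 - yp1)^2) + 0.7 * s_manual
  )
})

test_that("DropConnect masks at the configured rate and rescales survivors", {
  W <- matrix(rnorm(1000), 40, 25)
  expect_identical(apply_dropconnect(W, 0), W)
  expect_identical(apply_dropconnect(W, 0.5, mode = "eval"), W)

  masked <- apply_dropconnect(W, 0.5, seed = 11)
  n_zero <- sum(masked == 0)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_zero, bounds[1])
  expect_lte(n_zero, bounds[2])
  surviving <- masked != 0
  expect_equal(masked[surviving], W[surviving] / 0.5)
})

test_that("softmax attention is a proper distribution over random inputs", {
  set.seed(21)
  for (i in 1:200) {
    T <- sample(2:9, 1)
    h <- sample(2:6, 1)
    H <- array(rnorm(3 * T * h, sd = 2), c(3, T, h))
    W_a <- matrix(rnorm(h * h), h, h)
    alpha <- attention_weights(H, W_a)
    expect_true(all(alpha >= 0))
    expect_equal(rowSums(alpha), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("predict composes the equations and matches a scalar end-to-end oracle", {
  cfg <- model_config(
    n_channels = 2, n_layers = 2, hidden_size = 4,
    dropout_rate = 0.2, dropconnect_rate = 0.2, T = 6
  )
  params <- init_params(cfg, seed = 5)
  x <- array(runif(2 * 6 * 2), c(2, 6, 2))
  p1 <- predict_windows(x, params, cfg)
  p2 <- predict_windows(x, params, cfg)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1$alpha), c(1, 1), tolerance = 1e-6)

  # scalar chain: gate trace -> bilinear softmax -> context -> affine head
  w_x <- c(0.5, -0.3, 0.8, 0.2)
  w_h <- c(0.1, 0.4, -0.2, 0.3)
  b <- c(0.05, 1.0, -0.1, 0.2)
  x_seq <- c(0.7, -1.2)
  sig <- function(z) 1 / (1 + exp(-z))
  step1 <- oracle_lstm_scalar(x_seq[1], w_x, w_h, b)
  step2 <- oracle_lstm_scalar(x_seq, w_x, w_h, b)
  h_seq <- c(step1$h, step2$h)
  w_a <- 0.6
  logits <- h_seq * w_a * h_seq[2]
  alpha <- exp(logits - max(logits)) / sum(exp(logits - max(logits)))
  ctx <- sum(alpha * h_seq)
  y_oracle <- 1.4 * ctx + 0.3

  scfg <- tiny_config()
  sparams <- scalar_params(w_x, w_h, b, w_a, w_out = 1.4, b_out = 0.3)
  pred <- predict_windows(matrix(x_seq, 2, 1), sparams, scfg)
  expect_equal(pred$y_hat[1, 1], y_oracle, tolerance = 1e-10)
  expect_equal(pred$alpha[1, ], alpha, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  rel_err <- function(a, n) abs(a - n) / pmax(abs(a) + abs(n), 1e-6)

  check_grads <- function(cfg, x, y, groups = NULL) {
    params <- init_params(cfg, seed = 8)
    res <- hisforecast:::model_loss_grad(
      x, y, params, cfg,
      mode = "eval", groups = groups
    )
    analytic <- hisforecast:::flatten_params(res$grads)
    theta <- hisforecast:::flatten_params(params)
    f <- function(th) {
      p <- hisforecast:::unflatten_params(th, params)
      composite_loss(
        y, hisforecast:::model_forward(x, p, cfg, "eval")$y_hat,
        cfg$lambda, groups
      )
    }
    numeric <- numeric_gradient(f, theta)
    expect_lt(max(rel_err(analytic, numeric)), 1e-4)
  }

  set.seed(10)
  # one-step horizon with cross-window smoothness groups
  cfg1 <- model_config(
    n_channels = 2, n_layers = 1, hidden_size = 3,
    dropout_rate = 0, dropconnect_rate = 0, lambda = 0.1, T = 4, H = 1
  )
  check_grads(
    cfg1, array(runif(4 * 4 * 2), c(4, 4, 2)), matrix(runif(4), 4, 1),
    groups = c(1, 1, 2, 2)
  )

  # multi-step horizon, deeper stack, sigmoid head, within-row smoothness
  cfg2 <- model_config(
    n_channels = 2, n_layers = 2, hidden_size = 3, dropout_rate = 0,
    dropconnect_rate = 0, lambda = 0.5, T = 3, H = 3,
    output_activation = "scaled_sigmoid"
  )
  check_grads(
    cfg2, array(runif(2 * 3 * 2), c(2, 3, 2)), matrix(runif(6), 2, 3)
  )

  # attention-ablated configuration
  cfg3 <- model_config(
    n_channels = 2, n_layers = 1, hidden_size = 3, dropout_rate = 0,
    dropconnect_rate = 0, lambda = 0, T = 4, H = 1, attention = "last"
  )
  check_grads(
    cfg3, array(runif(3 * 4 * 2), c(3, 4, 2)), matrix(runif(3), 3, 1)
  )
})

test_that("train-mode gradients respect the sampled regularization masks", {
  # with fixed masks (captured via a seeded forward), the train-mode
  # gradient matches finite differences of the same masked network
  cfg <- model_config(
    n_channels = 2, n_layers = 2, hidden_size = 3,
    dropout_rate = 0.4, dropconnect_rate = 0.4, lambda = 0.1, T = 3, H = 1
  )
  params <- init_params(cfg, seed = 12)
  x <- array(runif(2 * 3 * 2), c(2, 3, 2))
  y <- matrix(runif(2), 2, 1)
  groups <- c(1, 1)

  res <- hisforecast:::with_seed(99, hisforecast:::model_loss_grad(
    x, y, params, cfg,
    mode = "train", groups = groups
  ))
  theta <- hisforecast:::flatten_params(params)
  f <- function(th) {
    r <- hisforecast:::with_seed(
      99, hisforecast:::model_forward(
        x, hisforecast:::unflatten_params(th, params), cfg, "train"
      )
    )
    composite_loss(y, r$y_hat, cfg$lambda, groups)
  }
  numeric <- numeric_gradient(f, theta)
  analytic <- hisforecast:::flatten_params(res$grads)
  expect_lt(max(abs(analytic - numeric) / pmax(abs(analytic) + abs(numeric), 1e-6)), 1e-4)
})
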