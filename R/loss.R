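#' Composite MSE + temporal-smoothness loss
#'
#' `L = mean((y - yhat)^2) + lambda * S`, where `S` is the mean squared
#' difference between temporally consecutive predictions. With a
#' multi-step horizon (`ncol >= 2`) the differences run along each row's
#' prediction steps. With a one-step horizon the temporal axis is
#' recovered from `groups`: consecutive rows sharing a group label are
#' consecutive windows of one participant (batches are built time-ordered
#' per participant), and differences are taken within groups. With a
#' single prediction step and no groups, `S = 0`.
#'
#' @param y_true,y_pred Matrices `(N, T')` (vectors are treated as one
#'   sample per row... a plain vector is one sample's `T'` steps when
#'   `groups` is `NULL`, else `N` one-step samples).
#' @param lambda Smoothness weight (>= 0).
#' @param groups Optional vector of length `N` labelling each row's
#'   participant, for the one-step cross-window smoothness form.
#' @return Scalar loss.
#' @examples
#' composite_loss(c(1, 2), c(1.5, 2.5), lambda = 0.1) # 0.25 + 0.1 * 1
#' @export
composite_loss <- function(y_true, y_pred, lambda = 0.1, groups = NULL) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  if (is.null(dim(y_true))) {
    if (is.null(groups)) {
      y_true <- matrix(y_true, 1)
      y_pred <- matrix(y_pred, 1)
    } else {
      y_true <- matrix(y_true, ncol = 1)
      y_pred <- matrix(y_pred, ncol = 1)
    }
  }
  if (!all(dim(y_true) == dim(y_pred))) {
    stop("`y_true` and `y_pred` must have identical shape", call. = FALSE)
  }
  mse <- mean((y_true - y_pred)^2)
  mse + lambda * smoothness_term(y_pred, groups)
}

smoothness_term <- function(y_pred, groups = NULL) {
  Tp <- ncol(y_pred)
  if (Tp >= 2) {
    d <- y_pred[, -1, drop = FALSE] - y_pred[, -Tp, drop = FALSE]
    return(mean(d^2))
  }
  if (is.null(groups) || nrow(y_pred) < 2) {
    return(0)
  }
  same <- groups[-1] == groups[-length(groups)]
  if (!any(same)) {
    return(0)
  }
  d <- diff(y_pred[, 1])[same]
  mean(d^2)
}

# Gradient of composite_loss w.r.t. y_pred (same shape as y_pred).
composite_loss_grad <- function(y_true, y_pred, lambda, groups = NULL) {
  g <- 2 * (y_pred - y_true) / length(y_true)
  Tp <- ncol(y_pred)
  if (lambda > 0 && Tp >= 2) {
    d <- y_pred[, -1, drop = FALSE] - y_pred[, -Tp, drop = FALSE]
    scale <- 2 * lambda / length(d)
    g[, -1] <- g[, -1, drop = FALSE] + scale * d
    g[, -Tp] <- g[, -Tp, drop = FALSE] - scale * d
  } else if (lambda > 0 && Tp == 1 && !is.null(groups) && nrow(y_pred) >= 2) {
    same <- which(groups[-1] == groups[-length(groups)])
    if (length(same) > 0) {
      d <- (y_pred[same + 1, 1] - y_pred[same, 1])
      scale <- 2 * lambda / length(d)
      for (k in seq_along(same)) {
        i <- same[k]
        g[i + 1, 1] <- g[i + 1, 1] + scale * d[k]
        g[i, 1] <- g[i, 1] - scale * d[k]
      }
    }
  }
  g
}
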