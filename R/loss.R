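#' Loss configuration
#'
#' Weights of the joint objective
#' `loss = alpha * MSE(y_r, yhat_r) + beta * CE(y_c, yhat_c)`. Only the
#' ratio matters, so `alpha` is fixed at 1 by convention and `beta` is the
#' searched hyperparameter (grid {10, 20, 200}).
#'
#' @param alpha Non-negative weight on the regression MSE.
#' @param beta Non-negative weight on the classification cross-entropy.
#' @return A `ktm_loss_config` list.
#' @export
loss_config <- function(alpha = 1, beta = 10) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (alpha + beta <= 0) {
    stop("alpha + beta must be positive: a zero loss cannot train anything",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "ktm_loss_config")
}

#' Regression loss: mean squared error
#'
#' Mean over all `N x 4` squared residuals (subjects and timepoints alike),
#' which keeps the loss weight comparable across designs with different
#' numbers of timepoints.
#'
#' @param y,y_hat Matrices of true and predicted scores, same shape.
#' @return A scalar.
#' @export
mse_loss <- function(y, y_hat) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!all(dim(y) == dim(y_hat))) {
    stop("mse_loss: shape mismatch", call. = FALSE)
  }
  as.numeric(mean((y - y_hat)^2))
}

#' Classification loss: categorical cross-entropy
#'
#' Mean over subjects of `-sum_c y_c log(p_c)` with the predicted
#' probabilities clamped to `[eps, 1 - eps]` to keep the logarithm finite.
#'
#' @param y One-hot label matrix (rows sum to 1, entries 0/1).
#' @param p Predicted probability matrix (rows sum to 1).
#' @param eps Clamping constant.
#' @return A scalar.
#' @export
ce_loss <- function(y, p, eps = 1e-7) {
  y <- as.matrix(y); p <- as.matrix(p)
  if (!all(dim(y) == dim(p))) stop("ce_loss: shape mismatch", call. = FALSE)
  if (any(y != 0 & y != 1) || any(abs(rowSums(y) - 1) > 1e-8)) {
    stop("ce_loss: y must be one-hot", call. = FALSE)
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  as.numeric(-mean(rowSums(y * log(p))))
}

#' Joint multitask loss
#'
#' `alpha * MSE + beta * CE`. With `beta = 0` this reduces to the weighted
#' regression loss, with `alpha = 0` to the weighted cross-entropy. The L1
#' penalty on the head weights is added separately during training (it
#' depends on the parameters, not the predictions).
#'
#' @param y_r,y_r_hat Regression targets and predictions (may be `NULL`
#'   when `alpha = 0`).
#' @param y_c,y_c_hat One-hot labels and predicted probabilities (may be
#'   `NULL` when `beta = 0`).
#' @param cfg A [loss_config()].
#' @return A scalar.
#' @export
joint_loss <- function(y_r, y_r_hat, y_c, y_c_hat, cfg = loss_config()) {
  stopifnot(inherits(cfg, "ktm_loss_config"))
  total <- 0
  if (cfg$alpha > 0) total <- total + cfg$alpha * mse_loss(y_r, y_r_hat)
  if (cfg$beta > 0) total <- total + cfg$beta * ce_loss(y_c, y_c_hat)
  total
}

# L1 penalty on the head weight matrices (not biases).
l1_penalty <- function(params, coeff) {
  pen <- 0
  for (nm in intersect(c("head_r.W", "head_c.W"), names(params))) {
    pen <- pen + sum(abs(params[[nm]]))
  }
  coeff * pen
}
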