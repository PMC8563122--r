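#' Per-task cross-entropy loss
#'
#' Binary cross-entropy of the predicted positive-class probability
#' against the binary label, averaged over the batch. Probabilities are
#' clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param p numeric vector of predicted positive-class probabilities.
#' @param y binary labels (0/1), same length.
#' @param eps clamping constant, default `1e-7`.
#' @return mean loss (length-1 numeric).
#' @export
task_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y)) stop("p and y must have equal length")
  if (!all(y %in% c(0, 1))) stop("labels must be exactly 0 or 1")
  pc <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Uncertainty weights
#'
#' The two learnable scalars `eta_h`, `eta_k` parameterize the per-task
#' observation-noise variances as `sigma^2 = exp(eta)`, keeping the
#' variances positive under unconstrained optimization.
#'
#' @param eta_h,eta_k initial values (0 gives `sigma = 1`).
#' @export
uncertainty_weights <- function(eta_h = 0, eta_k = 0) {
  stopifnot(is.finite(eta_h), is.finite(eta_k))
  structure(list(eta_h = eta_h, eta_k = eta_k),
            class = "uncertainty_weights")
}

#' Uncertainty-weighted total loss
#'
#' Combines the two task losses with learnable observation-noise
#' variances: `0.5 exp(-eta_h) L_h + 0.5 exp(-eta_k) L_k + eta_h + eta_k`
#' (the log-variance penalty keeps the weights from collapsing to zero).
#' Task P's loss is `L_h`; task M's is `L_k`.
#'
#' @param l_h,l_k per-task mean losses.
#' @param w an [uncertainty_weights()] object.
#' @return total loss (length-1 numeric).
#' @export
total_loss <- function(l_h, l_k, w = uncertainty_weights()) {
  stopifnot(is.finite(l_h), is.finite(l_k))
  0.5 * exp(-w$eta_h) * l_h + 0.5 * exp(-w$eta_k) * l_k + w$eta_h + w$eta_k
}

#' Optimizer and schedule configuration
#'
#' Defaults follow the training protocol: Adam with base learning rate
#' 0.01, beta1 0.9, beta2 0.999, no weight decay, batch size 32, up to
#' 500 epochs, with the stepped learning-rate decay of [lr_at()].
#'
#' @param l0 base learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @param weight_decay L2 coefficient (0 disables).
#' @param batch_size minibatch size.
#' @param max_epochs training epoch budget.
#' @export
schedule_config <- function(l0 = 0.01, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8, weight_decay = 0,
                            batch_size = 32L, max_epochs = 500L) {
  structure(list(l0 = l0, beta1 = beta1, beta2 = beta2, eps = eps,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs)),
            class = "schedule_config")
}

#' Stepped learning rate
#'
#' Piecewise-constant decay over the epoch counter `s`:
#' `l0` on `[0, 100]`, `0.5 l0` on `(100, 150]`, `0.1 l0` on `(150, 250]`,
#' `0.01 l0` on `(250, 400]`, and `0.001 l0` beyond 400.
#'
#' @param s epoch (non-negative; vectorized).
#' @param cfg a [schedule_config()].
#' @return learning rate(s).
#' @export
lr_at <- function(s, cfg = schedule_config()) {
  if (any(s < 0)) stop("schedule step must be non-negative")
  mult <- ifelse(s <= 100, 1,
          ifelse(s <= 150, 0.5,
          ifelse(s <= 250, 0.1,
          ifelse(s <= 400, 0.01, 0.001))))
  cfg$l0 * mult
}
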