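#' Tversky loss hyperparameters
#'
#' The Tversky index generalises Dice overlap with asymmetric penalties:
#' `alpha` weights false negatives and `beta` false positives, `gamma` is
#' the focal exponent applied as `(1 - TI)^(1/gamma)`, and `phi` is a small
#' smoothing constant preventing division by zero. Defaults `alpha = 0.3`,
#' `beta = 0.7`, `gamma = 1`, `phi = 1e-6`.
#'
#' @param alpha,beta Non-negative false-negative / false-positive weights.
#' @param gamma Positive focal parameter.
#' @param phi Positive smoothing constant.
#' @return An object of class `tversky_params`.
#' @export
tversky_params <- function(alpha = 0.3, beta = 0.7, gamma = 1, phi = 1e-6) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, phi > 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, phi = phi),
            class = "tversky_params")
}

#' Learnable task uncertainties for adaptive loss weighting
#'
#' Parameterises the per-task homoscedastic uncertainty as the log-variance
#' `s = log(sigma^2)`, so sigma^2 = exp(s) stays positive under
#' unconstrained optimisation. `s_b` belongs to the breast-area task and
#' `s_d` to the dense-tissue task; both default to 0 (sigma = 1).
#'
#' @param s_b,s_d Finite log-variances.
#' @param trainable Whether the optimiser updates them.
#' @return An object of class `task_uncertainty`.
#' @export
task_uncertainty <- function(s_b = 0, s_d = 0, trainable = TRUE) {
  stopifnot(is.finite(s_b), is.finite(s_d))
  structure(list(s_b = s_b, s_d = s_d, trainable = isTRUE(trainable)),
            class = "task_uncertainty")
}

#' Tversky index of a prediction against a binary target
#'
#' `TI = (TP + phi) / (TP + alpha*FN + beta*FP + phi)` with
#' `TP = sum(pred * target)`, `FN = sum((1 - pred) * target)` and
#' `FP = sum(pred * (1 - target))`, summed over all pixels. Soft
#' (probability) predictions are allowed; with `alpha = beta = 0.5` the
#' index equals the Dice coefficient.
#'
#' @param pred Per-pixel foreground probabilities (or a hard mask) for the
#'   class under evaluation.
#' @param target Binary ground-truth mask for the same class.
#' @param params A [tversky_params()].
#' @return Scalar index in `(0, 1]`.
#' @export
tversky_index <- function(pred, target, params = tversky_params()) {
  pred <- as_pixel_matrix(pred); target <- as_pixel_matrix(target)
  if (!all(dim(pred) == dim(target))) stop("dimension mismatch")
  stopifnot_binary(target, "target")
  tp <- sum(pred * target)
  fn <- sum((1 - pred) * target)
  fp <- sum(pred * (1 - target))
  (tp + params$phi) / (tp + params$alpha * fn + params$beta * fp + params$phi)
}

#' Focal Tversky loss over the two classes of a segmentation head
#'
#' `L = sum_c (1 - TI_c)^(1/gamma)` where c runs over the region-of-interest
#' class (`target`) and the background class (`1 - target`). For a two-class
#' probability map the background prediction is the complement channel. A
#' perfect hard prediction yields exactly 0.
#'
#' @param pred Either an `(H, W)` matrix of foreground probabilities or an
#'   `(H, W, 2)` array of class probabilities (channel 1 = foreground).
#' @param target Binary `(H, W)` ground-truth mask.
#' @param params A [tversky_params()].
#' @return Scalar loss; in `[0, 2]` for two classes with `gamma = 1`.
#' @export
focal_tversky_loss <- function(pred, target, params = tversky_params()) {
  pred <- as_pixel_matrix(pred); target <- as_pixel_matrix(target)
  if (length(dim(pred)) == 3L) pred <- pred[, , 1]
  if (!all(dim(pred) == dim(target))) stop("dimension mismatch")
  ti_fg <- tversky_index(pred, target, params)
  ti_bg <- tversky_index(1 - pred, 1 - target, params)
  (1 - ti_fg)^(1 / params$gamma) + (1 - ti_bg)^(1 / params$gamma)
}

# Loss and gradient w.r.t. the foreground probability map, one image.
# Returns list(loss, dpred) with dpred the same shape as pred.
ftl_with_grad <- function(pred, target, params) {
  a <- params$alpha; b <- params$beta; g <- params$gamma; phi <- params$phi
  loss <- 0
  dpred <- array(0, dim(pred))
  for (cls in 1:2) {
    p <- if (cls == 1) pred else 1 - pred
    y <- if (cls == 1) target else 1 - target
    tp <- sum(p * y)
    den <- tp + a * sum((1 - p) * y) + b * sum(p * (1 - y)) + phi
    ti <- (tp + phi) / den
    t1 <- 1 - ti
    loss <- loss + t1^(1 / g)
    # d(1-ti)^(1/g)/dti = -(1/g) (1-ti)^(1/g - 1)
    dl_dti <- if (t1 > 0) -(1 / g) * t1^(1 / g - 1) else 0
    dden_dp <- y - a * y + b * (1 - y)
    dti_dp <- (y * den - (tp + phi) * dden_dp) / den^2
    dp <- dl_dti * dti_dp
    dpred <- dpred + if (cls == 1) dp else -dp
  }
  list(loss = loss, dpred = dpred)
}

# Mean per-image FTL over a batch of probability maps (H, W, 2, N) against
# target masks (H, W, N); returns loss and gradient w.r.t. the full
# probability array (both channels), for the softmax backward.
ftl_batch <- function(probs, targets, params) {
  d <- dim(probs); N <- d[4]
  loss <- 0
  dprobs <- array(0, d)
  for (n in seq_len(N)) {
    r <- ftl_with_grad(probs[, , 1, n], targets[, , n], params)
    loss <- loss + r$loss
    dprobs[, , 1, n] <- r$dpred / N
    dprobs[, , 2, n] <- 0   # loss written in terms of the foreground channel
  }
  list(loss = loss / N, dprobs = dprobs)
}

#' Naive fixed-weight multitask loss
#'
#' `L_total = lambda * L_b + (1 - lambda) * L_d` with a single weight
#' `lambda` strictly inside (0, 1); the grid search over lambda is the
#' "naive" alternative to adaptive uncertainty weighting.
#'
#' @param loss_b,loss_d Non-negative per-task losses.
#' @param lambda Weight on the breast-area task, in (0, 1).
#' @return Scalar combined loss.
#' @export
naive_mtl_loss <- function(loss_b, loss_d, lambda) {
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly inside (0, 1)")
  lambda * loss_b + (1 - lambda) * loss_d
}

#' Weight-adaptive multitask loss with homoscedastic uncertainty
#'
#' `L_total = L_b / sigma_b^2 + log(sigma_b) + L_d / sigma_d^2 +
#' log(sigma_d)`, implemented with the log-variance parameterisation
#' `s = log(sigma^2)` as `exp(-s_b) L_b + s_b/2 + exp(-s_d) L_d + s_d/2`.
#' With sigma = 1 for both tasks this reduces to `L_b + L_d` exactly.
#' Minimising over sigma alone for a fixed task loss L has its stationary
#' point at `sigma^2 = 2L`.
#'
#' @param loss_b,loss_d Non-negative per-task losses.
#' @param u A [task_uncertainty()].
#' @return Scalar combined loss.
#' @export
adaptive_mtl_loss <- function(loss_b, loss_d, u = task_uncertainty()) {
  if (!is.finite(loss_b) || !is.finite(loss_d))
    stop("task losses must be finite")
  exp(-u$s_b) * loss_b + u$s_b / 2 + exp(-u$s_d) * loss_d + u$s_d / 2
}

# Gradient of the adaptive loss w.r.t. (s_b, s_d).
adaptive_mtl_grad_s <- function(loss_b, loss_d, u) {
  c(s_b = unname(-exp(-u$s_b) * loss_b + 0.5),
    s_d = unname(-exp(-u$s_d) * loss_d + 0.5))
}
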