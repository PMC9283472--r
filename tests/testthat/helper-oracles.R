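# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written from the definitions (pixel counting,
# exhaustive search), not by calling package internals.

# Tversky index by explicit confusion counting.
oracle_tversky <- function(pred, target, alpha, beta, phi = 1e-6) {
  tp <- sum(pred * target)
  fn <- sum((1 - pred) * target)
  fp <- sum(pred * (1 - target))
  (tp + phi) / (tp + alpha * fn + beta * fp + phi)
}

# Focal Tversky loss summed over foreground and background classes.
oracle_ftl <- function(pred, target, alpha = 0.3, beta = 0.7, gamma = 1,
                       phi = 1e-6) {
  (1 - oracle_tversky(pred, target, alpha, beta, phi))^(1 / gamma) +
    (1 - oracle_tversky(1 - pred, 1 - target, alpha, beta, phi))^(1 / gamma)
}

# Plain (unsmoothed) Dice coefficient.
oracle_dice <- function(pred, target) {
  2 * sum(pred * target) / (sum(pred) + sum(target))
}

# Otsu threshold by exhaustive between-class variance maximisation over all
# 255 candidate split points, lowest maximiser wins.
oracle_otsu <- function(v) {
  v <- as.integer(v)
  best_t <- NA_integer_
  best_var <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_var + 1e-12) { best_var <- bcv; best_t <- t }
  }
  best_t
}

# Random binary mask with approximate foreground probability p.
rand_mask <- function(h = 8, w = 8, p = 0.5) {
  matrix((runif(h * w) < p) * 1, h, w)
}

# Random non-degenerate mask (at least one fg and one bg pixel).
rand_mask_nondeg <- function(h = 8, w = 8, p = 0.5) {
  repeat {
    m <- rand_mask(h, w, p)
    if (sum(m) > 0 && sum(m) < h * w) return(m)
  }
}
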