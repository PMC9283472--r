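# Separable resampling via kernel-weight matrices (internal).
#
# For a 1-D resize from `n_in` to `n_out` samples we build an
# `n_out x n_in` weight matrix A with the chosen kernel under the
# center-aligned mapping s = (i + 0.5) * n_in/n_out - 0.5 (0-based), with
# border replication.  A 2-D resize is then R %*% X %*% t(C).

resample_matrix <- function(n_in, n_out, kernel = c("cubic", "linear")) {
  kernel <- match.arg(kernel)
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  # Keys bicubic convolution kernel, a = -0.5
  cub <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
           ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
  }
  lin <- function(t) pmax(0, 1 - abs(t))
  taps <- if (kernel == "cubic") -1:2 else 0:1
  kfun <- if (kernel == "cubic") cub else lin
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale - 0.5           # 0-based source coordinate
    base <- floor(s)
    t <- s - base
    for (k in taps) {
      w <- kfun(t - k)
      if (w == 0) next
      j <- min(max(base + k, 0), n_in - 1)  # replicate borders
      A[i, j + 1] <- A[i, j + 1] + w
    }
  }
  A
}

resize_matrix_interp <- function(m, h, w, kernel = "cubic") {
  R <- resample_matrix(nrow(m), h, kernel)
  C <- resample_matrix(ncol(m), w, kernel)
  R %*% m %*% t(C)
}

# Nearest-neighbour index mapping under the same center-aligned convention.
nearest_index <- function(n_in, n_out) {
  i <- seq_len(n_out) - 0.5
  pmin(pmax(floor(i * n_in / n_out), 0), n_in - 1) + 1
}

resize_matrix_nearest <- function(m, h, w) {
  m[nearest_index(nrow(m), h), nearest_index(ncol(m), w), drop = FALSE]
}
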