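# Differentiable layer primitives (internal).
#
# All activations are stored as R arrays with dim c(H, W, C, N).  Each layer
# is a plain list carrying a `type` field plus its trainable tensors; forward
# functions return list(out, cache [, layer]) and backward functions return
# list(dx, grads) with `grads` mirroring the trainable fields.

NORM_EPS <- 1e-5
NORM_MOMENTUM <- 0.1

## ---- initialisation ---------------------------------------------------

conv_init <- function(cin, cout, k = 3L, dil = 1L) {
  fan_in <- cin * k * k
  list(type = "conv",
       W = matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = cout, ncol = fan_in),
       b = numeric(cout), k = as.integer(k), dil = as.integer(dil))
}

upconv_init <- function(cin, cout) {
  fan_in <- cin * 4
  list(type = "upconv",
       W = matrix(rnorm(cout * 4 * cin, sd = sqrt(2 / fan_in)),
                  nrow = cout * 4, ncol = cin),
       b = numeric(cout))
}

norm_init <- function(C, norm = "batch", groups = 1L) {
  if (norm == "group" || norm == "wsgroup") {
    groups <- as.integer(groups)
    while (C %% groups != 0L) groups <- groups - 1L
  } else groups <- 1L
  list(type = "norm", norm = norm, groups = groups,
       gamma = rep(1, C), beta = numeric(C),
       running_mean = numeric(C), running_var = rep(1, C))
}

## ---- convolution ------------------------------------------------------

# Weight standardisation: zero-mean, unit-variance rows (per output filter).
ws_weights <- function(W) {
  mu <- rowMeans(W)
  ctr <- W - mu
  sdv <- sqrt(rowMeans(ctr^2) + 1e-10)
  list(What = ctr / sdv, mu = mu, sd = sdv, ctr = ctr)
}

conv_fwd <- function(layer, x, ws = FALSE) {
  if (ws && ncol(layer$W) > 1) {
    w <- ws_weights(layer$W)
    out <- cpp_conv2d_fwd(x, w$What, layer$b, layer$k, layer$dil)
    list(out = out, cache = list(x = x, ws = w))
  } else {
    out <- cpp_conv2d_fwd(x, layer$W, layer$b, layer$k, layer$dil)
    list(out = out, cache = list(x = x, ws = NULL))
  }
}

conv_bwd <- function(layer, cache, dout) {
  Wuse <- if (is.null(cache$ws)) layer$W else cache$ws$What
  r <- cpp_conv2d_bwd(cache$x, Wuse, dout, layer$k, layer$dil)
  dW <- r$dW
  if (!is.null(cache$ws)) {
    # chain rule through What = (W - mean)/sd, per row
    w <- cache$ws
    n <- ncol(layer$W)
    inner <- rowSums(dW * w$What) / n
    dW <- (dW - rowMeans(dW) - w$What * inner) / w$sd
  }
  list(dx = r$dx, grads = list(W = dW, b = as.numeric(r$db)))
}

upconv_fwd <- function(layer, x) {
  list(out = cpp_upconv_fwd(x, layer$W, layer$b), cache = list(x = x))
}

upconv_bwd <- function(layer, cache, dout) {
  r <- cpp_upconv_bwd(cache$x, layer$W, dout)
  list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

## ---- normalisation ----------------------------------------------------

# One normalisation slab: returns normalised values plus backward closure
# ingredients.  `sel` is an index list into the (H, W, C, N) array.
norm_fwd <- function(layer, x, training = TRUE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- x
  xhat <- x
  inv <- NULL
  mode_batch_stats <- TRUE
  if (layer$norm == "batch") {
    inv <- numeric(C)
    mode_batch_stats <- training
    for (c in seq_len(C)) {
      xs <- x[, , c, , drop = FALSE]
      if (training) {
        mu <- mean(xs); v <- mean((xs - mu)^2)
        layer$running_mean[c] <- (1 - NORM_MOMENTUM) * layer$running_mean[c] +
          NORM_MOMENTUM * mu
        layer$running_var[c] <- (1 - NORM_MOMENTUM) * layer$running_var[c] +
          NORM_MOMENTUM * v
      } else {
        mu <- layer$running_mean[c]; v <- layer$running_var[c]
      }
      iv <- 1 / sqrt(v + NORM_EPS)
      xh <- (xs - mu) * iv
      xhat[, , c, ] <- xh
      y[, , c, ] <- layer$gamma[c] * xh + layer$beta[c]
      inv[c] <- iv
    }
  } else {
    # instance norm == group norm with groups = C
    G <- if (layer$norm == "instance") C else layer$groups
    cw <- C %/% G
    inv <- matrix(0, G, N)
    for (n in seq_len(N)) for (g in seq_len(G)) {
      cc <- ((g - 1) * cw + 1):(g * cw)
      xs <- x[, , cc, n, drop = FALSE]
      mu <- mean(xs); v <- mean((xs - mu)^2)
      iv <- 1 / sqrt(v + NORM_EPS)
      xh <- (xs - mu) * iv
      xhat[, , cc, n] <- xh
      gam <- rep(layer$gamma[cc], each = H * W)
      bet <- rep(layer$beta[cc], each = H * W)
      y[, , cc, n] <- xh * gam + bet
      inv[g, n] <- iv
    }
  }
  list(out = y, cache = list(xhat = xhat, inv = inv,
                             batch_stats = mode_batch_stats),
       layer = layer)
}

norm_bwd <- function(layer, cache, dout) {
  d <- dim(dout); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xhat <- cache$xhat
  dx <- dout
  dgamma <- numeric(C); dbeta <- numeric(C)
  if (layer$norm == "batch") {
    for (c in seq_len(C)) {
      dy <- dout[, , c, , drop = FALSE]
      xh <- xhat[, , c, , drop = FALSE]
      dgamma[c] <- sum(dy * xh); dbeta[c] <- sum(dy)
      g <- dy * layer$gamma[c]
      if (cache$batch_stats) {
        dx[, , c, ] <- cache$inv[c] * (g - mean(g) - xh * mean(g * xh))
      } else {
        dx[, , c, ] <- cache$inv[c] * g
      }
    }
  } else {
    G <- if (layer$norm == "instance") C else layer$groups
    cw <- C %/% G
    for (n in seq_len(N)) for (g in seq_len(G)) {
      cc <- ((g - 1) * cw + 1):(g * cw)
      dy <- dout[, , cc, n, drop = FALSE]
      xh <- xhat[, , cc, n, drop = FALSE]
      for (j in seq_along(cc)) {
        dgamma[cc[j]] <- dgamma[cc[j]] + sum(dy[, , j, 1] * xh[, , j, 1])
        dbeta[cc[j]] <- dbeta[cc[j]] + sum(dy[, , j, 1])
      }
      gm <- dy * rep(layer$gamma[cc], each = H * W)
      dx[, , cc, n] <- cache$inv[g, n] *
        (gm - mean(gm) - xh * mean(gm * xh))
    }
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- activations ------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

# Channel-pair softmax for the two-class heads: z has dim (H, W, 2, N).
softmax2 <- function(z) {
  m <- pmax(z[, , 1, , drop = FALSE], z[, , 2, , drop = FALSE])
  e1 <- exp(z[, , 1, , drop = FALSE] - m)
  e2 <- exp(z[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  p <- z
  p[, , 1, ] <- e1 / s
  p[, , 2, ] <- e2 / s
  p
}

# dL/dz given dL/dp and p, per pixel over the 2-channel axis.
softmax2_bwd <- function(p, dp) {
  dot <- p[, , 1, , drop = FALSE] * dp[, , 1, , drop = FALSE] +
    p[, , 2, , drop = FALSE] * dp[, , 2, , drop = FALSE]
  dz <- dp
  dz[, , 1, ] <- p[, , 1, , drop = FALSE] * (dp[, , 1, , drop = FALSE] - dot)
  dz[, , 2, ] <- p[, , 2, , drop = FALSE] * (dp[, , 2, , drop = FALSE] - dot)
  dz
}

## ---- channel concat ---------------------------------------------------

cat_channels <- function(xs) {
  d <- dim(xs[[1]])
  Cs <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(d[1], d[2], sum(Cs), d[4]))
  at <- 0L
  for (x in xs) {
    C <- dim(x)[3]
    out[, , (at + 1):(at + C), ] <- x
    at <- at + C
  }
  out
}

split_channels <- function(dout, Cs) {
  at <- 0L
  lapply(Cs, function(C) {
    r <- dout[, , (at + 1):(at + C), , drop = FALSE]
    at <<- at + C
    r
  })
}
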