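test_that("forward pass honours the shape and probability contracts", {
  cfg <- tiny_config(side = 32L, base = 4L, depth = 2L)
  model <- build_model(cfg, seed = 1)
  x <- matrix(runif(32 * 32), 32, 32)
  pr <- forward(model, x)
  expect_named(pr, c("breast", "dense"))
  for (h in names(pr)) {
    expect_identical(dim(pr[[h]]), c(32L, 32L, 2L, 1L))
    expect_true(all(pr[[h]] >= 0 & pr[[h]] <= 1))
    sums <- pr[[h]][, , 1, ] + pr[[h]][, , 2, ]
    expect_lt(max(abs(sums - 1)), 1e-5)
  }
  expect_error(forward(model, matrix(0, 16, 16)), "input_side")
})

test_that("a desk-scale configuration builds and runs on CPU", {
  cfg <- network_config(input_side = 64L, depth = 2L, base_width = 8L)
  model <- build_model(cfg, seed = 2)
  pr <- forward(model, matrix(runif(64 * 64), 64, 64))
  expect_identical(dim(pr$dense), c(64L, 64L, 2L, 1L))
})

test_that("parameter count grows strictly with base width", {
  n1 <- n_parameters(build_model(tiny_config(base = 4L), seed = 1))
  n2 <- n_parameters(build_model(tiny_config(base = 8L), seed = 1))
  expect_gt(n2, n1)
  # parameter count is a pure function of the configuration
  n1b <- n_parameters(build_model(tiny_config(base = 4L), seed = 99))
  expect_identical(n1, n1b)
})

test_that("input side must be divisible by the downsampling factor", {
  expect_error(network_config(input_side = 48, depth = 5), "divisible")
})

test_that("an all-zero MDR block reduces to its identity shortcut", {
  blk <- mammoseg:::with_seed(3, mdr_block(3L, 3L, dilations = c(1L, 3L)))
  blk <- zero_tree(blk)
  blk$branches <- lapply(blk$branches, function(br) {
    br$norm$gamma[] <- 1   # zero gamma is not required for the identity
    br
  })
  expect_null(blk$proj)    # matching channels: identity shortcut
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  expect_equal(block_forward(blk, x, training = TRUE), x, tolerance = 1e-12)
})

test_that("dilated branches see the advertised receptive field", {
  # delta image through a single 3x3 convolution with dilation r:
  # the response support spans 2r + 1 pixels per axis
  for (r in c(1L, 3L, 5L)) {
    cv <- mammoseg:::conv_init(1L, 1L, k = 3L, dil = r)
    cv$W[] <- 1; cv$b[] <- 0
    x <- array(0, c(17, 17, 1, 1)); x[9, 9, 1, 1] <- 1
    y <- mammoseg:::conv_fwd(cv, x)$out
    nz <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
    expect_identical(range(nz[, 1]), c(9L - r, 9L + r))
    expect_identical(range(nz[, 2]), c(9L - r, 9L + r))
  }
})

test_that("MDR blocks preserve spatial dimensions at all dilation rates", {
  blk <- mammoseg:::with_seed(4, mdr_block(2L, 5L, dilations = c(1L, 3L, 5L)))
  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2, 1))
  y <- block_forward(blk, x, training = TRUE)
  expect_identical(dim(y), c(12L, 12L, 5L, 1L))
})

test_that("bottleneck-style block merges branches to the configured width", {
  # merged output width is set by the fuse layer however many branches
  for (rates in list(c(1L), c(1L, 3L), c(1L, 3L, 5L))) {
    blk <- mammoseg:::with_seed(5, mdr_block(4L, 6L, dilations = rates))
    y <- block_forward(blk, array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)),
                       training = TRUE)
    expect_identical(dim(y), c(8L, 8L, 6L, 1L))
  }
})

test_that("merged impulse support covers the union of branch supports", {
  blk <- mammoseg:::with_seed(6, mdr_block(1L, 1L, dilations = c(1L, 3L)))
  # make both branches pass the impulse straight through
  for (j in 1:2) {
    blk$branches[[j]]$conv$W[] <- 1
    blk$branches[[j]]$conv$b[] <- 5     # keep ReLU active everywhere
    blk$branches[[j]]$norm$gamma[] <- 1
  }
  blk$fuse$W[] <- 1
  x <- array(0, c(17, 17, 1, 1)); x[9, 9, 1, 1] <- 1
  y <- block_forward(blk, x, training = FALSE)
  # subtract the flat response of a zero image to isolate the impulse part
  y0 <- block_forward(blk, array(0, c(17, 17, 1, 1)), training = FALSE)
  nz <- which(abs(y - y0)[, , 1, 1] > 1e-9, arr.ind = TRUE)
  expect_identical(range(nz[, 1]), c(9L - 3L, 9L + 3L))
})

test_that("evaluation-mode forward passes are deterministic", {
  model <- build_model(tiny_config(), seed = 7)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(forward(model, x), forward(model, x))
})

test_that("zeroed head logits give 0.5 everywhere", {
  model <- build_model(tiny_config(), seed = 8)
  model$params$head$breast$W[] <- 0
  model$params$head$breast$b[] <- 0
  pr <- forward(model, matrix(runif(32 * 32), 32, 32))
  expect_true(all(abs(pr$breast - 0.5) < 1e-12))
})

test_that("decoders are parameter-independent across tasks", {
  model <- build_model(tiny_config(), seed = 9)
  x <- matrix(runif(32 * 32), 32, 32)
  before <- forward(model, x)$breast
  model$params$dec$dense <- zero_tree(model$params$dec$dense)
  model$params$head$dense <- zero_tree(model$params$head$dense)
  after <- forward(model, x)$breast
  expect_identical(after, before)
})

test_that("gradients reach the shared encoder but not the other decoder", {
  ns <- asNamespace("mammoseg")
  model <- build_model(tiny_config(side = 16L, base = 2L), seed = 10)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  fw <- ns$net_fwd(model, x, training = TRUE)
  dl <- list(breast = array(rnorm(16 * 16 * 2), c(16, 16, 2, 1)),
             dense = array(0, c(16, 16, 2, 1)))
  bk <- ns$net_bwd(fw$model, fw$cache, dl)
  expect_gt(sum(abs(bk$grads$enc[[1]]$branches[[1]]$conv$W)), 0)
  expect_gt(sum(abs(bk$grads$bottleneck$fuse$W)), 0)
  expect_gt(sum(abs(bk$grads$dec$breast[[1]]$up$W)), 0)
  expect_identical(sum(abs(bk$grads$dec$dense[[1]]$up$W)), 0)
  expect_identical(sum(abs(bk$grads$head$dense$W)), 0)
})

test_that("backpropagation matches finite differences end to end", {
  ns <- asNamespace("mammoseg")
  tv <- tversky_params()
  set.seed(11)
  cfg <- tiny_config(side = 16L, base = 2L, depth = 2L,
                     block_dilations = c(1L, 2L))
  model <- build_model(cfg, seed = 11)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  yb <- array(rand_mask(16, 32), c(16, 16, 2))
  yd <- array(rand_mask(16, 32, 0.3), c(16, 16, 2))
  loss_fn <- function(m) {
    fw <- ns$net_fwd(m, x, training = TRUE)
    ns$ftl_batch(fw$probs$breast, yb, tv)$loss +
      ns$ftl_batch(fw$probs$dense, yd, tv)$loss
  }
  fw <- ns$net_fwd(model, x, training = TRUE)
  dl <- list(
    breast = ns$softmax2_bwd(fw$probs$breast,
                             ns$ftl_batch(fw$probs$breast, yb, tv)$dprobs),
    dense = ns$softmax2_bwd(fw$probs$dense,
                            ns$ftl_batch(fw$probs$dense, yd, tv)$dprobs))
  bk <- ns$net_bwd(fw$model, fw$cache, dl)
  eps <- 1e-5
  probes <- list(
    list(g = bk$grads$enc[[1]]$branches[[1]]$conv$W,
         set = function(m, i, d) {
           m$params$enc[[1]]$branches[[1]]$conv$W[i] <-
             m$params$enc[[1]]$branches[[1]]$conv$W[i] + d; m }),
    list(g = bk$grads$bottleneck$branches[[2]]$norm$gamma,
         set = function(m, i, d) {
           m$params$bottleneck$branches[[2]]$norm$gamma[i] <-
             m$params$bottleneck$branches[[2]]$norm$gamma[i] + d; m }),
    list(g = bk$grads$dec$dense[[1]]$block$fuse$W,
         set = function(m, i, d) {
           m$params$dec$dense[[1]]$block$fuse$W[i] <-
             m$params$dec$dense[[1]]$block$fuse$W[i] + d; m }),
    list(g = bk$grads$head$breast$W,
         set = function(m, i, d) {
           m$params$head$breast$W[i] <- m$params$head$breast$W[i] + d; m }))
  for (pb in probes) {
    for (i in sample(length(pb$g), 2)) {
      num <- (loss_fn(pb$set(model, i, eps)) -
                loss_fn(pb$set(model, i, -eps))) / (2 * eps)
      expect_equal(pb$g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip weights and configuration", {
  model <- build_model(tiny_config(), seed = 12)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(unclass(back$config), unclass(model$config))
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(forward(back, x), forward(model, x))
})
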