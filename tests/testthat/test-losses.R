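test_that("tversky index matches hand-computed confusion counts", {
  # perfect hard prediction: the smoothing constant cancels
  m <- rand_mask_nondeg(6, 6)
  expect_identical(tversky_index(m, m), 1)
  # 2x2 worked case: TP=1, FN=0, FP=1 -> 1/1.7
  pred <- matrix(c(1, 0, 1, 0), 2, 2)    # fg at (1,1) and (1,2)
  targ <- matrix(c(1, 0, 0, 0), 2, 2)    # fg at (1,1)
  ti <- tversky_index(pred, targ)
  expect_equal(ti, 1 / 1.7, tolerance = 1e-4)
  expect_error(tversky_index(pred, matrix(0.5, 2, 2)), "binary")
  expect_error(tversky_index(pred, matrix(0, 3, 3)), "mismatch")
})

test_that("alpha = beta = 0.5 reduces the index to the Dice coefficient", {
  set.seed(1)
  prm <- tversky_params(alpha = 0.5, beta = 0.5, phi = 1e-12)
  for (i in 1:100) {
    p <- rand_mask_nondeg(); t <- rand_mask_nondeg()
    expect_equal(tversky_index(p, t, prm), oracle_dice(p, t),
                 tolerance = 1e-9)
  }
})

test_that("focal Tversky loss agrees with the counting oracle", {
  set.seed(2)
  prm <- tversky_params()
  for (i in 1:200) {
    p <- rand_mask(); t <- rand_mask()
    expect_equal(focal_tversky_loss(p, t, prm),
                 oracle_ftl(p, t), tolerance = 1e-6)
  }
  # soft predictions too
  for (i in 1:50) {
    p <- matrix(runif(64), 8, 8); t <- rand_mask()
    expect_equal(focal_tversky_loss(p, t, prm),
                 oracle_ftl(p, t), tolerance = 1e-6)
  }
})

test_that("worked 2x2 focal Tversky case sums both class terms", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)
  targ <- matrix(c(1, 0, 0, 0), 2, 2)
  # fg: TI = 1/1.7 -> 0.41176; bg: TP=2, FN=1, FP=0 -> TI = 2/2.3 -> 0.13043
  expect_equal(focal_tversky_loss(pred, targ), 0.54220, tolerance = 1e-4)
  # perfect one-hot prediction: both class indices are 1, loss exactly 0
  m <- rand_mask_nondeg()
  expect_identical(focal_tversky_loss(m, m), 0)
})

test_that("the focal exponent inflates sub-perfect losses", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)
  targ <- matrix(c(1, 0, 0, 0), 2, 2)
  l1 <- focal_tversky_loss(pred, targ, tversky_params(gamma = 1))
  l2 <- focal_tversky_loss(pred, targ, tversky_params(gamma = 2))
  expect_gt(l2, l1)   # t^(1/2) > t on (0,1)
})

test_that("loss stays within its two-class range", {
  set.seed(3)
  for (i in 1:50) {
    l <- focal_tversky_loss(matrix(runif(64), 8, 8), rand_mask())
    expect_gte(l, 0); expect_lte(l, 2)
  }
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(4)
  prm <- tversky_params()
  p <- matrix(runif(36, 0.05, 0.95), 6, 6)
  t <- rand_mask_nondeg(6, 6)
  g <- mammoseg:::ftl_with_grad(p, t, prm)
  eps <- 1e-6
  for (i in sample(36, 8)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    num <- (mammoseg:::ftl_with_grad(p1, t, prm)$loss -
              mammoseg:::ftl_with_grad(p2, t, prm)$loss) / (2 * eps)
    expect_equal(g$dpred[i], num, tolerance = 1e-4)
  }
})

test_that("naive combination is the lambda-weighted sum", {
  expect_identical(naive_mtl_loss(1.3, 1.3, 0.5), 1.3)
  expect_equal(naive_mtl_loss(0.5, 1.0, 0.3), 0.85, tolerance = 1e-12)
  expect_error(naive_mtl_loss(1, 1, 0), "lambda")
  expect_error(naive_mtl_loss(1, 1, 1), "lambda")
})

test_that("adaptive combination follows the uncertainty-weighted form", {
  # sigma = 1 for both tasks reduces to the plain sum
  expect_identical(adaptive_mtl_loss(0.37, 1.21, task_uncertainty(0, 0)),
                   0.37 + 1.21)
  # L_b=0.4 sigma_b=1; L_d=0.2 sigma_d=2 -> 0.4 + 0.05 + log 2
  u <- task_uncertainty(s_b = 0, s_d = log(4))
  expect_equal(adaptive_mtl_loss(0.4, 0.2, u), 0.4 + 0.05 + log(2),
               tolerance = 1e-12)
  expect_error(adaptive_mtl_loss(NaN, 1, task_uncertainty()), "finite")
})

test_that("optimising the uncertainties alone finds sigma^2 = 2L", {
  # gradient descent on s only, constant task losses
  L <- c(b = 0.35, d = 0.8)
  s <- c(0, 0)
  for (i in 1:4000) {
    g <- c(-exp(-s[1]) * L["b"] + 0.5, -exp(-s[2]) * L["d"] + 0.5)
    s <- s - 0.05 * g
  }
  expect_equal(unname(exp(s[1])), 2 * L[["b"]], tolerance = 1e-3)
  expect_equal(unname(exp(s[2])), 2 * L[["d"]], tolerance = 1e-3)
  # closed-form check of the per-task minimum value 1/2 + log(2L)/2
  expect_equal(unname(exp(-s[1]) * L[["b"]] + s[1] / 2),
               0.5 + 0.5 * log(2 * L[["b"]]), tolerance = 1e-6)
})
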