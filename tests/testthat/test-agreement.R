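test_that("Pearson correlation and Fisher-z interval match closed forms", {
  a <- c(1, 2, 3, 4, 5)
  r <- pearson_ci(a, a * 2 + 3)
  expect_equal(r$r, 1, tolerance = 1e-12)
  r <- pearson_ci(a, -a)
  expect_equal(r$r, -1, tolerance = 1e-12)
  r <- pearson_ci(a, c(1, 2, 3, 5, 4))
  expect_equal(r$r, 0.9, tolerance = 1e-12)
  # closed-form Fisher z: tanh(atanh(0.9) +- 1.96/sqrt(2))
  z <- atanh(0.9); se <- 1 / sqrt(5 - 3)
  expect_equal(r$ci_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-6)
  expect_equal(r$ci_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-6)
  expect_lt(abs(r$ci_low - 0.086), 1e-3)
  expect_lt(abs(r$ci_high - 0.993), 1e-3)
  expect_error(pearson_ci(a, rep(1, 5)), "variance")
  expect_error(pearson_ci(1:2, 1:2), "length")
})

test_that("correlation is invariant under positive affine transforms", {
  set.seed(10)
  a <- runif(20, 5, 60); b <- a + rnorm(20, sd = 5)
  r0 <- pearson_ci(a, b)
  r1 <- pearson_ci(3 * a + 7, 0.2 * b + 1)
  expect_equal(r0$r, r1$r, tolerance = 1e-12)
  expect_equal(r0$ci_low, r1$ci_low, tolerance = 1e-12)
})

test_that("confidence interval tightens as n grows", {
  width <- function(n) {
    z <- atanh(0.8); se <- 1 / sqrt(n - 3)
    diff(tanh(z + c(-1, 1) * qnorm(0.975) * se))
  }
  ws <- vapply(c(10, 50, 200, 1000), width, numeric(1))
  expect_true(all(diff(ws) < 0))
  # and the package agrees with the formula on a synthetic series
  set.seed(11)
  a <- runif(200, 1, 50); b <- a + rnorm(200, sd = 8)
  r <- pearson_ci(a, b)
  z <- atanh(r$r); se <- 1 / sqrt(r$n - 3)
  expect_equal(r$ci_high, tanh(z + qnorm(0.975) * se), tolerance = 1e-6)
})

test_that("log-transform mode admits zero densities via the epsilon shift", {
  a <- c(0, 5, 12, 30); b <- c(0.5, 6, 10, 28)
  r <- pearson_ci(a, b, transform = "log")
  expect_identical(r$transform, "log")
  expect_true(is.finite(r$r))
})

test_that("Bland-Altman bias and limits follow the 1.96 SD rule", {
  a <- c(5, 10, 15); b <- a - c(-1, 0, 1)       # diffs (-1, 0, 1)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 1, tolerance = 1e-12)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96), tolerance = 1e-12)
  # identical series collapse the limits
  ba0 <- bland_altman(a, a)
  expect_identical(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  expect_identical(ba0$within_loa_fraction, 1)
})

test_that("CDI acceptance counts raw differences against +-5 points", {
  a <- c(13, 6, 16); b <- c(10, 10, 10)          # diffs (3, -4, 6)
  ba <- bland_altman(a, b, cdi = 5)
  expect_equal(ba$within_cdi_fraction, 2 / 3, tolerance = 1e-12)
  # log transform changes the LoA scale but not the CDI count
  ba_log <- bland_altman(a, b, transform = "log", cdi = 5)
  expect_equal(ba_log$within_cdi_fraction, 2 / 3, tolerance = 1e-12)
})

test_that("swapping the series mirrors bias and limits", {
  set.seed(12)
  a <- runif(30, 5, 50); b <- a + rnorm(30, 1, 3)
  x <- bland_altman(a, b); y <- bland_altman(b, a)
  expect_equal(x$bias, -y$bias, tolerance = 1e-12)
  expect_equal(x$loa_low, -y$loa_high, tolerance = 1e-12)
  expect_equal(x$loa_high, -y$loa_low, tolerance = 1e-12)
})

test_that("mean-difference table reports signed offsets per method", {
  ref <- c(5, 10, 15)
  tab <- mean_difference_table(list(same = ref, up = ref + 2), ref)
  expect_identical(tab$mean_diff[tab$method == "same"], 0)
  expect_identical(tab$mean_diff[tab$method == "up"], 2)
  expect_identical(tab$method[1], "reference")
  # arithmetic-consistency fixture on synthetic inputs: means 9.42 and
  # 14.33 differ by 4.91
  r2 <- rep(9.42, 4); m2 <- rep(14.33, 4)
  tab2 <- mean_difference_table(list(libra_style = m2), r2)
  expect_equal(tab2$mean_diff[tab2$method == "libra_style"], 4.91,
               tolerance = 1e-9)
  expect_error(mean_difference_table(list(x = 1:3), 1:4), "aligned")
})

test_that("BI-RADS accuracy counts matching categories", {
  pd <- c(10, 30, 60, 90)
  expect_identical(birads_accuracy(pd, c(1, 2, 3, 4)), 1)
  expect_identical(birads_accuracy(pd, c(2, 3, 4, 1)), 0)
  pd10 <- c(5, 5, 30, 30, 55, 55, 80, 80, 10, 99)
  truth <- c(1, 1, 2, 2, 3, 3, 4, 4, 1, 3)       # one deliberate mismatch
  expect_identical(birads_accuracy(pd10, truth), 0.9)
  expect_error(birads_accuracy(pd, c(0, 1, 2, 3)), "categories")
})
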