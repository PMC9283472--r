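test_that("a tiny model overfits a handful of phantoms", {
  samples <- tiny_phantoms(10, side = 32L, seed = 21)
  fit <- mtl_segnet(samples, network = tiny_config(side = 32L, base = 4L),
                    epochs = 10, batch_size = 4, validation = c(9L, 10L),
                    seed = 1)
  rp <- fit$report
  expect_identical(nrow(rp), 10L)
  expect_lt(rp$loss_total[10], rp$loss_total[1])
  expect_lt(rp$loss_dense[10], rp$loss_dense[1])
  expect_true(all(is.finite(rp$sigma_b)) && all(rp$sigma_b > 0))
  # adaptive weighting keeps sigma^2 on the order of the running losses
  expect_lt(rp$sigma_d[10]^2, 10 * max(rp$loss_dense[10], 0.05))
})

test_that("training is reproducible for a fixed seed", {
  samples <- tiny_phantoms(6, side = 32L, seed = 22)
  cfg <- tiny_config(side = 32L, base = 2L)
  f1 <- mtl_segnet(samples, network = cfg, epochs = 3, batch_size = 3,
                   seed = 5)
  f2 <- mtl_segnet(samples, network = cfg, epochs = 3, batch_size = 3,
                   seed = 5)
  expect_identical(f1$report, f2$report)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("single-task mode drops the other decoder entirely", {
  samples <- tiny_phantoms(6, side = 32L, seed = 23)
  fit <- mtl_segnet(samples, network = tiny_config(side = 32L, base = 2L),
                    epochs = 2, batch_size = 3, loss_mode = "single_breast",
                    seed = 2)
  expect_identical(fit$config$heads, "breast")
  expect_null(fit$report$loss_dense)
  expect_null(fit$report$val_fscore_dense)
  expect_null(fit$model$params$dec$dense)
  expect_null(fit$model$params$head$dense)
  # checkpoint round trip keeps the single-head structure
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(fit, path)
  expect_identical(load_checkpoint(path)$config$heads, "breast")
  pr <- predict_masks(fit, normalize_intensity(samples[[1]]$image))
  expect_named(pr, c("breast", "prob"))
})

test_that("prediction restores masks to the original resolution", {
  model <- build_model(tiny_config(side = 32L, base = 2L), seed = 3)
  img <- mammogram(matrix(runif(50 * 41), 50, 41))
  pr <- predict_masks(model, img)
  expect_identical(dim(pr$breast$pixels), c(50L, 41L))
  expect_identical(dim(pr$dense$pixels), c(50L, 41L))
  expect_true(all(pr$breast$pixels %in% c(0, 1)))
})

test_that("threshold ties go to foreground", {
  model <- build_model(tiny_config(side = 32L, base = 2L), seed = 4)
  # zero head weights force logits 0 -> probability exactly 0.5 everywhere
  model$params$head$breast$W[] <- 0; model$params$head$breast$b[] <- 0
  img <- mammogram(matrix(runif(32 * 32), 32, 32))
  pr <- predict_masks(model, img, threshold = 0.5)
  expect_true(all(pr$breast$pixels == 1))
  # a sub-threshold constant probability gives all background
  model$params$head$breast$b <- c(log(0.4 / 0.6), 0)
  pr <- predict_masks(model, img, threshold = 0.5)
  expect_true(all(pr$breast$pixels == 0))
})

test_that("lambda grid trains one model per cell and tabulates by view", {
  samples <- tiny_phantoms(8, side = 32L, seed = 24,
                           view_mix = c(CC = 1, MLO = 0))
  tab <- lambda_grid(samples, grid = 0.5,
                     network = tiny_config(side = 32L, base = 2L),
                     epochs = 2, batch_size = 4, seed = 6)
  expect_identical(nrow(tab), 1L)     # single lambda, single view
  expect_identical(tab$lambda, 0.5)
  expect_true(all(c("fscore_breast", "iou_breast", "fscore_dense",
                    "iou_dense") %in% names(tab)))
  tab2 <- lambda_grid(samples, grid = 0.5,
                      network = tiny_config(side = 32L, base = 2L),
                      epochs = 2, batch_size = 4, seed = 6)
  expect_identical(tab, tab2)
  expect_error(lambda_grid(samples, grid = c(0, 0.5)), "inside")
})

test_that("fitted-model methods expose coefficients and predictions", {
  samples <- tiny_phantoms(8, side = 32L, seed = 25)
  fit <- mtl_segnet(samples, network = tiny_config(side = 32L, base = 2L),
                    epochs = 2, batch_size = 4, seed = 7)
  co <- coef(fit)
  expect_named(co, c("s_b", "s_d", "sigma_b", "sigma_d"))
  expect_true(all(is.finite(co)))
  out <- suppressWarnings(predict(fit, samples[[1]]))
  expect_true(all(c("breast", "dense", "pd") %in% names(out)))
  expect_gte(out$pd, 0); expect_lte(out$pd, 100)
  pds <- suppressWarnings(predict(fit, samples[1:2], type = "pd"))
  expect_identical(length(pds), 2L)
  expect_output(print(fit), "Multitask")
  expect_output(print(summary(fit)), "Best epoch")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("training logs the per-epoch loss CSV contract", {
  samples <- tiny_phantoms(6, side = 32L, seed = 26)
  log_file <- withr::local_tempfile(fileext = ".csv")
  mtl_segnet(samples, network = tiny_config(side = 32L, base = 2L),
             epochs = 2, batch_size = 3, seed = 8, log_file = log_file)
  lg <- read.csv(log_file)
  expect_identical(names(lg), c("epoch", "loss_total", "loss_breast",
                                "loss_dense", "sigma_b", "sigma_d"))
  expect_identical(nrow(lg), 2L)
})
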