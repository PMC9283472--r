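test_that("identical spec and seed reproduce the phantom bit for bit", {
  sp <- phantom_spec(height = 48, width = 48, view = "MLO", target_pd = 20,
                     seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$breast$pixels, b$breast$pixels)
  expect_identical(a$dense$pixels, b$dense$pixels)
  expect_identical(a$true_pd, b$true_pd)
})

test_that("dense mask is nested inside the breast mask", {
  for (seed in 1:5) {
    s <- generate_phantom(phantom_spec(height = 48, width = 48,
                                       view = sample(c("CC", "MLO"), 1),
                                       target_pd = runif(1, 5, 60),
                                       seed = seed))
    expect_true(all(s$dense$pixels <= s$breast$pixels))
    expect_true(all(s$image$pixels >= 0 & s$image$pixels <= 1))
  }
})

test_that("MLO pectoral wedge is carved out of the breast mask", {
  # same seed means identical ellipse geometry; the views differ only by
  # the wedge, so the MLO breast mask must be a strict subset
  cc <- generate_phantom(phantom_spec(height = 64, width = 64, view = "CC",
                                      target_pd = 20, seed = 3))
  mlo <- generate_phantom(phantom_spec(height = 64, width = 64, view = "MLO",
                                       target_pd = 20, seed = 3))
  expect_true(all(mlo$breast$pixels <= cc$breast$pixels))
  expect_lt(sum(mlo$breast$pixels), sum(cc$breast$pixels))
  # the corner pixel sits inside the wedge: bright in MLO, not in the mask
  expect_identical(mlo$breast$pixels[1, 1], 0)
  expect_gt(mlo$image$pixels[2, 2], cc$image$pixels[2, 2])
})

test_that("zero target density with no blobs gives an empty dense mask", {
  s <- generate_phantom(phantom_spec(height = 48, width = 48,
                                     target_pd = 0, n_dense_blobs = 0,
                                     seed = 5))
  expect_identical(sum(s$dense$pixels), 0)
  expect_identical(s$true_pd, 0)
})

test_that("a positive target density without blobs fails loudly", {
  expect_error(
    generate_phantom(phantom_spec(height = 48, width = 48, target_pd = 30,
                                  n_dense_blobs = 0, seed = 5)),
    "unsatisfiable")
})

test_that("realised density hits the target and matches pixel counting", {
  s <- generate_phantom(phantom_spec(height = 256, width = 256,
                                     target_pd = 25, seed = 7))
  # independent pixel counting of the returned masks
  pd_by_hand <- 100 * sum(s$dense$pixels) / sum(s$breast$pixels)
  expect_lte(abs(pd_by_hand - 25), 2)
  expect_identical(s$true_pd, pd_by_hand)
  expect_identical(percent_density(s$breast, s$dense), pd_by_hand)
})

test_that("phantom spec validation rejects bad inputs", {
  expect_error(phantom_spec(height = 16), ">= 32")
  expect_error(phantom_spec(target_pd = 120))
  expect_error(phantom_spec(pectoral_fraction = 0.6))
  expect_error(phantom_spec(intensity_levels = c(background = 0.5, fat = 0.3,
                                                 dense = 0.7,
                                                 pectoral = 0.8)),
               "ordered")
})

test_that("generate_dataset produces a complete, reproducible manifest", {
  d1 <- generate_dataset(10, seed = 42, height = 48, width = 48)
  d2 <- generate_dataset(10, seed = 42, height = 48, width = 48)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(nrow(d1$manifest), 10L)
  expect_identical(nrow(generate_dataset(1, seed = 1, height = 48,
                                         width = 48)$manifest), 1L)
  expect_true(all(d1$manifest$view %in% c("CC", "MLO")))
  # sampled targets in [5, 45] with +-2 realisation tolerance
  expect_true(all(d1$manifest$true_pd >= 3 & d1$manifest$true_pd <= 47))
  # manifest PD equals mask pixel counting exactly
  for (i in seq_len(10)) {
    s <- d1$samples[[i]]
    expect_identical(d1$manifest$true_pd[i], percent_density(s$breast, s$dense))
  }
})

test_that("written phantoms round-trip through PNG", {
  out <- withr::local_tempdir()
  d <- generate_dataset(2, seed = 9, height = 48, width = 48, out_dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  man <- read.csv(file.path(out, "manifest.csv"), stringsAsFactors = FALSE)
  expect_identical(names(man), c("id", "view", "true_pd", "image_path",
                                 "breast_mask_path", "dense_mask_path"))
  m <- load_mask(man$breast_mask_path[1], "breast")
  expect_identical(m$pixels, d$samples[[1]]$breast$pixels)
  img <- load_image(man$image_path[1])
  # 8-bit quantisation on write: within half a grey level
  expect_lt(max(abs(img$pixels - d$samples[[1]]$image$pixels)), 0.5 / 255 + 1e-9)
})
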