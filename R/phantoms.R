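# Synthetic phantom mammograms with exact ground truth.
#
# A phantom is a half-elliptical "breast" against a dark background, with
# fibroglandular-like dense regions formed by thresholding a smooth random
# blob field, an optional bright pectoral wedge in the top corner for
# MLO-style images (excluded from the breast mask, mimicking the hard case
# of pectoral delineation), mild smoothing and additive Gaussian noise.
# Masks are fixed before smoothing/noise, so ground truth stays exact.

#' Specification of a synthetic phantom mammogram
#'
#' @param height,width Image size in pixels (at least 32).
#' @param view `"CC"` or `"MLO"`; MLO phantoms carry a bright pectoral wedge
#'   in the top chest-wall corner that is *not* part of the breast mask.
#' @param target_pd Desired percent density in `[0, 100]`.
#' @param n_dense_blobs Number of Gaussian blobs forming the dense field.
#' @param blob_scale Characteristic blob radius in pixels.
#' @param pectoral_fraction Image-area fraction of the pectoral wedge (MLO
#'   only), in `[0, 0.4]`.
#' @param intensity_levels Named numeric vector `(background, fat, dense,
#'   pectoral)`, each in `[0, 1]`, ordered background < fat < dense.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Optional integer seed; identical spec + seed reproduce the
#'   phantom bit for bit.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 256L, width = 256L, view = c("CC", "MLO"),
                         target_pd = 25, n_dense_blobs = 6L,
                         blob_scale = round(min(height, width) / 10),
                         pectoral_fraction = 0.12,
                         intensity_levels = c(background = 0.03, fat = 0.35,
                                              dense = 0.75, pectoral = 0.85),
                         noise_sd = 0.02, seed = NULL) {
  view <- match.arg(view)
  stopifnot(height >= 32, width >= 32,
            target_pd >= 0, target_pd <= 100,
            pectoral_fraction >= 0, pectoral_fraction <= 0.4,
            n_dense_blobs >= 0, blob_scale >= 1, noise_sd >= 0)
  il <- intensity_levels
  if (!all(c("background", "fat", "dense", "pectoral") %in% names(il)))
    stop("intensity_levels must name background, fat, dense, pectoral")
  if (!(il["background"] < il["fat"] && il["fat"] < il["dense"]))
    stop("intensity_levels must be ordered background < fat < dense")
  if (any(il < 0 | il > 1)) stop("intensity_levels must lie in [0, 1]")
  structure(list(height = as.integer(height), width = as.integer(width),
                 view = view, target_pd = target_pd,
                 n_dense_blobs = as.integer(n_dense_blobs),
                 blob_scale = blob_scale,
                 pectoral_fraction = pectoral_fraction,
                 intensity_levels = il, noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

#' Generate one phantom mammogram with exact ground truth
#'
#' The dense mask is obtained by ranking breast pixels by a smooth random
#' blob field and taking exactly the top fraction needed for `target_pd`,
#' so the realised PD always lies within the ±2 percentage-point tolerance
#' (up to one-pixel rounding). The returned sample's `true_pd` equals
#' `percent_density()` of the returned masks exactly.
#'
#' @param spec A [phantom_spec()].
#' @return An [annotated_sample()] with `true_pd` set.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  H <- spec$height; W <- spec$width
  il <- spec$intensity_levels
  row <- matrix(seq_len(H) - 0.5, H, W)          # y, down the image
  col <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)  # x, chest wall at x=0

  # breast: half ellipse anchored on the left edge, jittered geometry
  cy <- H * runif(1, 0.45, 0.55)
  a <- H * runif(1, 0.38, 0.46)                  # vertical semi-axis
  b <- W * runif(1, 0.60, 0.75)                  # horizontal semi-axis
  ellipse <- (col / b)^2 + ((row - cy) / a)^2 <= 1

  wedge <- matrix(FALSE, H, W)
  if (spec$view == "MLO" && spec$pectoral_fraction > 0) {
    # right triangle in the top-left corner with the requested area;
    # legs in a fixed 2:1 (vertical:horizontal) aspect
    area <- spec$pectoral_fraction * H * W
    x0 <- sqrt(area)                              # horizontal leg
    y0 <- 2 * x0                                  # vertical leg
    sc <- min(1, H / y0, W / x0)
    x0 <- x0 * sc; y0 <- y0 * sc
    wedge <- col / x0 + row / y0 < 1
  }
  breast <- ellipse & !wedge
  nb <- sum(breast)
  if (nb == 0) stop("degenerate phantom spec: empty breast area")

  k <- round(spec$target_pd / 100 * nb)
  dense <- matrix(FALSE, H, W)
  if (k > 0) {
    if (spec$n_dense_blobs == 0)
      stop("unsatisfiable target_pd = ", spec$target_pd,
           " with n_dense_blobs = 0 in phantom spec")
    field <- matrix(0, H, W)
    idx_breast <- which(breast)
    for (i in seq_len(spec$n_dense_blobs)) {
      ctr <- idx_breast[sample.int(length(idx_breast), 1)]
      cyb <- (ctr - 1) %% H + 0.5
      cxb <- (ctr - 1) %/% H + 0.5
      s <- spec$blob_scale * runif(1, 0.5, 1.2)
      amp <- runif(1, 0.6, 1)
      # slightly anisotropic bump for irregular borders
      sx <- s * runif(1, 0.7, 1.3); sy <- s * runif(1, 0.7, 1.3)
      field <- field + amp * exp(-(((col - cxb) / sx)^2 +
                                     ((row - cyb) / sy)^2) / 2)
    }
    fb <- field[idx_breast]
    ord <- order(fb, decreasing = TRUE)
    dense[idx_breast[ord[seq_len(k)]]] <- TRUE
  }

  true_pd <- 100 * sum(dense) / nb
  if (abs(true_pd - spec$target_pd) > 2)
    stop("could not realise target_pd = ", spec$target_pd,
         " within tolerance for this phantom spec")

  img <- matrix(il[["background"]], H, W)
  img[ellipse] <- il[["fat"]]
  img[wedge] <- il[["pectoral"]]
  img[dense] <- il[["dense"]]
  img <- blur_gaussian(img, sigma = 1)
  if (spec$noise_sd > 0)
    img <- img + matrix(rnorm(H * W, sd = spec$noise_sd), H, W)
  img <- pmin(pmax(img, 0), 1)

  annotated_sample(
    image = mammogram(img, view = spec$view),
    breast = binary_mask(breast * 1, role = "breast"),
    dense = binary_mask(dense * 1, role = "dense"),
    true_pd = true_pd)
}

# Separable Gaussian blur with replicated borders (internal).
blur_gaussian <- function(m, sigma, ksize = NULL) {
  if (is.null(ksize)) ksize <- 2L * ceiling(2 * sigma) + 1L
  half <- (ksize - 1L) %/% 2L
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- w / sum(w)
  A_r <- conv_border_matrix(nrow(m), w)
  A_c <- conv_border_matrix(ncol(m), w)
  A_r %*% m %*% t(A_c)
}

conv_border_matrix <- function(n, w) {
  half <- (length(w) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- pmin(pmax(i + (-half:half), 1L), n)
    for (k in seq_along(js)) A[i, js[k]] <- A[i, js[k]] + w[k]
  }
  A
}

#' Generate a phantom dataset with manifest
#'
#' Draws per-sample views and target densities, generates phantoms with
#' derived per-sample seeds (reproducible from the one master seed), and
#' optionally writes images and masks as PNG plus a CSV manifest with
#' columns `id,view,true_pd,image_path,breast_mask_path,dense_mask_path`.
#'
#' @param n Number of phantoms (>= 1).
#' @param seed Master seed.
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @param height,width Image size.
#' @param view_mix Named probabilities for `c(CC = , MLO = )`.
#' @param pd_range Uniform sampling range of the target percent density.
#' @param blob_range Integer range of dense blob counts.
#' @param noise_sd Intensity noise level passed to every phantom.
#' @param ... Further arguments forwarded to [phantom_spec()].
#' @return A list with `manifest` (data.frame) and `samples` (list of
#'   [annotated_sample()]).
#' @export
generate_dataset <- function(n, seed = 1L, out_dir = NULL,
                             height = 256L, width = 256L,
                             view_mix = c(CC = 0.5, MLO = 0.5),
                             pd_range = c(5, 45), blob_range = c(4L, 10L),
                             noise_sd = 0.02, ...) {
  stopifnot(n >= 1, length(pd_range) == 2, pd_range[1] <= pd_range[2])
  draws <- with_seed(seed, list(
    views = sample(c("CC", "MLO"), n, replace = TRUE,
                   prob = view_mix[c("CC", "MLO")]),
    pds = runif(n, pd_range[1], pd_range[2]),
    blobs = sample(seq(blob_range[1], blob_range[2]), n, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, n)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  }
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(height = height, width = width, view = draws$views[i],
                       target_pd = draws$pds[i],
                       n_dense_blobs = draws$blobs[i],
                       noise_sd = noise_sd, seed = draws$seeds[i], ...)
    s <- generate_phantom(sp)
    id <- sprintf("phantom_%04d", i)
    s$image$source_id <- id
    paths <- c(NA_character_, NA_character_, NA_character_)
    if (!is.null(out_dir)) {
      paths <- file.path(out_dir, paste0(id, c(".png", "_breast.png",
                                               "_dense.png")))
      save_image(s$image, paths[1])
      save_mask(s$breast, paths[2])
      save_mask(s$dense, paths[3])
    }
    samples[[i]] <- s
    rows[[i]] <- data.frame(id = id, view = draws$views[i],
                            true_pd = s$true_pd,
                            image_path = paths[1],
                            breast_mask_path = paths[2],
                            dense_mask_path = paths[3],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, samples = samples)
}
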