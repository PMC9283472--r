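# Image and mask containers, file IO and the preprocessing steps applied
# before the network: background zeroing, intensity normalisation, square
# resize for the model, and restoration of predictions to original size.

#' Mammogram container
#'
#' Holds a grayscale pixel grid with intensities in `[0, 1]`, the
#' acquisition view, the original pixel dimensions and a source identifier.
#' Coordinates are row-major with origin at the top left.
#'
#' @param pixels Numeric matrix of intensities.
#' @param view One of `"CC"`, `"MLO"`, `"unknown"`.
#' @param original_size Integer `(rows, cols)` of the source image.
#' @param source_id Free-text identifier.
#' @return An object of class `mammogram`.
#' @export
mammogram <- function(pixels, view = c("unknown", "CC", "MLO"),
                      original_size = dim(pixels), source_id = "") {
  view <- match.arg(view)
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  structure(list(pixels = pixels, view = view,
                 original_size = as.integer(original_size),
                 source_id = source_id),
            class = "mammogram")
}

#' Binary mask container
#'
#' @param pixels Matrix with values in `{0, 1}`.
#' @param role `"breast"` or `"dense"`.
#' @param original_size Integer `(rows, cols)` of the source image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, role = c("breast", "dense"),
                        original_size = dim(pixels)) {
  role <- match.arg(role)
  stopifnot(is.matrix(pixels))
  stopifnot_binary(pixels)
  structure(list(pixels = pixels, role = role,
                 original_size = as.integer(original_size)),
            class = "binary_mask")
}

#' Annotated sample: image plus ground-truth masks
#'
#' Bundles one mammogram with its breast-area and dense-tissue binary masks
#' (and optionally the true percent density). All grids must share
#' dimensions; dense-mask foreground outside the breast mask raises a
#' warning (or an error with `strict = TRUE`).
#'
#' @param image A [mammogram()].
#' @param breast,dense [binary_mask()] objects.
#' @param true_pd Optional percent density in `[0, 100]`.
#' @param strict Escalate the nesting warning to an error.
#' @return An object of class `annotated_sample`.
#' @export
annotated_sample <- function(image, breast, dense, true_pd = NULL,
                             strict = FALSE) {
  stopifnot(inherits(image, "mammogram"), inherits(breast, "binary_mask"),
            inherits(dense, "binary_mask"))
  if (!all(dim(image$pixels) == dim(breast$pixels)) ||
      !all(dim(image$pixels) == dim(dense$pixels)))
    stop("image and masks must share dimensions")
  if (any(dense$pixels > breast$pixels)) {
    msg <- "dense mask has foreground outside the breast mask"
    if (strict) stop(msg) else warning(msg)
  }
  structure(list(image = image, breast = breast, dense = dense,
                 true_pd = true_pd),
            class = "annotated_sample")
}

#' Load a grayscale image from PNG or TIFF
#'
#' Pixel values are scaled to `[0, 1]` by the file's bit depth (1/255 for
#' 8-bit, 1/65535 for 16-bit); no other normalisation is applied. Colour
#' images are rejected; a multi-channel file whose channels are identical
#' (or a grayscale+alpha file) is collapsed to its first channel.
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @param view Acquisition view tag.
#' @return A [mammogram()].
#' @export
load_image <- function(path, view = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               dcm = ,
               dicom = stop("DICOM input is not supported by this build; ",
                            "convert to PNG or TIFF first"),
               stop("unsupported image format: .", ext))
  px <- collapse_gray(px, path)
  mammogram(px, view = match.arg(view, c("unknown", "CC", "MLO")),
            source_id = basename(path))
}

collapse_gray <- function(px, path) {
  if (is.matrix(px)) return(px)
  nc <- dim(px)[3]
  if (nc == 2) return(px[, , 1])          # gray + alpha
  chans <- lapply(seq_len(min(nc, 3)), function(k) px[, , k])
  if (all(vapply(chans[-1], function(ch) isTRUE(all.equal(ch, chans[[1]])),
                 logical(1))))
    return(chans[[1]])
  stop("colour input rejected (", path, "); mammograms must be grayscale")
}

#' Load a binary mask from PNG
#'
#' On-disk masks use `{0, 255}`; pixels at or above 128 (0.5 after the PNG
#' scaling) become foreground.
#'
#' @param path PNG file path.
#' @param role Mask role (`"breast"` or `"dense"`).
#' @return A [binary_mask()].
#' @export
load_mask <- function(path, role = "breast") {
  img <- load_image(path)
  binary_mask((img$pixels >= 0.5) * 1, role = role)
}

#' Write a mammogram (8-bit PNG) to disk
#' @param img A [mammogram()] or numeric matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
save_image <- function(img, path) {
  px <- as_pixel_matrix(img)
  png::writePNG(pmin(pmax(px, 0), 1), path)
  invisible(path)
}

#' Write a binary mask as `{0, 255}` 8-bit PNG
#' @param mask A [binary_mask()] or binary matrix.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
save_mask <- function(mask, path) {
  px <- as_pixel_matrix(mask)
  stopifnot_binary(px)
  png::writePNG(px, path)
  invisible(path)
}

#' Zero all pixels outside the breast area
#'
#' Background pixels (breast-mask value 0) are set exactly to zero; pixels
#' inside the mask are unchanged. Idempotent.
#'
#' @param img A [mammogram()] or matrix.
#' @param breast A [binary_mask()] or binary matrix of the same size.
#' @return Same type as `img`.
#' @export
apply_breast_mask <- function(img, breast) {
  px <- as_pixel_matrix(img); bm <- as_pixel_matrix(breast)
  if (!all(dim(px) == dim(bm))) stop("dimension mismatch")
  out <- px * bm
  if (inherits(img, "mammogram")) { img$pixels <- out; img } else out
}

#' Min-max intensity normalisation
#'
#' Rescales `(p - min) / (max - min)` with the minimum and maximum taken
#' over the whole image or, if given, over a region mask only (values
#' outside the region are transformed with the same affine map). A constant
#' region yields an all-zero image with a warning. Alternatively,
#' `method = "match"` maps the image's intensity quantiles onto those of a
#' reference image (histogram matching).
#'
#' @param img A [mammogram()] or matrix.
#' @param region Optional [binary_mask()] restricting the statistics.
#' @param method `"minmax"` (default) or `"match"`.
#' @param reference Reference [mammogram()] or matrix for `method="match"`.
#' @return Same type as `img`, values in `[0, 1]`.
#' @export
normalize_intensity <- function(img, region = NULL,
                                method = c("minmax", "match"),
                                reference = NULL) {
  method <- match.arg(method)
  px <- as_pixel_matrix(img)
  if (method == "match") {
    if (is.null(reference)) stop("method='match' needs a reference image")
    ref <- as_pixel_matrix(reference)
    qs <- seq(0, 1, length.out = 257)
    out <- matrix(stats::approx(quantile(px, qs, names = FALSE),
                                quantile(ref, qs, names = FALSE),
                                xout = px, ties = "ordered", rule = 2)$y,
                  nrow(px), ncol(px))
  } else {
    vals <- if (is.null(region)) px else px[as_pixel_matrix(region) == 1]
    lo <- min(vals); hi <- max(vals)
    if (hi - lo <= 0) {
      warning("constant intensity region; returning all zeros")
      out <- matrix(0, nrow(px), ncol(px))
    } else {
      out <- pmin(pmax((px - lo) / (hi - lo), 0), 1)
    }
  }
  if (inherits(img, "mammogram")) { img$pixels <- out; img } else out
}

#' Resize an image or mask to the square model input size
#'
#' Images are resampled with bicubic interpolation (clipped back to
#' `[0, 1]`); masks use nearest-neighbour resampling, so they remain
#' strictly binary. The original size is retained on the object so
#' predictions can be restored later. Non-square inputs are stretched
#' anisotropically to the square target.
#'
#' @param x A [mammogram()] or [binary_mask()].
#' @param side Target side length in pixels (default 256).
#' @return Same class as `x`, at `side x side`.
#' @export
resize_for_model <- function(x, side = 256L) {
  stopifnot(side >= 32)
  if (inherits(x, "mammogram")) {
    out <- pmin(pmax(resize_matrix_interp(x$pixels, side, side, "cubic"),
                     0), 1)
    mammogram(out, view = x$view, original_size = x$original_size,
              source_id = x$source_id)
  } else if (inherits(x, "binary_mask")) {
    binary_mask(resize_matrix_nearest(x$pixels, side, side), role = x$role,
                original_size = x$original_size)
  } else stop("x must be a mammogram or binary_mask")
}

#' Restore a mask or probability map to the original image size
#'
#' Binary masks are resampled nearest-neighbour (staying binary);
#' probability maps are resampled bilinearly and optionally re-thresholded.
#'
#' @param x A [binary_mask()], or a numeric probability matrix.
#' @param original_size Target `(rows, cols)`; defaults to the mask's
#'   recorded original size.
#' @param threshold Optional threshold applied to a probability map after
#'   bilinear resampling.
#' @return Same type as `x` at `original_size`.
#' @export
restore_to_original <- function(x, original_size = NULL, threshold = NULL) {
  if (inherits(x, "binary_mask")) {
    original_size <- original_size %||% x$original_size
    if (is.null(original_size)) stop("original_size not recorded")
    out <- resize_matrix_nearest(x$pixels, original_size[1], original_size[2])
    binary_mask(out, role = x$role, original_size = original_size)
  } else {
    if (is.null(original_size)) stop("original_size must be given")
    out <- resize_matrix_interp(x, original_size[1], original_size[2],
                                "linear")
    if (!is.null(threshold)) out <- (out >= threshold) * 1
    out
  }
}

#' @export
print.mammogram <- function(x, ...) {
  cat("<mammogram> ", nrow(x$pixels), "x", ncol(x$pixels),
      "  view=", x$view,
      "  range=[", signif(min(x$pixels), 3), ", ",
      signif(max(x$pixels), 3), "]",
      if (nzchar(x$source_id)) paste0("  id=", x$source_id), "\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", nrow(x$pixels), "x", ncol(x$pixels),
      "  role=", x$role, "  foreground=", sum(x$pixels), " px\n", sep = "")
  invisible(x)
}

#' @export
print.annotated_sample <- function(x, ...) {
  cat("<annotated_sample> ", nrow(x$image$pixels), "x",
      ncol(x$image$pixels), "  view=", x$image$view,
      if (!is.null(x$true_pd)) paste0("  true_pd=", round(x$true_pd, 2), "%"),
      "\n", sep = "")
  invisible(x)
}
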