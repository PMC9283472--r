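# Area-based percent density, the conventional Otsu baseline, BI-RADS
# categorisation, and the two-reader reference-PD construction.

#' Area-based percent density from a mask pair
#'
#' `PD = 100 * (dense foreground pixels) / (breast foreground pixels)`. The
#' masks are deliberately not intersected first; if dense foreground falls
#' outside the breast mask a warning is raised and the result is clipped to
#' 100 so PD always stays in `[0, 100]`.
#'
#' @param breast,dense [binary_mask()] objects or binary matrices of equal
#'   size.
#' @return Percent density in `[0, 100]`.
#' @export
percent_density <- function(breast, dense) {
  bm <- as_pixel_matrix(breast); dm <- as_pixel_matrix(dense)
  if (!all(dim(bm) == dim(dm))) stop("dimension mismatch")
  stopifnot_binary(bm, "breast mask"); stopifnot_binary(dm, "dense mask")
  nb <- sum(bm)
  if (nb == 0) stop("undefined percent density: breast mask is empty")
  pd <- 100 * sum(dm) / nb
  if (any(dm > bm)) {
    warning("dense mask extends outside the breast mask; PD clipped to 100")
    pd <- min(pd, 100)
  }
  pd
}

#' Otsu threshold of an 8-bit grayscale sample
#'
#' Exhaustively maximises the between-class variance over the 256-bin
#' histogram; the lowest maximising level is returned. Pixels with value
#' `<= level` form the lower class.
#'
#' @param gray Integer values in 0..255, or numerics in `[0, 1]` which are
#'   quantised by `round(x * 255)`. Any shape (vector or matrix).
#' @return The threshold level (integer in 0..254).
#' @export
otsu_threshold <- function(gray) {
  v <- as.vector(as_pixel_matrix(gray))
  if (max(v) <= 1 && min(v) >= 0 && !all(v == round(v))) v <- round(v * 255)
  if (any(v < 0 | v > 255)) stop("gray values must be 8-bit (0..255)")
  v <- as.integer(round(v))
  if (length(unique(v)) < 2) stop("constant image: Otsu threshold undefined")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # between-class variance at thresholds t = 0..254 (class 0 is <= t)
  num <- (mu_t * w0 - mu)^2
  den <- w0 * w1
  bcv <- ifelse(den > 0, num / den, 0)[1:255]
  which.max(bcv) - 1L
}

#' Percent density by the conventional Otsu baseline
#'
#' Four steps: zero the background through the breast mask, smooth with a
#' 5x5 Gaussian blur, threshold the fibroglandular tissue with Otsu
#' computed over breast-interior pixels only (the zeroed background would
#' otherwise corrupt the histogram), and apply the percent-density formula.
#' Pixels above the threshold inside the breast count as dense.
#'
#' @param img A [mammogram()] or intensity matrix in `[0, 1]`.
#' @param breast A [binary_mask()] or binary matrix.
#' @param blur_ksize Gaussian kernel size (default 5).
#' @return A list with `pd`, the `threshold` (8-bit level, `NA` for the
#'   degenerate constant-breast case) and the estimated `dense` mask.
#' @export
otsu_pd <- function(img, breast, blur_ksize = 5L) {
  px <- as_pixel_matrix(img); bm <- as_pixel_matrix(breast)
  if (!all(dim(px) == dim(bm))) stop("dimension mismatch")
  if (sum(bm) == 0) stop("undefined percent density: breast mask is empty")
  masked <- px * bm
  # degeneracy is judged on the unblurred breast interior: blurring mixes
  # boundary pixels with the zeroed background and would fake contrast
  # inside an actually constant breast
  if (length(unique(round(px[bm == 1] * 255))) < 2) {
    warning("constant breast region; Otsu PD degenerates to 0")
    return(list(pd = 0,
                threshold = NA_integer_,
                dense = binary_mask(matrix(0, nrow(px), ncol(px)),
                                    role = "dense")))
  }
  # sigma from kernel size by the usual rule sigma = 0.3*((k-1)/2 - 1) + 0.8
  sigma <- 0.3 * ((blur_ksize - 1) / 2 - 1) + 0.8
  sm <- blur_gaussian(masked, sigma = sigma, ksize = blur_ksize)
  q <- round(pmin(pmax(sm, 0), 1) * 255)
  inside <- q[bm == 1]
  thr <- otsu_threshold(inside)
  dense <- (q > thr & bm == 1) * 1
  list(pd = percent_density(bm, dense), threshold = thr,
       dense = binary_mask(dense, role = "dense"))
}

#' BI-RADS (4th edition) density category from percent density
#'
#' Four 25-point intervals: category 1 for PD in 0-25, 2 for 26-50, 3 for
#' 51-75, 4 for 76-100; interval upper bounds are inclusive (PD = 25 is
#' category 1). Vectorised.
#'
#' @param pd Percent density values in `[0, 100]`.
#' @return Integer categories in `{1, 2, 3, 4}`.
#' @export
birads_category <- function(pd) {
  if (any(!is.finite(pd)) || any(pd < 0 | pd > 100))
    stop("pd must lie in [0, 100]")
  as.integer(1L + (pd > 25) + (pd > 50) + (pd > 75))
}

#' Build reference PD values from two readers
#'
#' Two readers' PD values for the same images are compared against the
#' clinically acceptable difference (CDI, default ±5 percentage points);
#' pairs within the CDI are averaged into the reference PD, pairs outside
#' are retained but flagged and get no reference value.
#'
#' @param a,b Data frames with columns `sample_id` and `pd` (one row per
#'   image, the same ids in both).
#' @param cdi CDI half-width in percentage points.
#' @return Data frame with columns `sample_id`, `pd_a`, `pd_b`,
#'   `within_cdi`, `reference` (`NA` outside the CDI).
#' @export
build_reference_pd <- function(a, b, cdi = 5) {
  stopifnot(all(c("sample_id", "pd") %in% names(a)),
            all(c("sample_id", "pd") %in% names(b)))
  if (!setequal(a$sample_id, b$sample_id) ||
      anyDuplicated(a$sample_id) || anyDuplicated(b$sample_id))
    stop("reader series must cover the same sample_ids exactly once")
  b <- b[match(a$sample_id, b$sample_id), ]
  within <- abs(a$pd - b$pd) <= cdi
  data.frame(sample_id = a$sample_id, pd_a = a$pd, pd_b = b$pd,
             within_cdi = within,
             reference = ifelse(within, (a$pd + b$pd) / 2, NA_real_),
             stringsAsFactors = FALSE)
}
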