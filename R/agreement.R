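# Agreement statistics between percent-density series: Pearson correlation
# with Fisher-z confidence intervals, Bland-Altman limits of agreement,
# mean-difference summary tables and BI-RADS classification accuracy.

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation between two PD series with a two-sided
#' confidence interval from the Fisher z-transform (standard error
#' `1/sqrt(n - 3)`). With `transform = "log"` both series are shifted by a
#' small epsilon (to admit PD = 0) and log-transformed first, the
#' convention used when density distributions are right skewed.
#'
#' @param a,b Numeric series of equal length (>= 3).
#' @param level Confidence level (default 0.95).
#' @param transform `"none"` or `"log"`.
#' @param eps Shift used by the log transform, in percentage points.
#' @return An object of class `correlation_result`: list with `r`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `transform`, `level`.
#' @export
pearson_ci <- function(a, b, level = 0.95, transform = c("none", "log"),
                       eps = 0.01) {
  transform <- match.arg(transform)
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (transform == "log") {
    if (any(a + eps <= 0) || any(b + eps <= 0))
      stop("log transform needs values > -eps")
    a <- log(a + eps); b <- log(b + eps)
  }
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in a series: correlation undefined")
  ct <- cor.test(a, b, method = "pearson", conf.level = level)
  structure(list(r = unname(ct$estimate),
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 p_value = ct$p.value, n = length(a),
                 transform = transform, level = level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f [%d%% CI %.3f, %.3f], n = %d%s\n",
              x$r, round(100 * x$level), x$ci_low, x$ci_high, x$n,
              if (x$transform == "log") ", log scale" else ""))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` (optionally after a log transform) give the bias
#' (mean difference), the sample standard deviation of differences, and the
#' limits of agreement `bias ± 1.96 * SD`. The fraction of differences
#' within the LoA is computed on the same (possibly transformed)
#' differences; the CDI acceptance fraction is always computed on the raw,
#' untransformed differences against ±`cdi` percentage points.
#'
#' @param a,b Numeric series of equal length (>= 2).
#' @param transform `"none"` or `"log"` (applied with shift `eps`).
#' @param cdi Clinically acceptable difference, percentage points.
#' @param eps Shift used by the log transform.
#' @return An object of class `bland_altman_result`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `within_loa_fraction`,
#'   `within_cdi_fraction`, `n`, `transform`, plus the per-image `means`
#'   and `diffs` used for plotting.
#' @export
bland_altman <- function(a, b, transform = c("none", "log"), cdi = 5,
                         eps = 0.01) {
  transform <- match.arg(transform)
  stopifnot(length(a) == length(b), length(a) >= 2)
  raw_diff <- a - b
  if (transform == "log") {
    ta <- log(a + eps); tb <- log(b + eps)
  } else {
    ta <- a; tb <- b
  }
  d <- ta - tb
  bias <- mean(d)
  sd_diff <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_diff
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = loa[1], loa_high = loa[2],
                 within_loa_fraction = mean(d >= loa[1] & d <= loa[2]),
                 within_cdi_fraction = mean(abs(raw_diff) <= cdi),
                 n = length(a), transform = transform,
                 means = (ta + tb) / 2, diffs = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.4f, LoA [%.4f, %.4f], %.1f%% within LoA, %.1f%% within CDI (n = %d%s)\n",
    x$bias, x$loa_low, x$loa_high, 100 * x$within_loa_fraction,
    100 * x$within_cdi_fraction, x$n,
    if (x$transform == "log") ", log scale" else ""))
  invisible(x)
}

#' @describeIn bland_altman Scatter of differences against means with bias
#'   and LoA lines.
#' @param x A `bland_altman_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman_result <- function(x, ...) {
  plot(x$means, x$diffs, xlab = "Mean of methods",
       ylab = "Difference between methods", pch = 16, ...)
  abline(h = x$bias, lty = 2, col = "blue")
  abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Mean and mean-difference summary per method against a reference
#'
#' One row per method with its mean ± SD and the signed mean difference
#' `mean(method) - mean(reference)`; a negative value means the method
#' underestimates the reference. The reference row is included with a mean
#' difference of 0.
#'
#' @param methods Named list of numeric PD series, all aligned to
#'   `reference`.
#' @param reference Numeric reference PD series.
#' @param reference_name Label for the reference row.
#' @return Data frame with columns `method`, `mean`, `sd`, `mean_diff`.
#' @export
mean_difference_table <- function(methods, reference,
                                  reference_name = "reference") {
  stopifnot(is.list(methods), !is.null(names(methods)))
  for (m in names(methods))
    if (length(methods[[m]]) != length(reference))
      stop("series '", m, "' is not aligned with the reference")
  rows <- lapply(names(methods), function(m) {
    v <- methods[[m]]
    data.frame(method = m, mean = mean(v), sd = sd(v),
               mean_diff = mean(v) - mean(reference),
               stringsAsFactors = FALSE)
  })
  ref_row <- data.frame(method = reference_name, mean = mean(reference),
                        sd = sd(reference), mean_diff = 0,
                        stringsAsFactors = FALSE)
  out <- rbind(ref_row, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' BI-RADS classification accuracy of estimated percent densities
#'
#' Maps the estimated PD values to BI-RADS 4th-edition categories (25-point
#' intervals) and reports the fraction matching the given true categories.
#'
#' @param pred_pd Estimated percent densities.
#' @param true_categories Integer categories in `{1, 2, 3, 4}`.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
birads_accuracy <- function(pred_pd, true_categories) {
  stopifnot(length(pred_pd) == length(true_categories))
  if (!all(true_categories %in% 1:4))
    stop("true categories must be in {1, 2, 3, 4}")
  mean(birads_category(pred_pd) == as.integer(true_categories))
}
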