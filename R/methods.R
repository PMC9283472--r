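# S3 methods for the fitted model object.

#' @export
print.mtl_segnet <- function(x, ...) {
  cfg <- x$config
  cat("Multitask mammogram segmentation model\n")
  cat(sprintf("  input %dx%d, depth %d, base width %d, norm %s\n",
              cfg$input_side, cfg$input_side, cfg$depth, cfg$base_width,
              cfg$norm))
  cat(sprintf("  heads: %s  |  loss mode: %s\n",
              paste(cfg$heads, collapse = ", "), x$control$loss_mode))
  cat(sprintf("  parameters: %s  |  epochs: %d (best: %d)\n",
              format(n_parameters(x), big.mark = ","),
              x$control$epochs, x$best_epoch))
  last <- x$report[x$report$epoch == x$best_epoch, ]
  for (h in cfg$heads)
    cat(sprintf("  best validation %s: F = %.3f, IoU = %.3f\n", h,
                last[[paste0("val_fscore_", h)]],
                last[[paste0("val_iou_", h)]]))
  if (x$control$loss_mode == "adaptive")
    cat(sprintf("  task uncertainties: sigma_b = %.3f, sigma_d = %.3f\n",
                last$sigma_b, last$sigma_d))
  invisible(x)
}

#' @export
summary.mtl_segnet <- function(object, ...) {
  out <- list(config = object$config, control = object$control,
              best_epoch = object$best_epoch,
              n_parameters = n_parameters(object),
              report = object$report)
  class(out) <- "summary.mtl_segnet"
  out
}

#' @export
print.summary.mtl_segnet <- function(x, ...) {
  cat("Training report (one row per epoch):\n")
  print(utils::tail(x$report, 10))
  cat("\nBest epoch:", x$best_epoch, " Parameters:", x$n_parameters, "\n")
  invisible(x)
}

#' Extract fitted task weights
#'
#' Returns the learned log-variances and the implied task uncertainties
#' sigma of the adaptive multitask loss (and the fixed lambda for the
#' naive mode).
#'
#' @param object A fitted [mtl_segnet()].
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.mtl_segnet <- function(object, ...) {
  u <- object$model$uncertainty
  out <- c(s_b = u$s_b, s_d = u$s_d,
           sigma_b = sqrt(exp(u$s_b)), sigma_d = sqrt(exp(u$s_d)))
  if (object$control$loss_mode == "naive")
    out <- c(out, lambda = object$control$lambda)
  out
}

#' Predict segmentation masks and percent density
#'
#' @param object A fitted [mtl_segnet()].
#' @param newdata A [mammogram()], an [annotated_sample()], or a list of
#'   either.
#' @param type `"mask"` returns the binary masks (and PD when both heads
#'   exist); `"pd"` returns just the percent-density values; `"prob"`
#'   returns model-resolution probability maps.
#' @param threshold Probability threshold (default: the training setting).
#' @param ... Unused.
#' @return For a single input, a list with `breast`, `dense`, `pd` (or the
#'   requested type); for a list input, a list of such results (`type =
#'   "pd"` gives a numeric vector).
#' @export
predict.mtl_segnet <- function(object, newdata,
                               type = c("mask", "pd", "prob"),
                               threshold = NULL, ...) {
  type <- match.arg(type)
  threshold <- threshold %||% object$control$threshold
  one <- function(x) {
    img <- if (inherits(x, "annotated_sample")) x$image else x
    stopifnot(inherits(img, "mammogram"))
    pr <- predict_masks(object, normalize_intensity(img), threshold)
    if (type == "prob") return(pr$prob)
    res <- pr[object$config$heads]
    if (all(c("breast", "dense") %in% names(res)))
      res$pd <- percent_density(res$breast, res$dense)
    if (type == "pd") {
      if (is.null(res$pd)) stop("percent density needs both heads")
      return(res$pd)
    }
    res
  }
  if (inherits(newdata, c("mammogram", "annotated_sample"))) return(one(newdata))
  out <- lapply(newdata, one)
  if (type == "pd") unlist(out) else out
}

#' Plot training curves of a fitted model
#'
#' Left: total (and per-task) loss per epoch; right: validation F-score
#' per task with the selected best epoch marked.
#'
#' @param x A fitted [mtl_segnet()].
#' @param ... Unused.
#' @export
plot.mtl_segnet <- function(x, ...) {
  rp <- x$report
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(rp$epoch, rp$loss_total, type = "l", lwd = 2, xlab = "epoch",
       ylab = "loss", main = "training loss")
  if (!is.null(rp$loss_breast)) lines(rp$epoch, rp$loss_breast, col = "blue")
  if (!is.null(rp$loss_dense)) lines(rp$epoch, rp$loss_dense, col = "red")
  legend("topright", bty = "n", lwd = c(2, 1, 1),
         col = c("black", "blue", "red"),
         legend = c("total", "breast", "dense")[c(TRUE,
                                                  !is.null(rp$loss_breast),
                                                  !is.null(rp$loss_dense))])
  fcols <- grep("^val_fscore_", names(rp), value = TRUE)
  plot(NULL, xlim = range(rp$epoch), ylim = c(0, 1), xlab = "epoch",
       ylab = "validation F-score", main = "validation")
  for (i in seq_along(fcols))
    lines(rp$epoch, rp[[fcols[i]]], col = i, lwd = 2)
  abline(v = x$best_epoch, lty = 3)
  legend("bottomright", bty = "n", lwd = 2, col = seq_along(fcols),
         legend = sub("val_fscore_", "", fcols))
  invisible(x)
}

#' Save a fitted model to a single checkpoint file
#'
#' The checkpoint embeds the network configuration as JSON metadata next to
#' the weights, so it is self-describing.
#'
#' @param object A fitted [mtl_segnet()] or an `mtl_model`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(object, path) {
  model <- if (inherits(object, "mtl_segnet")) object$model else object
  payload <- list(
    config_json = jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE),
    params = model$params,
    uncertainty = model$uncertainty,
    fit = if (inherits(object, "mtl_segnet"))
      object[c("report", "best_epoch", "control")] else NULL)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return An `mtl_model` (with fit metadata attached as attribute `"fit"`
#'   when present).
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  cfg <- jsonlite::fromJSON(payload$config_json)
  config <- network_config(in_channels = cfg$in_channels,
                           input_side = cfg$input_side, depth = cfg$depth,
                           base_width = cfg$base_width,
                           block_dilations = cfg$block_dilations,
                           bottleneck_dilations = cfg$bottleneck_dilations,
                           norm = cfg$norm, groups = cfg$groups,
                           heads = cfg$heads)
  model <- structure(list(params = payload$params,
                          uncertainty = payload$uncertainty,
                          config = config),
                     class = "mtl_model")
  attr(model, "fit") <- payload$fit
  model
}
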