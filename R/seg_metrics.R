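# Pixel-overlap segmentation metrics and dataset-level aggregation.

#' Precision, recall, F-score and IoU for one mask pair
#'
#' All four derive from the pixel counts `TP = |pred ∩ target|`,
#' `|pred|` and `|target|`: precision `TP/|pred|`, recall `TP/|target|`,
#' `F = 2PR/(P+R)` and `IoU = TP/|pred ∪ target|`. Conventions for empty
#' masks: both empty gives all four equal to 1 (perfect agreement), exactly
#' one empty gives 0; `F = 0` when `P = R = 0`. Note the identity
#' `IoU = F / (2 - F)`.
#'
#' @param pred,target [binary_mask()] objects or binary matrices of equal
#'   size.
#' @return A one-row data frame with columns `precision`, `recall`,
#'   `fscore`, `iou`, `n` (= 1).
#' @export
seg_score <- function(pred, target) {
  pm <- as_pixel_matrix(pred); tm <- as_pixel_matrix(target)
  if (!all(dim(pm) == dim(tm))) stop("dimension mismatch")
  stopifnot_binary(pm, "pred"); stopifnot_binary(tm, "target")
  tp <- sum(pm * tm)
  np <- sum(pm); nt <- sum(tm)
  if (np == 0 && nt == 0) {
    p <- r <- f <- iou <- 1
  } else if (np == 0 || nt == 0) {
    p <- r <- f <- iou <- 0
  } else {
    p <- tp / np
    r <- tp / nt
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    iou <- tp / (np + nt - tp)
  }
  data.frame(precision = p, recall = r, fscore = f, iou = iou, n = 1L)
}

#' Aggregate segmentation scores over a dataset
#'
#' Computes image-wise scores for every prediction/target pair and reports
#' the macro mean and sample (n-1) standard deviation per group (view x
#' tissue), plus a pooled `CC-MLO` row per tissue concatenating both views.
#' Groups with a single image report a standard deviation of 0.
#'
#' @param pairs List of `list(pred =, target =)` mask pairs.
#' @param view Character vector (`"CC"`/`"MLO"`) per pair.
#' @param tissue Character vector (e.g. `"breast"`/`"dense"`) per pair.
#' @return Data frame with one row per group: `view`, `tissue`, `n`, and
#'   `<metric>_mean` / `<metric>_sd` for precision, recall, fscore, iou.
#' @export
evaluate_dataset <- function(pairs, view = rep("CC", length(pairs)),
                             tissue = rep("breast", length(pairs))) {
  if (length(pairs) == 0) stop("empty collection")
  stopifnot(length(view) == length(pairs), length(tissue) == length(pairs))
  scores <- do.call(rbind, lapply(pairs, function(p)
    seg_score(p$pred, p$target)))
  scores$view <- view
  scores$tissue <- tissue
  agg_one <- function(df, view_label) {
    metrics <- c("precision", "recall", "fscore", "iou")
    out <- data.frame(view = view_label, tissue = df$tissue[1],
                      n = nrow(df))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(df[[m]])
      out[[paste0(m, "_sd")]] <- if (nrow(df) > 1) sd(df[[m]]) else 0
    }
    out
  }
  rows <- list()
  for (ti in unique(tissue)) {
    sub <- scores[scores$tissue == ti, ]
    for (v in unique(sub$view))
      rows[[length(rows) + 1]] <- agg_one(sub[sub$view == v, ], v)
    if (length(unique(sub$view)) > 1)
      rows[[length(rows) + 1]] <- agg_one(sub, "CC-MLO")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
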