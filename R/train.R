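# Model fitting: optimisation loop, ablation modes, lambda grid search and
# mask prediction.

#' Fit the multitask breast/dense-tissue segmentation model
#'
#' Trains the shared-encoder dual-decoder network on annotated samples with
#' the focal Tversky loss per task and one of four combination modes:
#' weight-adaptive homoscedastic-uncertainty weighting (default), the naive
#' fixed-lambda combination, or a single-task ablation (the unused decoder
#' is not built). Optimisation is Adam; model selection keeps the epoch
#' with the best validation F-score on the dense-tissue task (the main
#' task; the breast task for `single_breast`). Fully reproducible for a
#' fixed seed on the same numerical backend.
#'
#' @param samples List of [annotated_sample()] objects. Images are min-max
#'   normalised and, if needed, resized to `network$input_side` (bicubic;
#'   masks nearest-neighbour).
#' @param network A [network_config()].
#' @param epochs Number of training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param loss_mode `"adaptive"`, `"naive"`, `"single_breast"` or
#'   `"single_dense"`.
#' @param lambda Breast-task weight for `loss_mode = "naive"`, in (0, 1).
#' @param tversky A [tversky_params()].
#' @param threshold Probability threshold used when binarising validation
#'   predictions (ties go to foreground).
#' @param validation Fraction of samples held out for validation, or an
#'   integer vector of sample indices.
#' @param seed Master seed driving the split, weight initialisation and
#'   shuffling.
#' @param log_file Optional CSV path receiving per-epoch
#'   `epoch,loss_total,loss_breast,loss_dense,sigma_b,sigma_d` rows.
#' @param verbose Print per-epoch progress.
#' @return An object of class `mtl_segnet` with elements `model` (best
#'   weights), `report` (per-epoch data frame), `best_epoch`, `config`,
#'   `control`.
#' @export
mtl_segnet <- function(samples, network = network_config(),
                       epochs = 30L, batch_size = 8L, learning_rate = 1e-3,
                       loss_mode = c("adaptive", "naive", "single_breast",
                                     "single_dense"),
                       lambda = 0.3, tversky = tversky_params(),
                       threshold = 0.5, validation = 0.2, seed = 1L,
                       log_file = NULL, verbose = FALSE) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(length(samples) >= 2, epochs >= 1, threshold > 0, threshold < 1)
  heads <- switch(loss_mode,
                  single_breast = "breast",
                  single_dense = "dense",
                  c("breast", "dense"))
  if (!identical(network$heads, heads))
    network <- do.call(network_config,
                       modifyList(unclass(network)[setdiff(
                         names(unclass(network)), "classes_per_head")],
                         list(heads = heads)))
  seeds <- derive_seeds(seed, 3L + epochs)
  data <- prepare_samples(samples, network$input_side)

  # validation split
  n <- length(samples)
  if (length(validation) == 1 && validation > 0 && validation < 1) {
    n_val <- max(1L, round(validation * n))
    val_idx <- with_seed(seeds[1], sample.int(n, n_val))
  } else {
    val_idx <- as.integer(validation)
    stopifnot(all(val_idx >= 1), all(val_idx <= n))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0) stop("empty training split")

  model <- build_model(network, seed = seeds[2])
  opt <- adam_state(learning_rate)
  report <- list()
  best <- list(score = -Inf, epoch = NA_integer_, model = model)
  main_task <- if (loss_mode == "single_breast") "breast" else "dense"

  for (ep in seq_len(epochs)) {
    ord <- with_seed(seeds[3 + ep], sample(train_idx))
    ep_loss <- c(total = 0, breast = 0, dense = 0)
    nb <- 0L
    for (start in seq(1, length(ord), by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1, length(ord))]
      st <- train_step(model, data, ids, loss_mode, lambda, tversky, opt)
      model <- st$model
      if (!is.finite(st$loss_total))
        stop("non-finite loss at epoch ", ep, "; aborting")
      ep_loss <- ep_loss + c(st$loss_total, st$loss_breast %||% 0,
                             st$loss_dense %||% 0)
      nb <- nb + 1L
    }
    ep_loss <- ep_loss / nb
    val <- eval_on_indices(model, data, val_idx, threshold)
    row <- data.frame(epoch = ep, loss_total = ep_loss[["total"]])
    if ("breast" %in% heads) row$loss_breast <- ep_loss[["breast"]]
    if ("dense" %in% heads) row$loss_dense <- ep_loss[["dense"]]
    row$sigma_b <- sqrt(exp(model$uncertainty$s_b))
    row$sigma_d <- sqrt(exp(model$uncertainty$s_d))
    for (h in heads) {
      row[[paste0("val_fscore_", h)]] <- val[[h]]["fscore"]
      row[[paste0("val_iou_", h)]] <- val[[h]]["iou"]
    }
    report[[ep]] <- row
    score <- val[[main_task]]["fscore"]
    if (is.finite(score) && score > best$score)
      best <- list(score = score, epoch = ep, model = model)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val F(%s) %.4f", ep,
                      ep_loss[["total"]], main_task, score))
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  if (!is.null(log_file)) {
    lg <- data.frame(epoch = report$epoch, loss_total = report$loss_total,
                     loss_breast = report$loss_breast %||% NA_real_,
                     loss_dense = report$loss_dense %||% NA_real_,
                     sigma_b = report$sigma_b, sigma_d = report$sigma_d)
    write.csv(lg, log_file, row.names = FALSE)
  }
  structure(list(model = best$model, report = report,
                 best_epoch = best$epoch, config = network,
                 control = list(epochs = epochs, batch_size = batch_size,
                                learning_rate = learning_rate,
                                loss_mode = loss_mode, lambda = lambda,
                                threshold = threshold, seed = seed,
                                validation_idx = val_idx,
                                tversky = tversky),
                 call = match.call()),
            class = "mtl_segnet")
}

# Stack samples into arrays at model resolution (internal).
prepare_samples <- function(samples, side) {
  n <- length(samples)
  X <- array(0, c(side, side, 1L, n))
  Yb <- array(0, c(side, side, n))
  Yd <- array(0, c(side, side, n))
  views <- character(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    stopifnot(inherits(s, "annotated_sample"))
    img <- normalize_intensity(s$image)
    breast <- s$breast; dense <- s$dense
    if (!all(dim(img$pixels) == c(side, side))) {
      img <- resize_for_model(img, side)
      breast <- resize_for_model(breast, side)
      dense <- resize_for_model(dense, side)
    }
    X[, , 1, i] <- img$pixels
    Yb[, , i] <- breast$pixels
    Yd[, , i] <- dense$pixels
    views[i] <- s$image$view
  }
  list(X = X, Yb = Yb, Yd = Yd, views = views, side = side)
}

## ---- Adam -------------------------------------------------------------

adam_state <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e$lr <- lr; e$b1 <- beta1; e$b2 <- beta2; e$eps <- eps
  e
}

adam_apply <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - opt$b1^opt$t
  corr2 <- 1 - opt$b2^opt$t
  tree_update(params, grads, function(value, grad, path) {
    m <- opt$m[[path]] %||% (grad * 0)
    v <- opt$v[[path]] %||% (grad * 0)
    m <- opt$b1 * m + (1 - opt$b1) * grad
    v <- opt$b2 * v + (1 - opt$b2) * grad^2
    opt$m[[path]] <- m
    opt$v[[path]] <- v
    value - opt$lr * (m / corr1) / (sqrt(v / corr2) + opt$eps)
  })
}

adam_apply_scalar <- function(opt, value, grad, path) {
  m <- opt$m[[path]] %||% 0
  v <- opt$v[[path]] %||% 0
  m <- opt$b1 * m + (1 - opt$b1) * grad
  v <- opt$b2 * v + (1 - opt$b2) * grad^2
  opt$m[[path]] <- m
  opt$v[[path]] <- v
  corr1 <- 1 - opt$b1^opt$t
  corr2 <- 1 - opt$b2^opt$t
  value - opt$lr * (m / corr1) / (sqrt(v / corr2) + opt$eps)
}

## ---- one optimisation step -------------------------------------------

train_step <- function(model, data, ids, loss_mode, lambda, tversky, opt) {
  xb <- data$X[, , , ids, drop = FALSE]
  fw <- net_fwd(model, xb, training = TRUE)
  model <- fw$model
  heads <- model$config$heads
  losses <- list(); dlogits <- list()
  for (h in heads) {
    tg <- (if (h == "breast") data$Yb else data$Yd)[, , ids, drop = FALSE]
    fb <- ftl_batch(fw$probs[[h]], tg, tversky)
    losses[[h]] <- fb$loss
    w <- switch(loss_mode,
                adaptive = exp(-(if (h == "breast") model$uncertainty$s_b
                                 else model$uncertainty$s_d)),
                naive = if (h == "breast") lambda else 1 - lambda,
                1)
    dlogits[[h]] <- softmax2_bwd(fw$probs[[h]], w * fb$dprobs)
  }
  bk <- net_bwd(model, fw$cache, dlogits)
  model$params <- adam_apply(opt, model$params, bk$grads)
  loss_total <- switch(
    loss_mode,
    adaptive = adaptive_mtl_loss(losses$breast, losses$dense,
                                 model$uncertainty),
    naive = naive_mtl_loss(losses$breast, losses$dense, lambda),
    single_breast = losses$breast,
    single_dense = losses$dense)
  if (loss_mode == "adaptive" && isTRUE(model$uncertainty$trainable)) {
    gs <- adaptive_mtl_grad_s(losses$breast, losses$dense, model$uncertainty)
    model$uncertainty$s_b <- unname(adam_apply_scalar(
      opt, model$uncertainty$s_b, gs[["s_b"]], "/s_b"))
    model$uncertainty$s_d <- unname(adam_apply_scalar(
      opt, model$uncertainty$s_d, gs[["s_d"]], "/s_d"))
  }
  list(model = model, loss_total = loss_total,
       loss_breast = losses$breast, loss_dense = losses$dense)
}

## ---- evaluation helpers ----------------------------------------------

# Mean F-score / IoU per head over a set of sample indices, at model scale.
eval_on_indices <- function(model, data, idx, threshold, chunk = 8L) {
  heads <- model$config$heads
  acc <- lapply(heads, function(h) c(fscore = 0, iou = 0))
  names(acc) <- heads
  cnt <- 0L
  for (start in seq(1, length(idx), by = chunk)) {
    ids <- idx[start:min(start + chunk - 1, length(idx))]
    fw <- net_fwd(model, data$X[, , , ids, drop = FALSE], training = FALSE)
    for (h in heads) {
      tg <- (if (h == "breast") data$Yb else data$Yd)[, , ids, drop = FALSE]
      pr <- fw$probs[[h]]
      for (j in seq_along(ids)) {
        pm <- (pr[, , 1, j] >= threshold) * 1
        sc <- seg_score(pm, tg[, , j])
        acc[[h]] <- acc[[h]] + c(fscore = sc$fscore, iou = sc$iou)
      }
    }
    cnt <- cnt + length(ids)
  }
  lapply(acc, function(a) a / cnt)
}

#' Predict breast and dense masks for one mammogram
#'
#' Runs the trained model in evaluation mode, thresholds the
#' region-of-interest probability at `threshold` (ties count as
#' foreground), and restores the masks to the image's original resolution
#' by nearest-neighbour resampling.
#'
#' @param object A fitted [mtl_segnet()] or an `mtl_model`.
#' @param img A [mammogram()], already intensity-normalised; it is resized
#'   to the model input side internally if needed.
#' @param threshold Probability threshold in (0, 1).
#' @return List with `breast` and `dense` [binary_mask()] objects (those
#'   heads the model has) at the original resolution, and `prob`, the
#'   model-resolution foreground probability maps.
#' @export
predict_masks <- function(object, img, threshold = 0.5) {
  model <- if (inherits(object, "mtl_segnet")) object$model else object
  stopifnot(inherits(model, "mtl_model"), inherits(img, "mammogram"))
  side <- model$config$input_side
  orig <- if (all(dim(img$pixels) == c(side, side))) img$original_size
          else dim(img$pixels)
  rimg <- if (all(dim(img$pixels) == c(side, side))) img
          else resize_for_model(img, side)
  fw <- net_fwd(model, as_batch(rimg$pixels, model$config), training = FALSE)
  if (any(!is.finite(unlist(lapply(fw$probs, range)))))
    stop("model produced non-finite probabilities; is it trained?")
  out <- list()
  for (h in model$config$heads) {
    p <- fw$probs[[h]][, , 1, 1]
    m <- binary_mask((p >= threshold) * 1,
                     role = if (h == "breast") "breast" else "dense",
                     original_size = orig)
    out[[h]] <- restore_to_original(m, orig)
    out$prob[[h]] <- p
  }
  out
}

#' Grid search over the naive multitask weight lambda
#'
#' Trains one model per lambda value under identical seeds and data splits
#' and evaluates mean F-score and IoU per task on the validation split,
#' split by view (plus a pooled `CC-MLO` row when both views are present).
#'
#' @param samples List of [annotated_sample()] objects.
#' @param grid Lambda values, all strictly inside (0, 1).
#' @param network A [network_config()].
#' @param ... Passed on to [mtl_segnet()] (epochs, seed, ...).
#' @return Data frame sorted by lambda with columns `lambda`, `view`,
#'   `fscore_breast`, `iou_breast`, `fscore_dense`, `iou_dense`.
#' @export
lambda_grid <- function(samples, grid = seq(0.1, 0.9, by = 0.2),
                        network = network_config(), ...) {
  if (any(grid <= 0 | grid >= 1)) stop("grid values must lie inside (0, 1)")
  grid <- sort(grid)
  rows <- list()
  for (lam in grid) {
    fit <- mtl_segnet(samples, network = network, loss_mode = "naive",
                      lambda = lam, ...)
    ev <- evaluate_fit(fit, samples[fit$control$validation_idx])
    for (v in unique(ev$view)) {
      sub <- ev[ev$view == v, ]
      rows[[length(rows) + 1]] <- data.frame(
        lambda = lam, view = v,
        fscore_breast = sub$fscore_mean[sub$tissue == "breast"],
        iou_breast = sub$iou_mean[sub$tissue == "breast"],
        fscore_dense = sub$fscore_mean[sub$tissue == "dense"],
        iou_dense = sub$iou_mean[sub$tissue == "dense"])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Evaluate a fitted model on annotated samples at original resolution,
# grouped by view and tissue (internal; powers lambda_grid and summaries).
evaluate_fit <- function(fit, samples, threshold = NULL) {
  threshold <- threshold %||% fit$control$threshold
  pairs <- list(); views <- character(0); tissues <- character(0)
  for (s in samples) {
    pr <- predict_masks(fit, normalize_intensity(s$image), threshold)
    for (h in fit$config$heads) {
      tgt <- if (h == "breast") s$breast else s$dense
      pairs[[length(pairs) + 1]] <- list(pred = pr[[h]], target = tgt)
      views <- c(views, s$image$view)
      tissues <- c(tissues, h)
    }
  }
  evaluate_dataset(pairs, view = views, tissue = tissues)
}
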