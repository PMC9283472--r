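#' Network configuration for the multitask segmentation model
#'
#' Describes the shared-encoder / dual-decoder architecture: an encoder of
#' multilevel dilated residual (MDR) blocks with max-pool downsampling, a
#' bottleneck of parallel dilated convolutions (default rates 1, 3, 5) that
#' widens the receptive field, and one structurally identical decoder per
#' task (breast area, dense tissue) with transpose-convolution upsampling,
#' encoder skip concatenation and residual shortcuts, ending in a 1x1
#' two-class softmax head.
#'
#' @param in_channels Number of input channels (grayscale mammograms: 1).
#' @param input_side Square input size in pixels; must be divisible by
#'   `2^depth`. The full-scale model uses 256.
#' @param depth Number of downsampling stages in the encoder.
#' @param base_width Channel width of the first encoder stage; widths double
#'   at each stage.
#' @param block_dilations Dilation rates of the parallel 3x3 branches inside
#'   every encoder/decoder MDR block.
#' @param bottleneck_dilations Dilation rates of the parallel bottleneck
#'   convolutions.
#' @param norm Normalisation layer: `"batch"`, `"instance"`, `"group"` or
#'   `"wsgroup"` (weight-standardised convolutions + group normalisation).
#' @param groups Number of groups for group normalisation.
#' @param heads Which task decoders to build; the multitask model uses both,
#'   single-task ablations use one.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 1L, input_side = 256L, depth = 4L,
                           base_width = 64L, block_dilations = c(1L, 3L),
                           bottleneck_dilations = c(1L, 3L, 5L),
                           norm = c("batch", "instance", "group", "wsgroup"),
                           groups = 2L, heads = c("breast", "dense")) {
  norm <- match.arg(norm)
  stopifnot(depth >= 1, base_width >= 1, in_channels >= 1,
            length(heads) >= 1, all(heads %in% c("breast", "dense")))
  if (any(diff(as.integer(bottleneck_dilations)) <= 0) ||
      any(bottleneck_dilations < 1))
    stop("bottleneck dilations must be positive and strictly increasing")
  if (any(diff(as.integer(block_dilations)) <= 0) || any(block_dilations < 1))
    stop("block dilations must be positive and strictly increasing")
  if (input_side %% (2^depth) != 0)
    stop("input_side (", input_side, ") is not divisible by 2^depth (",
         2^depth, ")")
  structure(list(in_channels = as.integer(in_channels),
                 input_side = as.integer(input_side),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 block_dilations = as.integer(block_dilations),
                 bottleneck_dilations = as.integer(bottleneck_dilations),
                 norm = norm, groups = as.integer(groups),
                 classes_per_head = 2L, heads = heads),
            class = "network_config")
}

#' Multilevel dilated residual block
#'
#' One block: parallel 3x3 convolutions at the given dilation rates (each
#' followed by normalisation and a rectifier), channel concatenation, 1x1
#' fusion back to `out_channels`, plus a residual shortcut (identity when the
#' channel counts match, 1x1 projection otherwise). Spatial size is
#' preserved at every dilation rate. With all convolution weights zero the
#' block reduces exactly to its shortcut path.
#'
#' @param in_channels,out_channels Channel counts.
#' @param dilations Dilation rates of the parallel branches.
#' @param norm,groups Normalisation settings (see [network_config()]).
#' @return A block parameter object usable with [block_forward()].
#' @export
mdr_block <- function(in_channels, out_channels, dilations = c(1L, 3L),
                      norm = "batch", groups = 2L) {
  branches <- lapply(dilations, function(d) {
    list(conv = conv_init(in_channels, out_channels, k = 3L, dil = d),
         norm = norm_init(out_channels, norm, groups))
  })
  fuse <- conv_init(out_channels * length(dilations), out_channels, k = 1L)
  proj <- if (in_channels == out_channels) NULL
          else conv_init(in_channels, out_channels, k = 1L)
  list(type = "mdr", branches = branches, fuse = fuse, proj = proj)
}

#' Run a multilevel dilated residual block
#'
#' @param block A block from [mdr_block()].
#' @param x Input array with dim `(H, W, in_channels, N)`.
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @param ws Standardise convolution weights before use.
#' @return The output array with dim `(H, W, out_channels, N)`.
#' @export
block_forward <- function(block, x, training = FALSE, ws = FALSE) {
  mdr_fwd(block, x, training = training, ws = ws)$out
}

mdr_fwd <- function(block, x, training = TRUE, ws = FALSE) {
  outs <- vector("list", length(block$branches))
  caches <- vector("list", length(block$branches))
  for (j in seq_along(block$branches)) {
    br <- block$branches[[j]]
    cv <- conv_fwd(br$conv, x, ws = ws)
    nm <- norm_fwd(br$norm, cv$out, training = training)
    block$branches[[j]]$norm <- nm$layer
    rl <- relu_fwd(nm$out)
    outs[[j]] <- rl$out
    caches[[j]] <- list(conv = cv$cache, norm = nm$cache, relu = rl$cache)
  }
  catted <- cat_channels(outs)
  fu <- conv_fwd(block$fuse, catted, ws = FALSE)
  if (is.null(block$proj)) {
    short <- x; pcache <- NULL
  } else {
    pj <- conv_fwd(block$proj, x, ws = FALSE)
    short <- pj$out; pcache <- pj$cache
  }
  list(out = fu$out + short,
       cache = list(branches = caches, fuse = fu$cache, proj = pcache,
                    nb = length(block$branches),
                    bw = dim(outs[[1]])[3], ws = ws),
       block = block)
}

mdr_bwd <- function(block, cache, dout) {
  grads <- list(branches = vector("list", cache$nb))
  # residual shortcut
  if (is.null(block$proj)) {
    dx <- dout
    grads$proj <- NULL
  } else {
    pj <- conv_bwd(block$proj, cache$proj, dout)
    dx <- pj$dx
    grads$proj <- pj$grads
  }
  fu <- conv_bwd(block$fuse, cache$fuse, dout)
  grads$fuse <- fu$grads
  dcat <- fu$dx
  Cs <- rep(cache$bw, cache$nb)
  at <- 0L
  for (j in seq_len(cache$nb)) {
    dbr <- dcat[, , (at + 1):(at + Cs[j]), , drop = FALSE]
    at <- at + Cs[j]
    br <- block$branches[[j]]
    bc <- cache$branches[[j]]
    drl <- relu_bwd(bc$relu, dbr)
    nm <- norm_bwd(br$norm, bc$norm, drl)
    cv <- conv_bwd(br$conv, bc$conv, nm$dx)
    grads$branches[[j]] <- list(conv = cv$grads, norm = nm$grads)
    dx <- dx + cv$dx
  }
  list(dx = dx, grads = grads)
}

#' Build the multitask segmentation model
#'
#' Instantiates all trainable parameters: encoder MDR blocks (widths
#' `base_width * 2^(stage-1)`) with 2x2 max pooling between stages, a
#' bottleneck MDR block at the configured parallel dilation rates, and per
#' task a decoder of transpose-convolution upsampling stages with encoder
#' skip concatenation followed by MDR blocks, ending in a 1x1 softmax head
#' with two channels (region of interest, background). The encoder is shared
#' by both tasks; the two decoders are structurally identical but hold
#' independent parameters. Log-variance task uncertainties `s = log(sigma^2)`
#' are initialised to 0 (`sigma = 1`).
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for weight initialisation.
#' @return An object of class `mtl_model` with elements `params`, `config`
#'   and `uncertainty`.
#' @export
build_model <- function(config = network_config(), seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  with_seed(seed, {
    depth <- config$depth
    widths <- config$base_width * 2^(seq_len(depth) - 1L)
    bw <- config$base_width * 2^depth
    nrm <- config$norm; grp <- config$groups
    enc <- vector("list", depth)
    cin <- config$in_channels
    for (i in seq_len(depth)) {
      enc[[i]] <- mdr_block(cin, widths[i], config$block_dilations, nrm, grp)
      cin <- widths[i]
    }
    bottleneck <- mdr_block(widths[depth], bw, config$bottleneck_dilations,
                            nrm, grp)
    make_decoder <- function() {
      dec <- vector("list", depth)
      cur <- bw
      for (i in rev(seq_len(depth))) {
        dec[[i]] <- list(
          up = upconv_init(cur, widths[i]),
          block = mdr_block(2L * widths[i], widths[i],
                            config$block_dilations, nrm, grp))
        cur <- widths[i]
      }
      dec
    }
    decoders <- lapply(stats::setNames(config$heads, config$heads),
                       function(h) make_decoder())
    heads <- lapply(stats::setNames(config$heads, config$heads),
                    function(h) conv_init(widths[1], config$classes_per_head,
                                          k = 1L))
    structure(list(params = list(enc = enc, bottleneck = bottleneck,
                                 dec = decoders, head = heads),
                   uncertainty = list(s_b = 0, s_d = 0, trainable = TRUE),
                   config = config),
              class = "mtl_model")
  })
}

#' Forward pass of the multitask model
#'
#' Maps a batch of images to per-pixel two-class probability maps for every
#' configured head. Probabilities are produced by a channelwise softmax;
#' channel 1 is the region-of-interest class.
#'
#' @param model An `mtl_model` from [build_model()].
#' @param x Input: an `(H, W)` matrix, an `(H, W, 1, N)` array, or a list of
#'   matrices (stacked into a batch).
#' @param training Use batch statistics in normalisation layers (training
#'   mode) instead of running statistics.
#' @return A list with one element per head, each an `(H, W, 2, N)`
#'   probability array; attribute `"logits"` carries the pre-softmax maps.
#' @export
forward <- function(model, x, training = FALSE) {
  x <- as_batch(x, model$config)
  r <- net_fwd(model, x, training = training)
  probs <- lapply(r$probs, identity)
  attr(probs, "logits") <- r$logits
  probs
}

as_batch <- function(x, config) {
  if (is.list(x) && !is.array(x))
    x <- simplify2array(lapply(x, as_pixel_matrix))
  x <- as_pixel_matrix(x)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) {           # (H, W, N) stack of grayscale images
    d <- dim(x)
    y <- array(x, c(d[1], d[2], 1L, d[3]))
    x <- y
  }
  d <- dim(x)
  if (d[1] != config$input_side || d[2] != config$input_side)
    stop("input spatial size ", d[1], "x", d[2], " does not match the ",
         "configured input_side ", config$input_side)
  x
}

# Full forward with caches (internal; used by the training step).
net_fwd <- function(model, x, training = TRUE) {
  p <- model$params
  cfg <- model$config
  ws <- cfg$norm == "wsgroup"
  depth <- cfg$depth
  skips <- vector("list", depth)
  enc_caches <- vector("list", depth)
  pool_caches <- vector("list", depth)
  a <- x
  for (i in seq_len(depth)) {
    r <- mdr_fwd(p$enc[[i]], a, training = training, ws = ws)
    p$enc[[i]] <- r$block
    skips[[i]] <- r$out
    enc_caches[[i]] <- r$cache
    pl <- cpp_maxpool_fwd(r$out)
    pool_caches[[i]] <- list(idx = pl$idx, H = dim(r$out)[1], W = dim(r$out)[2])
    a <- pl$y
  }
  bt <- mdr_fwd(p$bottleneck, a, training = training, ws = ws)
  p$bottleneck <- bt$block
  probs <- list(); logits <- list()
  dec_caches <- list()
  for (h in cfg$heads) {
    u <- bt$out
    hc <- vector("list", depth)
    for (i in rev(seq_len(depth))) {
      up <- upconv_fwd(p$dec[[h]][[i]]$up, u)
      cc <- cat_channels(list(up$out, skips[[i]]))
      bl <- mdr_fwd(p$dec[[h]][[i]]$block, cc, training = training, ws = ws)
      p$dec[[h]][[i]]$block <- bl$block
      hc[[i]] <- list(up = up$cache, block = bl$cache,
                      Cs = c(dim(up$out)[3], dim(skips[[i]])[3]))
      u <- bl$out
    }
    hd <- conv_fwd(p$head[[h]], u, ws = FALSE)
    dec_caches[[h]] <- list(stages = hc, head = hd$cache)
    logits[[h]] <- hd$out
    probs[[h]] <- softmax2(hd$out)
  }
  model$params <- p
  list(probs = probs, logits = logits, model = model,
       cache = list(enc = enc_caches, pool = pool_caches, bt = bt$cache,
                    dec = dec_caches, skips_dim = lapply(skips, dim)))
}

# Backward pass: dlogits is a named list (per head) of (H, W, 2, N) arrays.
net_bwd <- function(model, cache, dlogits) {
  p <- model$params
  cfg <- model$config
  depth <- cfg$depth
  grads <- list(enc = vector("list", depth), bottleneck = NULL,
                dec = list(), head = list())
  dskips <- lapply(cache$skips_dim, function(d) array(0, d))
  dbt_out <- NULL
  for (h in names(dlogits)) {
    dc <- cache$dec[[h]]
    hd <- conv_bwd(p$head[[h]], dc$head, dlogits[[h]])
    grads$head[[h]] <- hd$grads
    du <- hd$dx
    gstages <- vector("list", depth)
    for (i in seq_len(depth)) {
      st <- dc$stages[[i]]
      bl <- mdr_bwd(p$dec[[h]][[i]]$block, st$block, du)
      parts <- split_channels(bl$dx, st$Cs)
      dskips[[i]] <- dskips[[i]] + parts[[2]]
      up <- upconv_bwd(p$dec[[h]][[i]]$up, st$up, parts[[1]])
      gstages[[i]] <- list(up = up$grads, block = bl$grads)
      du <- up$dx
    }
    grads$dec[[h]] <- gstages
    dbt_out <- if (is.null(dbt_out)) du else dbt_out + du
  }
  bt <- mdr_bwd(p$bottleneck, cache$bt, dbt_out)
  grads$bottleneck <- bt$grads
  da <- bt$dx
  for (i in rev(seq_len(depth))) {
    dpooled <- cpp_maxpool_bwd(da, cache$pool[[i]]$idx,
                               cache$pool[[i]]$H, cache$pool[[i]]$W)
    dblock_out <- dpooled + dskips[[i]]
    er <- mdr_bwd(p$enc[[i]], cache$enc[[i]], dblock_out)
    grads$enc[[i]] <- er$grads
    da <- er$dx
  }
  list(grads = grads, dx = da)
}

#' Count trainable parameters of a model
#'
#' @param model An `mtl_model` or fitted `mtl_segnet` object.
#' @return Integer number of trainable scalar parameters (network weights;
#'   the two task log-variances are excluded).
#' @export
n_parameters <- function(model) {
  if (inherits(model, "mtl_segnet")) model <- model$model
  count_leaves <- function(x) {
    if (is.list(x)) {
      n <- 0
      if (!is.null(x$type)) {
        flds <- trainable_fields(x)
        for (f in flds) n <- n + length(x[[f]])
        others <- setdiff(names(x), c(flds, "type", "norm", "groups", "k",
                                      "dil", "running_mean", "running_var"))
        for (o in others) n <- n + count_leaves(x[[o]])
        return(n)
      }
      for (e in x) n <- n + count_leaves(e)
      return(n)
    }
    0
  }
  count_leaves(model$params)
}

trainable_fields <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"),
         upconv = c("W", "b"),
         norm = c("gamma", "beta"),
         character(0))
}

# Walk params and grads in lockstep, applying `fn(value, grad, path)` to every
# trainable tensor; returns the updated params tree.
tree_update <- function(params, grads, fn, path = "") {
  if (is.list(params) && !is.null(params$type) &&
      params$type %in% c("conv", "upconv", "norm")) {
    for (f in trainable_fields(params)) {
      g <- grads[[f]]
      if (!is.null(g)) params[[f]] <- fn(params[[f]], g, paste0(path, "/", f))
    }
    return(params)
  }
  if (is.list(params)) {
    for (i in seq_along(params)) {
      key <- if (!is.null(names(params)) && nzchar(names(params)[i]))
        names(params)[i] else i
      g <- if (is.list(grads)) grads[[key]] else NULL
      if (!is.null(g) && !is.null(params[[i]]))
        params[[i]] <- tree_update(params[[i]], g, fn,
                                   paste0(path, "/", key))
    }
  }
  params
}
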