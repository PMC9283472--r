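# Small shared helpers (internal).

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_binary <- function(m, what = "mask") {
  v <- as.vector(m)
  if (!all(v %in% c(0, 1)))
    stop(what, " must be strictly binary (values in {0, 1})", call. = FALSE)
  invisible(TRUE)
}

as_pixel_matrix <- function(x) {
  if (inherits(x, c("mammogram", "binary_mask"))) x$pixels else x
}
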