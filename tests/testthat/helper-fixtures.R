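# Shared small fixtures for network and training tests.

tiny_config <- function(side = 32L, base = 4L, depth = 2L, ...) {
  network_config(input_side = side, depth = depth, base_width = base, ...)
}

tiny_phantoms <- function(n, side = 32L, seed = 7L, ...) {
  generate_dataset(n, seed = seed, height = side, width = side, ...)$samples
}

# Zero out every trainable tensor reachable under a parameter subtree.
zero_tree <- function(x) {
  if (is.list(x)) {
    for (f in c("W", "b", "gamma", "beta"))
      if (!is.null(x[[f]])) x[[f]][] <- 0
    for (i in seq_along(x))
      if (is.list(x[[i]])) x[[i]] <- zero_tree(x[[i]])
  }
  x
}
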