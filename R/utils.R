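# Internal helpers shared across modules.

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Centred moving average of width `w` (odd); ends use the shrunken window.
moving_average <- function(y, w = 3L) {
  if (w <= 1L) return(y)
  half <- (w - 1L) %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Deterministic per-replicate sub-seed: a Lehmer step on the master seed with
# the replicate counter folded in, kept below 2^31 - 1 so set.seed() accepts it.
sub_seed <- function(master, r) {
  as.integer((((master %% 2147483647) * 48271) + r * 7919) %% 2147483647)
}

# Evaluate a function under a fixed seed when one is supplied, otherwise use
# the current RNG stream.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Union-find component labelling over an edge list (a[i], b[i]) on n nodes.
# Returns a list with `label` (root id per node, compacted to 1..n_comp) and
# `sizes` (component size per node order of first appearance).
component_labels <- function(n, a, b) {
  parent <- seq_len(n)
  for (i in seq_along(a)) {
    x <- a[i]
    while (parent[x] != x) {
      parent[x] <- parent[parent[x]]
      x <- parent[x]
    }
    y <- b[i]
    while (parent[y] != y) {
      parent[y] <- parent[parent[y]]
      y <- parent[y]
    }
    if (x != y) parent[y] <- x
  }
  repeat {
    pp <- parent[parent]
    if (identical(pp, parent)) break
    parent <- pp
  }
  label <- match(parent, unique(parent))
  sizes <- tabulate(label)
  list(label = label, sizes = sizes)
}

# Canonical key for a component-size histogram, e.g. c(2, 1, 1) -> "1+1+2".
hist_key <- function(sizes) paste(sort(sizes), collapse = "+")

stopf <- function(...) abort(sprintf(...))
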