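# Independent oracles used across the suite: brute-force flood fill for
# connected components, exhaustive grid search for the perfusion step, and
# small convenience helpers.

relErr <- function(a, b) abs(a - b) / abs(b)

# Breadth-first flood fill over face neighbours; independent of the
# package's label-propagation implementation.
bfComponents <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  lab <- array(0L, dim = d)
  coords <- which(mask, arr.ind = TRUE)
  if (is.vector(coords)) coords <- matrix(coords, ncol = 1L)
  nextLab <- 0L
  idxOf <- function(pt) {
    i <- pt[1L]
    if (nd >= 2L) i <- i + (pt[2L] - 1L) * d[1L]
    if (nd >= 3L) i <- i + (pt[3L] - 1L) * d[1L] * d[2L]
    i
  }
  for (r in seq_len(nrow(coords))) {
    start <- coords[r, ]
    if (lab[idxOf(start)] != 0L) next
    nextLab <- nextLab + 1L
    queue <- list(start)
    lab[idxOf(start)] <- nextLab
    while (length(queue)) {
      pt <- queue[[1L]]; queue <- queue[-1L]
      for (ax in seq_len(nd)) {
        for (dir in c(-1L, 1L)) {
          nb <- pt
          nb[ax] <- nb[ax] + dir
          if (nb[ax] < 1L || nb[ax] > d[ax]) next
          i <- idxOf(nb)
          if (mask[i] && lab[i] == 0L) {
            lab[i] <- nextLab
            queue[[length(queue) + 1L]] <- nb
          }
        }
      }
    }
  }
  lab
}

# Exhaustive (f, dStar) grid search for the perfusion step with S0 solved
# linearly per candidate; returns the global optimum on the grid.
gridSearchPerfusion <- function(y, b, dFixed,
                                fGrid = seq(0, 1, by = 0.01),
                                dsGrid = NULL) {
  if (is.null(dsGrid))
    dsGrid <- exp(seq(log(dFixed), log(0.5), length.out = 120))
  best <- list(sse = Inf)
  for (f in fGrid) {
    for (ds in dsGrid) {
      g <- f * exp(-b * ds) + (1 - f) * exp(-b * dFixed)
      s0 <- sum(y * g) / sum(g * g)
      sse <- sum((y - s0 * g)^2)
      if (sse < best$sse) best <- list(f = f, dStar = ds, s0 = s0, sse = sse)
    }
  }
  best
}

# Small noise-free phantom reused by several files (built once per run).
tinyPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makePhantom(c(16, 16, 8), seed = 11)
    cache
  }
})
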