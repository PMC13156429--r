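# Internal helpers: seeded evaluation, array shifts, connected components,
# smooth random fields.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Shift an array by one cell along dimension `along` (+1 or -1), zero-filling.
shiftArray <- function(x, along, by) {
  d <- dim(x)
  out <- array(if (is.logical(x)) FALSE else 0, dim = d)
  idxFrom <- idxTo <- lapply(d, seq_len)
  n <- d[along]
  if (n <= 1L) return(out)
  if (by > 0) {                      # cell i receives value from i - 1
    idxTo[[along]] <- 2L:n
    idxFrom[[along]] <- 1L:(n - 1L)
  } else {
    idxTo[[along]] <- 1L:(n - 1L)
    idxFrom[[along]] <- 2L:n
  }
  do.call(`[<-`, c(list(out), idxTo,
    list(value = do.call(`[`, c(list(x), idxFrom, list(drop = FALSE))))))
}

# Label face-connected components of a logical array (2D: 4-connectivity,
# 3D: 6-connectivity) by iterative minimum-label propagation. Returns an
# integer array, 0 for background, components numbered 1..k by decreasing size.
labelComponents <- function(mask) {
  if (!is.logical(mask)) stop("mask must be logical")
  d <- dim(mask)
  if (is.null(d)) stop("mask must be a matrix or 3D array")
  lab <- array(0, dim = d)
  lab[mask] <- seq_len(sum(mask))
  bigValue <- sum(mask) + 1
  lab[!mask] <- bigValue
  repeat {
    new <- lab
    for (ax in seq_along(d)) {
      for (by in c(1L, -1L)) {
        sh <- shiftArray(lab, ax, by)
        sh[sh == 0] <- bigValue   # zero-filled borders never propagate
        new <- pmin(new, sh)
      }
    }
    new[!mask] <- bigValue
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(lab == i), numeric(1))
    ord <- order(sizes, decreasing = TRUE)
    relab <- array(0, dim = d)
    for (k in seq_along(ord)) relab[lab == ids[ord[k]]] <- k
    lab <- relab
  }
  storage.mode(lab) <- "integer"
  lab
}

# Largest face-connected component of a logical array.
largestComponent <- function(mask) {
  lab <- labelComponents(mask)
  lab == 1L & mask
}

# Smooth zero-mean, unit-sd Gaussian random field on a grid: white noise
# followed by repeated 6-neighbourhood box blurs. Deterministic given the
# current RNG state.
smoothField <- function(dims, nBlur = 4L) {
  x <- array(stats::rnorm(prod(dims)), dim = dims)
  for (i in seq_len(nBlur)) {
    acc <- x
    cnt <- array(1, dim = dims)
    one <- array(1, dim = dims)
    for (ax in seq_along(dims)) {
      for (by in c(1L, -1L)) {
        acc <- acc + shiftArray(x, ax, by)
        cnt <- cnt + shiftArray(one, ax, by)
      }
    }
    x <- acc / cnt
  }
  (x - mean(x)) / stats::sd(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a stage seed from a base seed, staying within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}
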