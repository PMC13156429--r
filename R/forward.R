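#' Biexponential IVIM signal model
#'
#' Evaluates the two-compartment intravoxel-incoherent-motion signal
#' \deqn{S(b) = S_0 [ F e^{-b D^*} + (1 - F) e^{-b D} ]}
#' where \eqn{F} is the perfusion fraction, \eqn{D^*} the perfusion-related
#' pseudo-diffusion coefficient and \eqn{D} the tissue diffusion coefficient.
#' All arguments are recycled elementwise, so parameter maps can be passed
#' directly.
#'
#' @param s0 signal at b = 0 (intensity units, >= 0).
#' @param f perfusion fraction in [0, 1].
#' @param dStar pseudo-diffusion coefficient, mm^2/s.
#' @param d tissue diffusion coefficient, mm^2/s; requires 0 < d <= dStar.
#' @param b diffusion weighting, s/mm^2, >= 0.
#' @return signal intensity, same shape as the broadcast arguments;
#'   continuous and non-increasing in \code{b}.
#' @examples
#' biexpSignal(100, 0.1, 0.01, 0.0008, 50)  # ~92.54
#' @export
biexpSignal <- function(s0, f, dStar, d, b) {
  if (anyNA(b) || any(b < 0)) stop("'b' must be non-negative")
  if (anyNA(f) || any(f < 0 | f > 1)) stop("'f' must lie in [0, 1]")
  if (anyNA(s0) || any(s0 < 0)) stop("'s0' must be non-negative")
  if (anyNA(d) || any(d <= 0)) stop("'d' must be strictly positive")
  if (anyNA(dStar) || any(dStar < d)) stop("'dStar' must be >= 'd'")
  .biexp(s0, f, dStar, d, b)
}

# unchecked kernel shared with the fitting and synthesis code
.biexp <- function(s0, f, dStar, d, b)
  s0 * (f * exp(-b * dStar) + (1 - f) * exp(-b * d))

#' Trace image from three orthogonal diffusion directions
#'
#' Combines per-direction diffusion-weighted volumes into a single
#' direction-averaged (trace) series as the voxelwise geometric mean, which is
#' equivalent to arithmetic averaging of the per-direction log-signal decay
#' rates. Zero-valued voxels in any direction propagate to a zero trace value
#' (with a warning), matching the geometric mean's behaviour.
#'
#' @param dir1,dir2,dir3 4D non-negative arrays (x, y, z, b) of identical
#'   shape, one per orthogonal diffusion direction.
#' @param scheme the \linkS4class{BValueScheme} of the acquisition.
#' @param voxelDims voxel dimensions in mm.
#' @return a \linkS4class{DWISeries} with \code{nDirections = 3}.
#' @export
computeTrace <- function(dir1, dir2, dir3, scheme, voxelDims = c(2, 2, 6)) {
  dims <- dim(dir1)
  if (length(dims) != 4L)
    stop("direction volumes must be 4D (x, y, z, b) arrays")
  if (!identical(dims, dim(dir2)) || !identical(dims, dim(dir3)))
    stop("the three direction volumes must have identical dimensions")
  if (anyNA(dir1) || anyNA(dir2) || anyNA(dir3) ||
      any(dir1 < 0) || any(dir2 < 0) || any(dir3 < 0))
    stop("direction signals must be finite and non-negative")
  prod3 <- dir1 * dir2 * dir3
  if (any(prod3 == 0 & (dir1 + dir2 + dir3) > 0))
    warning("zero-valued voxels in one direction propagate to a zero trace")
  trace <- prod3^(1 / 3)
  new("DWISeries", signal = trace, scheme = scheme,
    voxelDims = as.numeric(voxelDims), nDirections = 3)
}
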