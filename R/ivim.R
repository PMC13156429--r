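#' Brain mask from the b = 0 volume
#'
#' Thresholds the non-diffusion-weighted volume at a fraction of its
#' 99th-percentile intensity (zero-intensity background always excluded) and
#' keeps the largest face-connected component, discarding detached bright
#' structures such as scalp fat or eyes.
#'
#' @param b0 non-negative 3D array, the b = 0 volume.
#' @param fraction relative threshold, default 0.2 of the 99th percentile.
#' @return logical 3D mask.
#' @export
makeBrainMask <- function(b0, fraction = 0.2) {
  if (anyNA(b0) || any(b0 < 0)) stop("b0 volume must be non-negative")
  if (is.null(dim(b0)) || length(dim(b0)) != 3L)
    stop("b0 must be a 3D array")
  thr <- fraction * stats::quantile(b0, 0.99, names = FALSE)
  cand <- b0 > thr & b0 > 0
  if (!any(cand))
    stop("brain mask is empty; lower the masking fraction")
  largestComponent(cand)
}

#' Brain volume from a mask
#'
#' @param mask logical 3D array.
#' @param voxelDims voxel dimensions in mm.
#' @return volume in mL (sum of voxel volumes).
#' @examples
#' brainVolume(array(TRUE, c(10, 10, 10)), c(2, 2, 6))  # 24 mL
#' @export
brainVolume <- function(mask, voxelDims) {
  if (any(voxelDims <= 0)) stop("voxelDims must be positive")
  sum(mask) * prod(voxelDims) / 1000
}

#' Step 1: tissue diffusion coefficient from high-b signal
#'
#' Log-linear least-squares fit of \code{ln S} against \code{b} restricted to
#' b-values at or above \code{highBThreshold}, where the fast perfusion
#' compartment has decayed away and the signal is effectively
#' monoexponential. The slope magnitude is the tissue diffusion coefficient
#' D (clamped to the configured bounds and flagged if clamping occurred);
#' the exponentiated intercept estimates the tissue-compartment amplitude.
#'
#' @param signal signal vector over all b-values (same order as
#'   \code{bValues}).
#' @param bValues b-value table (s/mm^2); must contain
#'   \code{config@highBThreshold}.
#' @param config a \linkS4class{FitConfig}.
#' @return list with \code{d} (mm^2/s), \code{s0High} (intensity),
#'   \code{ok} (usable fit) and \code{atBound} (D was clamped).
#' @export
fitDiffusionStep <- function(signal, bValues, config = fitConfig()) {
  if (length(signal) != length(bValues))
    stop("signal and bValues must have equal length")
  if (!(config@highBThreshold %in% bValues))
    stop("highBThreshold must be present in the b-value table")
  idx <- bValues >= config@highBThreshold
  if (sum(idx) < 3L)
    stop("need at least 3 b-values at or above highBThreshold")
  y <- signal[idx]
  if (anyNA(y) || any(y <= 0))
    return(list(d = NA_real_, s0High = NA_real_, ok = FALSE, atBound = FALSE))
  x <- bValues[idx]
  ly <- log(y)
  xc <- x - mean(x)
  slope <- sum(xc * ly) / sum(xc * xc)
  inter <- mean(ly) - slope * mean(x)
  dRaw <- -slope
  d <- clamp(dRaw, config@dLower, config@dUpper)
  list(d = d, s0High = exp(inter), ok = TRUE, atBound = d != dRaw)
}

#' Step 2: perfusion fraction and pseudo-diffusion with D frozen
#'
#' Box-constrained nonlinear least squares of the biexponential model over
#' (S0, F, D*) at all b-values, with the tissue diffusion coefficient frozen
#' at the step-1 estimate. Uses Levenberg-Marquardt with an analytic Jacobian
#' and parameter bounds (F in [0, 1], D* in [D, dStarUpper], S0 >= 0).
#' Initialization: S0 from the b = 0 signal, F from the tissue-compartment
#' amplitude deficit \code{1 - s0High/S0} clamped to [0, 0.5], D* at
#' 10e-3 mm^2/s. On solver failure the initialization is returned with
#' \code{converged = FALSE}.
#'
#' @param signal signal vector over all b-values.
#' @param bValues b-value table (s/mm^2), first entry 0.
#' @param dFixed tissue diffusion coefficient from
#'   \code{\link{fitDiffusionStep}} (mm^2/s), within the configured bounds.
#' @param config a \linkS4class{FitConfig}.
#' @param s0High optional tissue-compartment amplitude from step 1, used for
#'   the F initialization.
#' @return list with \code{s0}, \code{f}, \code{dStar}, \code{converged} and
#'   \code{quality} (list: nrmse, converged, nPoints).
#' @export
fitPerfusionStep <- function(signal, bValues, dFixed, config = fitConfig(),
                             s0High = NULL) {
  if (length(signal) != length(bValues))
    stop("signal and bValues must have equal length")
  if (is.na(dFixed) || dFixed < config@dLower || dFixed > config@dUpper)
    stop("dFixed must lie within the configured D bounds")
  if (anyNA(signal) || any(signal < 0))
    stop("signal must be finite and non-negative")

  ib0 <- which(bValues == 0)
  s0i <- if (length(ib0)) signal[ib0[1L]] else max(signal)
  fi <- if (!is.null(s0High) && is.finite(s0High) && s0i > 0)
    clamp(1 - s0High / s0i, 0, 0.5) else 0.1
  fi <- clamp(fi, config@fLower, config@fUpper)
  dsi <- clamp(10e-3, dFixed, config@dStarUpper)
  init <- c(s0 = s0i, f = fi, dStar = dsi)

  resFn <- function(p) .biexp(p[1L], p[2L], p[3L], dFixed, bValues) - signal
  jacFn <- function(p) {
    e1 <- exp(-bValues * p[3L]); e2 <- exp(-bValues * dFixed)
    cbind(p[2L] * e1 + (1 - p[2L]) * e2,
          p[1L] * (e1 - e2),
          -p[1L] * p[2L] * bValues * e1)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init,
      lower = c(0, config@fLower, dFixed),
      upper = c(Inf, config@fUpper, config@dStarUpper),
      fn = resFn, jac = jacFn,
      control = minpack.lm::nls.lm.control(
        maxiter = config@maxIterations,
        ftol = config@tolerance, ptol = config@tolerance)),
    error = function(e) NULL)

  converged <- !is.null(fit) && fit$info %in% 1:4
  p <- if (converged) fit$par else init
  fitted <- .biexp(p[1L], p[2L], p[3L], dFixed, bValues)
  nrmse <- if (mean(signal) > 0) computeNRMSE(signal, fitted) else NA_real_
  list(s0 = unname(p[1L]), f = unname(p[2L]), dStar = unname(p[3L]),
    converged = converged,
    quality = list(nrmse = nrmse, converged = converged,
      nPoints = length(bValues)))
}

#' Normalized root-mean-square error
#'
#' \code{sqrt(mean((observed - fitted)^2)) / mean(observed)}. The normalizer
#' is the mean observed signal over all points, which makes the measure
#' invariant to a common positive rescaling of both vectors and comparable
#' across voxels of different intensity.
#'
#' @param observed,fitted numeric vectors of equal length >= 2;
#'   \code{mean(observed)} must be positive.
#' @return dimensionless error >= 0; 0 for a perfect fit.
#' @export
computeNRMSE <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L)
    stop("observed and fitted must have equal length >= 2")
  mo <- mean(observed)
  if (!is.finite(mo) || mo <= 0)
    stop("mean of the observed signal must be positive")
  sqrt(mean((observed - fitted)^2)) / mo
}

# Full stepwise fit for one voxel, with optional perfusion-corrected
# refinement of the high-b diffusion step.
.fitVoxel <- function(y, bValues, config) {
  s1 <- fitDiffusionStep(y, bValues, config)
  if (!s1$ok)
    return(c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, 0))
  s2 <- fitPerfusionStep(y, bValues, s1$d, config, s0High = s1$s0High)
  if (config@nRefine > 0 && s2$converged) {
    idx <- bValues >= config@highBThreshold
    xh <- bValues[idx]
    xc <- xh - mean(xh)
    sxx <- sum(xc * xc)
    for (r in seq_len(config@nRefine)) {
      yc <- y[idx] - s2$s0 * s2$f * exp(-xh * s2$dStar)
      if (any(yc <= 0)) break
      ly <- log(yc)
      dNew <- clamp(-sum(xc * ly) / sxx, config@dLower, config@dUpper)
      s2New <- fitPerfusionStep(y, bValues, dNew, config,
        s0High = exp(mean(ly) + dNew * mean(xh)))
      if (!s2New$converged) break
      stable <- abs(dNew - s1$d) <= 1e-7 * s1$d
      s1$d <- dNew
      s2 <- s2New
      if (stable) break
    }
  }
  if (!s2$converged)
    return(c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, 0))
  c(s2$s0, s2$f, s2$dStar, s1$d, s2$quality$nrmse, 1)
}

#' Voxelwise stepwise biexponential IVIM fit
#'
#' Applies the two-step fit (\code{\link{fitDiffusionStep}} then
#' \code{\link{fitPerfusionStep}}) at every voxel of the brain mask,
#' followed by perfusion-corrected refinement passes (up to \code{nRefine}):
#' the fitted perfusion compartment is subtracted from the high-b signal, D
#' is re-estimated on the corrected values, and the perfusion step is
#' repeated with the refined D, stopping early once D is stable to 1e-7
#' relative. This removes the positive D bias left by residual perfusion
#' signal at the high-b cutoff, which otherwise propagates into F and D*.
#' Voxels whose fit fails are flagged non-converged and carry NA in every
#' map; they are excluded from downstream calibration sums. The convergence
#' fraction is reported via \code{message()}.
#'
#' @param dwi a \linkS4class{DWISeries}.
#' @param mask logical 3D brain mask; derived with
#'   \code{\link{makeBrainMask}} from the b = 0 volume when omitted.
#' @param config a \linkS4class{FitConfig}.
#' @param preprocess optional volume-to-volume transform applied to the 4D
#'   signal before fitting (e.g. a denoising hook); identity when NULL.
#' @return an \linkS4class{IVIMParameterMap}.
#' @export
fitIVIM <- function(dwi, mask = NULL, config = fitConfig(),
                    preprocess = NULL) {
  sig <- dwi@signal
  if (!is.null(preprocess)) {
    sig <- preprocess(sig)
    if (!identical(dim(sig), dim(dwi@signal)))
      stop("preprocess hook must preserve the signal dimensions")
  }
  b <- dwi@scheme@bValues
  if (!(config@highBThreshold %in% b))
    stop("highBThreshold must be present in the b-value table")
  shape <- dim(sig)[1:3]
  if (is.null(mask)) {
    ib0 <- which(b == 0)[1L]
    mask <- makeBrainMask(sig[, , , ib0, drop = TRUE], config@maskFraction)
  }
  if (!identical(dim(mask), as.integer(shape)) &&
      !identical(dim(mask), shape))
    stop("mask dimensions must match the DWI grid")

  emptyMap <- function() array(NA_real_, dim = shape)
  if (!any(mask)) {
    warning("brain mask is empty; returning an empty parameter map")
    return(new("IVIMParameterMap", s0 = emptyMap(), f = emptyMap(),
      dStar = emptyMap(), d = emptyMap(), fdStar = emptyMap(),
      nrmse = emptyMap(), mask = mask,
      converged = array(FALSE, dim = shape),
      voxelDims = dwi@voxelDims, scheme = dwi@scheme@scheme))
  }

  vox <- which(mask)
  nvol <- prod(shape)
  sigMat <- matrix(sig, nrow = nvol)[vox, , drop = FALSE]
  res <- matrix(NA_real_, nrow = length(vox), ncol = 6L)
  for (i in seq_along(vox))
    res[i, ] <- .fitVoxel(sigMat[i, ], b, config)

  conv <- res[, 6L] == 1 & !is.na(res[, 6L])
  frac <- mean(conv)
  message(sprintf("fitIVIM: %d/%d voxels converged (%.1f%%)",
    sum(conv), length(vox), 100 * frac))
  if (frac < config@minConvergedFraction)
    stop(sprintf("only %.2f%% of voxels converged; aborting", 100 * frac))

  fill <- function(col) { m <- emptyMap(); m[vox] <- res[, col]; m }
  s0 <- fill(1L); f <- fill(2L); dStar <- fill(3L); d <- fill(4L)
  nrmse <- fill(5L)
  convArr <- array(FALSE, dim = shape)
  convArr[vox] <- conv
  new("IVIMParameterMap", s0 = s0, f = f, dStar = dStar, d = d,
    fdStar = f * dStar, nrmse = nrmse, mask = mask, converged = convArr,
    voxelDims = dwi@voxelDims, scheme = dwi@scheme@scheme)
}
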