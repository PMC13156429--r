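#' Pulsatility-based vessel lumen segmentation
#'
#' Delineates an arterial lumen on a velocity cine by waveform similarity:
#' the velocity-versus-cardiac-phase curve at a seed pixel serves as the
#' arterial reference, every pixel's waveform is correlated against it, and
#' the lumen is the face-connected component containing the seed among pixels
#' whose Pearson correlation reaches the threshold. Pixels with a constant
#' waveform (zero variance, e.g. noise-free background) cannot correlate and
#' are never included.
#'
#' @param cine a \linkS4class{VelocityCine}.
#' @param seedPoint integer (x, y) pixel inside the vessel.
#' @param threshold correlation threshold in (0, 1), default 0.85.
#' @param vesselLabel label recorded in the ROI (L_ICA, R_ICA, L_VA, R_VA).
#' @return a \linkS4class{VesselROI}.
#' @export
segmentLumen <- function(cine, seedPoint, threshold = 0.85,
                         vesselLabel = "L_ICA") {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  v <- cine@velocity
  d <- dim(v)
  seedPoint <- as.integer(round(seedPoint))
  if (length(seedPoint) != 2L || any(seedPoint < 1L) ||
      seedPoint[1L] > d[1L] || seedPoint[2L] > d[2L])
    stop("seedPoint must index a pixel of the cine plane")
  ref <- v[seedPoint[1L], seedPoint[2L], ]
  if (stats::var(ref) == 0)
    stop("no pulsatility at seed: the seed waveform is constant")
  W <- matrix(v, nrow = d[1L] * d[2L], ncol = d[3L])
  Wc <- W - rowMeans(W)
  refc <- ref - mean(ref)
  denom <- sqrt(rowSums(Wc^2)) * sqrt(sum(refc^2))
  corv <- as.vector(Wc %*% refc) / denom
  corv[!is.finite(corv)] <- -Inf   # constant waveforms: no pulsatility
  cand <- matrix(corv >= threshold, nrow = d[1L], ncol = d[2L])
  if (!cand[seedPoint[1L], seedPoint[2L]])
    stop("empty lumen: the seed pixel itself fails the threshold")
  lab <- labelComponents(cand)
  comp <- lab == lab[seedPoint[1L], seedPoint[2L]] & cand
  if (!any(comp)) stop("empty lumen at the requested threshold")
  new("VesselROI", mask = comp, seedPoint = as.numeric(seedPoint),
    vesselLabel = vesselLabel)
}

#' Volumetric flow through a vessel ROI
#'
#' Integrates the signed through-plane velocity over the lumen and averages
#' over the cardiac cycle:
#' \code{Q = mean over phases of sum(v) * pixelArea * 0.6}, where v in cm/s
#' times area in mm^2 gives 10 mm^3/s, hence the factor 60/100 = 0.6 to
#' mL/min. Signed velocities are summed as-is, preserving flow direction.
#'
#' @param cine a \linkS4class{VelocityCine}.
#' @param roi a \linkS4class{VesselROI} on the same plane.
#' @return flow in mL/min.
#' @examples
#' # constant 10 cm/s over 30 mm^2 -> 180 mL/min
#' @export
vesselFlow <- function(cine, roi) {
  v <- cine@velocity
  d <- dim(v)
  if (!identical(dim(roi@mask), d[1:2]))
    stop("ROI mask must match the cine plane")
  perPhase <- vapply(seq_len(d[3L]),
    function(p) sum(v[, , p][roi@mask]), numeric(1))
  mean(perPhase) * cine@pixelArea * 0.6
}

#' Total cerebral blood flow
#'
#' Arithmetic sum of the four feeding-artery flows (left/right internal
#' carotid, left/right vertebral).
#'
#' @param flows numeric(4) of vessel flows in mL/min.
#' @return total CBF in mL/min; warns if any flow is non-positive.
#' @export
totalCBF <- function(flows) {
  if (length(flows) != 4L) stop("exactly four vessel flows are required")
  if (any(flows <= 0))
    warning("non-positive vessel flow encountered")
  sum(flows)
}

#' Normalize total CBF by brain tissue mass
#'
#' Converts mL/min to mL/100 g/min by dividing by brain mass (volume times
#' tissue density, 1.06 g/mL by convention) and scaling to 100 g.
#'
#' @param tcbf total CBF in mL/min.
#' @param brainVolumeMl brain volume in mL (> 0).
#' @param density brain tissue density in g/mL.
#' @return normalized tCBF in mL/100 g/min.
#' @examples
#' normalizeTCBF(700, 1400, 1.06)  # ~47.17
#' @export
normalizeTCBF <- function(tcbf, brainVolumeMl, density = 1.06) {
  if (brainVolumeMl <= 0) stop("brainVolumeMl must be positive")
  if (density <= 0) stop("density must be positive")
  tcbf / (brainVolumeMl * density) * 100
}

#' Calibrate the relative perfusion map to absolute rCBF
#'
#' Assuming rCBF is proportional to F*D*, a single conversion factor maps
#' the relative perfusion map to absolute units. The factor is the ratio of
#' the normalized total CBF to the brain-mean F*D* over converged voxels, so
#' the calibrated map conserves the phase-contrast measurement exactly: its
#' mean over the calibration voxels equals the normalized tCBF, and any
#' global gain in the DWI signal chain cancels. Non-converged voxels are
#' excluded from the mean but remain in the output map as NA (invalid).
#'
#' @param map an \linkS4class{IVIMParameterMap}, or a plain 3D F*D* array
#'   (then \code{mask} is required and all mask voxels count as converged).
#' @param tcbfNormalized normalized total CBF in mL/100 g/min; may be
#'   omitted when \code{vesselFlows} and \code{brainVolumeMl} are given.
#' @param mask logical 3D calibration mask (only for a plain-array
#'   \code{map}).
#' @param vesselFlows optional numeric(4) of vessel flows (mL/min); recorded
#'   in the calibration and used to derive \code{tcbfNormalized} when that
#'   is missing.
#' @param brainVolumeMl optional brain volume (mL), required to derive
#'   \code{tcbfNormalized} from flows.
#' @param density tissue density, g/mL.
#' @param method method tag of the output map (e.g. \code{"2nd-mc-dip"}).
#' @return list with \code{rcbf} (an \linkS4class{RCBFMap}) and
#'   \code{calibration} (a \linkS4class{PerfusionCalibration}).
#' @export
calibrateRCBF <- function(map, tcbfNormalized = NULL, mask = NULL,
                          vesselFlows = NULL, brainVolumeMl = NULL,
                          density = 1.06, method = "2nd-mc-dip") {
  if (is(map, "IVIMParameterMap")) {
    fd <- map@fdStar
    mask <- map@mask
    used <- map@mask & map@converged
  } else {
    if (is.null(mask)) stop("mask is required for a plain F*D* array")
    fd <- map
    used <- mask & is.finite(fd)
  }
  if (!any(mask)) stop("calibration mask is empty")
  if (!any(used)) stop("no converged voxels available for calibration")

  if (!is.null(vesselFlows)) {
    tcbfMlMin <- totalCBF(vesselFlows)
    if (is.null(tcbfNormalized)) {
      if (is.null(brainVolumeMl))
        stop("brainVolumeMl is required to normalize tCBF from flows")
      tcbfNormalized <- normalizeTCBF(tcbfMlMin, brainVolumeMl, density)
    }
  } else {
    if (is.null(tcbfNormalized))
      stop("either tcbfNormalized or vesselFlows must be supplied")
    vesselFlows <- rep(NA_real_, 4L)
    tcbfMlMin <- if (!is.null(brainVolumeMl))
      tcbfNormalized * brainVolumeMl * density / 100 else NA_real_
  }

  fdUsed <- fd[used]
  totalFd <- sum(fdUsed)
  if (!is.finite(totalFd) || totalFd <= 0)
    stop("total F*D* over the calibration mask must be positive")
  meanFd <- mean(fdUsed)
  cf <- tcbfNormalized / meanFd

  values <- array(NA_real_, dim = dim(fd))
  values[mask] <- cf * fd[mask]
  stopifnot(all(values[used] >= 0))   # bounds make negative F*D* impossible

  names(vesselFlows) <- .VESSELS
  calib <- new("PerfusionCalibration", vesselFlows = vesselFlows,
    tcbfMlMin = tcbfMlMin,
    brainVolumeMl = if (is.null(brainVolumeMl)) NA_real_ else brainVolumeMl,
    tissueDensity = density, tcbfNormalized = tcbfNormalized,
    totalFdStar = totalFd, meanFdStar = meanFd, conversionFactor = cf,
    nVoxelsUsed = sum(used))
  rcbf <- new("RCBFMap", values = values, mask = mask, method = method)
  list(rcbf = rcbf, calibration = calib)
}
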