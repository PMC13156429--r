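#' @import methods
NULL

.SCHEMES <- c("2nd-mc", "1st-mc", "non-mc")
.RCBF_METHODS <- c("2nd-mc-dip", "1st-mc-dip", "non-mc-dip", "asl", "truth")
.VESSELS <- c("L_ICA", "R_ICA", "L_VA", "R_VA")

#' Diffusion weighting scheme
#'
#' Holds the b-value table and the gradient-moment compensation properties of
#' one diffusion encoding scheme. The residual moment weights \code{(w1, w2)}
#' express how sensitive the encoding remains to coherent bulk velocity (first
#' moment) and acceleration (second moment): a second-order motion-compensated
#' waveform nulls both, a first-order one nulls velocity only, and an
#' uncompensated waveform nulls neither.
#'
#' @slot bValues numeric, ascending diffusion weightings in s/mm^2, first 0.
#' @slot scheme one of \code{"2nd-mc"}, \code{"1st-mc"}, \code{"non-mc"}.
#' @slot momentWeights numeric(2), dimensionless residual first/second moment
#'   weights \code{(w1, w2)}.
#' @slot gradientSeparation,gradientDuration acquisition metadata (ms),
#'   may be \code{NA}.
#' @exportClass BValueScheme
setClass("BValueScheme",
  representation(bValues = "numeric", scheme = "character",
    momentWeights = "numeric", gradientSeparation = "numeric",
    gradientDuration = "numeric"))

setValidity("BValueScheme", function(object) {
  b <- object@bValues
  w <- object@momentWeights
  msgs <- character()
  if (length(b) < 2L) msgs <- c(msgs, "need at least two b-values")
  if (length(b) && b[1L] != 0) msgs <- c(msgs, "first b-value must be 0")
  if (any(diff(b) <= 0)) msgs <- c(msgs, "b-values must be strictly increasing")
  if (!(object@scheme %in% .SCHEMES))
    msgs <- c(msgs, sprintf("scheme must be one of %s",
      paste(.SCHEMES, collapse = ", ")))
  if (length(w) != 2L || any(w < 0))
    msgs <- c(msgs, "momentWeights must be two non-negative numbers")
  if (length(w) == 2L && object@scheme == "2nd-mc" && any(w != 0))
    msgs <- c(msgs, "2nd-mc scheme must have momentWeights (0, 0)")
  if (length(w) == 2L && object@scheme == "1st-mc" && w[1L] != 0)
    msgs <- c(msgs, "1st-mc scheme must have w1 == 0")
  if (length(msgs)) msgs else TRUE
})

#' Default b-value table
#'
#' The 11 diffusion weightings used throughout the package: 0, 10, 20, 30, 50,
#' 100, 200, 400, 600, 800, 1000 s/mm^2 (dense low-b sampling for the perfusion
#' compartment, five points at or above 200 s/mm^2 for the tissue compartment).
#'
#' @return numeric vector of b-values (s/mm^2).
#' @export
defaultBValues <- function() c(0, 10, 20, 30, 50, 100, 200, 400, 600, 800, 1000)

#' Construct a BValueScheme
#'
#' @param scheme compensation scheme: \code{"2nd-mc"} (velocity and
#'   acceleration nulled), \code{"1st-mc"} (velocity nulled) or
#'   \code{"non-mc"} (uncompensated).
#' @param bValues ascending b-values in s/mm^2 starting at 0.
#' @param momentWeights residual moment weights (w1, w2); defaults are
#'   (0,0), (0,1), (1,1) for 2nd-mc, 1st-mc and non-mc respectively.
#' @param gradientSeparation,gradientDuration optional Delta/delta metadata in
#'   ms; scheme-specific defaults are supplied.
#' @return a \linkS4class{BValueScheme}.
#' @examples
#' bValueScheme("2nd-mc")
#' @export
bValueScheme <- function(scheme = c("2nd-mc", "1st-mc", "non-mc"),
                         bValues = defaultBValues(),
                         momentWeights = NULL,
                         gradientSeparation = NULL,
                         gradientDuration = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(momentWeights))
    momentWeights <- switch(scheme,
      "2nd-mc" = c(0, 0), "1st-mc" = c(0, 1), "non-mc" = c(1, 1))
  if (is.null(gradientSeparation))
    gradientSeparation <- switch(scheme,
      "2nd-mc" = 105.7, "1st-mc" = 26.0, "non-mc" = 71.6)
  if (is.null(gradientDuration))
    gradientDuration <- switch(scheme,
      "2nd-mc" = 16.9, "1st-mc" = 25.1, "non-mc" = 51.1)
  new("BValueScheme", bValues = as.numeric(bValues), scheme = scheme,
    momentWeights = as.numeric(momentWeights),
    gradientSeparation = as.numeric(gradientSeparation),
    gradientDuration = as.numeric(gradientDuration))
}

#' 4D diffusion-weighted series
#'
#' Trace diffusion-weighted signal over a 3D grid, one volume per b-value.
#'
#' @slot signal 4D non-negative array (x, y, z, b), arbitrary intensity units.
#' @slot scheme a \linkS4class{BValueScheme}.
#' @slot voxelDims voxel dimensions in mm.
#' @slot nDirections number of orthogonal diffusion directions averaged into
#'   the trace.
#' @exportClass DWISeries
setClass("DWISeries",
  representation(signal = "array", scheme = "BValueScheme",
    voxelDims = "numeric", nDirections = "numeric"))

setValidity("DWISeries", function(object) {
  msgs <- character()
  d <- dim(object@signal)
  if (length(d) != 4L) msgs <- c(msgs, "signal must be a 4D array")
  else if (d[4L] != length(object@scheme@bValues))
    msgs <- c(msgs, "4th dimension must match the number of b-values")
  if (anyNA(object@signal) || any(object@signal < 0))
    msgs <- c(msgs, "signal intensities must be finite and >= 0")
  if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
    msgs <- c(msgs, "voxelDims must be three positive lengths (mm)")
  if (length(msgs)) msgs else TRUE
})

#' Voxelwise IVIM parameter maps
#'
#' Result of stepwise biexponential fitting. Voxels outside the brain mask
#' hold \code{NA} in every map; voxels inside the mask where the fit failed
#' are flagged \code{FALSE} in \code{converged} and also hold \code{NA}.
#'
#' @slot s0 signal at b = 0 (intensity units).
#' @slot f perfusion fraction in [0, 1].
#' @slot dStar perfusion-related pseudo-diffusion coefficient (mm^2/s).
#' @slot d tissue diffusion coefficient (mm^2/s).
#' @slot fdStar product F * D* (mm^2/s), relative blood-flow surrogate.
#' @slot nrmse normalized root-mean-square fit error (dimensionless).
#' @slot mask logical 3D brain mask.
#' @slot converged logical 3D map of per-voxel fit success.
#' @slot voxelDims voxel dimensions (mm).
#' @slot scheme scheme label of the fitted series.
#' @exportClass IVIMParameterMap
setClass("IVIMParameterMap",
  representation(s0 = "array", f = "array", dStar = "array", d = "array",
    fdStar = "array", nrmse = "array", mask = "array", converged = "array",
    voxelDims = "numeric", scheme = "character"))

setValidity("IVIMParameterMap", function(object) {
  msgs <- character()
  dm <- dim(object@mask)
  for (s in c("s0", "f", "dStar", "d", "fdStar", "nrmse", "converged"))
    if (!identical(dim(slot(object, s)), dm))
      msgs <- c(msgs, sprintf("map '%s' must share the mask dimensions", s))
  ok <- object@mask & object@converged
  if (!length(msgs) && any(ok)) {
    f <- object@f[ok]; d <- object@d[ok]; ds <- object@dStar[ok]
    if (anyNA(f) || any(f < 0 | f > 1))
      msgs <- c(msgs, "converged f values must lie in [0, 1]")
    if (anyNA(d) || anyNA(ds) || any(d <= 0) || any(ds < d))
      msgs <- c(msgs, "converged voxels must satisfy 0 < d <= dStar")
    if (max(abs(object@fdStar[ok] - f * ds)) > 1e-12)
      msgs <- c(msgs, "fdStar must equal f * dStar elementwise")
  }
  if (!length(msgs) && any(!object@mask) &&
      !all(is.na(object@f[!object@mask])))
    msgs <- c(msgs, "maps must be NA outside the mask")
  if (length(msgs)) msgs else TRUE
})

#' Phase-contrast velocity cine for one vessel plane
#'
#' @slot velocity 3D array (x, y, cardiac phase) of signed through-plane
#'   velocities in cm/s.
#' @slot pixelArea in-plane pixel area in mm^2.
#' @slot venc velocity-encoding limit in cm/s.
#' @slot heartRate beats/min (metadata).
#' @exportClass VelocityCine
setClass("VelocityCine",
  representation(velocity = "array", pixelArea = "numeric", venc = "numeric",
    heartRate = "numeric"))

setValidity("VelocityCine", function(object) {
  msgs <- character()
  d <- dim(object@velocity)
  if (length(d) != 3L) msgs <- c(msgs, "velocity must be a 3D (x, y, phase) array")
  else if (d[3L] < 2L) msgs <- c(msgs, "need at least 2 cardiac phases")
  if (object@pixelArea <= 0) msgs <- c(msgs, "pixelArea must be positive")
  if (object@venc <= 0) msgs <- c(msgs, "venc must be positive")
  if (!length(msgs) && max(abs(object@velocity)) > object@venc + 1e-9)
    msgs <- c(msgs, "|velocity| must not exceed venc")
  if (length(msgs)) msgs else TRUE
})

#' Vessel lumen region of interest
#'
#' @slot mask logical 2D lumen mask on the cine plane.
#' @slot seedPoint integer (x, y) pixel index of the seed.
#' @slot vesselLabel one of L_ICA, R_ICA, L_VA, R_VA.
#' @exportClass VesselROI
setClass("VesselROI",
  representation(mask = "matrix", seedPoint = "numeric",
    vesselLabel = "character"))

setValidity("VesselROI", function(object) {
  msgs <- character()
  if (!is.logical(object@mask)) msgs <- c(msgs, "mask must be logical")
  if (length(object@seedPoint) != 2L)
    msgs <- c(msgs, "seedPoint must be an (x, y) pair")
  else if (is.logical(object@mask) &&
           !object@mask[object@seedPoint[1L], object@seedPoint[2L]])
    msgs <- c(msgs, "mask must contain the seed point")
  if (!(object@vesselLabel %in% .VESSELS))
    msgs <- c(msgs, sprintf("vesselLabel must be one of %s",
      paste(.VESSELS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Perfusion calibration record
#'
#' Book-keeping for the conversion of the relative perfusion map (F*D*) to
#' absolute rCBF: the four feeding-artery flows, total CBF raw and normalized
#' by brain mass, the F*D* summary statistics and the resulting conversion
#' factor. Fields that are unknown in a standalone calibration may be NA.
#'
#' @slot vesselFlows named numeric(4), mL/min for L/R ICA and L/R VA.
#' @slot tcbfMlMin total CBF, mL/min (sum of the four flows).
#' @slot brainVolumeMl total brain volume, mL.
#' @slot tissueDensity brain tissue density, g/mL (1.06 by convention).
#' @slot tcbfNormalized total CBF per tissue mass, mL/100 g/min.
#' @slot totalFdStar sum of F*D* over calibration voxels (mm^2/s).
#' @slot meanFdStar mean F*D* over calibration voxels (mm^2/s).
#' @slot conversionFactor (mL/100 g/min) per (mm^2/s).
#' @slot nVoxelsUsed number of converged voxels entering the calibration.
#' @exportClass PerfusionCalibration
setClass("PerfusionCalibration",
  representation(vesselFlows = "numeric", tcbfMlMin = "numeric",
    brainVolumeMl = "numeric", tissueDensity = "numeric",
    tcbfNormalized = "numeric", totalFdStar = "numeric",
    meanFdStar = "numeric", conversionFactor = "numeric",
    nVoxelsUsed = "numeric"))

setValidity("PerfusionCalibration", function(object) {
  msgs <- character()
  fl <- object@vesselFlows
  if (length(fl) != 4L) msgs <- c(msgs, "vesselFlows must have length 4")
  if (length(fl) == 4L && !anyNA(fl) && !is.na(object@tcbfMlMin) &&
      abs(object@tcbfMlMin - sum(fl)) > 1e-6 * max(1, abs(sum(fl))))
    msgs <- c(msgs, "tcbfMlMin must equal the sum of vesselFlows")
  if (!is.na(object@tissueDensity) && object@tissueDensity <= 0)
    msgs <- c(msgs, "tissueDensity must be positive")
  if (!is.na(object@tcbfMlMin) && !is.na(object@brainVolumeMl) &&
      !is.na(object@tcbfNormalized) && !is.na(object@tissueDensity)) {
    expect <- object@tcbfMlMin /
      (object@brainVolumeMl * object@tissueDensity) * 100
    if (abs(object@tcbfNormalized - expect) > 1e-6 * max(1, abs(expect)))
      msgs <- c(msgs,
        "tcbfNormalized must equal tcbfMlMin / (volume * density) * 100")
  }
  if (length(msgs)) msgs else TRUE
})

#' ASL quantification parameters
#'
#' Constants of the single-compartment kinetic model used for pseudo-continuous
#' arterial spin labeling. All times are in seconds.
#'
#' @slot lambdaPartition brain-blood partition coefficient, mL/g.
#' @slot t1Blood longitudinal relaxation time of arterial blood, s.
#' @slot pld post-labeling delay, s.
#' @slot tau labeling duration, s.
#' @slot alpha labeling efficiency, dimensionless in (0, 1].
#' @exportClass ASLParams
setClass("ASLParams",
  representation(lambdaPartition = "numeric", t1Blood = "numeric",
    pld = "numeric", tau = "numeric", alpha = "numeric"))

setValidity("ASLParams", function(object) {
  v <- c(object@lambdaPartition, object@t1Blood, object@pld, object@tau,
    object@alpha)
  msgs <- character()
  if (anyNA(v) || any(v <= 0))
    msgs <- c(msgs, "all ASL parameters must be strictly positive")
  if (!is.na(object@alpha) && object@alpha > 1)
    msgs <- c(msgs, "alpha must be <= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct ASLParams
#'
#' Defaults are the consensus values for 3T pCASL: lambda = 0.9 mL/g,
#' T1,blood = 1.65 s, PLD = 1.525 s, tau = 1.8 s, alpha = 0.85. Times given
#' in milliseconds (> 20) are converted to seconds on ingestion.
#'
#' @param lambdaPartition partition coefficient (mL/g).
#' @param t1Blood,pld,tau times in seconds (values > 20 are treated as ms).
#' @param alpha labeling efficiency.
#' @return an \linkS4class{ASLParams}.
#' @examples
#' aslParams()
#' aslParams(pld = 1525, tau = 1800)  # ms accepted
#' @export
aslParams <- function(lambdaPartition = 0.9, t1Blood = 1.65, pld = 1.525,
                      tau = 1.8, alpha = 0.85) {
  msToS <- function(x) if (!is.na(x) && x > 20) x / 1000 else x
  new("ASLParams", lambdaPartition = lambdaPartition,
    t1Blood = msToS(t1Blood), pld = msToS(pld), tau = msToS(tau),
    alpha = alpha)
}

#' Regional cerebral blood flow map
#'
#' @slot values 3D map in mL/100 g/min; NA outside the mask. Negative values
#'   (possible for noisy ASL differences) are retained, not clamped.
#' @slot mask logical 3D mask of quantified voxels.
#' @slot method provenance: \code{"2nd-mc-dip"}, \code{"1st-mc-dip"},
#'   \code{"non-mc-dip"}, \code{"asl"} or \code{"truth"}.
#' @exportClass RCBFMap
setClass("RCBFMap",
  representation(values = "array", mask = "array", method = "character"))

setValidity("RCBFMap", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msgs <- c(msgs, "values and mask must share dimensions")
  if (!(object@method %in% .RCBF_METHODS))
    msgs <- c(msgs, sprintf("method must be one of %s",
      paste(.RCBF_METHODS, collapse = ", ")))
  if (!length(msgs)) {
    v <- object@values[object@mask]
    if (any(is.infinite(v)))
      msgs <- c(msgs, "values within the mask must be finite or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Phantom ground truth
#'
#' Everything the synthetic brain phantom knows about itself: tissue
#' probabilities, true IVIM parameter maps, the true rCBF map, the four
#' feeding-artery flows consistent with it, and the bulk-motion dispersion
#' fields that drive scheme-dependent signal corruption.
#'
#' @slot tissueProbs list of 3D arrays \code{gm}, \code{wm}, \code{csf} with
#'   per-voxel probabilities in [0, 1] summing to <= 1.
#' @slot trueS0,trueF,trueDStar,trueD true IVIM parameter maps (NA outside
#'   the head).
#' @slot trueRCBF \linkS4class{RCBFMap} with method \code{"truth"}.
#' @slot brainMask logical: voxels counted as brain tissue (GM or WM).
#' @slot vesselTrueFlows named numeric(4), mL/min.
#' @slot sigmaV,sigmaA bulk-motion velocity (cm/s) and acceleration (cm/s^2)
#'   dispersion maps.
#' @slot voxelDims voxel dimensions (mm).
#' @slot seed integer seed that reproduces the phantom bit-identically.
#' @slot config full parameter list used for construction.
#' @exportClass PhantomGroundTruth
setClass("PhantomGroundTruth",
  representation(tissueProbs = "list", trueS0 = "array", trueF = "array",
    trueDStar = "array", trueD = "array", trueRCBF = "RCBFMap",
    brainMask = "array", vesselTrueFlows = "numeric", sigmaV = "array",
    sigmaA = "array", voxelDims = "numeric", seed = "numeric",
    config = "list"))

setValidity("PhantomGroundTruth", function(object) {
  msgs <- character()
  if (!all(c("gm", "wm", "csf") %in% names(object@tissueProbs)))
    msgs <- c(msgs, "tissueProbs must contain gm, wm and csf arrays")
  else {
    tp <- object@tissueProbs
    tot <- tp$gm + tp$wm + tp$csf
    if (any(tp$gm < 0 | tp$gm > 1 | tp$wm < 0 | tp$wm > 1 |
            tp$csf < 0 | tp$csf > 1) || any(tot > 1 + 1e-9))
      msgs <- c(msgs, "tissue probabilities must lie in [0,1] and sum to <= 1")
    br <- object@brainMask
    if (any(br) && (anyNA(object@trueF[br]) || any(object@trueF[br] < 0) ||
        any(object@trueD[br] <= 0) || any(object@trueDStar[br] <= 0)))
      msgs <- c(msgs, "true parameter maps must be positive within the brain")
  }
  if (length(object@vesselTrueFlows) != 4L)
    msgs <- c(msgs, "vesselTrueFlows must have length 4")
  if (length(msgs)) msgs else TRUE
})

#' Stepwise-fit configuration
#'
#' Tunables of the two-step biexponential fit. The tissue-diffusion step uses
#' only b-values at or above \code{highBThreshold}; the perfusion step runs a
#' box-constrained Levenberg-Marquardt fit of (S0, F, D*) with D frozen.
#'
#' @slot highBThreshold b-value (s/mm^2) above which perfusion is neglected.
#' @slot dLower,dUpper bounds on D (mm^2/s).
#' @slot dStarUpper upper bound on D* (mm^2/s); the lower bound is the fitted D.
#' @slot fLower,fUpper bounds on the perfusion fraction.
#' @slot maxIterations solver iteration cap.
#' @slot tolerance solver convergence tolerance.
#' @slot nRefine number of perfusion-corrected refinement passes in
#'   \code{\link{fitIVIM}} (0 disables refinement).
#' @slot maskFraction relative intensity threshold for brain masking.
#' @slot minConvergedFraction abort threshold for \code{\link{fitIVIM}}.
#' @exportClass FitConfig
setClass("FitConfig",
  representation(highBThreshold = "numeric", dLower = "numeric",
    dUpper = "numeric", dStarUpper = "numeric", fLower = "numeric",
    fUpper = "numeric", maxIterations = "numeric", tolerance = "numeric",
    nRefine = "numeric", maskFraction = "numeric",
    minConvergedFraction = "numeric"))

setValidity("FitConfig", function(object) {
  msgs <- character()
  if (object@dLower <= 0 || object@dLower >= object@dUpper)
    msgs <- c(msgs, "need 0 < dLower < dUpper")
  if (object@dUpper >= object@dStarUpper)
    msgs <- c(msgs, "need dUpper < dStarUpper")
  if (object@fLower < 0 || object@fLower >= object@fUpper ||
      object@fUpper > 1)
    msgs <- c(msgs, "need 0 <= fLower < fUpper <= 1")
  if (object@highBThreshold <= 0)
    msgs <- c(msgs, "highBThreshold must be positive")
  if (object@nRefine < 0) msgs <- c(msgs, "nRefine must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FitConfig
#'
#' @param highBThreshold high-b cutoff for the tissue-diffusion step
#'   (s/mm^2); must be present in the b-value table at fit time.
#' @param dLower,dUpper bounds on D in mm^2/s.
#' @param dStarUpper upper bound on D* in mm^2/s.
#' @param fLower,fUpper bounds on F.
#' @param maxIterations,tolerance solver controls.
#' @param nRefine perfusion-corrected refinement passes (see
#'   \code{\link{fitIVIM}}).
#' @param maskFraction fraction of the 99th-percentile b0 intensity used as
#'   the brain-mask threshold.
#' @param minConvergedFraction minimum converged-voxel fraction before
#'   \code{fitIVIM} aborts.
#' @return a \linkS4class{FitConfig}.
#' @export
fitConfig <- function(highBThreshold = 200, dLower = 1e-5, dUpper = 4e-3,
                      dStarUpper = 0.5, fLower = 0, fUpper = 1,
                      maxIterations = 200, tolerance = 1e-12, nRefine = 8,
                      maskFraction = 0.2, minConvergedFraction = 0.01) {
  new("FitConfig", highBThreshold = highBThreshold, dLower = dLower,
    dUpper = dUpper, dStarUpper = dStarUpper, fLower = fLower,
    fUpper = fUpper, maxIterations = maxIterations, tolerance = tolerance,
    nRefine = nRefine, maskFraction = maskFraction,
    minConvergedFraction = minConvergedFraction)
}
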