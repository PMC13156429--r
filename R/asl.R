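#' ASL kinetic-model scale factor
#'
#' Closed-form scale factor of the single-compartment pCASL quantification
#' model,
#' \deqn{K = \frac{6000\,\lambda\,e^{PLD/T_{1,blood}}}
#'   {2\,\alpha\,T_{1,blood}\,(1 - e^{-\tau/T_{1,blood}})},}
#' in (mL/100 g/min) per unit of the normalized label difference
#' \eqn{\Delta M / S_{PD}}. All times must be in seconds (the
#' \code{\link{aslParams}} constructor converts millisecond inputs); the
#' factor 6000 converts mL/g/s to mL/100 g/min.
#'
#' @param params an \linkS4class{ASLParams}.
#' @return the scale factor K.
#' @examples
#' aslScaleFactor(aslParams())  # ~7305 at the default 3T constants
#' @export
aslScaleFactor <- function(params) {
  stopifnot(is(params, "ASLParams"))
  t1 <- params@t1Blood
  6000 * params@lambdaPartition * exp(params@pld / t1) /
    (2 * params@alpha * t1 * (1 - exp(-params@tau / t1)))
}

#' Quantify rCBF from ASL control/label/PD volumes
#'
#' Voxelwise \code{rCBF = K * (control - label) / pd} within the mask, with
#' \code{K} from \code{\link{aslScaleFactor}}. Noise can drive the
#' control-label difference negative; such values are retained (not clamped)
#' so ROI statistics remain unbiased, while voxels with non-positive proton
#' density are flagged invalid (NA).
#'
#' @param control,label,pd co-registered 3D arrays of equal shape.
#' @param params an \linkS4class{ASLParams}.
#' @param mask logical 3D mask of voxels to quantify; defaults to
#'   \code{pd > 0}.
#' @return an \linkS4class{RCBFMap} with method \code{"asl"}.
#' @export
aslRCBF <- function(control, label, pd, params = aslParams(), mask = NULL) {
  d <- dim(control)
  if (!identical(d, dim(label)) || !identical(d, dim(pd)))
    stop("control, label and pd must be co-registered arrays of equal shape")
  if (is.null(mask)) mask <- pd > 0
  if (!identical(dim(mask), d)) stop("mask must match the volume shape")
  K <- aslScaleFactor(params)
  values <- array(NA_real_, dim = d)
  ok <- mask & pd > 0
  nBad <- sum(mask & !(pd > 0))
  if (nBad > 0)
    warning(sprintf("%d mask voxels have non-positive PD; flagged invalid",
      nBad))
  values[ok] <- K * (control[ok] - label[ok]) / pd[ok]
  new("RCBFMap", values = values, mask = mask, method = "asl")
}
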