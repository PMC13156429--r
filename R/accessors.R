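#' Accessors
#'
#' Small accessor generics for the package's S4 containers, so user code never
#' reaches into slots directly.
#'
#' @param object an mcdip S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setMethod("bValues", "BValueScheme", function(object) object@bValues)
#' @rdname accessors
#' @export
setMethod("bValues", "DWISeries", function(object) object@scheme@bValues)

#' @rdname accessors
#' @export
setGeneric("schemeName", function(object) standardGeneric("schemeName"))
#' @rdname accessors
#' @export
setMethod("schemeName", "BValueScheme", function(object) object@scheme)
#' @rdname accessors
#' @export
setMethod("schemeName", "DWISeries", function(object) object@scheme@scheme)
#' @rdname accessors
#' @export
setMethod("schemeName", "IVIMParameterMap", function(object) object@scheme)

#' @rdname accessors
#' @export
setGeneric("momentWeights", function(object) standardGeneric("momentWeights"))
#' @rdname accessors
#' @export
setMethod("momentWeights", "BValueScheme", function(object) object@momentWeights)

#' @rdname accessors
#' @export
setGeneric("signalArray", function(object) standardGeneric("signalArray"))
#' @rdname accessors
#' @export
setMethod("signalArray", "DWISeries", function(object) object@signal)

#' @rdname accessors
#' @export
setGeneric("voxelDims", function(object) standardGeneric("voxelDims"))
#' @rdname accessors
#' @export
setMethod("voxelDims", "DWISeries", function(object) object@voxelDims)
#' @rdname accessors
#' @export
setMethod("voxelDims", "IVIMParameterMap", function(object) object@voxelDims)
#' @rdname accessors
#' @export
setMethod("voxelDims", "PhantomGroundTruth", function(object) object@voxelDims)

#' @rdname accessors
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setMethod("brainMask", "IVIMParameterMap", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("brainMask", "PhantomGroundTruth", function(object) object@brainMask)
#' @rdname accessors
#' @export
setMethod("brainMask", "RCBFMap", function(object) object@mask)

#' Extract one IVIM parameter map
#'
#' @param object an \linkS4class{IVIMParameterMap}.
#' @param which one of \code{"s0"}, \code{"f"}, \code{"dStar"}, \code{"d"},
#'   \code{"fdStar"}, \code{"nrmse"}, \code{"converged"}.
#' @return a 3D array (NA outside the mask; \code{converged} is logical).
#' @export
setGeneric("paramMap", function(object, which) standardGeneric("paramMap"))
#' @rdname paramMap
#' @export
setMethod("paramMap", "IVIMParameterMap", function(object, which) {
  which <- match.arg(which,
    c("s0", "f", "dStar", "d", "fdStar", "nrmse", "converged"))
  slot(object, which)
})

#' @rdname accessors
#' @export
setGeneric("convergedMask", function(object) standardGeneric("convergedMask"))
#' @rdname accessors
#' @export
setMethod("convergedMask", "IVIMParameterMap",
  function(object) object@mask & object@converged)

#' @rdname accessors
#' @export
setGeneric("rcbfValues", function(object) standardGeneric("rcbfValues"))
#' @rdname accessors
#' @export
setMethod("rcbfValues", "RCBFMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("rcbfMethod", function(object) standardGeneric("rcbfMethod"))
#' @rdname accessors
#' @export
setMethod("rcbfMethod", "RCBFMap", function(object) object@method)

#' @rdname accessors
#' @export
setGeneric("nPhases", function(object) standardGeneric("nPhases"))
#' @rdname accessors
#' @export
setMethod("nPhases", "VelocityCine", function(object) dim(object@velocity)[3L])

#' @rdname accessors
#' @export
setGeneric("pixelArea", function(object) standardGeneric("pixelArea"))
#' @rdname accessors
#' @export
setMethod("pixelArea", "VelocityCine", function(object) object@pixelArea)

#' @rdname accessors
#' @export
setGeneric("lumenMask", function(object) standardGeneric("lumenMask"))
#' @rdname accessors
#' @export
setMethod("lumenMask", "VesselROI", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("vesselFlows", function(object) standardGeneric("vesselFlows"))
#' @rdname accessors
#' @export
setMethod("vesselFlows", "PerfusionCalibration",
  function(object) object@vesselFlows)
#' @rdname accessors
#' @export
setMethod("vesselFlows", "PhantomGroundTruth",
  function(object) object@vesselTrueFlows)

#' @rdname accessors
#' @export
setGeneric("conversionFactor",
  function(object) standardGeneric("conversionFactor"))
#' @rdname accessors
#' @export
setMethod("conversionFactor", "PerfusionCalibration",
  function(object) object@conversionFactor)

#' @rdname accessors
#' @export
setGeneric("tissueProbability",
  function(object, tissue) standardGeneric("tissueProbability"))
#' @rdname accessors
#' @param tissue \code{"gm"}, \code{"wm"} or \code{"csf"}.
#' @export
setMethod("tissueProbability", "PhantomGroundTruth", function(object, tissue) {
  tissue <- match.arg(tissue, c("gm", "wm", "csf"))
  object@tissueProbs[[tissue]]
})

#' @rdname accessors
#' @export
setGeneric("trueMap", function(object, which) standardGeneric("trueMap"))
#' @rdname accessors
#' @param which ground-truth map name: \code{"s0"}, \code{"f"},
#'   \code{"dStar"}, \code{"d"}, \code{"rcbf"}, \code{"sigmaV"},
#'   \code{"sigmaA"}.
#' @export
setMethod("trueMap", "PhantomGroundTruth", function(object, which) {
  which <- match.arg(which,
    c("s0", "f", "dStar", "d", "rcbf", "sigmaV", "sigmaA"))
  switch(which,
    s0 = object@trueS0, f = object@trueF, dStar = object@trueDStar,
    d = object@trueD, rcbf = object@trueRCBF@values,
    sigmaV = object@sigmaV, sigmaA = object@sigmaA)
})

#' @rdname accessors
#' @export
setGeneric("trueRCBF", function(object) standardGeneric("trueRCBF"))
#' @rdname accessors
#' @export
setMethod("trueRCBF", "PhantomGroundTruth", function(object) object@trueRCBF)

#' @rdname accessors
#' @export
setGeneric("phantomConfig", function(object) standardGeneric("phantomConfig"))
#' @rdname accessors
#' @export
setMethod("phantomConfig", "PhantomGroundTruth", function(object) object@config)

setMethod("show", "BValueScheme", function(object) {
  cat(sprintf("BValueScheme '%s': %d b-values (%g..%g s/mm^2), w = (%g, %g)\n",
    object@scheme, length(object@bValues), min(object@bValues),
    max(object@bValues), object@momentWeights[1L], object@momentWeights[2L]))
})

setMethod("show", "DWISeries", function(object) {
  d <- dim(object@signal)
  cat(sprintf(
    "DWISeries: %d x %d x %d grid, %d b-values, scheme '%s', voxels %s mm\n",
    d[1L], d[2L], d[3L], d[4L], object@scheme@scheme,
    paste(object@voxelDims, collapse = " x ")))
})

setMethod("show", "IVIMParameterMap", function(object) {
  n <- sum(object@mask)
  nc <- sum(object@mask & object@converged)
  cat(sprintf(
    "IVIMParameterMap (%s): %d mask voxels, %d converged (%.1f%%)\n",
    object@scheme, n, nc, if (n) 100 * nc / n else 0))
  if (nc) {
    ok <- object@mask & object@converged
    cat(sprintf("  median F = %.3f, D = %.2e, D* = %.2e, FD* = %.2e mm^2/s\n",
      stats::median(object@f[ok]), stats::median(object@d[ok]),
      stats::median(object@dStar[ok]), stats::median(object@fdStar[ok])))
  }
})

setMethod("show", "RCBFMap", function(object) {
  v <- object@values[object@mask]
  v <- v[is.finite(v)]
  cat(sprintf("RCBFMap [%s]: %d voxels, mean %.1f mL/100 g/min\n",
    object@method, length(v), if (length(v)) mean(v) else NA_real_))
})

setMethod("show", "PerfusionCalibration", function(object) {
  cat("PerfusionCalibration\n")
  cat(sprintf("  tCBF: %.1f mL/min, brain %.0f mL, %.1f mL/100 g/min\n",
    object@tcbfMlMin, object@brainVolumeMl, object@tcbfNormalized))
  cat(sprintf("  mean FD*: %.3e mm^2/s over %d voxels; factor %.4g\n",
    object@meanFdStar, object@nVoxelsUsed, object@conversionFactor))
})

setMethod("show", "PhantomGroundTruth", function(object) {
  d <- dim(object@brainMask)
  cat(sprintf(
    "PhantomGroundTruth: %d x %d x %d grid, %d brain voxels, seed %d\n",
    d[1L], d[2L], d[3L], sum(object@brainMask), as.integer(object@seed)))
  cat(sprintf("  true brain-mean rCBF %.1f mL/100 g/min, tCBF %.1f mL/min\n",
    mean(object@trueRCBF@values[object@brainMask]),
    sum(object@vesselTrueFlows)))
})

setMethod("show", "ASLParams", function(object) {
  cat(sprintf(
    "ASLParams: lambda %.2f mL/g, T1b %.3f s, PLD %.3f s, tau %.3f s, alpha %.2f\n",
    object@lambdaPartition, object@t1Blood, object@pld, object@tau,
    object@alpha))
})
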