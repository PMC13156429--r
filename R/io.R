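#' Read a NIfTI volume as a plain array
#'
#' @param path path to a NIfTI-1 file.
#' @return numeric array with the image dimensions.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img), dim = dim(img))
}

#' Write an array as a NIfTI-1 volume
#'
#' @param x numeric array (3D or 4D).
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param voxelDims optional voxel dimensions in mm recorded in the header.
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, voxelDims = NULL) {
  img <- RNifti::asNifti(x)
  if (!is.null(voxelDims))
    RNifti::pixdim(img) <- c(voxelDims, rep(1, length(dim(x)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a b-value table
#'
#' Whitespace-separated plain text (FSL bval dialect), values in s/mm^2.
#'
#' @param path path to the bval file.
#' @return numeric vector of b-values.
#' @export
readBValues <- function(path) scan(path, quiet = TRUE)

#' Write a b-value table
#'
#' @param bValues numeric vector of b-values (s/mm^2).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBValues <- function(bValues, path) {
  cat(paste(bValues, collapse = " "), "\n", file = path)
  invisible(path)
}

#' Write a complete synthetic study to disk
#'
#' Serializes everything the analysis pipeline consumes for one synthetic
#' subject: trace DWI series for the requested gradient schemes (NIfTI-1
#' plus an FSL-dialect bval file), the four phase-contrast vessel cines with
#' a JSON sidecar of seeds and plane metadata, the ASL control/label/PD
#' triplet, tissue probability maps, and a ground-truth sidecar (true rCBF
#' map plus a JSON record of flows, seed and configuration).
#'
#' @param truth a \linkS4class{PhantomGroundTruth}.
#' @param dir output directory (created if needed).
#' @param schemes character vector of scheme names to synthesize.
#' @param noiseSigma DWI Rician channel noise SD.
#' @param nsa DWI magnitude averages.
#' @param nPhases phase-contrast cardiac phases.
#' @param noiseSigmaV phase-contrast background velocity noise SD (cm/s).
#' @param params ASL quantification constants.
#' @param sPdLevel ASL proton-density level.
#' @param aslNoiseSigma ASL additive noise SD.
#' @param seed integer base seed; per-volume seeds are derived from it.
#' @return named list of written paths (the study manifest), invisibly.
#' @export
writePhantomStudy <- function(truth, dir,
                              schemes = c("2nd-mc", "1st-mc", "non-mc"),
                              noiseSigma = 15, nsa = 2, nPhases = 16,
                              noiseSigmaV = 0, params = aslParams(),
                              sPdLevel = 1000, aslNoiseSigma = 0, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vd <- truth@voxelDims
  manifest <- list(dir = dir)

  bv <- defaultBValues()
  manifest$bvals <- file.path(dir, "dwi.bval")
  writeBValues(bv, manifest$bvals)
  for (i in seq_along(schemes)) {
    sc <- bValueScheme(schemes[i], bValues = bv)
    dwi <- synthesizeDWI(truth, sc, noiseSigma = noiseSigma, nsa = nsa,
      seed = deriveSeed(seed, i))
    p <- file.path(dir, sprintf("dwi_%s.nii.gz", schemes[i]))
    writeVolume(dwi@signal, p, vd)
    manifest[[paste0("dwi_", schemes[i])]] <- p
  }

  pc <- synthesizePC(truth, nPhases = nPhases, noiseSigmaV = noiseSigmaV,
    seed = deriveSeed(seed, 10))
  pcMeta <- list()
  for (label in names(pc)) {
    p <- file.path(dir, sprintf("pc_%s.nii.gz", label))
    writeVolume(pc[[label]]$cine@velocity, p)
    manifest[[paste0("pc_", label)]] <- p
    pcMeta[[label]] <- list(seedPoint = as.integer(pc[[label]]$seedPoint),
      pixelArea = pc[[label]]$cine@pixelArea, venc = pc[[label]]$cine@venc,
      heartRate = pc[[label]]$cine@heartRate)
  }
  manifest$pc_meta <- file.path(dir, "pc_meta.json")
  jsonlite::write_json(pcMeta, manifest$pc_meta, auto_unbox = TRUE,
    digits = NA)

  asl <- synthesizeASL(truth, params = params, sPdLevel = sPdLevel,
    noiseSigma = aslNoiseSigma, seed = deriveSeed(seed, 20))
  for (nm in names(asl)) {
    p <- file.path(dir, sprintf("asl_%s.nii.gz", nm))
    writeVolume(asl[[nm]], p, vd)
    manifest[[paste0("asl_", nm)]] <- p
  }

  for (tis in c("gm", "wm", "csf")) {
    p <- file.path(dir, sprintf("tissue_%s.nii.gz", tis))
    writeVolume(truth@tissueProbs[[tis]], p, vd)
    manifest[[paste0("tissue_", tis)]] <- p
  }

  manifest$truth_rcbf <- file.path(dir, "truth_rcbf.nii.gz")
  rc <- truth@trueRCBF@values
  rc[is.na(rc)] <- 0
  writeVolume(rc, manifest$truth_rcbf, vd)

  manifest$truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    seed = as.integer(truth@seed),
    studySeed = as.integer(seed),
    voxelDims = vd,
    vesselTrueFlows = as.list(truth@vesselTrueFlows),
    tcbfNormalized = truth@config$tcbfNormalized,
    tissueDensity = truth@config$tissueDensity,
    aslParams = list(lambdaPartition = params@lambdaPartition,
      t1Blood = params@t1Blood, pld = params@pld, tau = params@tau,
      alpha = params@alpha)),
    manifest$truth_json, auto_unbox = TRUE, digits = NA)

  invisible(manifest)
}
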