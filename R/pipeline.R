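#' Assemble and validate a pipeline configuration
#'
#' Collects the input paths of a study directory laid out by
#' \code{\link{writePhantomStudy}} together with the analysis parameters.
#' Inputs that exist are recorded; missing optional stages (e.g. the
#' phase-contrast cines) leave their entry NULL so that
#' \code{\link{runPipeline}} fails at the stage that needs them, naming it.
#'
#' @param inputDir study directory.
#' @param outputDir output directory (created by \code{runPipeline}).
#' @param schemes gradient schemes to process.
#' @param fit a \linkS4class{FitConfig}.
#' @param asl an \linkS4class{ASLParams}.
#' @param jsdBinEdges histogram bin edges for the JSD map comparison.
#' @param tissueThreshold tissue probability threshold for ROIs.
#' @param seed integer seed recorded in every output sidecar.
#' @return a validated configuration list of class \code{mcdipConfig}.
#' @export
pipelineConfig <- function(inputDir, outputDir,
                           schemes = c("2nd-mc", "1st-mc", "non-mc"),
                           fit = fitConfig(), asl = aslParams(),
                           jsdBinEdges = seq(0, 150, length.out = 65),
                           tissueThreshold = 0.9, seed = 1) {
  if (!dir.exists(inputDir)) stop("inputDir does not exist")
  need <- function(p) if (file.exists(p)) p else NULL
  dwi <- lapply(schemes, function(s)
    need(file.path(inputDir, sprintf("dwi_%s.nii.gz", s))))
  names(dwi) <- schemes
  if (any(vapply(dwi, is.null, logical(1))))
    stop("missing DWI series for scheme(s): ",
      paste(schemes[vapply(dwi, is.null, logical(1))], collapse = ", "))
  bvals <- need(file.path(inputDir, "dwi.bval"))
  if (is.null(bvals)) stop("missing b-value table dwi.bval")
  pcPaths <- lapply(.VESSELS, function(v)
    need(file.path(inputDir, sprintf("pc_%s.nii.gz", v))))
  names(pcPaths) <- .VESSELS
  pcMeta <- need(file.path(inputDir, "pc_meta.json"))
  pc <- if (any(vapply(pcPaths, is.null, logical(1))) || is.null(pcMeta))
    NULL else list(paths = pcPaths, meta = pcMeta)
  aslPaths <- lapply(c("control", "label", "pd"), function(v)
    need(file.path(inputDir, sprintf("asl_%s.nii.gz", v))))
  names(aslPaths) <- c("control", "label", "pd")
  if (any(vapply(aslPaths, is.null, logical(1)))) aslPaths <- NULL
  tissue <- lapply(c("gm", "wm"), function(t)
    need(file.path(inputDir, sprintf("tissue_%s.nii.gz", t))))
  names(tissue) <- c("gm", "wm")
  if (any(vapply(tissue, is.null, logical(1)))) tissue <- NULL

  structure(list(inputDir = inputDir, outputDir = outputDir,
    schemes = schemes, dwi = dwi, bvals = bvals, pc = pc, asl = aslPaths,
    tissue = tissue, fit = fit, aslParams = asl, jsdBinEdges = jsdBinEdges,
    tissueThreshold = tissueThreshold, seed = as.integer(seed)),
    class = "mcdipConfig")
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis on a study directory: brain masking and
#' stepwise IVIM fitting per gradient scheme, pulsatility-based vessel
#' segmentation and flow summation on the phase-contrast cines,
#' normalization of total CBF by brain mass, calibration of each F*D* map
#' to absolute rCBF, ASL reference quantification, and ROI/JSD evaluation.
#' All maps, the calibration records and the evaluation report are written
#' under \code{outputDir}; every JSON sidecar carries the seed. A stage
#' failure aborts with the failing stage named and leaves a \code{FAILED}
#' marker file; completed outputs are retained. Given fixed inputs and seed
#' the run is deterministic (byte-identical reports).
#'
#' @param config a configuration from \code{\link{pipelineConfig}}.
#' @return manifest list: output paths plus the in-memory report.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "mcdipConfig"))
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      writeLines(c(name, conditionMessage(e)), file.path(out, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE)
    })
  }
  manifest <- list(outputDir = out)
  report <- list(seed = config$seed)

  bv <- stage("load", readBValues(config$bvals))
  dwiList <- stage("load", lapply(config$schemes, function(s) {
    sig <- readVolume(config$dwi[[s]])
    vd <- RNifti::pixdim(RNifti::readNifti(config$dwi[[s]]))[1:3]
    new("DWISeries", signal = sig, scheme = bValueScheme(s, bValues = bv),
      voxelDims = as.numeric(vd), nDirections = 3)
  }))
  names(dwiList) <- config$schemes

  fits <- list(); masks <- list()
  for (s in config$schemes) {
    dwi <- dwiList[[s]]
    masks[[s]] <- stage("mask", {
      ib0 <- which(bv == 0)[1L]
      makeBrainMask(dwi@signal[, , , ib0, drop = TRUE],
        config$fit@maskFraction)
    })
    fits[[s]] <- stage("fit", fitIVIM(dwi, masks[[s]], config$fit))
  }

  pcResult <- stage("calibrate", {
    if (is.null(config$pc))
      stop("phase-contrast inputs are missing")
    meta <- jsonlite::read_json(config$pc$meta, simplifyVector = TRUE)
    flows <- vapply(.VESSELS, function(v) {
      vel <- readVolume(config$pc$paths[[v]])
      cine <- new("VelocityCine", velocity = vel,
        pixelArea = meta[[v]]$pixelArea, venc = meta[[v]]$venc,
        heartRate = meta[[v]]$heartRate)
      roi <- segmentLumen(cine, meta[[v]]$seedPoint, vesselLabel = v)
      vesselFlow(cine, roi)
    }, numeric(1))
    list(flows = flows, tcbf = totalCBF(flows))
  })
  report$vesselFlows <- as.list(pcResult$flows)
  report$tcbfMlMin <- pcResult$tcbf

  rcbfMaps <- list()
  for (s in config$schemes) {
    res <- stage("calibrate", {
      vol <- brainVolume(masks[[s]], fits[[s]]@voxelDims)
      calibrateRCBF(fits[[s]], vesselFlows = pcResult$flows,
        brainVolumeMl = vol, method = paste0(s, "-dip"))
    })
    rcbfMaps[[s]] <- res$rcbf
    p <- file.path(out, sprintf("rcbf_%s.nii.gz", s))
    v <- res$rcbf@values; v[is.na(v)] <- 0
    writeVolume(v, p, fits[[s]]@voxelDims)
    manifest[[paste0("rcbf_", s)]] <- p
    pj <- file.path(out, sprintf("calibration_%s.json", s))
    cal <- res$calibration
    jsonlite::write_json(list(seed = config$seed, scheme = s,
      vesselFlows = as.list(cal@vesselFlows), tcbfMlMin = cal@tcbfMlMin,
      brainVolumeMl = cal@brainVolumeMl, tissueDensity = cal@tissueDensity,
      tcbfNormalized = cal@tcbfNormalized, totalFdStar = cal@totalFdStar,
      meanFdStar = cal@meanFdStar, conversionFactor = cal@conversionFactor,
      nVoxelsUsed = cal@nVoxelsUsed,
      normalization = "brain-mean F*D* over converged voxels"),
      pj, auto_unbox = TRUE, digits = NA)
    manifest[[paste0("calibration_", s)]] <- pj
    report[[paste0("calibration_", s)]] <- list(
      conversionFactor = cal@conversionFactor,
      tcbfNormalized = cal@tcbfNormalized,
      convergedFraction = sum(convergedMask(fits[[s]])) / sum(masks[[s]]))
    pn <- file.path(out, sprintf("ivim_%s_fdstar.nii.gz", s))
    fd <- fits[[s]]@fdStar; fd[is.na(fd)] <- 0
    writeVolume(fd, pn, fits[[s]]@voxelDims)
    manifest[[paste0("fdstar_", s)]] <- pn
  }

  aslMap <- stage("asl", {
    if (is.null(config$asl)) stop("ASL inputs are missing")
    ctl <- readVolume(config$asl$control)
    lbl <- readVolume(config$asl$label)
    pd <- readVolume(config$asl$pd)
    aslRCBF(ctl, lbl, pd, config$aslParams)
  })
  p <- file.path(out, "rcbf_asl.nii.gz")
  v <- aslMap@values; v[is.na(v)] <- 0
  writeVolume(v, p)
  manifest$rcbf_asl <- p

  evalReport <- stage("evaluate", {
    if (is.null(config$tissue)) stop("tissue probability maps are missing")
    gmProb <- readVolume(config$tissue$gm)
    wmProb <- readVolume(config$tissue$wm)
    rois <- list(GM = tissueROIMask(gmProb, config$tissueThreshold),
      WM = tissueROIMask(wmProb, config$tissueThreshold))
    allMaps <- c(rcbfMaps, list(asl = aslMap))
    stats <- do.call(rbind, unlist(lapply(names(rois), function(tn)
      lapply(allMaps, function(m) roiStats(m, rois[[tn]], tn))),
      recursive = FALSE))
    jsdTab <- do.call(rbind, unlist(lapply(names(rois), function(tn)
      lapply(config$schemes, function(s) {
        sel <- rois[[tn]] & rcbfMaps[[s]]@mask & aslMap@mask
        data.frame(tissue = tn, scheme = s,
          jsd = jsd(rcbfMaps[[s]]@values[sel], aslMap@values[sel],
            config$jsdBinEdges), stringsAsFactors = FALSE)
      })), recursive = FALSE))
    nrmseTab <- do.call(rbind, unlist(lapply(names(rois), function(tn)
      lapply(config$schemes, function(s) {
        sel <- rois[[tn]] & convergedMask(fits[[s]])
        data.frame(tissue = tn, scheme = s,
          meanNrmse = mean(fits[[s]]@nrmse[sel]), stringsAsFactors = FALSE)
      })), recursive = FALSE))
    list(roiStats = stats, jsdVsAsl = jsdTab, nrmse = nrmseTab)
  })
  report$roiStats <- evalReport$roiStats
  report$jsdVsAsl <- evalReport$jsdVsAsl
  report$nrmse <- evalReport$nrmse

  manifest$report <- file.path(out, "report.json")
  jsonlite::write_json(report, manifest$report, auto_unbox = TRUE,
    digits = NA, dataframe = "rows")
  manifest$reportData <- report
  invisible(manifest)
}
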