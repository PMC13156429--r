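#' Default phantom configuration
#'
#' Parameters of the synthetic brain phantom. The geometry is a concentric-
#' shell "brain" (WM core, GM shell, thin CSF rim) on a desk-scale grid with
#' anisotropic voxels echoing a thick-slice acquisition. IVIM truth values are
#' typical parenchymal figures: D = 0.8/0.7 um^2/ms for GM/WM, D* = 10
#' um^2/ms, perfusion fractions 0.10 (GM) and 0.05 (WM), with a smooth 8%
#' within-tissue modulation so parameter histograms are continuous. The b0
#' contrast suppresses CSF (bright-fluid attenuation) so intensity-based
#' masking isolates parenchyma. Bulk-motion dispersion uses a uniform cardiac
#' velocity scale of 1 cm/s and an acceleration scale rising from 10 cm/s^2
#' at the cortex to 40 cm/s^2 in deep/periventricular tissue, coupled to
#' phase dispersion by c1/c2; the whole-brain perfusion level is 50 mL/100
#' g/min, split over the four feeding arteries roughly 70/30 between the
#' internal carotid and vertebral pairs.
#'
#' @return named list of defaults; any subset may be overridden via the
#'   \code{config} argument of \code{\link{makePhantom}}.
#' @export
phantomDefaults <- function() list(
  voxelDims = c(2, 2, 6),          # mm
  axesFrac = 0.8,                  # ellipsoid semi-axes as fraction of grid/2
  wmFrac = 0.55,                   # WM core outer radius (fraction of brain)
  gmFrac = 0.92,                   # GM shell outer radius; CSF rim beyond
  s0 = c(gm = 1000, wm = 900, csf = 120),
  d = c(gm = 0.8e-3, wm = 0.7e-3, csf = 3.0e-3),   # mm^2/s
  dStar = 10e-3,                   # mm^2/s
  f = c(gm = 0.10, wm = 0.05, csf = 0),
  fSpatialCV = 0.08,               # smooth within-tissue modulation of F
  tcbfNormalized = 50,             # mL/100 g/min, brain-mean truth
  tissueDensity = 1.06,            # g/mL
  sigmaV = 1.0,                    # cm/s, bulk velocity dispersion
  sigmaACortex = 10,               # cm/s^2 at the cortex
  sigmaADeep = 40,                 # cm/s^2 deep/periventricular
  deepRadius = 0.6,                # normalized radius where deep weighting ends
  c1 = 0.015,                      # (cm/s)^-1 per sqrt(s/mm^2)
  c2 = 0.0011,                     # (cm/s^2)^-1 per sqrt(s/mm^2)
  vesselFractions = c(L_ICA = 0.36, R_ICA = 0.34, L_VA = 0.16, R_VA = 0.14),
  vesselRadiiMm = c(L_ICA = 2.5, R_ICA = 2.5, L_VA = 1.9, R_VA = 1.9),
  pcGrid = 32,                     # phase-contrast plane size (pixels)
  pcPixelMm = 0.586,               # in-plane pixel size, mm
  venc = 80,                       # cm/s
  heartRate = 60,                  # beats/min
  pulsatility = 0.8,               # raised-cosine modulation amplitude
  uniformTissue = NULL             # set to "gm"/"wm" for a single-tissue grid
)

#' Build a synthetic brain phantom with known ground truth
#'
#' Constructs co-registered tissue probabilities, true IVIM parameter maps, a
#' true rCBF map, feeding-artery flows consistent with it, and bulk-motion
#' dispersion fields. The true rCBF is proportional to F*D* and scaled so its
#' brain mean equals the configured normalized total CBF; the four vessel
#' flows are derived from that same total and the phantom's brain mass, so
#' the phase-contrast calibration chain is exactly self-consistent.
#'
#' @param shape 3D grid size; every dimension must be >= 8.
#' @param seed integer; the phantom is bit-identical for equal
#'   (shape, seed, config).
#' @param config named list overriding entries of
#'   \code{\link{phantomDefaults}}.
#' @return a \linkS4class{PhantomGroundTruth}.
#' @examples
#' ph <- makePhantom(c(16, 16, 8), seed = 7)
#' ph
#' @export
makePhantom <- function(shape = c(48, 48, 24), seed = 1, config = list()) {
  if (length(shape) != 3L || any(shape < 8))
    stop("every phantom grid dimension must be >= 8")
  shape <- as.integer(shape)
  cfg <- utils::modifyList(phantomDefaults(), config)

  ctr <- (shape + 1) / 2
  ax <- cfg$axesFrac * shape / 2
  xs <- ((seq_len(shape[1L]) - ctr[1L]) / ax[1L])^2
  ys <- ((seq_len(shape[2L]) - ctr[2L]) / ax[2L])^2
  zs <- ((seq_len(shape[3L]) - ctr[3L]) / ax[3L])^2
  r <- sqrt(outer(outer(xs, ys, `+`), zs, `+`))

  if (!is.null(cfg$uniformTissue)) {
    tis <- match.arg(cfg$uniformTissue, c("gm", "wm"))
    gm <- array(tis == "gm", dim = shape)
    wm <- array(tis == "wm", dim = shape)
    csf <- array(FALSE, dim = shape)
  } else {
    wm <- r <= cfg$wmFrac
    gm <- r > cfg$wmFrac & r <= cfg$gmFrac
    csf <- r > cfg$gmFrac & r <= 1
  }
  head <- gm | wm | csf
  brain <- gm | wm

  asProb <- function(m) { p <- array(0, dim = shape); p[m] <- 1; p }
  tissueProbs <- list(gm = asProb(gm), wm = asProb(wm), csf = asProb(csf))

  trueS0 <- cfg$s0[["gm"]] * gm + cfg$s0[["wm"]] * wm + cfg$s0[["csf"]] * csf
  naOutside <- function(x) { x[!head] <- NA_real_; x }
  trueD <- naOutside(cfg$d[["gm"]] * gm + cfg$d[["wm"]] * wm +
    cfg$d[["csf"]] * csf)
  trueDStar <- naOutside(array(cfg$dStar, dim = shape))

  fBase <- cfg$f[["gm"]] * gm + cfg$f[["wm"]] * wm
  mod <- if (cfg$fSpatialCV > 0)
    1 + cfg$fSpatialCV * withSeed(seed, smoothField(shape))
  else array(1, dim = shape)
  trueF <- naOutside(clamp(fBase * mod, 0, 0.5))
  trueF[csf] <- 0

  sigmaV <- array(0, dim = shape); sigmaV[head] <- cfg$sigmaV
  sigmaA <- array(0, dim = shape)
  deepW <- pmax(0, 1 - r / cfg$deepRadius)
  sigmaA[head] <- cfg$sigmaACortex +
    (cfg$sigmaADeep - cfg$sigmaACortex) * deepW[head]

  raw <- trueF * trueDStar
  if (!any(brain)) stop("phantom has no brain voxels; adjust geometry")
  scale <- cfg$tcbfNormalized / mean(raw[brain])
  rcbfValues <- array(NA_real_, dim = shape)
  rcbfValues[brain] <- raw[brain] * scale
  trueRCBF <- new("RCBFMap", values = rcbfValues, mask = brain,
    method = "truth")

  brainVolumeMl <- sum(brain) * prod(cfg$voxelDims) / 1000
  tcbfMlMin <- cfg$tcbfNormalized * brainVolumeMl * cfg$tissueDensity / 100
  flows <- cfg$vesselFractions / sum(cfg$vesselFractions) * tcbfMlMin

  new("PhantomGroundTruth", tissueProbs = tissueProbs, trueS0 = trueS0,
    trueF = trueF, trueDStar = trueDStar, trueD = trueD,
    trueRCBF = trueRCBF, brainMask = brain, vesselTrueFlows = flows,
    sigmaV = sigmaV, sigmaA = sigmaA, voxelDims = as.numeric(cfg$voxelDims),
    seed = as.numeric(seed), config = cfg)
}

#' Bulk-motion signal attenuation factor
#'
#' Coherent bulk motion during diffusion encoding disperses the signal phase
#' across the voxel and across shots; on magnitude images this appears as a
#' deterministic attenuation \eqn{\exp(-\sigma_\phi^2/2)} with
#' \eqn{\sigma_\phi = \sqrt{b}\,(c_1 w_1 \sigma_v + c_2 w_2 \sigma_a)}:
#' the residual gradient-moment weights \eqn{(w_1, w_2)} gate the velocity
#' and acceleration dispersion contributions, and the \eqn{\sqrt{b}} factor
#' reflects gradient amplitude scaling at fixed timing. A second-order
#' motion-compensated scheme (weights 0, 0) is unattenuated at every b.
#'
#' @param b diffusion weighting, s/mm^2 (scalar or array).
#' @param weights residual moment weights (w1, w2), e.g.
#'   \code{momentWeights(scheme)}.
#' @param sigmaV velocity dispersion, cm/s (scalar or array).
#' @param sigmaA acceleration dispersion, cm/s^2 (scalar or array).
#' @param c1,c2 coupling constants mapping dispersions to phase-dispersion
#'   standard deviation per sqrt(b).
#' @return attenuation factor in (0, 1], broadcast over the inputs.
#' @examples
#' motionAttenuation(100, c(0, 0), 1, 20)   # 1: both moments nulled
#' @export
motionAttenuation <- function(b, weights, sigmaV, sigmaA,
                              c1 = phantomDefaults()$c1,
                              c2 = phantomDefaults()$c2) {
  if (anyNA(b) || any(b < 0)) stop("'b' must be non-negative")
  if (length(weights) != 2L || any(weights < 0))
    stop("'weights' must be two non-negative moment weights")
  sigmaPhi <- sqrt(b) * (c1 * weights[1L] * sigmaV +
    c2 * weights[2L] * sigmaA)
  exp(-sigmaPhi^2 / 2)
}

#' Synthesize a diffusion-weighted series from phantom truth
#'
#' Evaluates the biexponential forward model at every voxel and b-value,
#' applies the scheme-dependent bulk-motion attenuation, and corrupts the
#' result with Rician noise: independent complex Gaussian channel noise is
#' added, magnitudes are formed, and \code{nsa} magnitude realizations are
#' averaged, matching scanner-style magnitude averaging.
#'
#' @param truth a \linkS4class{PhantomGroundTruth}.
#' @param scheme a \linkS4class{BValueScheme}; its moment weights select the
#'   motion sensitivity.
#' @param noiseSigma per-channel Gaussian noise SD in signal units
#'   (0 disables noise).
#' @param nsa number of averaged magnitude acquisitions (>= 1).
#' @param seed integer RNG seed.
#' @return a \linkS4class{DWISeries}.
#' @export
synthesizeDWI <- function(truth, scheme, noiseSigma = 15, nsa = 2, seed = 1) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (nsa < 1) stop("nsa must be >= 1")
  b <- scheme@bValues
  if (!length(b)) stop("scheme has an empty b-value table")
  cfg <- truth@config
  shape <- dim(truth@trueS0)
  headIdx <- which(truth@trueS0 > 0)

  s0 <- truth@trueS0[headIdx]
  f <- truth@trueF[headIdx]
  d <- truth@trueD[headIdx]
  ds <- truth@trueDStar[headIdx]
  sv <- truth@sigmaV[headIdx]
  sa <- truth@sigmaA[headIdx]
  w <- scheme@momentWeights

  clean <- array(0, dim = c(shape, length(b)))
  nvol <- prod(shape)
  for (k in seq_along(b)) {
    att <- motionAttenuation(b[k], w, sv, sa, cfg$c1, cfg$c2)
    vol <- numeric(nvol)
    vol[headIdx] <- .biexp(s0, f, ds, d, b[k]) * att
    clean[, , , k] <- vol
  }

  signal <- if (noiseSigma > 0) {
    withSeed(seed, {
      n <- length(clean)
      acc <- 0
      for (a in seq_len(nsa)) {
        re <- clean + stats::rnorm(n, 0, noiseSigma)
        im <- stats::rnorm(n, 0, noiseSigma)
        acc <- acc + sqrt(re * re + im * im)
      }
      acc / nsa
    })
  } else clean

  new("DWISeries", signal = signal, scheme = scheme,
    voxelDims = truth@voxelDims, nDirections = 3)
}

#' Synthesize phase-contrast velocity cines for the four feeding arteries
#'
#' Each vessel is a circular lumen on its own through-plane cine with a
#' spatially uniform raised-cosine velocity waveform,
#' \eqn{v(p) = \bar v (1 + A \cos 2\pi p / n)}, whose cycle mean reproduces
#' that vessel's configured volumetric flow exactly at any number of phases.
#' Background pixels carry zero-mean Gaussian velocity noise; velocities are
#' clipped to the venc with a warning if exceeded.
#'
#' @param truth a \linkS4class{PhantomGroundTruth}.
#' @param nPhases cardiac phases per cycle (>= 4).
#' @param noiseSigmaV background velocity noise SD, cm/s.
#' @param seed integer RNG seed.
#' @return named list (L_ICA, R_ICA, L_VA, R_VA) of lists with elements
#'   \code{cine} (\linkS4class{VelocityCine}), \code{lumen} (logical matrix),
#'   \code{seedPoint} (pixel index of the lumen centre) and \code{label}.
#' @export
synthesizePC <- function(truth, nPhases = 16, noiseSigmaV = 0, seed = 1) {
  if (nPhases < 4) stop("nPhases must be >= 4")
  cfg <- truth@config
  g <- cfg$pcGrid
  px <- cfg$pcPixelMm
  flows <- truth@vesselTrueFlows
  out <- vector("list", 4L)
  names(out) <- .VESSELS
  clipped <- FALSE
  for (v in seq_along(.VESSELS)) {
    label <- .VESSELS[v]
    radPx <- cfg$vesselRadiiMm[[label]] / px
    if (2 * radPx >= g)
      stop(sprintf("requested lumen for %s larger than the cine field", label))
    ctr <- c((g + 1) / 2, (g + 1) / 2)
    dx <- outer((seq_len(g) - ctr[1L])^2, (seq_len(g) - ctr[2L])^2, `+`)
    lumen <- sqrt(dx) <= radPx
    areaMm2 <- sum(lumen) * px^2
    vMean <- flows[[label]] / (0.6 * areaMm2)     # cm/s
    wave <- vMean * (1 + cfg$pulsatility *
      cos(2 * pi * (seq_len(nPhases) - 1) / nPhases))
    vel <- array(0, dim = c(g, g, nPhases))
    for (p in seq_len(nPhases)) vel[, , p] <- lumen * wave[p]
    if (noiseSigmaV > 0)
      vel <- vel + withSeed(deriveSeed(seed, v),
        array(stats::rnorm(length(vel), 0, noiseSigmaV), dim = dim(vel)))
    if (max(abs(vel)) > cfg$venc) {
      clipped <- TRUE
      vel <- clamp(vel, -cfg$venc, cfg$venc)
    }
    cine <- new("VelocityCine", velocity = vel, pixelArea = px^2,
      venc = cfg$venc, heartRate = cfg$heartRate)
    out[[v]] <- list(cine = cine, lumen = lumen,
      seedPoint = round(ctr), label = label)
  }
  if (clipped)
    warning("velocities exceeding venc were clipped")
  out
}

#' Synthesize an ASL control/label/proton-density triplet
#'
#' Inverts the single-compartment kinetic model: the control-label difference
#' is set to \code{trueRCBF * pd / K} with \code{K} the
#' \code{\link{aslScaleFactor}} of \code{params}, so that
#' \code{\link{aslRCBF}} recovers the true map exactly in the noise-free
#' limit. The proton-density volume is flat at \code{sPdLevel} over the head.
#'
#' @param truth a \linkS4class{PhantomGroundTruth}.
#' @param params an \linkS4class{ASLParams}.
#' @param sPdLevel proton-density signal level (> 0).
#' @param noiseSigma additive Gaussian noise SD applied to each volume.
#' @param seed integer RNG seed.
#' @return list with 3D arrays \code{control}, \code{label}, \code{pd}.
#' @export
synthesizeASL <- function(truth, params = aslParams(), sPdLevel = 1000,
                          noiseSigma = 0, seed = 1) {
  if (sPdLevel <= 0) stop("sPdLevel must be positive")
  shape <- dim(truth@trueS0)
  head <- truth@trueS0 > 0
  pd <- array(0, dim = shape); pd[head] <- sPdLevel
  rcbf <- truth@trueRCBF@values
  rcbf[is.na(rcbf)] <- 0
  K <- aslScaleFactor(params)
  dM <- rcbf * pd / K
  base <- 0.6 * pd
  control <- base + dM
  label <- base
  if (noiseSigma > 0) {
    vols <- withSeed(seed, list(
      control + stats::rnorm(length(control), 0, noiseSigma),
      label + stats::rnorm(length(label), 0, noiseSigma),
      pd + stats::rnorm(length(pd), 0, noiseSigma)))
    control <- vols[[1L]]; label <- vols[[2L]]; pd <- vols[[3L]]
  }
  list(control = control, label = label, pd = pd)
}
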