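test_that("pulsatility segmentation matches a hand-built case", {
  # 5x5 plane, 4 phases: three pulsatile pixels, one disconnected
  vel <- array(0, dim = c(5, 5, 4))
  wave <- c(4, 8, 4, 0)
  vel[2, 2, ] <- wave
  vel[2, 3, ] <- 1.5 * wave
  vel[5, 5, ] <- wave          # disconnected from the seed component
  cine <- new("VelocityCine", velocity = vel, pixelArea = 1, venc = 80,
    heartRate = 60)
  roi <- segmentLumen(cine, c(2, 2), threshold = 0.85)
  expect_equal(sum(lumenMask(roi)), 2L)
  expect_true(lumenMask(roi)[2, 2] && lumenMask(roi)[2, 3])
  expect_false(lumenMask(roi)[5, 5])
})

test_that("segmentation shrinks monotonically with the threshold", {
  ph <- tinyPhantom()
  pc <- synthesizePC(ph, nPhases = 16, noiseSigmaV = 0.4, seed = 2)
  v <- pc$L_ICA
  masks <- lapply(c(0.5, 0.85, 0.999), function(th)
    lumenMask(segmentLumen(v$cine, v$seedPoint, threshold = th)))
  expect_true(all(!(masks[[2]] & !masks[[1]])))   # 0.85 subset of 0.5
  expect_true(all(!(masks[[3]] & !masks[[2]])))   # 0.999 subset of 0.85
  # with noise, a stringent threshold stays within the true lumen
  expect_true(all(!(masks[[3]] & !v$lumen)))
})

test_that("segmentation recovers the exact lumen on a noise-free cine", {
  ph <- tinyPhantom()
  pc <- synthesizePC(ph, nPhases = 16, noiseSigmaV = 0)
  for (v in names(pc)) {
    roi <- segmentLumen(pc[[v]]$cine, pc[[v]]$seedPoint, vesselLabel = v)
    expect_identical(lumenMask(roi), pc[[v]]$lumen)
  }
})

test_that("vesselFlow converts velocity-area products to mL/min", {
  vel <- array(0, dim = c(4, 4, 5))
  m <- matrix(FALSE, 4, 4); m[1:3, 1] <- TRUE      # 3 pixels of 10 mm^2
  for (p in 1:5) vel[, , p][m] <- 10               # cm/s
  cine <- new("VelocityCine", velocity = vel, pixelArea = 10, venc = 80,
    heartRate = 60)
  roi <- new("VesselROI", mask = m, seedPoint = c(1, 1),
    vesselLabel = "L_ICA")
  expect_equal(vesselFlow(cine, roi), 180)          # 10 cm/s over 30 mm^2
  cine0 <- new("VelocityCine", velocity = vel * 0, pixelArea = 10,
    venc = 80, heartRate = 60)
  expect_equal(vesselFlow(cine0, roi), 0)
})

test_that("totalCBF sums four flows, order independent", {
  expect_equal(totalCBF(c(200, 210, 80, 90)), 580)
  expect_equal(totalCBF(c(90, 80, 210, 200)), 580)
  expect_warning(tc <- totalCBF(c(0, 0, 0, 0)), "non-positive")
  expect_equal(tc, 0)
  expect_error(totalCBF(c(1, 2, 3)), "four")
})

test_that("tCBF normalization divides by brain mass", {
  expect_equal(normalizeTCBF(700, 1400, 1.06), 47.1698113208,
    tolerance = 1e-10)
  expect_equal(normalizeTCBF(0, 1400, 1.06), 0)
  expect_equal(normalizeTCBF(700, 2800, 1.06),
    normalizeTCBF(700, 1400, 1.06) / 2)
  expect_error(normalizeTCBF(700, 0), "positive")
})

test_that("calibration conserves the normalized tCBF over the mask", {
  set.seed(12)
  for (i in 1:10) {
    dims <- c(6, 6, 4)
    mask <- array(runif(prod(dims)) < 0.7, dim = dims)
    if (!any(mask)) next
    fd <- array(NA_real_, dim = dims)
    fd[mask] <- runif(sum(mask), 1e-5, 3e-3)
    tn <- runif(1, 20, 80)
    res <- calibrateRCBF(fd, tcbfNormalized = tn, mask = mask)
    expect_equal(mean(rcbfValues(res$rcbf)[mask]), tn, tolerance = 1e-10)
    # global gain in the DWI chain cancels exactly
    res2 <- calibrateRCBF(fd * 7.3, tcbfNormalized = tn, mask = mask)
    expect_equal(rcbfValues(res2$rcbf), rcbfValues(res$rcbf),
      tolerance = 1e-12)
  }
})

test_that("uniform FD* calibrates to a flat map at the normalized tCBF", {
  dims <- c(5, 5, 3)
  mask <- array(TRUE, dim = dims)
  fd <- array(2e-3, dim = dims)
  res <- calibrateRCBF(fd, tcbfNormalized = 47.2, mask = mask)
  expect_true(all(abs(rcbfValues(res$rcbf) - 47.2) < 1e-10))
  expect_error(calibrateRCBF(fd * 0, tcbfNormalized = 47.2, mask = mask),
    "positive")
})

test_that("end-to-end calibration recovers phantom truth without noise", {
  ph <- tinyPhantom()
  dwi <- synthesizeDWI(ph, bValueScheme("2nd-mc"), noiseSigma = 0)
  mask <- makeBrainMask(signalArray(dwi)[, , , 1])
  fit <- suppressMessages(fitIVIM(dwi, mask))
  pc <- synthesizePC(ph, noiseSigmaV = 0)
  flows <- vapply(names(pc), function(v)
    vesselFlow(pc[[v]]$cine,
      segmentLumen(pc[[v]]$cine, pc[[v]]$seedPoint, vesselLabel = v)),
    numeric(1))
  res <- calibrateRCBF(fit, vesselFlows = flows,
    brainVolumeMl = brainVolume(mask, voxelDims(ph)),
    method = "2nd-mc-dip")
  ok <- convergedMask(fit)
  truth <- rcbfValues(trueRCBF(ph))
  frac <- mean(relErr(rcbfValues(res$rcbf)[ok], truth[ok]) < 0.02)
  expect_gte(frac, 0.95)
  expect_equal(conversionFactor(res$calibration),
    res$calibration@tcbfNormalized / res$calibration@meanFdStar)
})
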