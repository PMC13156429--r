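test_that("phantom generation is bit-identical under a fixed seed", {
  a <- makePhantom(c(12, 12, 8), seed = 5)
  b <- makePhantom(c(12, 12, 8), seed = 5)
  expect_identical(trueMap(a, "f"), trueMap(b, "f"))
  expect_identical(rcbfValues(trueRCBF(a)), rcbfValues(trueRCBF(b)))
  expect_identical(vesselFlows(a), vesselFlows(b))
  c <- makePhantom(c(12, 12, 8), seed = 6)
  expect_false(identical(trueMap(a, "f"), trueMap(c, "f")))
})

test_that("phantom rejects grids smaller than 8 per dimension", {
  expect_error(makePhantom(c(6, 12, 12)), ">= 8")
})

test_that("single-tissue configuration yields uniform truth maps", {
  ph <- makePhantom(c(10, 10, 10), seed = 2,
    config = list(uniformTissue = "gm", fSpatialCV = 0))
  expect_equal(length(unique(as.vector(trueMap(ph, "f")))), 1L)
  expect_equal(length(unique(as.vector(trueMap(ph, "d")))), 1L)
  expect_true(all(brainMask(ph)))
})

test_that("brain-mean true rCBF equals the configured perfusion level", {
  ph <- makePhantom(c(20, 20, 10), seed = 9)
  m <- brainMask(ph)
  target <- phantomConfig(ph)$tcbfNormalized
  expect_equal(mean(rcbfValues(trueRCBF(ph))[m]), target, tolerance = 1e-9)
  # and the vessel flows are consistent with that same total
  vol <- brainVolume(m, voxelDims(ph))
  expect_equal(normalizeTCBF(sum(vesselFlows(ph)), vol,
    phantomConfig(ph)$tissueDensity), target, tolerance = 1e-9)
})

test_that("motionAttenuation follows the phase-dispersion formula", {
  expect_equal(motionAttenuation(500, c(0, 0), 3, 50), 1)
  expect_equal(motionAttenuation(0, c(1, 1), 3, 50), 1)
  # sigma_phi = sqrt(100) * (1*1*0.025 + 1*1*0.025) = 0.5 -> exp(-0.125)
  expect_equal(
    motionAttenuation(100, c(1, 1), 0.025, 0.025, c1 = 1, c2 = 1),
    exp(-0.125), tolerance = 1e-12)
  expect_error(motionAttenuation(-5, c(1, 1), 1, 1), "'b'")
})

test_that("noise-free 2nd-mc synthesis equals the forward model exactly", {
  ph <- tinyPhantom()
  dwi <- synthesizeDWI(ph, bValueScheme("2nd-mc"), noiseSigma = 0)
  b <- bValues(dwi)
  head <- trueMap(ph, "s0") > 0
  for (k in c(1L, 5L, 11L)) {
    expected <- biexpSignal(trueMap(ph, "s0")[head], trueMap(ph, "f")[head],
      trueMap(ph, "dStar")[head], trueMap(ph, "d")[head], b[k])
    expect_equal(signalArray(dwi)[, , , k][head], expected, tolerance = 1e-12)
  }
  expect_true(all(signalArray(dwi)[, , , 1][!head] == 0))
})

test_that("motion corrupts schemes in the expected order at every voxel", {
  ph <- tinyPhantom()
  b <- defaultBValues()
  clean <- signalArray(synthesizeDWI(ph, bValueScheme("2nd-mc"),
    noiseSigma = 0))
  s1 <- signalArray(synthesizeDWI(ph, bValueScheme("1st-mc"),
    noiseSigma = 0))
  sn <- signalArray(synthesizeDWI(ph, bValueScheme("non-mc"),
    noiseSigma = 0))
  # attenuation can only reduce signal, more so with more residual moments
  expect_true(all(sn <= s1 + 1e-12))
  expect_true(all(s1 <= clean + 1e-12))
  devN <- apply((sn - clean)^2, 1:3, sum)
  dev1 <- apply((s1 - clean)^2, 1:3, sum)
  brain <- brainMask(ph)
  expect_true(all(devN[brain] >= dev1[brain]))
  expect_true(all(dev1[brain] > 0))   # sigmaV = 0 but sigmaA > 0 everywhere
})

test_that("synthesis is seeded and Rician noise has the Rayleigh floor", {
  ph <- tinyPhantom()
  sc <- bValueScheme("2nd-mc")
  d1 <- synthesizeDWI(ph, sc, noiseSigma = 10, seed = 3)
  d2 <- synthesizeDWI(ph, sc, noiseSigma = 10, seed = 3)
  expect_identical(signalArray(d1), signalArray(d2))
  d3 <- synthesizeDWI(ph, sc, noiseSigma = 10, seed = 4)
  expect_false(identical(signalArray(d1), signalArray(d3)))
  # background voxels carry pure noise: mean magnitude sigma * sqrt(pi/2)
  bg <- trueMap(ph, "s0") == 0
  vals <- as.vector(signalArray(d1))[rep(bg, length(bValues(sc)))]
  expect_gt(length(vals), 5000)
  expect_equal(mean(vals), 10 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("phase-contrast cines integrate back to the configured flows", {
  ph <- tinyPhantom()
  pc <- synthesizePC(ph, nPhases = 16, noiseSigmaV = 0)
  flows <- vesselFlows(ph)
  for (v in names(pc)) {
    roi <- new("VesselROI", mask = pc[[v]]$lumen,
      seedPoint = as.numeric(pc[[v]]$seedPoint), vesselLabel = v)
    expect_equal(vesselFlow(pc[[v]]$cine, roi), flows[[v]],
      tolerance = 1e-9)
  }
  # the cycle mean of the raised-cosine waveform is phase-count invariant
  pc32 <- synthesizePC(ph, nPhases = 32, noiseSigmaV = 0)
  roi <- new("VesselROI", mask = pc32$L_ICA$lumen,
    seedPoint = as.numeric(pc32$L_ICA$seedPoint), vesselLabel = "L_ICA")
  expect_equal(vesselFlow(pc32$L_ICA$cine, roi), flows[["L_ICA"]],
    tolerance = 1e-9)
})

test_that("a flat waveform defeats pulsatility-based segmentation", {
  ph <- makePhantom(c(16, 16, 8), seed = 11,
    config = list(pulsatility = 0))
  pc <- synthesizePC(ph, nPhases = 8, noiseSigmaV = 0)
  expect_error(
    segmentLumen(pc$L_ICA$cine, pc$L_ICA$seedPoint),
    "no pulsatility")
})

test_that("oversized lumen requests are rejected", {
  ph <- makePhantom(c(16, 16, 8), seed = 1,
    config = list(vesselRadiiMm = c(L_ICA = 50, R_ICA = 2.5,
      L_VA = 1.9, R_VA = 1.9)))
  expect_error(synthesizePC(ph), "larger than the cine field")
})
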