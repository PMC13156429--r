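test_that("connected-component labelling matches a brute-force flood fill", {
  set.seed(21)
  for (i in 1:8) {
    mask <- array(runif(8 * 8 * 8) < 0.35, dim = c(8, 8, 8))
    ours <- mcdip:::labelComponents(mask)
    oracle <- bfComponents(mask)
    # same partition: component ids must be in bijection
    expect_equal(max(ours), max(oracle))
    tab <- table(ours[mask], oracle[mask])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(max(mcdip:::labelComponents(m2)), 2L)
})

test_that("makeBrainMask keeps the largest bright component only", {
  vol <- array(0, dim = c(10, 10, 10))
  vol[2:6, 2:6, 2:6] <- 100          # 125 voxels
  vol[8:9, 8:9, 8:9] <- 100          # 8 voxels, disjoint
  mask <- makeBrainMask(vol, fraction = 0.2)
  lab <- bfComponents(vol > 0)
  sizes <- table(lab[lab > 0])
  expect_equal(sum(mask), max(sizes))
  expect_true(all(mask[2:6, 2:6, 2:6]))
  expect_false(any(mask[8:9, 8:9, 8:9]))
  expect_error(makeBrainMask(array(0, dim = c(5, 5, 5))), "empty")
})

test_that("makeBrainMask recovers the exact phantom brain support", {
  ph <- tinyPhantom()
  dwi <- synthesizeDWI(ph, bValueScheme("2nd-mc"), noiseSigma = 0)
  mask <- makeBrainMask(signalArray(dwi)[, , , 1])
  expect_identical(mask, brainMask(ph))
})

test_that("brainVolume sums voxel volumes", {
  mask <- array(FALSE, dim = c(20, 10, 10))
  mask[seq_len(1000)] <- TRUE
  expect_equal(brainVolume(mask, c(2, 2, 6)), 24)
  expect_equal(brainVolume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
})

test_that("diffusion step is exact on monoexponential signal", {
  b <- defaultBValues()
  y <- 850 * exp(-b * 0.8e-3)
  s1 <- fitDiffusionStep(y, b)
  expect_equal(s1$d, 0.8e-3, tolerance = 1e-11)
  expect_equal(s1$s0High, 850, tolerance = 1e-11)
  expect_false(s1$atBound)
})

test_that("diffusion step clamps degenerate slopes and flags bad voxels", {
  b <- defaultBValues()
  s1 <- fitDiffusionStep(rep(500, length(b)), b)
  expect_equal(s1$d, fitConfig()@dLower)
  expect_true(s1$atBound)
  y <- 500 * exp(-b * 1e-3); y[8] <- 0
  expect_false(fitDiffusionStep(y, b)$ok)
  expect_error(fitDiffusionStep(y, b, fitConfig(highBThreshold = 250)),
    "present in the b-value table")
})

test_that("perfusion contamination biases the plain diffusion step < 5%", {
  b <- defaultBValues()
  y <- biexpSignal(1000, 0.1, 10e-3, 0.8e-3, b)
  s1 <- fitDiffusionStep(y, b)
  expect_lt(relErr(s1$d, 0.8e-3), 0.05)
  expect_gt(s1$d, 0.8e-3)   # residual perfusion signal inflates D
})

test_that("perfusion step finds the grid-search global optimum", {
  b <- defaultBValues()
  set.seed(33)
  for (i in 1:25) {
    f <- runif(1, 0.02, 0.3)
    d <- runif(1, 4e-4, 1.5e-3)
    ds <- runif(1, 5e-3, 5e-2)
    s0 <- runif(1, 200, 2000)
    y <- biexpSignal(s0, f, ds, d, b)
    fit <- fitPerfusionStep(y, b, dFixed = d)
    expect_true(fit$converged)
    expect_lt(relErr(fit$f, f), 1e-6)
    expect_lt(relErr(fit$dStar, ds), 1e-6)
    expect_lt(relErr(fit$s0, s0), 1e-6)
    # never worse than the exhaustive grid optimum
    oracle <- gridSearchPerfusion(y, b, d)
    g <- fit$f * exp(-b * fit$dStar) + (1 - fit$f) * exp(-b * d)
    expect_lte(sum((y - fit$s0 * g)^2), oracle$sse + 1e-9)
  }
})

test_that("perfusion step handles a vanishing perfusion fraction", {
  b <- defaultBValues()
  y <- 1000 * exp(-b * 0.9e-3)
  fit <- fitPerfusionStep(y, b, dFixed = 0.9e-3)
  expect_true(fit$converged)
  expect_equal(fit$f, 0, tolerance = 1e-8)
  expect_equal(fit$f * fit$dStar, 0, tolerance = 1e-8)
})

test_that("nRMSE follows its definition and is scale invariant", {
  expect_equal(computeNRMSE(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(computeNRMSE(rep(10, 4), rep(9, 4)), 0.1)
  set.seed(7)
  o <- runif(11, 5, 20); f <- o + rnorm(11)
  expect_equal(computeNRMSE(3.7 * o, 3.7 * f), computeNRMSE(o, f),
    tolerance = 1e-12)
  expect_error(computeNRMSE(c(-1, 1), c(0, 0)), "positive")
  expect_error(computeNRMSE(1, 1), "length")
})

test_that("fitIVIM recovers noise-free truth and flags an empty mask", {
  ph <- tinyPhantom()
  dwi <- synthesizeDWI(ph, bValueScheme("2nd-mc"), noiseSigma = 0)
  fit <- suppressMessages(fitIVIM(dwi, brainMask(ph)))
  ok <- convergedMask(fit)
  expect_gte(mean(ok[brainMask(ph)]), 0.99)
  truthFd <- trueMap(ph, "f") * trueMap(ph, "dStar")
  expect_gte(mean(relErr(paramMap(fit, "fdStar")[ok], truthFd[ok]) < 0.01),
    0.99)
  expect_warning(
    empty <- suppressMessages(
      fitIVIM(dwi, array(FALSE, dim = dim(brainMask(ph))))),
    "empty")
  expect_true(all(is.na(paramMap(empty, "f"))))
})

test_that("motion masquerades as perfusion: FD* is inflated, nRMSE rises", {
  ph <- tinyPhantom()
  truthFd <- trueMap(ph, "f") * trueMap(ph, "dStar")
  # noise-free: uncompensated encoding inflates D* hence FD*
  dwiN <- synthesizeDWI(ph, bValueScheme("non-mc"), noiseSigma = 0)
  fitN <- suppressMessages(fitIVIM(dwiN, brainMask(ph)))
  okN <- convergedMask(fitN)
  expect_gte(mean(paramMap(fitN, "fdStar")[okN] >= truthFd[okN] - 1e-12),
    0.99)
  # with noise: white-matter fit error is worse without motion compensation
  wm <- tissueROIMask(tissueProbability(ph, "wm"))
  dwi2 <- synthesizeDWI(ph, bValueScheme("2nd-mc"), noiseSigma = 15,
    seed = 31)
  dwiNn <- synthesizeDWI(ph, bValueScheme("non-mc"), noiseSigma = 15,
    seed = 31)
  fit2 <- suppressMessages(fitIVIM(dwi2, brainMask(ph)))
  fitNn <- suppressMessages(fitIVIM(dwiNn, brainMask(ph)))
  sel2 <- wm & convergedMask(fit2)
  selN <- wm & convergedMask(fitNn)
  expect_gt(mean(paramMap(fitNn, "nrmse")[selN]),
    mean(paramMap(fit2, "nrmse")[sel2]))
})
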