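test_that("tissue ROI thresholding is inclusive and monotone", {
  p <- array(1, dim = c(3, 3, 3))
  expect_true(all(tissueROIMask(p)))
  q <- array(c(0.89, 0.90, 0.95), dim = c(3, 1, 1))
  expect_equal(sum(tissueROIMask(q, 0.9)), 2L)
  lo <- tissueROIMask(q, 0.5); hi <- tissueROIMask(q, 0.95)
  expect_true(all(!(hi & !lo)))
  expect_warning(tissueROIMask(q, 0.99), "empty")
  expect_error(tissueROIMask(array(1.5, dim = c(2, 1, 1))), "\\[0, 1\\]")
})

test_that("roiStats reports mean, n-1 sd and auditable voxel counts", {
  dims <- c(3, 1, 1)
  mk <- function(v) new("RCBFMap", values = array(v, dims),
    mask = array(TRUE, dims), method = "truth")
  roi <- array(TRUE, dims)
  r <- roiStats(mk(c(42, 42, 42)), roi, "GM")
  expect_equal(r$mean, 42); expect_equal(r$sd, 0)
  r2 <- roiStats(mk(c(1, 2, 3)), roi, "WM")
  expect_equal(r2$mean, 2); expect_equal(r2$sd, 1)
  expect_equal(r2$nVoxels, 3L)
  # invalid voxels are excluded and the count reflects it
  m <- mk(c(1, NA, 3))
  r3 <- roiStats(m, roi, "WM")
  expect_equal(r3$nVoxels, 2L); expect_equal(r3$mean, 2)
  expect_warning(r4 <- roiStats(mk(1), array(FALSE, dims), "GM"), "empty")
  expect_null(r4)
})

test_that("JSD hits its analytic extremes and the two-bin hand value", {
  x <- runif(500, 10, 60)
  expect_equal(jsd(x, x), 0)
  expect_equal(jsd(runif(400, 0, 50), runif(400, 80, 150)), 1,
    tolerance = 1e-12)
  # P = (1, 0), Q = (1/2, 1/2) on two bins
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 1.5), binEdges = c(0, 1, 2)),
    0.3112781245, tolerance = 1e-9)
  expect_equal(jsd(c(0.5, 0.5), c(0.5, 1.5), binEdges = c(0, 1, 2)),
    jsd(c(0.5, 1.5), c(0.5, 0.5), binEdges = c(0, 1, 2)))  # symmetry
  expect_error(jsd(1:3, 1:3, binEdges = c(1, 1, 2)), "increasing")
  expect_error(jsd(numeric(0), 1:3), "non-empty")
})

test_that("JSD is invariant to values beyond the edge range via clipping", {
  a <- c(200, 300, 500)   # all clip into the top bin
  b <- c(151, 160)
  expect_equal(jsd(a, b), 0)
})

test_that("Bland-Altman agreement matches hand computation", {
  x <- c(3, 7, 11)
  r <- blandAltman(x, x)
  expect_equal(r$bias, 0); expect_equal(r$loaHigh - r$loaLow, 0)
  r2 <- blandAltman(x, x - 5)
  expect_equal(r2$bias, 5); expect_equal(r2$loaHigh - r2$loaLow, 0)
  r3 <- blandAltman(c(2, 4), c(2, 2))   # differences {0, 2}
  expect_equal(r3$bias, 1)
  expect_equal(r3$loaHigh, 1 + 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(r3$loaLow, 1 - 1.96 * sqrt(2), tolerance = 1e-12)
  # swapping arguments flips the bias but keeps the width
  r4 <- blandAltman(c(2, 2), c(2, 4))
  expect_equal(r4$bias, -r3$bias)
  expect_equal(r4$loaHigh - r4$loaLow, r3$loaHigh - r3$loaLow)
  expect_error(blandAltman(1, 1), "at least 2")
})

test_that("Spearman correlation handles monotone and tied data", {
  x <- 1:6
  expect_equal(spearmanRho(x, x^3)$rho, 1)
  expect_equal(spearmanRho(x, -2 * x + 1)$rho, -1)
  r <- spearmanRho(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)
  expect_warning(rc <- spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(rc$rho))
})

test_that("scheme comparison reproduces the Friedman rank statistic", {
  m <- matrix(c(1, 2, 3, 4, 5), 5, 3)   # identical columns
  r <- compareSchemes(m)
  expect_equal(r$friedman$statistic, 0)
  set.seed(9)
  m2 <- matrix(rnorm(15), 5, 3)
  expect_equal(compareSchemes(m2)$friedman$statistic,
    compareSchemes(m2[, c(2, 3, 1)])$friedman$statistic)
  # hand-built table: within-subject ranks computed manually
  m3 <- matrix(c(
    1, 2, 3,
    1, 3, 2,
    2, 1, 3,
    1, 2, 3,
    1, 2, 3), 5, 3, byrow = TRUE)
  ranks <- t(apply(m3, 1, rank))
  Rj <- colSums(ranks)
  n <- 5; k <- 3
  oracle <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  r3 <- compareSchemes(m3)
  expect_equal(r3$friedman$statistic, oracle)
  expect_equal(nrow(r3$pairwise), 3L)
  expect_true(all(r3$pairwise$pAdjusted >= r3$pairwise$p))
  # listwise exclusion of incomplete subjects
  m4 <- rbind(m2, c(NA, 1, 2))
  expect_warning(r4 <- compareSchemes(m4), "listwise")
  expect_equal(r4$friedman$n, 5)
  expect_error(compareSchemes(m2[1:3, ]), "at least 5")
})
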