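test_that("biexpSignal reproduces hand-checked values", {
  # b = 0 collapses both exponentials to 1 regardless of the other params
  expect_equal(biexpSignal(100, 0.37, 0.02, 1e-3, 0), 100)
  expect_equal(biexpSignal(0, 0.5, 0.01, 1e-3, 123), 0)
  # f = 0 collapses to the monoexponential tissue compartment
  expect_equal(biexpSignal(100, 0, 0.01, 0.0008, 1000), 100 * exp(-0.8))
  # direct evaluation of the two-compartment sum
  expect_equal(biexpSignal(100, 0.1, 0.01, 0.0008, 50), 92.5363561208,
    tolerance = 1e-10)
})

test_that("biexpSignal rejects invalid parameters by name", {
  expect_error(biexpSignal(100, 0.1, 0.01, 8e-4, -1), "'b'")
  expect_error(biexpSignal(100, 1.2, 0.01, 8e-4, 10), "'f'")
  expect_error(biexpSignal(100, -0.1, 0.01, 8e-4, 10), "'f'")
  expect_error(biexpSignal(-5, 0.1, 0.01, 8e-4, 10), "'s0'")
  expect_error(biexpSignal(100, 0.1, 0.01, 0, 10), "'d'")
  expect_error(biexpSignal(100, 0.1, 1e-4, 8e-4, 10), "'dStar'")
})

test_that("biexpSignal is monotone in b and bounded by its envelopes", {
  set.seed(101)
  b <- sort(c(0, runif(30, 0, 1500)))
  for (i in 1:200) {
    s0 <- runif(1, 1, 2000)
    f <- runif(1)
    d <- runif(1, 1e-4, 3e-3)
    dStar <- runif(1, d, 0.3)
    s <- biexpSignal(s0, f, dStar, d, b)
    expect_true(all(diff(s) <= 1e-9 * s0))
    expect_true(all(s >= s0 * (1 - f) * exp(-b * dStar) - 1e-9 * s0))
    expect_true(all(s <= s0 * exp(-b * d) + 1e-9 * s0))
  }
})

test_that("computeTrace is the geometric mean of the directions", {
  sc <- bValueScheme("2nd-mc", bValues = c(0, 100, 500))
  a <- array(runif(2 * 2 * 2 * 3, 1, 10), dim = c(2, 2, 2, 3))
  # idempotent on identical inputs
  tr <- computeTrace(a, a, a, sc)
  expect_equal(signalArray(tr), a)
  # hand value: (1 * 8 * 64)^(1/3) = 8
  one <- array(1, dim = c(1, 1, 1, 3))
  tr2 <- computeTrace(one * 1, one * 8, one * 64, sc)
  expect_equal(as.vector(signalArray(tr2)), rep(8, 3))
  # commutes with permutation of its inputs
  x <- array(runif(24, 0.5, 4), dim = c(2, 2, 2, 3))
  y <- array(runif(24, 0.5, 4), dim = c(2, 2, 2, 3))
  z <- array(runif(24, 0.5, 4), dim = c(2, 2, 2, 3))
  expect_equal(signalArray(computeTrace(x, y, z, sc)),
    signalArray(computeTrace(z, x, y, sc)))
})

test_that("computeTrace propagates zeros with a warning and checks shapes", {
  sc <- bValueScheme("2nd-mc", bValues = c(0, 100, 500))
  a <- array(2, dim = c(2, 2, 1, 3))
  bb <- a; bb[1, 1, 1, 1] <- 0
  expect_warning(tr <- computeTrace(a, bb, a, sc), "zero")
  expect_equal(signalArray(tr)[1, 1, 1, 1], 0)
  small <- array(1, dim = c(2, 2, 2, 3))
  expect_error(computeTrace(a, a, small, sc), "identical dimensions")
})

test_that("BValueScheme enforces scheme-specific moment weights", {
  expect_equal(momentWeights(bValueScheme("2nd-mc")), c(0, 0))
  expect_equal(momentWeights(bValueScheme("1st-mc")), c(0, 1))
  expect_equal(momentWeights(bValueScheme("non-mc")), c(1, 1))
  expect_error(bValueScheme("2nd-mc", momentWeights = c(0, 1)), "2nd-mc")
  expect_error(bValueScheme("1st-mc", momentWeights = c(1, 1)), "w1")
  expect_error(bValueScheme("non-mc", bValues = c(10, 20)), "first b-value")
  expect_error(bValueScheme("non-mc", bValues = c(0, 20, 20)), "increasing")
})
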