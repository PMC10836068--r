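test_that("biexpDecay evaluates the two-component model exactly", {
  # a1 + a2 = 1 makes I(0) = 1 for any parameters
  expect_identical(biexpDecay(0, decayParams(0.37, 0.2, 3)), 1)
  # single-exponential limit
  expect_equal(biexpDecay(0.4, decayParams(1, 0.4, 2.0)), exp(-1))
  # direct substitution
  expect_equal(biexpDecay(2.0, decayParams(0.5, 0.4, 2.0)),
               0.5 * exp(-5) + 0.5 * exp(-1))
  expect_error(biexpDecay(-0.1, decayParams(0.5, 0.4, 2.0)), "nonnegative")
})

test_that("biexpDecay is positive and strictly decreasing", {
  t <- seq(0, 12, length.out = 200)
  for (p in list(decayParams(0.2, 0.3, 2.5), decayParams(0.9, 0.15, 4.8))) {
    v <- biexpDecay(t, p)
    expect_true(all(v > 0))
    expect_true(all(diff(v) < 0))
  }
})

test_that("decay parameter invariants are enforced", {
  expect_error(decayParams(1.2, 0.3, 2.5), "a1")
  expect_error(decayParams(0.5, -0.1, 2.5), "tau1")
  expect_error(decayParams(0.5, 2.5, 0.3), "tau2 > tau1")
})

test_that("meanLifetime reproduces a1*tau1 + a2*tau2 and its bounds", {
  expect_identical(meanLifetime(decayParams(1.0, 0.4, 2.5)), 0.4)
  expect_identical(meanLifetime(decayParams(0.5, 0.4, 2.0)), 1.2)
  expect_equal(meanLifetime(decayParams(0.7, 0.4, 2.5)), 1.03)
  # grid property: bounded by [tau1, tau2], strictly decreasing in a1
  for (tau1 in c(0.1, 0.3, 0.5)) for (tau2 in c(1, 2.5, 5)) {
    a1 <- seq(0, 1, by = 0.05)
    tm <- meanLifetime(a1, tau1 = tau1, tau2 = tau2)
    expect_true(all(tm >= tau1 - 1e-12 & tm <= tau2 + 1e-12))
    expect_true(all(diff(tm) < 0))
  }
})

test_that("folded bin probabilities normalize and match brute-force folding", {
  acq <- acquisitionConfig()
  edges <- binEdges(acq)
  period <- repetitionPeriod(acq)
  e1 <- edges[-length(edges)]
  e2 <- edges[-1]
  bruteForce <- function(a1, t1, t2, nPeriods = 50) {
    u <- 0
    for (k in seq_len(nPeriods) - 1) {
      u <- u + a1 * t1 * (exp(-(e1 + k * period) / t1) -
                            exp(-(e2 + k * period) / t1)) +
        (1 - a1) * t2 * (exp(-(e1 + k * period) / t2) -
                           exp(-(e2 + k * period) / t2))
    }
    u / sum(u)
  }
  set.seed(42)
  for (i in 1:10) {
    a1 <- runif(1, 0.05, 0.95)
    t1 <- runif(1, 0.1, 0.5)
    t2 <- runif(1, 1, 5)
    p <- foldedBinProbabilities(decayParams(a1, t1, t2), acq)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_lt(max(abs(p - bruteForce(a1, t1, t2))), 1e-9)
  }
})

test_that("folding vanishes in the long-period limit", {
  # period = 100 * tau2: folded and unfolded models coincide to 1e-9
  tau2 <- 2.5
  acq <- acquisitionConfig(repetitionRate = 1e9 / (100 * tau2),
                           nTimeBins = 256L, binWidth = 12.5 / 256)
  p <- decayParams(0.6, 0.3, tau2)
  folded <- foldedBinProbabilities(p, acq, fold = TRUE)
  unfolded <- foldedBinProbabilities(p, acq, fold = FALSE)
  expect_lt(max(abs(folded - unfolded)), 1e-9)
})

test_that("folding raises the first-bin probability of a slow decay", {
  # tau2 = 5 ns against the 12.5 ns period: wrapped photons from earlier
  # pulses add mass to every bin relative to the single-pulse decay
  acq <- acquisitionConfig()
  a1 <- 0.5; t1 <- 0.3; t2 <- 5.0
  folded <- foldedBinProbabilities(decayParams(a1, t1, t2), acq)
  edges <- binEdges(acq)
  e1 <- edges[-length(edges)]; e2 <- edges[-1]
  uInf <- a1 * t1 * (exp(-e1 / t1) - exp(-e2 / t1)) +
    (1 - a1) * t2 * (exp(-e1 / t2) - exp(-e2 / t2))
  pInf <- uInf / (a1 * t1 + (1 - a1) * t2)  # single-pulse, infinite support
  expect_gt(folded[1], pInf[1])
})

test_that("IRF convolution is a sum-preserving circular smoothing", {
  acq <- acquisitionConfig()
  p <- foldedBinProbabilities(decayParams(0.8, 0.2, 2.5), acq)
  # delta kernel is the identity
  expect_identical(convolveIRF(p, 0, acq), p)
  for (sigma in c(0.05, 0.1, 0.3)) {
    q <- convolveIRF(p, sigma, acq)
    expect_lt(abs(sum(q) - 1), 1e-12)
    expect_lt(max(q), max(p))  # smoothing strictly lowers the peak
  }
  # cross-check against a direct O(n^2) circular convolution
  n <- acq@nTimeBins
  edges <- binEdges(acq)
  window <- n * acq@binWidth
  kern <- diff(pnorm(edges, 0, 0.1)) + diff(pnorm(edges - window, 0, 0.1)) +
    diff(pnorm(edges + window, 0, 0.1))
  kern <- kern / sum(kern)
  direct <- vapply(seq_len(n), function(j) {
    sum(p * kern[((j - seq_len(n)) %% n) + 1L])
  }, numeric(1))
  expect_equal(convolveIRF(p, 0.1, acq), direct, tolerance = 1e-12)
})

test_that("acquisition window larger than the repetition period is rejected", {
  expect_error(acquisitionConfig(repetitionRate = 80e6, nTimeBins = 256L,
                                 binWidth = 0.1),
               "exceeds the repetition period")
})
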