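test_that("sliding 2x2 binning sums the available neighbourhood", {
  acq <- smallAcq(c(4L, 4L), photons = 16)
  cnt <- array(1L, c(4, 4, acq@nTimeBins))
  cube <- decayCube(cnt, acq)
  out <- counts(spatialBin(cube, 2L))
  expect_true(all(out[1:3, 1:3, ] == 4L))   # full window in the interior
  expect_true(all(out[4, 1:3, ] == 2L))     # edge rows use the sub-window
  expect_true(all(out[4, 4, ] == 1L))       # corner keeps its own counts
  # binning never loses a pixel's own photons
  expect_true(all(apply(out, c(1, 2), sum) >=
                    apply(cnt, c(1, 2), sum)))
})

test_that("2x2 frame bins to an anchor total of 10", {
  acq <- acquisitionConfig(frameShape = c(2L, 2L), nTimeBins = 4L,
                           binWidth = 0.5, meanPhotonsPerPixel = 10)
  cnt <- array(0L, c(2, 2, 4))
  cnt[1, 1, 1] <- 1L; cnt[2, 1, 1] <- 2L
  cnt[1, 2, 1] <- 3L; cnt[2, 2, 1] <- 4L
  out <- counts(spatialBin(decayCube(cnt, acq), 2L))
  expect_identical(sum(out[1, 1, ]), 10L)
})

test_that("block-mode binning conserves the grand total of counts", {
  truth <- buildScene(uniformScene(shape = c(8L, 8L), a1Sd = 0.05, seed = 1L))
  cube <- simulateDecayCube(truth, smallAcq(c(8L, 8L)), seed = 2L)
  binned <- spatialBin(cube, 2L, mode = "block")
  expect_identical(dim(counts(binned))[1:2], c(4L, 4L))
  expect_identical(sum(counts(binned)), sum(counts(cube)))
})

test_that("intensity mask thresholds behave at the bounds and monotonically", {
  img <- matrix(c(0, 5, 10, 200, 500, 1000), 2, 3)
  expect_true(all(maskMatrix(intensityMask(img, "fixed", value = 0))))
  expect_warning(m <- intensityMask(img, "fixed", value = 1001),
                 class = "flimetab_empty_selection")
  expect_false(any(maskMatrix(m)))
  # raising the threshold never adds pixels
  prev <- rep(TRUE, length(img))
  for (thr in c(0, 5, 10, 200, 500, 1000)) {
    cur <- as.vector(maskMatrix(intensityMask(img, "fixed", value = thr)))
    expect_true(all(!cur | prev))
    prev <- cur
  }
  expect_error(intensityMask(img - 1), "nonnegative")
})

test_that("noiseless histograms are recovered to high relative accuracy", {
  acq <- pixelAcq()
  truth <- decayParams(0.6, 0.35, 2.2)
  h <- noiselessHistogram(truth, acq, photons = 5000)
  fit <- fitPixel(h, acq, fitOptions())
  expect_true(fit$converged)
  expect_lt(relErr(fit$a1, 0.6), 1e-3)
  expect_lt(relErr(fit$tau1, 0.35), 1e-3)
  expect_lt(relErr(fit$tau2, 2.2), 1e-3)
  expect_equal(fit$amplitude, sum(h))
})

test_that("a million-photon Poisson histogram fits within 1% of truth", {
  acq <- pixelAcq()
  truth <- decayParams(0.6, 0.35, 2.2)
  p <- foldedBinProbabilities(truth, acq)
  set.seed(99)
  h <- rpois(length(p), 1e6 * p)
  fit <- fitPixel(h, acq, fitOptions())
  expect_lt(relErr(fit$a1, 0.6), 0.01)
  expect_lt(relErr(fit$tau1, 0.35), 0.01)
  expect_lt(relErr(fit$tau2, 2.2), 0.01)
})

test_that("degenerate histograms are flagged unfit without an exception", {
  acq <- pixelAcq()
  fit <- fitPixel(rep(0, acq@nTimeBins), acq, fitOptions())
  expect_false(fit$fitOk)
  expect_true(is.nan(fit$a1))
  expect_error(fitPixel(rep(1, 10), acq, fitOptions()), "nTimeBins")
  expect_error(fitPixel(rep(-1, acq@nTimeBins), acq, fitOptions()),
               "nonnegative")
})

test_that("fitting an IRF-blurred forward model recovers the parameters", {
  acq <- pixelAcq(irfSigma = 0.1)
  truth <- decayParams(0.7, 0.3, 2.5)
  h <- noiselessHistogram(truth, acq, photons = 10000)
  fit <- fitPixel(h, acq, fitOptions())
  expect_lt(relErr(fit$a1, 0.7), 1e-3)
  expect_lt(relErr(fit$tau1, 0.3), 1e-3)
  expect_lt(relErr(fit$tau2, 2.5), 1e-3)
})

test_that("identical pixels give constant maps equal to the single-pixel fit", {
  acq <- smallAcq(c(4L, 4L), photons = 5000)
  p <- foldedBinProbabilities(decayParams(0.6, 0.3, 2.5), acq)
  h <- round(5000 * p)
  cnt <- array(rep(h, each = 16), c(4, 4, acq@nTimeBins))
  cube <- decayCube(cnt, acq)
  maps <- fitCube(cube, NULL, fitOptions(), binWindow = 2L)
  expect_true(all(fitOkMap(maps)))
  expect_equal(max(a1Map(maps)) - min(a1Map(maps)), 0)
  # binning identical pixels only rescales the histogram: same optimum as
  # the unbinned single-pixel fit
  single <- fitPixel(h, acq, fitOptions())
  expect_equal(unname(a1Map(maps)[1, 1]), single$a1, tolerance = 1e-6)
  expect_equal(unname(tau2Map(maps)[1, 1]), single$tau2, tolerance = 1e-5)
})

test_that("masked-out pixels carry missing values in every map", {
  acq <- smallAcq(c(4L, 4L))
  truth <- buildScene(uniformScene(shape = c(4L, 4L), seed = 1L))
  cube <- simulateDecayCube(truth, acq, seed = 3L)
  inc <- matrix(TRUE, 4, 4); inc[2, 3] <- FALSE
  mask <- new("ROIMask", include = inc, provenance = "manual")
  maps <- fitCube(cube, mask, fitOptions())
  expect_false(fitOkMap(maps)[2, 3])
  expect_true(is.nan(a1Map(maps)[2, 3]))
  expect_true(is.nan(tauMMap(maps)[2, 3]))
  expect_true(all(fitOkMap(maps)[inc]))
  # an all-FALSE mask is an explicit empty-selection condition
  none <- new("ROIMask", include = matrix(FALSE, 4, 4), provenance = "none")
  expect_error(fitCube(cube, none, fitOptions()),
               class = "flimetab_empty_selection")
})

test_that("fitted maps satisfy the parameter-map invariants", {
  spec <- bimodalScene(shape = c(10L, 10L), seed = 31L)
  cube <- simulateDecayCube(buildScene(spec), smallAcq(c(10L, 10L)),
                            seed = 32L)
  maps <- fitCube(cube, NULL, fitOptions())
  expect_true(validObject(maps))
  ok <- fitOkMap(maps)
  expect_true(any(ok))
  expect_lt(max(abs(a1Map(maps)[ok] + a2Map(maps)[ok] - 1)), 1e-9)
  tm <- a1Map(maps)[ok] * tau1Map(maps)[ok] +
    a2Map(maps)[ok] * tau2Map(maps)[ok]
  expect_lt(max(abs(tauMMap(maps)[ok] - tm)), 1e-9)
  expect_true(all(tau2Map(maps)[ok] > tau1Map(maps)[ok]))
})

test_that("Poisson-MLE and weighted-least-squares agree at high photon counts", {
  acq <- pixelAcq()
  truths <- randomTruths(6, seed = 55)
  set.seed(56)
  for (i in seq_len(nrow(truths))) {
    p <- foldedBinProbabilities(
      decayParams(truths$a1[i], truths$tau1[i], truths$tau2[i]), acq)
    h <- rpois(length(p), 1e5 * p)
    f1 <- fitPixel(h, acq, fitOptions("poisson_mle"))
    f2 <- fitPixel(h, acq, fitOptions("weighted_least_squares"))
    expect_lt(relErr(f2$a1, f1$a1), 0.02)
    expect_lt(relErr(f2$tau1, f1$tau1), 0.02)
    expect_lt(relErr(f2$tau2, f1$tau2), 0.02)
  }
})

test_that("a1 estimation error shrinks as the photon budget grows", {
  budgets <- c(500, 5000, 50000)
  medErr <- vapply(seq_along(budgets), function(i) {
    spec <- uniformScene(shape = c(32L, 32L), a1 = 0.65, a1Sd = 0.02,
                         intensityScale = budgets[i], seed = 60L)
    truth <- buildScene(spec)
    acq <- acquisitionConfig(frameShape = c(32L, 32L),
                             meanPhotonsPerPixel = budgets[i])
    cube <- simulateDecayCube(truth, acq, seed = 61L + i)
    maps <- fitCube(cube, NULL, fitOptions(minPhotons = 50), binWindow = 1L)
    ok <- fitOkMap(maps)
    median(abs(a1Map(maps)[ok] - a1Map(truth)[ok]))
  }, numeric(1))
  expect_true(all(diff(medErr) < 0))
})
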