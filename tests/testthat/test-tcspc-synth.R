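test_that("zero-variance scenes realize their region means exactly", {
  truth <- buildScene(uniformScene(shape = c(6L, 6L), a1 = 0.7, a1Sd = 0))
  expect_true(all(a1Map(truth) == 0.7))
  expect_equal(a2Map(truth), matrix(0.3, 6, 6))
  expect_equal(tauMMap(truth), matrix(0.7 * 0.3 + 0.3 * 2.5, 6, 6))
})

test_that("bimodal scenes draw region a1 around the requested means", {
  spec <- bimodalScene(shape = c(64L, 64L), a1Means = c(0.55, 0.75),
                       a1Sd = 0.02, seed = 11L)
  truth <- buildScene(spec)
  rs <- regionSummary(spec, a1Map(truth))
  expect_equal(rs$mean, c(0.55, 0.75), tolerance = 0.01)
  # the pooled distribution has two well-separated sample modes
  d <- density(a1Map(truth))
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  modes <- d$x[peaks[order(d$y[peaks], decreasing = TRUE)][1:2]]
  expect_equal(sort(modes), c(0.55, 0.75), tolerance = 0.03)
  # deterministic given the scene seed
  expect_identical(a1Map(buildScene(spec)), a1Map(truth))
})

test_that("scene invariant violations raise domain and partition errors", {
  bad <- bimodalScene(shape = c(8L, 8L))
  bad@regions$a1Mean[1] <- 1.2
  expect_error(buildScene(bad), "a1Mean")
  # unassigned pixels break the partition
  rm <- matrix(1L, 4, 4); rm[2, 2] <- NA
  expect_error(
    sceneSpec(rm, data.frame(label = "r", a1Mean = 0.6, a1Sd = 0,
                             tau1 = 0.3, tau2 = 2.5, intensityScale = 100)),
    "partition")
  # a region index with no table row is not a partition either
  rm2 <- matrix(c(1L, 2L), 4, 4)
  expect_error(
    sceneSpec(rm2, data.frame(label = "r", a1Mean = 0.6, a1Sd = 0,
                              tau1 = 0.3, tau2 = 2.5, intensityScale = 100)),
    "not present")
})

test_that("expected counts conserve the pixel intensity exactly", {
  truth <- buildScene(uniformScene(shape = c(4L, 4L), a1 = 0.6, a1Sd = 0.05,
                                   seed = 3L))
  E <- expectedDecayCube(truth, smallAcq(c(4L, 4L)))
  totals <- apply(E, c(1, 2), sum)
  expect_equal(totals, intensityMap(truth), tolerance = 1e-12)
})

test_that("single-exponential refit of the noiseless forward model recovers tau", {
  # pure short component: an independent single-exponential ML refit of the
  # expected histogram returns tau1 (folding negligible at 0.3 ns)
  acq <- smallAcq(c(2L, 2L))
  truth <- uniformTruth(c(2L, 2L), a1 = 1, tau1 = 0.3, tau2 = 2.5)
  h <- expectedDecayCube(truth, acq)[1, 1, ]
  edges <- binEdges(acq)
  e1 <- edges[-length(edges)]; e2 <- edges[-1]
  nll <- function(tau) {
    p <- (exp(-e1 / tau) - exp(-e2 / tau))
    -sum(h * log(p / sum(p)))
  }
  tauHat <- optimize(nll, c(0.05, 1), tol = 1e-12)$minimum
  expect_lt(abs(tauHat - 0.3), 1e-6)
})

test_that("simulated totals follow the Poisson photon budget", {
  truth <- buildScene(uniformScene(shape = c(64L, 64L), a1 = 0.7,
                                   a1Sd = 0.02, intensityScale = 5000,
                                   seed = 2L))
  cube <- simulateDecayCube(truth, acquisitionConfig(), seed = 21L)
  grand <- mean(apply(counts(cube), c(1, 2), sum))
  # mean of 4096 iid Poisson(5000) totals: 3-sigma band
  expect_lt(abs(grand - 5000), 3 * sqrt(5000 / 4096))
})

test_that("the simulator is bit-identical under a fixed seed", {
  truth <- buildScene(uniformScene(shape = c(6L, 6L), seed = 4L))
  acq <- smallAcq(c(6L, 6L))
  expect_identical(counts(simulateDecayCube(truth, acq, seed = 9L)),
                   counts(simulateDecayCube(truth, acq, seed = 9L)))
  expect_identical(simulateIntensityImages(truth, acq, seed = 9L),
                   simulateIntensityImages(truth, acq, seed = 9L))
})

test_that("intensity channels reflect region scales and zero background", {
  spec <- tumorScene(shape = c(64L, 64L), tumorScale = 1000,
                     backgroundScale = 0, seed = 5L)
  truth <- buildScene(spec)
  ch <- simulateIntensityImages(truth, smallAcq(c(64L, 64L)), seed = 6L)
  bg <- sceneRegionMap(spec) == 1L
  expect_true(all(ch$egfp[bg] == 0L))
  expect_true(all(ch$mcherry[bg] == 0L))
  expect_gt(mean(ch$egfp[!bg]), 900)
})

test_that("Otsu thresholding separates tumor from dim background", {
  spec <- tumorScene(shape = c(64L, 64L), tumorScale = 1000,
                     backgroundScale = 10, seed = 7L)
  truth <- buildScene(spec)
  ch <- simulateIntensityImages(truth, smallAcq(c(64L, 64L)), seed = 8L)
  mask <- intensityMask(ch$egfp + ch$mcherry, "otsu")
  truthMask <- sceneRegionMap(spec) == 2L
  accuracy <- mean(maskMatrix(mask) == truthMask)
  expect_gte(accuracy, 0.99)
})
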