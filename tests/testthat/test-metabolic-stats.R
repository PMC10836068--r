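constantMaps <- function(shape, a1 = 0.7) {
  parameterMaps(matrix(a1, shape[1], shape[2]),
                matrix(0.3, shape[1], shape[2]),
                matrix(2.5, shape[1], shape[2]))
}

test_that("maskedValues extracts fitted pixels and honours the mask", {
  maps <- constantMaps(c(4, 4))
  v <- maskedValues(maps, NULL, "a1")
  expect_equal(nrow(v), 16)
  expect_true(all(v$value == 0.7))
  # unfit pixels are excluded from the sample
  maps@fitOk[1, 1] <- FALSE
  maps@a1[1, 1] <- NaN
  expect_equal(nrow(maskedValues(maps, NULL, "a1")), 15)
  # empty selection is an explicit condition
  none <- new("ROIMask", include = matrix(FALSE, 4, 4), provenance = "none")
  expect_error(maskedValues(maps, none, "a1"),
               class = "flimetab_empty_selection")
})

test_that("single-Gaussian fits recover a normal sample", {
  set.seed(101)
  x <- rnorm(5000, 0.60, 0.03)
  m <- fitMixture(x, k = 1)
  expect_equal(nComponents(m), 1L)
  expect_lt(abs(mixMeans(m) - 0.60), 0.01)
  expect_lt(abs(mixSds(m) - 0.03), 0.005)
  # closed form: exactly the ML estimates
  expect_equal(mixMeans(m), mean(x))
  expect_equal(mixSds(m), sqrt(mean((x - mean(x))^2)))
})

test_that("EM recovers a balanced two-component mixture across seeds", {
  for (s in 1:5) {
    set.seed(s)
    x <- c(rnorm(2500, 0.55, 0.02), rnorm(2500, 0.75, 0.02))
    m <- fitMixture(x, k = 2, seed = s)
    expect_true(m@converged)
    expect_lt(max(abs(mixMeans(m) - c(0.55, 0.75))), 0.01)
    expect_lt(max(abs(mixWeights(m) - 0.5)), 0.05)
    expect_lt(abs(sum(mixWeights(m)) - 1), 1e-9)
    expect_true(diff(mixMeans(m)) > 0)
  }
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(7)
  x <- c(rnorm(1500, 0.55, 0.02), rnorm(1500, 0.75, 0.02))
  m <- fitMixture(x, k = 2, seed = 1)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(mixMeans(m), sort(unname(mc$parameters$mean)),
               tolerance = 1e-3)
  expect_equal(m@logLik, mc$loglik, tolerance = 1e-4)
})

test_that("degenerate samples are rejected", {
  expect_error(fitMixture(rep(0.5, 100), k = 1), "zero-variance")
  expect_error(fitMixture(rnorm(15), k = 2), "at least 20")
  expect_error(selectModality(rnorm(49)), "at least 50")
})

test_that("BIC selection separates unimodal from bimodal samples", {
  set.seed(202)
  uni <- rnorm(2000, 0.60, 0.03)
  sel <- selectModality(uni, seed = 1)
  expect_identical(sel$k, 1L)
  # separation of 10 pooled sd: decisively bimodal
  bi <- c(rnorm(1000, 0.55, 0.02), rnorm(1000, 0.75, 0.02))
  sel2 <- selectModality(bi, seed = 1)
  expect_identical(sel2$k, 2L)
  expect_gt(sel2$deltaBic, 2)
})

test_that("the unpaired t-test works on per-unit means", {
  # identical groups: no effect, p = 1
  same <- compareGroups(c(0.6, 0.6, 0.6), c(0.6, 0.6, 0.6))
  expect_identical(same@statistic, 0)
  expect_identical(same@pValue, 1)
  # planted separation: significant with positive direction
  set.seed(303)
  brain <- rnorm(8, 0.75, 0.04)
  skel <- rnorm(8, 0.60, 0.04)
  cmp <- compareGroups(brain, skel)
  expect_lt(cmp@pValue, 0.05)
  expect_identical(cmp@effectDirection, 1)
  expect_identical(cmp@groupSizes, c(8L, 8L))
  expect_error(compareGroups(0.7, c(0.6, 0.65)), "at least 2")
})

test_that("two-way ANOVA on per-unit histograms detects a distribution shift", {
  set.seed(404)
  mkUnits <- function(mu) replicate(4, rnorm(800, mu, 0.03), simplify = FALSE)
  ht <- histogramTable(list(brain = mkUnits(0.72), skeletal = mkUnits(0.62)))
  # relative frequencies sum to 1 within each unit histogram
  sums <- tapply(ht$frequency, ht$unit, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  cmp <- compareGroups(ht, test = "two_way_anova")
  expect_lt(cmp@pValue, 0.001)
  expect_identical(cmp@effectDirection, 1)
  expect_true(is.data.frame(cmp@details$anovaTable) ||
                inherits(cmp@details$anovaTable, "anova"))
  # a single pooled histogram per group leaves nothing to test against
  pooled <- histogramTable(list(brain = rnorm(800, 0.7, 0.03),
                                skeletal = rnorm(800, 0.6, 0.03)))
  expect_error(compareGroups(pooled, test = "two_way_anova"), "replicated")
})

test_that("per-unit summaries aggregate masked fitted pixels", {
  maps <- constantMaps(c(4, 4))
  tab <- summarizeUnits(list(list(label = "u1", maps = maps, mask = NULL)))
  expect_equal(tab$meanA1, 0.7)
  expect_equal(tab$meanTauM, 0.7 * 0.3 + 0.3 * 2.5)
  expect_equal(tab$nPixels, 16L)
  # identical units give identical rows
  tab2 <- summarizeUnits(list(list(label = "a", maps = maps, mask = NULL),
                              list(label = "b", maps = maps, mask = NULL)))
  expect_equal(tab2$meanA1[1], tab2$meanA1[2])
  # a unit with no fitted pixels is flagged, not dropped silently
  bad <- maps
  bad@fitOk[] <- FALSE
  bad@a1[] <- NaN
  expect_warning(
    tab3 <- summarizeUnits(list(list(label = "ok", maps = maps, mask = NULL),
                                list(label = "void", maps = bad,
                                     mask = NULL))),
    "flagged")
  expect_true(tab3$flagged[tab3$unit == "void"])
  expect_true(is.na(tab3$meanA1[tab3$unit == "void"]))
})

test_that("full pipeline orders brain-like above skeletal-like groups", {
  # higher true a1 (more glycolytic) must come out as higher fitted a1 and
  # lower mean lifetime after simulation + masking + fitting
  acq <- acquisitionConfig(frameShape = c(16L, 16L),
                           meanPhotonsPerPixel = 2000)
  runUnit <- function(a1, seed) {
    truth <- buildScene(uniformScene(shape = c(16L, 16L), a1 = a1,
                                     a1Sd = 0.03, intensityScale = 2000,
                                     seed = seed))
    maps <- fitCube(simulateDecayCube(truth, acq, seed + 1L), NULL,
                    fitOptions())
    list(label = paste0("u", seed), maps = maps, mask = NULL,
         group = if (a1 > 0.7) "brain-like" else "skeletal-like")
  }
  units <- c(lapply(1:2, function(s) runUnit(0.75, 10L + s)),
             lapply(1:2, function(s) runUnit(0.60, 20L + s)))
  tab <- summarizeUnits(units)
  brain <- tab$group == "brain-like"
  expect_gt(mean(tab$meanA1[brain]), mean(tab$meanA1[!brain]))
  expect_lt(mean(tab$meanTauM[brain]), mean(tab$meanTauM[!brain]))
})
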