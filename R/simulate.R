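#' @include AllClasses.R constructors.R decay-model.R scene.R
NULL

## Per-pixel bin-probability matrix (pixels x bins) for a truth map.
## Lifetimes are constant within regions, so the bin-integrated (and
## optionally IRF-convolved) component masses are computed once per unique
## lifetime; each pixel's distribution is then the a1-weighted mixture.
## Both convolution and normalization commute with the mixture, so
## convolving the component masses first is exact.
.pixelBinProbs <- function(a1, tau1, tau2, acq, fold = TRUE) {
  edges <- binEdges(acq)
  period <- repetitionPeriod(acq)
  compMass <- function(taus) {
    m <- vapply(taus, .componentBinMass, numeric(acq@nTimeBins),
                edges = edges, period = period, fold = fold)
    if (acq@irfSigma > 0)
      m <- apply(m, 2, convolveIRF, irfSigma = acq@irfSigma, acq = acq)
    m
  }
  u1 <- unique(tau1); u2 <- unique(tau2)
  M1 <- compMass(u1); M2 <- compMass(u2)
  U <- a1 * t(M1[, match(tau1, u1), drop = FALSE]) +
    (1 - a1) * t(M2[, match(tau2, u2), drop = FALSE])
  U / rowSums(U)
}

#' Simulate a TCSPC decay cube from ground truth
#'
#' Forward model of the acquisition: for every pixel the expected photon
#' count in time bin j is `intensity * p_j`, where `p_j` are the
#' bin-integrated, repetition-period-folded (and, when the acquisition has
#' `irfSigma > 0`, IRF-convolved) probabilities of the pixel's two-component
#' decay, normalized so the expected total equals the pixel intensity
#' exactly. Observed counts are independent Poisson draws with those means.
#'
#' @param truth a [ParameterMaps-class] ground truth (e.g. from
#'   [buildScene()]).
#' @param acq an [AcquisitionConfig-class]; its time window must fit inside
#'   the repetition period.
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @param fold wrap incomplete decay from earlier pulses (default `TRUE`).
#' @return A [DecayCube-class].
#' @examples
#' truth <- buildScene(uniformScene(shape = c(8L, 8L)))
#' cube <- simulateDecayCube(truth, acquisitionConfig(frameShape = c(8L, 8L)),
#'                           seed = 1L)
#' @export
simulateDecayCube <- function(truth, acq, seed, fold = TRUE) {
  stopifnot(is(truth, "ParameterMaps"), is(acq, "AcquisitionConfig"))
  validObject(acq)
  shape <- dim(truth@a1)
  P <- .pixelBinProbs(as.vector(truth@a1), as.vector(truth@tau1),
                      as.vector(truth@tau2), acq, fold = fold)
  mu <- as.vector(truth@intensity) * P
  set.seed(seed)
  cnt <- stats::rpois(length(mu), as.vector(mu))
  counts <- array(as.integer(cnt), dim = c(shape, acq@nTimeBins))
  decayCube(counts, acq)
}

#' Noiseless expected decay cube
#'
#' The Poisson means of [simulateDecayCube()] without the noise draw -
#' useful as an exact forward-model oracle for the fitter.
#'
#' @inheritParams simulateDecayCube
#' @return 3D numeric array of expected counts (not integer-valued).
#' @export
expectedDecayCube <- function(truth, acq, fold = TRUE) {
  shape <- dim(truth@a1)
  P <- .pixelBinProbs(as.vector(truth@a1), as.vector(truth@tau1),
                      as.vector(truth@tau2), acq, fold = fold)
  array(as.vector(truth@intensity) * P, dim = c(shape, acq@nTimeBins))
}

#' Simulate EGFP/mCherry-like intensity channels
#'
#' Two Poisson-noised intensity images proportional to the per-region
#' intensity scale (tumor regions bright, background dim). These play the
#' role of the fluorescent-protein channels used to locate tumors: they are
#' consumed only by intensity thresholding ([intensityMask()]), never by the
#' decay fit.
#'
#' @param truth a [ParameterMaps-class] ground truth.
#' @param acq an [AcquisitionConfig-class] (unused beyond validation; kept
#'   so channel simulation shares the simulator interface).
#' @param seed integer seed.
#' @param channelGain per-channel multiplicative gain on the pixel
#'   intensity, default `c(egfp = 1, mcherry = 0.8)`.
#' @return Named list of two matrices, `egfp` and `mcherry`.
#' @export
simulateIntensityImages <- function(truth, acq, seed,
                                    channelGain = c(egfp = 1, mcherry = 0.8)) {
  stopifnot(is(truth, "ParameterMaps"))
  lam <- truth@intensity
  set.seed(seed)
  imgs <- lapply(channelGain, function(g) {
    m <- matrix(stats::rpois(length(lam), g * as.vector(lam)),
                nrow(lam), ncol(lam))
    storage.mode(m) <- "integer"
    m
  })
  names(imgs) <- names(channelGain)
  imgs
}
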