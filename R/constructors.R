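#' @include AllClasses.R AllGenerics.R
NULL

#' Create an acquisition configuration
#'
#' The defaults emulate a FALCON-style two-photon FLIM acquisition: 80 MHz
#' pulsed excitation with 256 TCSPC bins tiling the full 12.5 ns repetition
#' period, a 64 x 64 frame (desk-scale stand-in for the instrument's
#' 512 x 512 format), an ideal delta instrument response and 5,000 detected
#' photons per pixel.
#'
#' @param repetitionRate laser repetition rate in Hz (default `80e6`).
#' @param nTimeBins number of TCSPC time bins (default 256).
#' @param binWidth bin width in ns; default tiles the repetition period
#'   exactly (`1e9 / repetitionRate / nTimeBins`).
#' @param frameShape integer `c(rows, cols)` (default `c(64, 64)`).
#' @param irfSigma Gaussian IRF standard deviation in ns; 0 (default) is a
#'   delta IRF.
#' @param meanPhotonsPerPixel expected photons per pixel (default 5000).
#' @return An [AcquisitionConfig-class] object.
#' @examples
#' acq <- acquisitionConfig(frameShape = c(32, 32))
#' @export
acquisitionConfig <- function(repetitionRate = 80e6,
                              nTimeBins = 256L,
                              binWidth = 1e9 / repetitionRate / nTimeBins,
                              frameShape = c(64L, 64L),
                              irfSigma = 0,
                              meanPhotonsPerPixel = 5000) {
  new("AcquisitionConfig",
      repetitionRate = as.numeric(repetitionRate),
      nTimeBins = as.integer(nTimeBins),
      binWidth = as.numeric(binWidth),
      frameShape = as.integer(frameShape),
      irfSigma = as.numeric(irfSigma),
      meanPhotonsPerPixel = as.numeric(meanPhotonsPerPixel))
}

#' Repetition period of an acquisition in ns
#' @param acq an [AcquisitionConfig-class].
#' @return Period `1e9 / repetitionRate` in ns.
#' @export
repetitionPeriod <- function(acq) 1e9 / acq@repetitionRate

#' Time-bin edges of an acquisition
#' @param acq an [AcquisitionConfig-class].
#' @return Numeric vector of `nTimeBins + 1` bin edges in ns, starting at 0.
#' @export
binEdges <- function(acq) seq(0, by = acq@binWidth, length.out = acq@nTimeBins + 1L)

#' Create two-component decay parameters
#'
#' @param a1 free (short-lifetime) NADH amplitude fraction in `[0, 1]`;
#'   the bound fraction is `a2 = 1 - a1`.
#' @param tau1 free NADH lifetime (ns), typically 0.1-0.5 ns.
#' @param tau2 bound NADH lifetime (ns), typically 1-5 ns; must exceed
#'   `tau1`.
#' @return A [DecayParams-class] object.
#' @export
decayParams <- function(a1, tau1, tau2) {
  new("DecayParams", a1 = as.numeric(a1), tau1 = as.numeric(tau1),
      tau2 = as.numeric(tau2))
}

#' Create fit options for per-pixel decay fitting
#'
#' Defaults follow the physiology of NADH: initial lifetimes at the
#' midpoints of the free (0.1-0.5 ns) and bound (1-5 ns) windows, and box
#' bounds `tau1` in `[0.05, 1]` ns, `tau2` in `[0.5, 6]` ns that contain
#' those windows with margin.
#'
#' @param objective `"poisson_mle"` (default; TCSPC counts are Poisson) or
#'   `"weighted_least_squares"` (Pearson chi-square with model-based
#'   weights, asymptotically equivalent to the MLE).
#' @param initTau1,initTau2 starting lifetimes in ns.
#' @param a1Bounds,tau1Bounds,tau2Bounds length-2 box constraints.
#' @param maxIterations optimizer iteration cap (default 200).
#' @param convergenceTol relative objective convergence tolerance
#'   (default 1e-12).
#' @param minPhotons minimum photons per (binned) pixel to attempt a fit
#'   (default 100; below this the two-component model is practically
#'   unidentifiable and the pixel is flagged unfit).
#' @return A [FitOptions-class] object.
#' @export
fitOptions <- function(objective = c("poisson_mle", "weighted_least_squares"),
                       initTau1 = 0.3, initTau2 = 2.5,
                       a1Bounds = c(0, 1),
                       tau1Bounds = c(0.05, 1),
                       tau2Bounds = c(0.5, 6),
                       maxIterations = 200L,
                       convergenceTol = 1e-12,
                       minPhotons = 100) {
  new("FitOptions",
      objective = match.arg(objective),
      initTau1 = as.numeric(initTau1), initTau2 = as.numeric(initTau2),
      a1Bounds = as.numeric(a1Bounds),
      tau1Bounds = as.numeric(tau1Bounds),
      tau2Bounds = as.numeric(tau2Bounds),
      maxIterations = as.integer(maxIterations),
      convergenceTol = as.numeric(convergenceTol),
      minPhotons = as.numeric(minPhotons))
}

#' Assemble parameter maps from component images
#'
#' Low-level constructor; `a2` and `tauM` are derived from `a1`, `tau1`,
#' `tau2` so the fraction and mean-lifetime identities hold by construction.
#'
#' @param a1,tau1,tau2 numeric matrices of equal dimensions.
#' @param intensity photon-count matrix (defaults to zeros).
#' @param fitOk logical matrix; defaults to `TRUE` wherever `a1` is finite.
#' @param objectiveValue numeric matrix of per-pixel objective values
#'   (defaults to NaN, e.g. for ground-truth maps).
#' @return A [ParameterMaps-class] object.
#' @export
parameterMaps <- function(a1, tau1, tau2,
                          intensity = array(0, dim(a1)),
                          fitOk = NULL, objectiveValue = NULL) {
  a1 <- as.matrix(a1)
  if (is.null(fitOk)) fitOk <- is.finite(a1)
  if (is.null(objectiveValue)) objectiveValue <- array(NaN, dim(a1))
  a2 <- 1 - a1
  tauM <- a1 * tau1 + a2 * tau2
  new("ParameterMaps", a1 = a1, a2 = a2,
      tau1 = as.matrix(tau1), tau2 = as.matrix(tau2), tauM = tauM,
      intensity = as.matrix(intensity), fitOk = fitOk,
      objectiveValue = as.matrix(objectiveValue))
}

#' Assemble a decay cube
#'
#' @param counts 3D nonnegative integer array (rows, cols, time bins).
#' @param acq the [AcquisitionConfig-class] describing the time axis.
#' @return A [DecayCube-class].
#' @export
decayCube <- function(counts, acq) {
  new("DecayCube", counts = counts,
      timeAxis = binEdges(acq)[seq_len(acq@nTimeBins)],
      acquisition = acq)
}

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
#' @aliases a1Map,ParameterMaps-method
setMethod("a1Map", "ParameterMaps", function(x) x@a1)
#' @rdname accessors
setMethod("a2Map", "ParameterMaps", function(x) x@a2)
#' @rdname accessors
setMethod("tau1Map", "ParameterMaps", function(x) x@tau1)
#' @rdname accessors
setMethod("tau2Map", "ParameterMaps", function(x) x@tau2)
#' @rdname accessors
setMethod("tauMMap", "ParameterMaps", function(x) x@tauM)
#' @rdname accessors
setMethod("intensityMap", "ParameterMaps", function(x) x@intensity)
#' @rdname accessors
setMethod("fitOkMap", "ParameterMaps", function(x) x@fitOk)
#' @rdname accessors
setMethod("objectiveMap", "ParameterMaps", function(x) x@objectiveValue)
#' @rdname accessors
setMethod("counts", "DecayCube", function(x) x@counts)
#' @rdname accessors
setMethod("timeAxis", "DecayCube", function(x) x@timeAxis)
#' @rdname accessors
setMethod("acquisition", "DecayCube", function(x) x@acquisition)
#' @rdname accessors
setMethod("maskMatrix", "ROIMask", function(x) x@include)
#' @rdname accessors
setMethod("maskProvenance", "ROIMask", function(x) x@provenance)
#' @rdname accessors
setMethod("nComponents", "MixtureModel", function(x) x@k)
#' @rdname accessors
setMethod("mixWeights", "MixtureModel", function(x) x@weights)
#' @rdname accessors
setMethod("mixMeans", "MixtureModel", function(x) x@means)
#' @rdname accessors
setMethod("mixSds", "MixtureModel", function(x) x@sds)
#' @rdname accessors
setMethod("scoreBIC", "MixtureModel", function(x) x@bic)
#' @rdname accessors
setMethod("scoreAIC", "MixtureModel", function(x) x@aic)

## ---- show methods ---------------------------------------------------------

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(
    "AcquisitionConfig: %.1f MHz (period %.4g ns), %d bins x %.4g ns, frame %d x %d\n",
    object@repetitionRate / 1e6, repetitionPeriod(object),
    object@nTimeBins, object@binWidth,
    object@frameShape[1], object@frameShape[2]))
  cat(sprintf("  IRF sigma: %.4g ns | mean photons/pixel: %.5g\n",
              object@irfSigma, object@meanPhotonsPerPixel))
})

setMethod("show", "DecayParams", function(object) {
  cat(sprintf(
    "DecayParams: a1 = %.4f (free), a2 = %.4f (bound), tau1 = %.4g ns, tau2 = %.4g ns, tauM = %.4g ns\n",
    object@a1, 1 - object@a1, object@tau1, object@tau2,
    meanLifetime(object)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec '%s' (%s): %d x %d frame, %d regions, seed %d\n",
              object@groupLabel, object@modality,
              nrow(object@regionMap), ncol(object@regionMap),
              nrow(object@regions), object@seed))
  print(object@regions, row.names = FALSE)
})

setMethod("show", "ParameterMaps", function(object) {
  d <- dim(object@a1)
  nok <- sum(object@fitOk)
  cat(sprintf("ParameterMaps: %d x %d pixels, %d valid (%.1f%%)\n",
              d[1], d[2], nok, 100 * nok / prod(d)))
  if (nok > 0) {
    ok <- object@fitOk
    cat(sprintf("  a1:   mean %.4f  sd %.4f\n",
                mean(object@a1[ok]), stats::sd(object@a1[ok])))
    cat(sprintf("  tauM: mean %.4g ns\n", mean(object@tauM[ok])))
  }
})

setMethod("show", "DecayCube", function(object) {
  d <- dim(object@counts)
  cat(sprintf("DecayCube: %d x %d pixels x %d time bins, %.4g ns window\n",
              d[1], d[2], d[3],
              d[3] * object@acquisition@binWidth))
  cat(sprintf("  total photons: %.6g (mean %.5g / pixel)\n",
              sum(object@counts), mean(apply(object@counts, c(1, 2), sum))))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask: %d / %d pixels included | rule: %s\n",
              sum(object@include), length(object@include),
              object@provenance))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: k = %d | logLik %.3f | BIC %.3f | AIC %.3f\n",
              object@k, object@logLik, object@bic, object@aic))
  for (i in seq_len(object@k))
    cat(sprintf("  component %d: weight %.3f, mean %.4f, sd %.4f\n",
                i, object@weights[i], object@means[i], object@sds[i]))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s): statistic %.4g, p = %.4g, direction %+d\n",
              object@testName, object@statistic, object@pValue,
              as.integer(object@effectDirection)))
  cat(sprintf("  group sizes: %s\n", paste(object@groupSizes, collapse = ", ")))
})
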