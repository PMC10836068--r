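#' @import methods
NULL

## Central S4 containers for the TCSPC/FLIM pipeline.  All lifetimes are in
## nanoseconds, all fractions unitless, all counts photons.

#' Acquisition configuration for a TCSPC FLIM measurement
#'
#' Describes the pulsed-excitation timing, the TCSPC histogram geometry, the
#' frame size, an optional Gaussian instrument response and the photon budget
#' used by the simulator. The default emulates an 80 MHz multiphoton system:
#' 256 time bins spanning the full 12.5 ns repetition period.
#'
#' @slot repetitionRate laser repetition rate in Hz.
#' @slot nTimeBins number of TCSPC histogram bins.
#' @slot binWidth width of one time bin in ns.
#' @slot frameShape integer vector `c(rows, cols)` of the image frame.
#' @slot irfSigma standard deviation (ns) of the Gaussian instrument
#'   response; `0` means an ideal delta IRF.
#' @slot meanPhotonsPerPixel expected total photons collected per pixel.
#'
#' @seealso [acquisitionConfig()] for the user-facing constructor.
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(
    repetitionRate = "numeric",
    nTimeBins = "integer",
    binWidth = "numeric",
    frameShape = "integer",
    irfSigma = "numeric",
    meanPhotonsPerPixel = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  scal <- function(x) length(x) == 1L && is.finite(x)
  if (!scal(object@repetitionRate) || object@repetitionRate <= 0)
    msg <- c(msg, "repetitionRate must be a single positive number (Hz)")
  if (!scal(object@nTimeBins) || object@nTimeBins < 2L)
    msg <- c(msg, "nTimeBins must be a single integer >= 2")
  if (!scal(object@binWidth) || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a single positive number (ns)")
  if (length(object@frameShape) != 2L || any(object@frameShape < 1L))
    msg <- c(msg, "frameShape must be two positive integers (rows, cols)")
  if (!scal(object@irfSigma) || object@irfSigma < 0)
    msg <- c(msg, "irfSigma must be a single number >= 0 (ns)")
  if (!scal(object@meanPhotonsPerPixel) || object@meanPhotonsPerPixel <= 0)
    msg <- c(msg, "meanPhotonsPerPixel must be a single positive number")
  if (length(msg) == 0L) {
    # measurement window cannot exceed the excitation period
    window <- object@nTimeBins * object@binWidth
    period <- 1e9 / object@repetitionRate
    if (window > period * (1 + 1e-9))
      msg <- c(msg, sprintf(
        "time window (%.6g ns) exceeds the repetition period (%.6g ns)",
        window, period))
  }
  if (length(msg)) msg else TRUE
})

#' Two-component decay parameters
#'
#' Amplitude fractions and lifetimes of the bi-exponential NADH decay
#' `I(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2)` with `a1 + a2 = 1`. The short
#' component (`a1`, `tau1`) is free NADH, the long component bound NADH.
#'
#' @slot a1 fractional amplitude of the short (free NADH) component, in
#'   `[0, 1]`; `a2 = 1 - a1` is implied.
#' @slot tau1 short lifetime in ns.
#' @slot tau2 long lifetime in ns, strictly greater than `tau1`.
#'
#' @exportClass DecayParams
setClass("DecayParams",
  representation(a1 = "numeric", tau1 = "numeric", tau2 = "numeric")
)

setValidity("DecayParams", function(object) {
  msg <- character()
  if (length(object@a1) != 1L || !is.finite(object@a1) ||
      object@a1 < 0 || object@a1 > 1)
    msg <- c(msg, "a1 must be a single number in [0, 1]")
  if (length(object@tau1) != 1L || !is.finite(object@tau1) ||
      object@tau1 <= 0)
    msg <- c(msg, "tau1 must be a single positive number (ns)")
  if (length(object@tau2) != 1L || !is.finite(object@tau2) ||
      object@tau2 <= object@tau1)
    msg <- c(msg, "tau2 must be a single number (ns) with tau2 > tau1")
  if (length(msg)) msg else TRUE
})

#' Ground-truth scene specification
#'
#' A labelled partition of the image frame into regions, each with its own
#' free-fraction distribution (truncated Gaussian), fixed lifetimes and
#' intensity scale. The pixel-level ground truth built from a scene is the
#' input to the TCSPC simulator.
#'
#' @slot regionMap integer matrix (rows x cols); entry `r` assigns the pixel
#'   to row `r` of `regions`. Every pixel belongs to exactly one region, so
#'   the regions partition the frame (background is itself a region).
#' @slot regions data.frame with one row per region and columns `label`,
#'   `a1Mean`, `a1Sd`, `tau1`, `tau2`, `intensityScale`.
#' @slot modality `"unimodal"` or `"bimodal"` - the intended shape of the
#'   pooled a1 distribution.
#' @slot groupLabel free-text group tag (e.g. `"brain-like"`).
#' @slot seed integer seed making the scene draw reproducible.
#'
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    regionMap = "matrix",
    regions = "data.frame",
    modality = "character",
    groupLabel = "character",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  reg <- object@regions
  need <- c("label", "a1Mean", "a1Sd", "tau1", "tau2", "intensityScale")
  if (!all(need %in% names(reg)))
    msg <- c(msg, paste("regions must have columns:",
                        paste(need, collapse = ", ")))
  rm <- object@regionMap
  if (anyNA(rm))
    msg <- c(msg, "regionMap does not partition the frame: unassigned pixels")
  else if (length(msg) == 0L) {
    if (!all(rm %in% seq_len(nrow(reg))))
      msg <- c(msg, "regionMap refers to regions not present in the table")
    if (any(reg$a1Mean <= 0 | reg$a1Mean >= 1))
      msg <- c(msg, "every a1Mean must lie strictly inside (0, 1)")
    if (any(reg$a1Sd < 0))
      msg <- c(msg, "a1Sd must be >= 0")
    if (any(reg$tau1 <= 0 | reg$tau1 >= 1))
      msg <- c(msg, "tau1 must lie in (0, 1) ns")
    if (any(reg$tau2 <= 0.5 | reg$tau2 > 6))
      msg <- c(msg, "tau2 must lie in (0.5, 6] ns")
    if (any(reg$tau2 <= reg$tau1))
      msg <- c(msg, "tau1 < tau2 required in every region")
    if (any(reg$intensityScale < 0))
      msg <- c(msg, "intensityScale must be >= 0")
    if (anyDuplicated(reg$label))
      msg <- c(msg, "region labels must be unique")
  }
  if (!object@modality %in% c("unimodal", "bimodal"))
    msg <- c(msg, "modality must be 'unimodal' or 'bimodal'")
  if (length(msg)) msg else TRUE
})

#' Per-pixel decay-parameter maps
#'
#' Holds the pixel images of the two-component decay parameters - either
#' ground truth from a scene or estimates from the fitter - plus the derived
#' maps `a2 = 1 - a1` and the amplitude-weighted mean lifetime
#' `tauM = a1*tau1 + a2*tau2`, the pixel intensity, and fit diagnostics.
#' Pixels that were never fitted (masked out, too few photons, or failed
#' convergence) carry `NaN` in the float maps and `FALSE` in `fitOk`.
#'
#' @slot a1,a2 fraction images; `a1 + a2 = 1` wherever finite.
#' @slot tau1,tau2,tauM lifetime images in ns.
#' @slot intensity total photon-count image.
#' @slot fitOk logical image: pixel has valid parameters.
#' @slot objectiveValue final objective value per fitted pixel (NaN for
#'   ground-truth maps).
#'
#' @exportClass ParameterMaps
setClass("ParameterMaps",
  representation(
    a1 = "matrix", a2 = "matrix",
    tau1 = "matrix", tau2 = "matrix", tauM = "matrix",
    intensity = "matrix",
    fitOk = "matrix",
    objectiveValue = "matrix"
  )
)

setValidity("ParameterMaps", function(object) {
  msg <- character()
  d <- dim(object@a1)
  mats <- list(a2 = object@a2, tau1 = object@tau1, tau2 = object@tau2,
               tauM = object@tauM, intensity = object@intensity,
               fitOk = object@fitOk, objectiveValue = object@objectiveValue)
  for (nm in names(mats))
    if (!identical(dim(mats[[nm]]), d))
      msg <- c(msg, sprintf("map '%s' has mismatched dimensions", nm))
  if (!is.logical(object@fitOk))
    msg <- c(msg, "fitOk must be a logical matrix")
  if (length(msg) == 0L) {
    ok <- object@fitOk & is.finite(object@a1)
    if (any(ok)) {
      if (max(abs(object@a1[ok] + object@a2[ok] - 1)) > 1e-9)
        msg <- c(msg, "a1 + a2 must equal 1 (within 1e-9) at fitted pixels")
      tm <- object@a1[ok] * object@tau1[ok] + object@a2[ok] * object@tau2[ok]
      if (max(abs(object@tauM[ok] - tm)) > 1e-9)
        msg <- c(msg, "tauM must equal a1*tau1 + a2*tau2 (within 1e-9)")
      if (any(object@a1[ok] < 0 | object@a1[ok] > 1))
        msg <- c(msg, "a1 must lie in [0, 1] at fitted pixels")
      if (any(object@tau1[ok] <= 0))
        msg <- c(msg, "tau1 must be positive at fitted pixels")
      if (any(object@tau2[ok] <= object@tau1[ok]))
        msg <- c(msg, "tau2 > tau1 required at fitted pixels")
    }
  }
  if (length(msg)) msg else TRUE
})

#' TCSPC photon-count decay cube
#'
#' Three-dimensional nonnegative integer photon-count array
#' (rows x cols x time bins) with its time axis and acquisition metadata:
#' the raw data of a FLIM measurement.
#'
#' @slot counts integer array `rows x cols x nTimeBins` of photon counts.
#' @slot timeAxis left edge (ns) of each time bin, strictly increasing.
#' @slot acquisition the [AcquisitionConfig-class] the cube was recorded
#'   (or simulated) under.
#'
#' @exportClass DecayCube
setClass("DecayCube",
  representation(
    counts = "array",
    timeAxis = "numeric",
    acquisition = "AcquisitionConfig"
  )
)

setValidity("DecayCube", function(object) {
  msg <- character()
  cnt <- object@counts
  if (length(dim(cnt)) != 3L)
    msg <- c(msg, "counts must be a 3D array (rows, cols, time bins)")
  else {
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be nonnegative integers")
    if (dim(cnt)[3] != length(object@timeAxis))
      msg <- c(msg, "timeAxis length must equal the number of time bins")
  }
  if (is.unsorted(object@timeAxis, strictly = TRUE))
    msg <- c(msg, "timeAxis must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Region-of-interest mask
#'
#' Boolean pixel-inclusion image, normally derived by thresholding the
#' EGFP/mCherry-like intensity channels to restrict analysis to tumor
#' pixels, together with a record of the rule that produced it.
#'
#' @slot include logical matrix (rows x cols), `TRUE` = analyse this pixel.
#' @slot provenance human-readable description of the threshold rule.
#'
#' @exportClass ROIMask
setClass("ROIMask",
  representation(include = "matrix", provenance = "character")
)

setValidity("ROIMask", function(object) {
  msg <- character()
  if (!is.logical(object@include) || length(dim(object@include)) != 2L)
    msg <- c(msg, "include must be a logical matrix")
  if (anyNA(object@include))
    msg <- c(msg, "include must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Options for per-pixel decay fitting
#'
#' @slot objective `"poisson_mle"` (counts are Poisson; default) or
#'   `"weighted_least_squares"`.
#' @slot initTau1,initTau2 starting lifetimes in ns; defaults 0.3 and 2.5 ns,
#'   the midpoints of the free (0.1-0.5 ns) and bound (1-5 ns) NADH windows.
#' @slot a1Bounds,tau1Bounds,tau2Bounds box constraints for the optimizer.
#' @slot maxIterations optimizer iteration cap.
#' @slot convergenceTol relative objective-change tolerance.
#' @slot minPhotons minimum total photons in a (binned) pixel decay for a
#'   fit to be attempted; below this the pixel is flagged unfit.
#'
#' @exportClass FitOptions
setClass("FitOptions",
  representation(
    objective = "character",
    initTau1 = "numeric", initTau2 = "numeric",
    a1Bounds = "numeric", tau1Bounds = "numeric", tau2Bounds = "numeric",
    maxIterations = "integer",
    convergenceTol = "numeric",
    minPhotons = "numeric"
  )
)

setValidity("FitOptions", function(object) {
  msg <- character()
  if (!object@objective %in% c("poisson_mle", "weighted_least_squares"))
    msg <- c(msg, "objective must be 'poisson_mle' or 'weighted_least_squares'")
  bounds_ok <- function(b) length(b) == 2L && all(is.finite(b)) && b[1] < b[2]
  if (!bounds_ok(object@a1Bounds) || object@a1Bounds[1] < 0 ||
      object@a1Bounds[2] > 1)
    msg <- c(msg, "a1Bounds must be an increasing pair within [0, 1]")
  if (!bounds_ok(object@tau1Bounds) || object@tau1Bounds[1] <= 0)
    msg <- c(msg, "tau1Bounds must be an increasing positive pair (ns)")
  if (!bounds_ok(object@tau2Bounds) || object@tau2Bounds[1] <= 0)
    msg <- c(msg, "tau2Bounds must be an increasing positive pair (ns)")
  if (length(msg) == 0L) {
    if (object@tau2Bounds[2] <= object@tau1Bounds[1])
      msg <- c(msg, "tau2 upper bound must exceed tau1 lower bound")
    if (object@initTau1 < object@tau1Bounds[1] ||
        object@initTau1 > object@tau1Bounds[2])
      msg <- c(msg, "initTau1 outside tau1Bounds")
    if (object@initTau2 < object@tau2Bounds[1] ||
        object@initTau2 > object@tau2Bounds[2])
      msg <- c(msg, "initTau2 outside tau2Bounds")
    if (object@initTau1 >= object@initTau2)
      msg <- c(msg, "initTau1 must be smaller than initTau2")
  }
  if (object@maxIterations < 1L)
    msg <- c(msg, "maxIterations must be >= 1")
  if (object@convergenceTol <= 0)
    msg <- c(msg, "convergenceTol must be positive")
  if (object@minPhotons < 0)
    msg <- c(msg, "minPhotons must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture model of a parameter distribution
#'
#' A one- or two-component Gaussian model of the per-pixel a1 (or tauM)
#' distribution inside the tumor mask, with model-selection scores. Two
#' coexisting metabolic subpopulations in one tumor show up as `k = 2`.
#'
#' @slot k number of components (1 or 2).
#' @slot weights mixing proportions, positive, summing to 1.
#' @slot means component means (increasing order for `k = 2`).
#' @slot sds component standard deviations.
#' @slot logLik maximized log-likelihood.
#' @slot bic,aic model-selection scores (lower is better).
#' @slot converged did the EM iteration converge (always `TRUE` for k = 1).
#'
#' @exportClass MixtureModel
setClass("MixtureModel",
  representation(
    k = "integer", weights = "numeric", means = "numeric", sds = "numeric",
    logLik = "numeric", bic = "numeric", aic = "numeric",
    converged = "logical"
  )
)

setValidity("MixtureModel", function(object) {
  msg <- character()
  k <- object@k
  if (!k %in% c(1L, 2L)) msg <- c(msg, "k must be 1 or 2")
  if (length(object@weights) != k || length(object@means) != k ||
      length(object@sds) != k)
    msg <- c(msg, "weights, means and sds must each have length k")
  else {
    if (any(object@weights <= 0) ||
        abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must be positive and sum to 1 (within 1e-9)")
    if (k == 2L && object@means[1] > object@means[2])
      msg <- c(msg, "means must be reported in increasing order for k = 2")
    if (any(object@sds <= 0))
      msg <- c(msg, "sds must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a two-group statistical comparison
#'
#' @slot testName `"unpaired_t_two_tailed"` or `"two_way_anova"`.
#' @slot statistic test statistic (t, or the F of the group x bin
#'   interaction for the ANOVA).
#' @slot pValue two-sided p-value in `[0, 1]`.
#' @slot groupSizes number of units (or bins) per group.
#' @slot effectDirection sign of (first group mean - second group mean).
#' @slot details test-specific extras (e.g. the full ANOVA table).
#'
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    testName = "character", statistic = "numeric", pValue = "numeric",
    groupSizes = "integer", effectDirection = "numeric", details = "list"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!object@testName %in% c("unpaired_t_two_tailed", "two_way_anova"))
    msg <- c(msg, "unknown testName")
  if (length(object@pValue) != 1L || is.na(object@pValue) ||
      object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
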