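#' @include AllClasses.R
NULL

#' Accessors for flimetab objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `a1Map`, `a2Map`, `tau1Map`, `tau2Map`, `tauMMap`, `intensityMap`,
#' `fitOkMap` and `objectiveMap` extract images from a
#' [ParameterMaps-class]; `counts`, `timeAxis` and `acquisition` read a
#' [DecayCube-class]; `maskMatrix` and `maskProvenance` read an
#' [ROIMask-class]; `nComponents`, `mixWeights`, `mixMeans`, `mixSds` and
#' `scoreBIC`/`scoreAIC` read a [MixtureModel-class].
#'
#' @param x the object to access.
#' @return The matrix, vector or scalar stored in the corresponding slot.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("a1Map", function(x) standardGeneric("a1Map"))
#' @rdname accessors
#' @export
setGeneric("a2Map", function(x) standardGeneric("a2Map"))
#' @rdname accessors
#' @export
setGeneric("tau1Map", function(x) standardGeneric("tau1Map"))
#' @rdname accessors
#' @export
setGeneric("tau2Map", function(x) standardGeneric("tau2Map"))
#' @rdname accessors
#' @export
setGeneric("tauMMap", function(x) standardGeneric("tauMMap"))
#' @rdname accessors
#' @export
setGeneric("intensityMap", function(x) standardGeneric("intensityMap"))
#' @rdname accessors
#' @export
setGeneric("fitOkMap", function(x) standardGeneric("fitOkMap"))
#' @rdname accessors
#' @export
setGeneric("objectiveMap", function(x) standardGeneric("objectiveMap"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("acquisition", function(x) standardGeneric("acquisition"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("maskProvenance", function(x) standardGeneric("maskProvenance"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("mixWeights", function(x) standardGeneric("mixWeights"))
#' @rdname accessors
#' @export
setGeneric("mixMeans", function(x) standardGeneric("mixMeans"))
#' @rdname accessors
#' @export
setGeneric("mixSds", function(x) standardGeneric("mixSds"))
#' @rdname accessors
#' @export
setGeneric("scoreBIC", function(x) standardGeneric("scoreBIC"))
#' @rdname accessors
#' @export
setGeneric("scoreAIC", function(x) standardGeneric("scoreAIC"))

#' Amplitude-weighted mean fluorescence lifetime
#'
#' Computes the overall lifetime `tauM = a1*tau1 + a2*tau2`, the
#' amplitude-weighted average of the free and bound NADH lifetimes. Since
#' `tau1 < tau2`, `tauM` always lies in `[tau1, tau2]` and decreases as the
#' free fraction `a1` (the glycolysis readout) increases.
#'
#' @param params a [DecayParams-class] object, or for the numeric method the
#'   free-fraction value(s) `a1`.
#' @param ... passed to methods; the numeric method takes `tau1` and `tau2`
#'   (ns), recycled against `a1`.
#' @return Mean lifetime in ns.
#' @examples
#' meanLifetime(decayParams(a1 = 0.5, tau1 = 0.4, tau2 = 2.0))  # 1.2 ns
#' meanLifetime(0.7, tau1 = 0.4, tau2 = 2.5)                    # 1.03 ns
#' @export
setGeneric("meanLifetime", function(params, ...) standardGeneric("meanLifetime"))
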