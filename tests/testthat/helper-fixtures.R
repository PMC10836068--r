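# Shared in-code fixtures: everything is generated at test time.

# small acquisition for fast cube work
smallAcq <- function(shape = c(8L, 8L), photons = 5000, ...) {
  acquisitionConfig(frameShape = as.integer(shape),
                    meanPhotonsPerPixel = photons, ...)
}

# single-pixel acquisition for histogram-level fitting
pixelAcq <- function(...) acquisitionConfig(frameShape = c(1L, 1L), ...)

# noiseless expected histogram for one parameter set
noiselessHistogram <- function(params, acq, photons = 5000) {
  photons * foldedBinProbabilities(params, acq)
}

# uniform-truth maps built directly (allows boundary values like a1 = 1
# that scene specs deliberately exclude)
uniformTruth <- function(shape, a1, tau1, tau2, intensity = 5000) {
  parameterMaps(matrix(a1, shape[1], shape[2]),
                matrix(tau1, shape[1], shape[2]),
                matrix(tau2, shape[1], shape[2]),
                intensity = matrix(intensity, shape[1], shape[2]))
}

# random decay parameters in the physiological NADH regime (free fraction
# and lifetimes in the ranges the scenes and group protocols use); in this
# regime all three parameters are identifiable to ~1% at 1e5 photons
randomTruths <- function(n, seed) {
  set.seed(seed)
  data.frame(a1 = runif(n, 0.55, 0.85),
             tau1 = runif(n, 0.2, 0.4),
             tau2 = runif(n, 1.8, 4.0))
}

relErr <- function(est, true) abs(est - true) / abs(true)
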