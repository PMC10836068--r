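#' @include AllClasses.R constructors.R decay-model.R simulate.R
NULL

## signal used when a mask or extraction selects no pixels
.emptySelection <- function(msg, warn = FALSE) {
  cls <- c("flimetab_empty_selection",
           if (warn) c("warning", "condition") else c("error", "condition"))
  cond <- structure(class = cls, list(message = msg, call = sys.call(-1)))
  if (warn) warning(cond) else stop(cond)
}

#' Spatially bin a decay cube
#'
#' Sums the photon-count histograms of neighbouring pixels to increase the
#' counts in each decay before fitting ("bin of 4": each output pixel pools
#' its 2 x 2 neighbourhood). The default `"sliding"` mode anchors the window
#' at the top-left pixel and preserves the image dimensions; edge pixels sum
#' over the available sub-window. `"block"` mode sums disjoint
#' `window x window` blocks (output is `window`-fold smaller and the grand
#' total of counts is conserved exactly).
#'
#' @param cube a [DecayCube-class].
#' @param window side of the square binning window (default 2).
#' @param mode `"sliding"` (default) or `"block"`.
#' @return A [DecayCube-class] of binned counts.
#' @export
spatialBin <- function(cube, window = 2L, mode = c("sliding", "block")) {
  stopifnot(is(cube, "DecayCube"), window >= 1L)
  mode <- match.arg(mode)
  cnt <- cube@counts
  d <- dim(cnt)
  w <- as.integer(window)
  if (mode == "sliding") {
    out <- array(0L, d)
    for (di in seq_len(w) - 1L) for (dj in seq_len(w) - 1L) {
      out[seq_len(d[1] - di), seq_len(d[2] - dj), ] <-
        out[seq_len(d[1] - di), seq_len(d[2] - dj), , drop = FALSE] +
        cnt[seq.int(1L + di, d[1]), seq.int(1L + dj, d[2]), , drop = FALSE]
    }
    newDim <- d[1:2]
  } else {
    if (d[1] %% w != 0L || d[2] %% w != 0L)
      stop("block mode requires frame dimensions divisible by the window")
    newDim <- d[1:2] %/% w
    out <- array(0L, c(newDim, d[3]))
    for (di in seq_len(w) - 1L) for (dj in seq_len(w) - 1L) {
      out <- out + cnt[seq.int(1L + di, d[1], by = w),
                       seq.int(1L + dj, d[2], by = w), , drop = FALSE]
    }
  }
  storage.mode(out) <- "integer"
  acq <- cube@acquisition
  acq@frameShape <- as.integer(newDim)
  decayCube(out, acq)
}

## exact discrete Otsu threshold on a 256-level histogram of the image
.otsuThreshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  s1 <- cumsum(h * mids); s2 <- sum(h * mids) - s1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, levels)
  between[valid] <- w1[valid] * w2[valid] *
    (s1[valid] / w1[valid] - s2[valid] / w2[valid])^2
  breaks[which.max(between) + 1L]
}

#' Threshold an intensity image into a region-of-interest mask
#'
#' Emulates locating the tumor by its fluorescent-protein (EGFP/mCherry)
#' intensity: pixels at or above the threshold are included. Three rules are
#' available: a fixed intensity value, an upper quantile, or Otsu's
#' between-class-variance criterion (the natural choice for the bright
#' tumor / dim background contrast). The rule used is recorded in the
#' mask's provenance. An empty mask raises a warning of class
#' `"flimetab_empty_selection"`.
#'
#' @param intensity nonnegative intensity matrix.
#' @param method `"otsu"` (default), `"fixed"` or `"quantile"`.
#' @param value the fixed threshold, or the quantile probability for
#'   `method = "quantile"`.
#' @return An [ROIMask-class].
#' @examples
#' img <- matrix(c(rep(10, 8), rep(1000, 8)), 4, 4)
#' intensityMask(img, "fixed", value = 500)
#' @export
intensityMask <- function(intensity, method = c("otsu", "fixed", "quantile"),
                          value = NULL) {
  method <- match.arg(method)
  intensity <- as.matrix(intensity)
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensityMask: intensity must be nonnegative")
  thr <- switch(method,
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs a threshold value")
      value
    },
    quantile = {
      if (is.null(value)) stop("method 'quantile' needs a probability")
      stats::quantile(intensity, probs = value, na.rm = TRUE, names = FALSE)
    },
    otsu = .otsuThreshold(intensity)
  )
  inc <- !is.na(intensity) & intensity >= thr
  mask <- new("ROIMask", include = inc,
              provenance = sprintf("%s threshold at %.6g", method, thr))
  if (!any(inc))
    .emptySelection("intensity mask selects no pixels", warn = TRUE)
  mask
}

## factory for the model's bin-probability function at fixed acquisition;
## precomputes edges and the IRF kernel FFT for the fit hot loop
.makeProbFun <- function(acq, fold = TRUE) {
  edges <- binEdges(acq)
  period <- repetitionPeriod(acq)
  n <- acq@nTimeBins
  e1 <- edges[-(n + 1L)]
  e2 <- edges[-1L]
  kernFft <- NULL
  if (acq@irfSigma > 0) {
    window <- n * acq@binWidth
    kern <- diff(stats::pnorm(edges, 0, acq@irfSigma)) +
      diff(stats::pnorm(edges - window, 0, acq@irfSigma)) +
      diff(stats::pnorm(edges + window, 0, acq@irfSigma))
    kernFft <- stats::fft(kern / sum(kern))
  }
  function(a1, t1, t2) {
    m1 <- t1 * (exp(-e1 / t1) - exp(-e2 / t1))
    m2 <- t2 * (exp(-e1 / t2) - exp(-e2 / t2))
    if (fold) {
      m1 <- m1 / (1 - exp(-period / t1))
      m2 <- m2 / (1 - exp(-period / t2))
    }
    u <- a1 * m1 + (1 - a1) * m2
    p <- u / sum(u)
    if (!is.null(kernFft)) {
      p <- Re(stats::fft(stats::fft(p) * kernFft, inverse = TRUE)) / n
      p[p < 0] <- 0
      p <- p / sum(p)
    }
    p
  }
}

.unfitResult <- function(objective = NA_real_) {
  list(a1 = NaN, tau1 = NaN, tau2 = NaN, amplitude = NaN,
       objectiveValue = objective, converged = FALSE, fitOk = FALSE,
       iterations = 0L)
}

## core constrained optimization shared by fitPixel and fitCube; probFun is
## the precomputed model closure
.fitHistogram <- function(y, N, probFun, opts) {
  poisson <- opts@objective == "poisson_mle"
  pos <- y > 0
  ypos <- y[pos]
  y2 <- y * y
  obj <- if (poisson) {
    # amplitude profiles out to A = N; minimize the cross-entropy term
    function(par) {
      p <- probFun(par[1], par[2], par[3])
      -sum(ypos * log(pmax(p[pos], 1e-300)))
    }
  } else {
    # Pearson chi-square: model-based weights 1/(A p) avoid the low-count
    # bias of data-based weights; the amplitude profiles out in closed form
    function(par) {
      p <- pmax(probFun(par[1], par[2], par[3]), 1e-300)
      A <- sqrt(sum(y2 / p) / sum(p))
      sum((y - A * p)^2 / (A * p))
    }
  }
  lower <- c(opts@a1Bounds[1], opts@tau1Bounds[1], opts@tau2Bounds[1])
  upper <- c(opts@a1Bounds[2], opts@tau1Bounds[2], opts@tau2Bounds[2])
  clip <- function(s) pmin(pmax(s, lower), upper)
  run1 <- function(start) {
    try(stats::optim(start, obj, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(
                       maxit = opts@maxIterations,
                       factr = opts@convergenceTol / .Machine$double.eps,
                       pgtol = 1e-10)),
        silent = TRUE)
  }
  opt <- run1(c(mean(opts@a1Bounds), opts@initTau1, opts@initTau2))
  # a solution pinned to a box bound is often the swapped-component corner
  # trap (tau1 high, tau2 low); rescue with diverse restarts and keep the
  # best objective
  suspicious <- inherits(opt, "try-error") || opt$convergence != 0L ||
    any(abs(opt$par[2:3] - lower[2:3]) < 1e-8 |
          abs(opt$par[2:3] - upper[2:3]) < 1e-8)
  if (suspicious) {
    evals <- if (inherits(opt, "try-error")) 0L else opt$counts[1]
    for (s in list(c(0.5, 0.2, 1.0), c(0.7, 0.4, 4.0), c(0.3, 0.15, 1.8))) {
      alt <- run1(clip(s))
      if (inherits(alt, "try-error")) next
      evals <- evals + alt$counts[1]
      if (inherits(opt, "try-error") ||
          (alt$convergence == 0L && (opt$convergence != 0L ||
                                     alt$value < opt$value)))
        opt <- alt
    }
    if (!inherits(opt, "try-error")) opt$counts[1] <- evals
  }
  if (inherits(opt, "try-error")) return(.unfitResult())
  par <- opt$par
  # relabel so tau1 < tau2 if the optimizer crossed the components
  if (par[2] > par[3]) par <- c(1 - par[1], par[3], par[2])
  p <- pmax(probFun(par[1], par[2], par[3]), 1e-300)
  A <- if (poisson) N else sqrt(sum(y2 / p) / sum(p))
  objective <- if (poisson) {
    A - sum(ypos * log(pmax(A * p[pos], 1e-300)))
  } else {
    sum((y - A * p)^2 / (A * p))
  }
  list(a1 = par[1], tau1 = par[2], tau2 = par[3], amplitude = A,
       objectiveValue = objective, converged = opt$convergence == 0L,
       fitOk = opt$convergence == 0L && par[2] < par[3],
       iterations = as.integer(opt$counts[1]))
}

#' Fit a two-component decay to a single pixel histogram
#'
#' Constrained optimization of the chosen objective for the model
#' `amplitude * p(a1, tau1, tau2)`, where `p` are the folded (and, if the
#' acquisition declares one, IRF-convolved) bin probabilities of
#' [foldedBinProbabilities()]. The constraint `a1 + a2 = 1` holds by
#' construction because only `a1` is parameterized; the total amplitude is
#' profiled out in closed form (it equals the total count under Poisson
#' maximum likelihood). Lifetimes are reported ordered (`tau1 < tau2`),
#' relabelling the components if the optimizer crossed them.
#'
#' Histograms with fewer than `minPhotons` total counts are flagged unfit
#' (all-`NaN` parameters, `fitOk = FALSE`) without raising an error.
#'
#' @param histogram nonnegative numeric vector of per-bin photon counts
#'   (length `acq@nTimeBins`); non-integer values are allowed so noiseless
#'   expected histograms can be fitted.
#' @param acq the [AcquisitionConfig-class] the histogram was recorded under.
#' @param opts a [FitOptions-class].
#' @param fold model incomplete-decay folding (default `TRUE`; must match
#'   the forward model).
#' @return List with elements `a1`, `tau1`, `tau2`, `amplitude`,
#'   `objectiveValue`, `converged`, `fitOk`, `iterations`.
#' @examples
#' acq <- acquisitionConfig(frameShape = c(1L, 1L))
#' p <- foldedBinProbabilities(decayParams(0.6, 0.35, 2.2), acq)
#' fit <- fitPixel(5000 * p, acq, fitOptions())
#' @export
fitPixel <- function(histogram, acq, opts = fitOptions(), fold = TRUE) {
  stopifnot(is(acq, "AcquisitionConfig"), is(opts, "FitOptions"))
  validObject(opts)
  if (length(histogram) != acq@nTimeBins)
    stop("histogram length does not match acquisition nTimeBins")
  if (any(histogram < 0)) stop("histogram counts must be nonnegative")
  N <- sum(histogram)
  if (!is.finite(N) || N < opts@minPhotons) return(.unfitResult())
  .fitHistogram(histogram, N, .makeProbFun(acq, fold), opts)
}

#' Fit every masked pixel of a decay cube
#'
#' The full per-pixel analysis: spatial binning ([spatialBin()], 2 x 2 by
#' default, disable with `binWindow = 1`), then constrained two-component
#' fitting of every pixel inside the mask, assembling [ParameterMaps-class]
#' with the derived `a2` and `tauM = a1*tau1 + a2*tau2` images. Pixels
#' outside the mask, below the photon floor, or failing to converge carry
#' `NaN` in every float map and `FALSE` in `fitOk`.
#'
#' @param cube a [DecayCube-class].
#' @param mask an [ROIMask-class] matching the cube's frame, or `NULL` to
#'   fit all pixels. An all-`FALSE` mask raises an error of class
#'   `"flimetab_empty_selection"`.
#' @param opts a [FitOptions-class].
#' @param binWindow spatial binning window applied before fitting
#'   (default 2; 1 disables binning).
#' @param fold model incomplete-decay folding (default `TRUE`).
#' @return A [ParameterMaps-class] of fitted parameters.
#' @export
fitCube <- function(cube, mask = NULL, opts = fitOptions(),
                    binWindow = 2L, fold = TRUE) {
  stopifnot(is(cube, "DecayCube"))
  if (binWindow > 1L) cube <- spatialBin(cube, window = binWindow)
  acq <- cube@acquisition
  d <- dim(cube@counts)
  if (is.null(mask)) {
    inc <- matrix(TRUE, d[1], d[2])
  } else {
    stopifnot(is(mask, "ROIMask"))
    if (!identical(dim(mask@include), d[1:2]))
      stop("mask shape does not match the cube's spatial dimensions")
    inc <- mask@include
  }
  if (!any(inc))
    .emptySelection("mask excludes every pixel; nothing to fit")
  Y <- matrix(as.numeric(cube@counts), d[1] * d[2], d[3])
  probFun <- .makeProbFun(acq, fold)
  a1 <- tau1 <- tau2 <- objv <- matrix(NaN, d[1], d[2])
  fitOk <- matrix(FALSE, d[1], d[2])
  totals <- matrix(rowSums(Y), d[1], d[2])
  for (idx in which(inc)) {
    y <- Y[idx, ]
    N <- totals[idx]
    res <- if (N < opts@minPhotons) .unfitResult()
           else .fitHistogram(y, N, probFun, opts)
    if (res$fitOk) {
      a1[idx] <- res$a1
      tau1[idx] <- res$tau1
      tau2[idx] <- res$tau2
      fitOk[idx] <- TRUE
    }
    objv[idx] <- res$objectiveValue
  }
  parameterMaps(a1, tau1, tau2, intensity = totals,
                fitOk = fitOk, objectiveValue = objv)
}
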