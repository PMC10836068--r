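#' @include AllClasses.R constructors.R pixelfit.R
NULL

#' Extract fitted values inside a region-of-interest mask
#'
#' Pulls the finite, successfully fitted values of one parameter map at the
#' masked pixels - the per-pixel sample that feeds the histogram and
#' mixture analysis. Pixel provenance (row/col) is retained.
#'
#' @param maps a [ParameterMaps-class].
#' @param mask an [ROIMask-class] of the same shape, or `NULL` for all
#'   pixels.
#' @param field `"a1"` (free NADH fraction, default) or `"tau_m"` (mean
#'   lifetime, ns).
#' @return data.frame with columns `row`, `col`, `value`. An empty
#'   selection raises an error of class `"flimetab_empty_selection"`.
#' @export
maskedValues <- function(maps, mask = NULL, field = c("a1", "tau_m")) {
  stopifnot(is(maps, "ParameterMaps"))
  field <- match.arg(field)
  img <- if (field == "a1") maps@a1 else maps@tauM
  inc <- if (is.null(mask)) matrix(TRUE, nrow(img), ncol(img))
         else {
           stopifnot(is(mask, "ROIMask"))
           if (!identical(dim(mask@include), dim(img)))
             stop("mask shape does not match the maps")
           mask@include
         }
  sel <- which(inc & maps@fitOk & is.finite(img), arr.ind = TRUE)
  if (nrow(sel) == 0L)
    .emptySelection("no fitted pixels inside the mask")
  data.frame(row = sel[, 1], col = sel[, 2], value = img[sel])
}

## log-likelihood of a Gaussian mixture
.mixLogLik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w),
                 function(i) w[i] * stats::dnorm(x, mu[i], sd[i]),
                 numeric(length(x)))
  sum(log(pmax(rowSums(as.matrix(dens)), 1e-300)))
}

## one EM run for a 2-component Gaussian mixture from given centers
.emRun <- function(x, mu0, tol, maxIter) {
  n <- length(x)
  mu <- mu0
  sd <- rep(stats::sd(x) / 2, 2)
  sd[sd <= 0] <- 1e-8
  w <- c(0.5, 0.5)
  ll <- -Inf
  converged <- FALSE
  sdFloor <- max(stats::sd(x), 1e-12) * 1e-4
  for (it in seq_len(maxIter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- pmax(d1 + d2, 1e-300)
    r <- d1 / tot
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # component collapsed
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sd <- sqrt(c(sum(r * (x - mu[1])^2) / n1,
                 sum((1 - r) * (x - mu[2])^2) / n2))
    sd <- pmax(sd, sdFloor)
    w <- c(n1, n2) / n
    llNew <- .mixLogLik(x, w, mu, sd)
    if (is.finite(ll) && abs(llNew - ll) <= tol * (abs(ll) + 1)) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  list(w = w, mu = mu, sd = sd, ll = ll, converged = converged)
}

#' Fit a one- or two-component Gaussian mixture
#'
#' Maximum-likelihood Gaussian model of a per-pixel value sample (typically
#' the a1 values inside the tumor mask). `k = 1` is the closed-form normal
#' MLE; `k = 2` runs expectation-maximization with `nRestarts` random
#' initializations (first start: the two halves of the sorted sample, the
#' k-means-style split; further starts: random pairs of observations),
#' keeping the best likelihood. Reports BIC and AIC for model selection.
#' Deterministic given `seed`.
#'
#' @param values numeric sample; at least `10 * k` observations.
#' @param k number of Gaussian components, 1 or 2.
#' @param nRestarts EM restarts for `k = 2` (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter EM iteration cap per restart (default 500).
#' @param seed integer seed for the random restarts.
#' @return A [MixtureModel-class]; for `k = 2` the means are in increasing
#'   order.
#' @examples
#' set.seed(1)
#' m <- fitMixture(rnorm(500, 0.6, 0.03), k = 1)
#' @export
fitMixture <- function(values, k = 1L, nRestarts = 10L, tol = 1e-8,
                       maxIter = 500L, seed = 1L) {
  k <- as.integer(k)
  stopifnot(k %in% c(1L, 2L))
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 10L * k)
    stop(sprintf("fitMixture needs at least %d values for k = %d", 10L * k, k))
  if (stats::sd(x) == 0)
    stop("fitMixture: zero-variance sample is degenerate")
  if (k == 1L) {
    mu <- mean(x)
    sdev <- sqrt(sum((x - mu)^2) / n)  # ML estimate, denominator n
    ll <- sum(stats::dnorm(x, mu, sdev, log = TRUE))
    nPar <- 2
    return(new("MixtureModel", k = 1L, weights = 1, means = mu, sds = sdev,
               logLik = ll, bic = -2 * ll + nPar * log(n),
               aic = -2 * ll + 2 * nPar, converged = TRUE))
  }
  set.seed(seed)
  xs <- sort(x)
  starts <- vector("list", nRestarts)
  starts[[1]] <- c(mean(xs[seq_len(n %/% 2)]), mean(xs[-seq_len(n %/% 2)]))
  for (i in seq_len(nRestarts - 1L))
    starts[[i + 1L]] <- sort(sample(x, 2L))
  best <- NULL
  for (s in starts) {
    if (diff(s) == 0) next
    run <- .emRun(x, s, tol, maxIter)
    if (is.null(best) || run$ll > best$ll) best <- run
  }
  if (is.null(best))
    stop("fitMixture: EM failed from every initialization")
  ord <- order(best$mu)
  nPar <- 5  # 2 means + 2 sds + 1 free weight
  new("MixtureModel", k = 2L,
      weights = best$w[ord], means = best$mu[ord], sds = best$sd[ord],
      logLik = best$ll, bic = -2 * best$ll + nPar * log(n),
      aic = -2 * best$ll + 2 * nPar, converged = best$converged)
}

#' Choose between a unimodal and bimodal Gaussian description
#'
#' Fits both `k = 1` and `k = 2` Gaussian models ([fitMixture()]) and keeps
#' the lower BIC; when the BIC difference is below `deltaBicTie` (default 2,
#' the conventional "barely worth mentioning" band) the single Gaussian wins
#' on parsimony. This is the quantitative version of reading an a1 histogram
#' as "single gaussian" versus "bimodal gaussian": two metabolic
#' subpopulations in one tumor.
#'
#' @param values numeric sample, at least 50 observations.
#' @param deltaBicTie parsimony band on `BIC(k=1) - BIC(k=2)` (default 2).
#' @param ... passed on to [fitMixture()] (`nRestarts`, `seed`, ...).
#' @return List with `k` (selected component count), `deltaBic`
#'   (`BIC(k=1) - BIC(k=2)`, positive favours bimodal), and both fitted
#'   models as `model1` and `model2`.
#' @export
selectModality <- function(values, deltaBicTie = 2, ...) {
  x <- values[is.finite(values)]
  if (length(x) < 50L)
    stop("selectModality needs at least 50 values")
  m1 <- fitMixture(x, k = 1L, ...)
  m2 <- fitMixture(x, k = 2L, ...)
  deltaBic <- m1@bic - m2@bic
  k <- if (deltaBic >= deltaBicTie) 2L else 1L
  list(k = k, deltaBic = deltaBic, model1 = m1, model2 = m2)
}

#' Bin values into the fixed histogram used for display and ANOVA
#'
#' Relative-frequency histogram on a fixed grid (bin width 0.01 on a1 in
#' `[0, 1]` by default). Each group entry may be a single numeric vector
#' (one pooled histogram per group, for display) or a list of per-unit
#' vectors - one histogram per fish, normalized per unit, which provides
#' the replication the two-way ANOVA needs.
#'
#' @param valuesByGroup named list: one numeric vector, or one list of
#'   numeric vectors, per group.
#' @param binWidth histogram bin width (default 0.01).
#' @param range value range covered by the grid (default `c(0, 1)`).
#' @return data.frame with columns `group`, `unit`, `bin` (bin center),
#'   `frequency` (relative frequency; sums to 1 within each unit).
#' @export
histogramTable <- function(valuesByGroup, binWidth = 0.01, range = c(0, 1)) {
  stopifnot(is.list(valuesByGroup), length(names(valuesByGroup)) > 0)
  breaks <- seq(range[1], range[2], by = binWidth)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  oneHist <- function(g, unit, x) {
    x <- x[is.finite(x)]
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                    nbins = length(mids))
    data.frame(group = g, unit = unit, bin = mids,
               frequency = cnt / max(sum(cnt), 1), stringsAsFactors = FALSE)
  }
  out <- lapply(names(valuesByGroup), function(g) {
    v <- valuesByGroup[[g]]
    if (is.list(v)) {
      labs <- names(v) %||% paste0(g, "_", seq_along(v))
      do.call(rbind, Map(oneHist, g, labs, v))
    } else {
      oneHist(g, g, v)
    }
  })
  do.call(rbind, out)
}

#' Compare two groups of units, or two histogram distributions
#'
#' Two tests mirroring the figure-level statistics:
#' * `"unpaired_t_two_tailed"`: Student's two-sample t-test on per-unit
#'   (per-fish) mean values - one number per animal, so pixels within a
#'   tumor are never treated as independent replicates. Requires at least
#'   two units per group.
#' * `"two_way_anova"`: for histogram comparisons; takes a
#'   (group, bin, frequency) table (see [histogramTable()]) with per-unit
#'   histograms as replicates and crosses group with histogram bin on the
#'   relative frequencies. Because the
#'   frequencies sum to 1 within each group, the group main effect is zero
#'   by construction and the informative term is the group x bin
#'   interaction, whose F and p are reported as the primary statistic (the
#'   full ANOVA table is kept in `details`).
#'
#' @param groupA,groupB numeric vectors of per-unit means (t-test), or for
#'   the ANOVA a single data.frame passed as `groupA` with columns `group`,
#'   `bin`, `frequency` and exactly two groups.
#' @param test `"unpaired_t_two_tailed"` (default) or `"two_way_anova"`.
#' @return A [GroupComparison-class]. `effectDirection` is the sign of
#'   (mean of `groupA` - mean of `groupB`); for the ANOVA it is the sign of
#'   the difference in frequency-weighted mean bin value.
#' @examples
#' compareGroups(c(0.74, 0.77, 0.72), c(0.60, 0.63, 0.58))
#' @export
compareGroups <- function(groupA, groupB = NULL,
                          test = c("unpaired_t_two_tailed", "two_way_anova")) {
  test <- match.arg(test)
  if (test == "unpaired_t_two_tailed") {
    a <- groupA[is.finite(groupA)]
    b <- groupB[is.finite(groupB)]
    if (length(a) < 2L || length(b) < 2L)
      stop("unpaired t-test needs at least 2 units per group")
    if (identical(sort(a), sort(b)) && stats::sd(c(a, b)) == 0) {
      # identical constant samples: no evidence of any difference
      return(new("GroupComparison", testName = test, statistic = 0,
                 pValue = 1, groupSizes = c(length(a), length(b)),
                 effectDirection = 0, details = list()))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
    new("GroupComparison", testName = test,
        statistic = unname(tt$statistic), pValue = tt$p.value,
        groupSizes = c(length(a), length(b)),
        effectDirection = sign(mean(a) - mean(b)),
        details = list(df = unname(tt$parameter),
                       means = c(mean(a), mean(b))))
  } else {
    tab <- groupA
    stopifnot(is.data.frame(tab),
              all(c("group", "bin", "frequency") %in% names(tab)))
    groups <- unique(tab$group)
    if (length(groups) != 2L)
      stop("two-way ANOVA expects exactly two groups")
    tab$group <- factor(tab$group)
    tab$bin <- factor(tab$bin)
    cells <- table(tab$group, tab$bin)
    if (max(cells) < 2L)
      stop(paste("two-way ANOVA needs replicated histograms (several units",
                 "per group); one pooled histogram per group leaves no",
                 "residual degrees of freedom for the interaction"))
    fit <- stats::aov(frequency ~ group * bin, data = tab)
    an <- summary(fit)[[1]]
    irow <- grep("group:bin", rownames(an))
    if (length(irow) != 1L || is.na(an[irow, "F value"]))
      stop("two-way ANOVA interaction could not be estimated")
    wmean <- vapply(groups, function(g) {
      s <- tab[tab$group == g, ]
      sum(as.numeric(as.character(s$bin)) * s$frequency) / sum(s$frequency)
    }, numeric(1))
    new("GroupComparison", testName = test,
        statistic = an[irow, "F value"], pValue = an[irow, "Pr(>F)"],
        groupSizes = as.integer(table(tab$group)),
        effectDirection = unname(sign(wmean[1] - wmean[2])),
        details = list(anovaTable = an))
  }
}

#' Per-unit summary of fitted metabolic maps
#'
#' One row per unit (per fish): mean a1, mean tauM and fitted-pixel count
#' over the masked, successfully fitted pixels. Units whose mask contains no
#' fitted pixel are flagged (`flagged = TRUE`, `NA` means) and should be
#' excluded from group tests; a warning reports them.
#'
#' @param units list of lists, each with elements `label` (character),
#'   `maps` ([ParameterMaps-class]) and `mask` ([ROIMask-class] or `NULL`),
#'   and optionally `group`.
#' @return data.frame with columns `unit`, `group`, `nPixels`, `meanA1`,
#'   `meanTauM`, `flagged`.
#' @export
summarizeUnits <- function(units) {
  stopifnot(is.list(units), length(units) > 0)
  rows <- lapply(units, function(u) {
    stopifnot(is(u$maps, "ParameterMaps"))
    vals <- tryCatch(maskedValues(u$maps, u$mask, "a1"),
                     flimetab_empty_selection = function(e) NULL)
    if (is.null(vals)) {
      data.frame(unit = u$label, group = u$group %||% NA_character_,
                 nPixels = 0L, meanA1 = NA_real_, meanTauM = NA_real_,
                 flagged = TRUE, stringsAsFactors = FALSE)
    } else {
      tm <- maskedValues(u$maps, u$mask, "tau_m")
      data.frame(unit = u$label, group = u$group %||% NA_character_,
                 nPixels = nrow(vals), meanA1 = mean(vals$value),
                 meanTauM = mean(tm$value), flagged = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (any(out$flagged))
    warning(sprintf("%d unit(s) had no fitted pixels and were flagged: %s",
                    sum(out$flagged),
                    paste(out$unit[out$flagged], collapse = ", ")))
  out
}
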