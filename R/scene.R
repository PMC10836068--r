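#' @include AllClasses.R constructors.R
NULL

#' Construct a scene specification
#'
#' A scene is a labelled partition of the frame into regions (the background
#' is itself a region), each carrying a truncated-Gaussian distribution for
#' the free NADH fraction a1, fixed lifetimes and an intensity scale. Scenes
#' are the ground truth the TCSPC simulator turns into photon data.
#'
#' @param regionMap integer matrix; entry `r` assigns the pixel to row `r`
#'   of `regions`. `NA` entries (unassigned pixels) are a partition error.
#' @param regions data.frame with columns `label`, `a1Mean`, `a1Sd`,
#'   `tau1`, `tau2`, `intensityScale` (one row per region).
#' @param modality `"unimodal"` or `"bimodal"`.
#' @param groupLabel free-text group tag, e.g. `"brain-like"`.
#' @param seed integer seed for the scene's random draws.
#' @return A [SceneSpec-class].
#' @seealso [uniformScene()], [tumorScene()], [bimodalScene()] for ready-made
#'   geometries; [buildScene()] to realize the ground truth.
#' @export
sceneSpec <- function(regionMap, regions, modality = "unimodal",
                      groupLabel = "scene", seed = 1L) {
  storage.mode(regionMap) <- "integer"
  new("SceneSpec", regionMap = regionMap,
      regions = as.data.frame(regions, stringsAsFactors = FALSE),
      modality = modality, groupLabel = groupLabel, seed = as.integer(seed))
}

#' @rdname sceneSpec
#' @param spec a [SceneSpec-class].
#' @export
sceneRegionMap <- function(spec) spec@regionMap

#' @rdname sceneSpec
#' @export
sceneRegions <- function(spec) spec@regions

.regionRow <- function(label, a1Mean, a1Sd, tau1, tau2, intensityScale) {
  data.frame(label = label, a1Mean = a1Mean, a1Sd = a1Sd,
             tau1 = tau1, tau2 = tau2, intensityScale = intensityScale,
             stringsAsFactors = FALSE)
}

#' Ready-made scene geometries
#'
#' Three standard synthetic scenes used throughout the package:
#' * `uniformScene()`: one region filling the frame - the simplest truth for
#'   calibration runs.
#' * `tumorScene()`: a bright circular "tumor" (disc of radius
#'   `0.35 * min(shape)` centered in the frame) over a dim background, for
#'   exercising intensity-based masking.
#' * `bimodalScene()`: the frame split into two equal half-frames with
#'   distinct a1 means - two coexisting metabolic subpopulations, the
#'   situation that makes the pooled a1 histogram bimodal.
#'
#' Defaults place lifetimes at 0.3 ns (free) and 2.5 ns (bound), mid-window
#' for the two NADH species, with 5,000 expected photons per tumor pixel.
#'
#' @param shape integer `c(rows, cols)`; default `c(64, 64)`.
#' @param a1Mean,a1Means region mean free fraction(s) in (0, 1).
#' @param a1Sd pixel-to-pixel standard deviation of a1 within a region.
#' @param tau1,tau2 free and bound lifetimes in ns.
#' @param tumorScale,backgroundScale,intensityScale expected photons per
#'   pixel for the respective regions.
#' @param groupLabel free-text group tag.
#' @param seed integer seed.
#' @return A [SceneSpec-class].
#' @name sceneGeometries
NULL

#' @rdname sceneGeometries
#' @param a1 the single region's a1 mean (`uniformScene`).
#' @export
uniformScene <- function(shape = c(64L, 64L), a1 = 0.7, a1Sd = 0,
                         tau1 = 0.3, tau2 = 2.5, intensityScale = 5000,
                         groupLabel = "uniform", seed = 1L) {
  sceneSpec(matrix(1L, shape[1], shape[2]),
            .regionRow("bulk", a1, a1Sd, tau1, tau2, intensityScale),
            modality = "unimodal", groupLabel = groupLabel, seed = seed)
}

#' @rdname sceneGeometries
#' @param backgroundA1 a1 mean of the background region.
#' @export
tumorScene <- function(shape = c(64L, 64L), a1Mean = 0.7, a1Sd = 0.02,
                       tau1 = 0.3, tau2 = 2.5,
                       tumorScale = 5000, backgroundScale = 10,
                       backgroundA1 = 0.6,
                       groupLabel = "tumor", seed = 1L) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ctr <- (shape + 1) / 2
  disc <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= (0.35 * min(shape))^2
  regionMap <- matrix(1L, shape[1], shape[2])
  regionMap[disc] <- 2L
  regions <- rbind(
    .regionRow("background", backgroundA1, a1Sd, tau1, tau2, backgroundScale),
    .regionRow("tumor", a1Mean, a1Sd, tau1, tau2, tumorScale))
  sceneSpec(regionMap, regions, modality = "unimodal",
            groupLabel = groupLabel, seed = seed)
}

#' @rdname sceneGeometries
#' @export
bimodalScene <- function(shape = c(64L, 64L), a1Means = c(0.55, 0.75),
                         a1Sd = 0.02, tau1 = 0.3, tau2 = 2.5,
                         intensityScale = 5000,
                         groupLabel = "bimodal", seed = 1L) {
  stopifnot(length(a1Means) == 2L)
  regionMap <- matrix(1L, shape[1], shape[2])
  regionMap[, seq_len(shape[2]) > shape[2] / 2] <- 2L
  regions <- rbind(
    .regionRow("low_a1", a1Means[1], a1Sd, tau1, tau2, intensityScale),
    .regionRow("high_a1", a1Means[2], a1Sd, tau1, tau2, intensityScale))
  sceneSpec(regionMap, regions, modality = "bimodal",
            groupLabel = groupLabel, seed = seed)
}

## truncated-Gaussian draw on (0,1) by rejection; sd = 0 degenerates to the
## mean so calibration scenes are exactly reproducible
.rtruncA1 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > 0 & draw < 1
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Realize a scene into ground-truth parameter maps
#'
#' Draws each pixel's free fraction a1 from its region's Gaussian (truncated
#' to (0, 1) by rejection), sets the lifetimes and intensity constant per
#' region, and assembles the derived a2 and tauM maps. Deterministic given
#' the scene's seed.
#'
#' @param spec a [SceneSpec-class].
#' @return A [ParameterMaps-class] holding the ground truth.
#' @examples
#' truth <- buildScene(bimodalScene(shape = c(16L, 16L), seed = 7L))
#' @export
buildScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  reg <- spec@regions
  rm <- spec@regionMap
  shape <- dim(rm)
  a1 <- tau1 <- tau2 <- intensity <- matrix(NA_real_, shape[1], shape[2])
  set.seed(spec@seed)
  # fixed region order keeps draws reproducible and independent of labels
  for (r in seq_len(nrow(reg))) {
    idx <- which(rm == r)
    a1[idx] <- .rtruncA1(length(idx), reg$a1Mean[r], reg$a1Sd[r])
    tau1[idx] <- reg$tau1[r]
    tau2[idx] <- reg$tau2[r]
    intensity[idx] <- reg$intensityScale[r]
  }
  parameterMaps(a1, tau1, tau2, intensity = intensity)
}

#' Per-region summary of a map image against a scene's partition
#'
#' @param spec the [SceneSpec-class] whose partition to use.
#' @param image a matrix with the scene's frame shape (e.g. a fitted a1 map).
#' @return data.frame with columns `label`, `n`, `mean`, `sd` over finite
#'   pixels of each region.
#' @export
regionSummary <- function(spec, image) {
  stopifnot(identical(dim(spec@regionMap), dim(image)))
  reg <- spec@regions
  out <- lapply(seq_len(nrow(reg)), function(r) {
    v <- image[spec@regionMap == r]
    v <- v[is.finite(v)]
    data.frame(label = reg$label[r], n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
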