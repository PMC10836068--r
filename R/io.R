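#' @include AllClasses.R constructors.R
NULL

## TIFF payloads are 32-bit integer samples with an affine [lo, hi] scale
## recorded in the JSON sidecar: ~2^-32 relative precision, and count data
## round-trip exactly. Non-finite pixels are stored as lo and restored from
## the fit_ok map on read.

.writeScaledTIFF <- function(img, path, lo = NULL, hi = NULL) {
  v <- img * 1.0
  fin <- is.finite(v)
  if (is.null(lo)) lo <- if (any(fin)) min(v[fin]) else 0
  if (is.null(hi)) hi <- if (any(fin)) max(v[fin]) else 1
  if (hi <= lo) hi <- lo + 1
  v[!fin] <- lo
  if (is.list(img)) stop("use the multi-page writer for lists")
  tiff::writeTIFF((v - lo) / (hi - lo), path, bits.per.sample = 32L,
                  reduce = FALSE)
  list(lo = lo, hi = hi)
}

.readScaledTIFF <- function(path, lo, hi) {
  m <- tiff::readTIFF(path)  # native [0,1] doubles
  m * (hi - lo) + lo
}

#' Persist and reload decay cubes
#'
#' A cube is written as a multi-page 32-bit float TIFF (one page per time
#' bin) plus a JSON sidecar (`<file>.json`) holding the acquisition
#' parameters, the time axis and any extra metadata (seed, scene config) so
#' a run can be reproduced from its files alone.
#'
#' @param cube a [DecayCube-class].
#' @param path output TIFF path (sidecar written next to it).
#' @param meta named list of extra metadata for the sidecar.
#' @return `writeDecayCube` returns `path` invisibly; `readDecayCube`
#'   returns the reconstructed [DecayCube-class].
#' @export
writeDecayCube <- function(cube, path, meta = list()) {
  stopifnot(is(cube, "DecayCube"))
  acq <- cube@acquisition
  maxCount <- max(cube@counts, 1L)
  pages <- lapply(seq_len(dim(cube@counts)[3]),
                  function(k) cube@counts[, , k] / maxCount)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- c(list(
    container = "flimetab DecayCube v1",
    count_scale = maxCount,
    repetition_rate_hz = acq@repetitionRate,
    n_time_bins = acq@nTimeBins,
    bin_width_ns = acq@binWidth,
    frame_shape = dim(cube@counts)[1:2],
    irf_sigma_ns = acq@irfSigma,
    mean_photons_per_pixel = acq@meanPhotonsPerPixel,
    time_axis_ns = cube@timeAxis
  ), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDecayCube
#' @export
readDecayCube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  acq <- acquisitionConfig(
    repetitionRate = side$repetition_rate_hz,
    nTimeBins = side$n_time_bins,
    binWidth = side$bin_width_ns,
    frameShape = side$frame_shape,
    irfSigma = side$irf_sigma_ns,
    meanPhotonsPerPixel = side$mean_photons_per_pixel)
  counts <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    counts[, , k] <- as.integer(round(pages[[k]] * side$count_scale))
  decayCube(counts, acq)
}

#' Persist and reload parameter maps
#'
#' Each map (`a1`, `tau1`, `tau2`, `tau_m`, `intensity`, `objective`) is
#' written as a separate single-channel 32-bit TIFF under `dir` with the
#' given stem; `fit_ok` is written as a 0/1 TIFF. The JSON sidecar records
#' each map's value range (for exact rescaling on read) plus any extra
#' metadata; unfit (`NaN`) pixels are restored from `fit_ok` on read.
#'
#' @param maps a [ParameterMaps-class].
#' @param dir output directory (created if needed).
#' @param stem filename stem, default `"map"` (files
#'   `<stem>_a1.tif`, ...).
#' @param meta named list of extra metadata for the sidecar.
#' @return `writeParameterMaps` returns the sidecar path invisibly;
#'   `readParameterMaps` the reconstructed [ParameterMaps-class].
#' @export
writeParameterMaps <- function(maps, dir, stem = "map", meta = list()) {
  stopifnot(is(maps, "ParameterMaps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(s) file.path(dir, sprintf("%s_%s.tif", stem, s))
  imgs <- list(a1 = maps@a1, tau1 = maps@tau1, tau2 = maps@tau2,
               tau_m = maps@tauM, intensity = maps@intensity,
               objective = maps@objectiveValue)
  scales <- lapply(names(imgs), function(s) .writeScaledTIFF(imgs[[s]], f(s)))
  names(scales) <- names(imgs)
  scales$fit_ok <- .writeScaledTIFF(maps@fitOk + 0, f("fit_ok"),
                                    lo = 0, hi = 1)
  sidecar <- c(list(container = "flimetab ParameterMaps v1", stem = stem,
                    shape = dim(maps@a1), scales = scales),
               meta)
  side <- file.path(dir, sprintf("%s_maps.json", stem))
  jsonlite::write_json(sidecar, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}

#' @rdname writeParameterMaps
#' @export
readParameterMaps <- function(dir, stem = "map") {
  f <- function(s) file.path(dir, sprintf("%s_%s.tif", stem, s))
  side <- jsonlite::read_json(file.path(dir, sprintf("%s_maps.json", stem)),
                              simplifyVector = TRUE)
  rd <- function(s) .readScaledTIFF(f(s), side$scales[[s]]$lo,
                                    side$scales[[s]]$hi)
  fitOk <- rd("fit_ok") > 0.5
  mask <- function(m) { m[!fitOk] <- NaN; m }
  parameterMaps(mask(rd("a1")), mask(rd("tau1")), mask(rd("tau2")),
                intensity = rd("intensity"), fitOk = fitOk,
                objectiveValue = mask(rd("objective")))
}

#' Write intensity images and ROI masks as TIFF
#'
#' `writeIntensityImage` stores a photon-count image as a 32-bit TIFF with
#' a JSON range sidecar so the counts round-trip exactly;
#' `readIntensityImage` reverses it. `writeMask` stores an
#' [ROIMask-class] as a 0/1 TIFF.
#'
#' @param img nonnegative intensity matrix.
#' @param mask an [ROIMask-class].
#' @param path output TIFF path.
#' @return The written path (invisibly); `readIntensityImage` returns the
#'   matrix.
#' @export
writeIntensityImage <- function(img, path) {
  sc <- .writeScaledTIFF(img, path, lo = 0)
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeIntensityImage
#' @export
readIntensityImage <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  round(.readScaledTIFF(path, sc$lo, sc$hi))
}

#' @rdname writeIntensityImage
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "ROIMask"))
  .writeScaledTIFF(mask@include + 0, path, lo = 0, hi = 1)
  invisible(path)
}

#' Per-pixel CSV export of fitted parameters
#'
#' Long-format table (`row`, `col`, `a1`, `tau1`, `tau2`, `tau_m`,
#' `fit_ok`) of every pixel, 0-based indices, written with 9 significant
#' digits.
#'
#' @param maps a [ParameterMaps-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePixelTable <- function(maps, path) {
  stopifnot(is(maps, "ParameterMaps"))
  d <- dim(maps@a1)
  tab <- data.frame(
    row = rep(seq_len(d[1]) - 1L, times = d[2]),
    col = rep(seq_len(d[2]) - 1L, each = d[1]),
    a1 = signif(as.vector(maps@a1), 9),
    tau1 = signif(as.vector(maps@tau1), 9),
    tau2 = signif(as.vector(maps@tau2), 9),
    tau_m = signif(as.vector(maps@tauM), 9),
    fit_ok = as.integer(as.vector(maps@fitOk)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a run manifest
#'
#' A manifest is a CSV with header columns `unit`, `group`, `organ`,
#' `cube`, `egfp`, `mcherry`, `seed`: one row per animal/lesion. Unit
#' labels must be unique and, when `checkPaths = TRUE`, every referenced
#' file must exist (checked before any compute starts).
#'
#' @param path manifest CSV path.
#' @param checkPaths verify that referenced files resolve (default `TRUE`).
#' @param baseDir directory relative paths are resolved against (defaults
#'   to the manifest's directory).
#' @return data.frame of the manifest rows with paths resolved.
#' @export
readRunManifest <- function(path, checkPaths = TRUE,
                            baseDir = dirname(path)) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit", "group", "organ", "cube", "egfp", "mcherry", "seed")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(man$unit))
    stop("manifest unit labels must be unique")
  for (col in c("cube", "egfp", "mcherry")) {
    rel <- !file.exists(man[[col]]) & nzchar(man[[col]])
    man[[col]][rel] <- file.path(baseDir, man[[col]][rel])
    if (checkPaths) {
      bad <- !file.exists(man[[col]])
      if (any(bad))
        stop(sprintf("manifest column '%s': unresolvable path(s): %s",
                     col, paste(man[[col]][bad], collapse = ", ")))
    }
  }
  man
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with nested blocks `acquisition`, `scene`, `fit`,
#' `threshold`, `analysis` and a global `seed`. Every block is validated
#' against its module's type invariants (by constructing the corresponding
#' objects) before any stage runs; an invalid block fails here, not mid-run.
#'
#' @param path YAML file path.
#' @return List with validated components: `acquisition`
#'   ([AcquisitionConfig-class]), `fit` ([FitOptions-class]), `threshold`
#'   (list), `scene` (list of unit scene descriptions), `analysis` (list),
#'   `seed` (integer), and `hash` (content hash for provenance).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  acqArgs <- cfg$acquisition %||% list()
  acq <- do.call(acquisitionConfig, acqArgs)
  validObject(acq)
  fitArgs <- cfg$fit %||% list()
  opts <- do.call(fitOptions, fitArgs)
  validObject(opts)
  thr <- cfg$threshold %||% list(method = "otsu")
  if (!thr$method %in% c("otsu", "fixed", "quantile"))
    stop("threshold method must be otsu, fixed or quantile")
  analysis <- cfg$analysis %||% list()
  analysis$field <- analysis$field %||% "a1"
  if (!analysis$field %in% c("a1", "tau_m"))
    stop("analysis field must be 'a1' or 'tau_m'")
  analysis$binWidth <- analysis$binWidth %||% 0.01
  scene <- cfg$scene %||% list()
  for (u in scene) {
    if (is.null(u$label)) stop("every scene unit needs a label")
    if (!(u$kind %||% "uniform") %in% c("uniform", "tumor", "bimodal"))
      stop("scene kind must be uniform, tumor or bimodal")
  }
  labels <- vapply(scene, function(u) u$label, character(1))
  if (anyDuplicated(labels)) stop("scene unit labels must be unique")
  list(acquisition = acq, fit = opts, threshold = thr, scene = scene,
       analysis = analysis, seed = as.integer(cfg$seed %||% 1L),
       hash = .contentHash(cfg))
}
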