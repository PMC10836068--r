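#' @include io.R scene.R simulate.R pixelfit.R metabolic-stats.R utils.R
NULL

## instantiate a SceneSpec from one config "scene" unit entry
.sceneFromConfig <- function(u, shape, seed) {
  kind <- u$kind %||% "uniform"
  grp <- u$group %||% "group"
  switch(kind,
    uniform = uniformScene(shape, a1 = u$a1 %||% 0.7,
                           a1Sd = u$a1Sd %||% 0.02,
                           tau1 = u$tau1 %||% 0.3, tau2 = u$tau2 %||% 2.5,
                           intensityScale = u$intensityScale %||% 5000,
                           groupLabel = grp, seed = seed),
    tumor = tumorScene(shape, a1Mean = u$a1 %||% 0.7,
                       a1Sd = u$a1Sd %||% 0.02,
                       tau1 = u$tau1 %||% 0.3, tau2 = u$tau2 %||% 2.5,
                       tumorScale = u$intensityScale %||% 5000,
                       backgroundScale = u$backgroundScale %||% 10,
                       groupLabel = grp, seed = seed),
    bimodal = bimodalScene(shape, a1Means = unlist(u$a1Means %||% c(0.55, 0.75)),
                           a1Sd = u$a1Sd %||% 0.02,
                           tau1 = u$tau1 %||% 0.3, tau2 = u$tau2 %||% 2.5,
                           intensityScale = u$intensityScale %||% 5000,
                           groupLabel = grp, seed = seed))
}

#' Histogram of a value sample with Gaussian mixture overlay
#'
#' Base-graphics rendering of the per-pixel a1 (or tauM) histogram with the
#' selected Gaussian model drawn on top - the figure-style view of the
#' modality analysis.
#'
#' @param values numeric sample.
#' @param modality result of [selectModality()] for the same sample.
#' @param main plot title.
#' @param file optional PNG path; when given the plot is written there.
#' @return `NULL`, invisibly.
#' @export
plotMixtureHistogram <- function(values, modality, main = "a1 distribution",
                                 file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  m <- if (modality$k == 2L) modality$model2 else modality$model1
  graphics::hist(values, breaks = 50, freq = FALSE, col = "grey85",
                 border = "grey60", main = main, xlab = "value")
  xs <- seq(min(values), max(values), length.out = 400)
  dens <- rowSums(vapply(seq_len(m@k), function(i) {
    m@weights[i] * stats::dnorm(xs, m@means[i], m@sds[i])
  }, numeric(length(xs))))
  graphics::lines(xs, dens, lwd = 2, col = "firebrick")
  graphics::legend("topright", bty = "n",
                   legend = sprintf("k = %d (dBIC = %.2f)",
                                    modality$k, modality$deltaBic))
  invisible(NULL)
}

.logLine <- function(logFile, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  sprintf(fmt, ...))
  message(line)
  cat(line, "\n", file = logFile, append = TRUE, sep = "")
}

#' Run the full simulate / fit / analyze pipeline
#'
#' Orchestrates the three analysis stages under one validated configuration:
#' * **simulate** (skipped when `manifest` is given): realizes every scene
#'   unit of the config, simulates its decay cube and EGFP/mCherry-like
#'   intensity channels, and writes them under `out/units/<label>/`.
#' * **fit**: thresholds the summed intensity channels into a tumor mask,
#'   spatially bins and fits every masked pixel, and writes the parameter
#'   map TIFFs plus a per-pixel CSV per unit.
#' * **analyze**: per-unit summary table, pooled per-group a1 (or tauM)
#'   values with unimodal/bimodal Gaussian selection, the between-group
#'   unpaired two-tailed t-test on per-unit means, the two-way ANOVA on the
#'   binned group histograms, and histogram/overlay PNGs.
#'
#' Seeds are derived per unit and stage from the config's global seed
#' ([deriveSeed()]), so a rerun with the same config and manifest
#' reproduces every numerical output bit for bit. A provenance JSON (config
#' hash, seeds, package version, per-stage wall time) and an ISO-8601
#' timestamped run log are written alongside the outputs; a failing stage
#' leaves a `FAILED` marker naming the stage.
#'
#' @param config path to a YAML pipeline configuration, or the list
#'   returned by [readPipelineConfig()].
#' @param outDir output directory (created; reused if existing).
#' @param manifest optional path to a run-manifest CSV
#'   ([readRunManifest()]) of pre-existing cubes; when given, the simulate
#'   stage is skipped.
#' @return Invisibly, a list with the per-unit summary table, the modality
#'   selections per group, the group tests and the provenance record.
#' @export
runPipeline <- function(config, outDir, manifest = NULL) {
  cfg <- if (is.character(config)) readPipelineConfig(config) else config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  cat("", file = logFile)
  failed <- file.path(outDir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stageTimes <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    .logLine(logFile, "stage %s: start", name)
    res <- tryCatch(force(expr), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 failed)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stageTimes[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    .logLine(logFile, "stage %s: done (%.2f s)", name, stageTimes[[name]])
    res
  }

  acq <- cfg$acquisition
  units <- stage("simulate", {
    if (!is.null(manifest)) {
      man <- readRunManifest(manifest)
      lapply(seq_len(nrow(man)), function(i) as.list(man[i, ]))
    } else {
      if (length(cfg$scene) == 0L) stop("config has no scene units")
      lapply(seq_along(cfg$scene), function(i) {
        u <- cfg$scene[[i]]
        useed <- deriveSeed(cfg$seed, i)
        spec <- .sceneFromConfig(u, acq@frameShape, useed)
        truth <- buildScene(spec)
        cube <- simulateDecayCube(truth, acq, deriveSeed(useed, 1L))
        chans <- simulateIntensityImages(truth, acq, deriveSeed(useed, 2L))
        udir <- file.path(outDir, "units", u$label)
        dir.create(udir, showWarnings = FALSE, recursive = TRUE)
        cubePath <- file.path(udir, "cube.tif")
        writeDecayCube(cube, cubePath,
                       meta = list(seed = useed, unit = u$label,
                                   group = u$group %||% "group",
                                   scene = u))
        egfp <- file.path(udir, "egfp.tif")
        mcherry <- file.path(udir, "mcherry.tif")
        writeIntensityImage(chans$egfp, egfp)
        writeIntensityImage(chans$mcherry, mcherry)
        writeParameterMaps(truth, udir, stem = "truth",
                           meta = list(seed = useed))
        list(unit = u$label, group = u$group %||% "group",
             organ = u$organ %||% "", cube = cubePath,
             egfp = egfp, mcherry = mcherry, seed = useed)
      })
    }
  })

  fitted <- stage("fit", {
    lapply(units, function(u) {
      cube <- readDecayCube(u$cube)
      inten <- readIntensityImage(u$egfp) + readIntensityImage(u$mcherry)
      mask <- do.call(intensityMask,
                      c(list(intensity = inten), cfg$threshold))
      maps <- fitCube(cube, mask, cfg$fit)
      udir <- file.path(outDir, "units", u$unit)
      dir.create(udir, showWarnings = FALSE, recursive = TRUE)
      writeParameterMaps(maps, udir, stem = "fit",
                         meta = list(unit = u$unit,
                                     maskRule = maskProvenance(mask)))
      writeMask(mask, file.path(udir, "mask.tif"))
      writePixelTable(maps, file.path(udir, "pixels.csv"))
      .logLine(logFile, "unit %s: %d/%d pixels fitted", u$unit,
               sum(fitOkMap(maps)), length(fitOkMap(maps)))
      list(unit = u$unit, group = u$group, maps = maps, mask = mask,
           label = u$unit)
    })
  })

  results <- stage("analyze", {
    summary <- summarizeUnits(fitted)
    utils::write.csv(summary, file.path(outDir, "unit_summary.csv"),
                     row.names = FALSE)
    field <- cfg$analysis$field
    byGroup <- split(fitted, vapply(fitted, `[[`, "", "group"))
    pooled <- lapply(byGroup, function(us) {
      unlist(lapply(us, function(u) {
        maskedValues(u$maps, u$mask, field)$value
      }))
    })
    modality <- lapply(names(pooled), function(g) {
      sel <- selectModality(pooled[[g]], seed = deriveSeed(cfg$seed, 9000L))
      plotMixtureHistogram(pooled[[g]], sel,
                           main = sprintf("%s: %s", g, field),
                           file = file.path(outDir,
                                            sprintf("hist_%s.png", g)))
      m <- if (sel$k == 2L) sel$model2 else sel$model1
      list(group = g, k = sel$k, deltaBic = sel$deltaBic,
           weights = mixWeights(m), means = mixMeans(m), sds = mixSds(m),
           bic = c(k1 = scoreBIC(sel$model1), k2 = scoreBIC(sel$model2)))
    })
    jsonlite::write_json(modality, file.path(outDir, "mixture_models.json"),
                         auto_unbox = TRUE, digits = 9, pretty = TRUE)
    tests <- list()
    ok <- summary[!summary$flagged, ]
    grps <- unique(ok$group)
    if (length(grps) >= 2L) {
      a <- ok$meanA1[ok$group == grps[1]]
      b <- ok$meanA1[ok$group == grps[2]]
      if (length(a) >= 2L && length(b) >= 2L) {
        tt <- compareGroups(a, b)
        tests$t_test <- list(groups = grps[1:2],
                             statistic = tt@statistic, p = tt@pValue,
                             direction = tt@effectDirection)
      }
      perUnit <- lapply(byGroup[grps[1:2]], function(us) {
        vals <- lapply(us, function(u)
          maskedValues(u$maps, u$mask, field)$value)
        names(vals) <- vapply(us, `[[`, "", "unit")
        vals
      })
      if (all(vapply(perUnit, length, 0L) >= 2L)) {
        ht <- histogramTable(perUnit, binWidth = cfg$analysis$binWidth,
                             range = if (field == "a1") c(0, 1) else c(0, 6))
        av <- compareGroups(ht, test = "two_way_anova")
        tests$two_way_anova <- list(groups = grps[1:2],
                                    statistic = av@statistic, p = av@pValue,
                                    direction = av@effectDirection)
      }
    }
    jsonlite::write_json(tests, file.path(outDir, "group_tests.json"),
                         auto_unbox = TRUE, digits = 9, pretty = TRUE)
    list(summary = summary, modality = modality, tests = tests)
  })

  provenance <- list(
    package_version = as.character(utils::packageVersion("flimetab")),
    config_hash = cfg$hash %||% .contentHash(cfg),
    global_seed = cfg$seed,
    unit_seeds = vapply(units, function(u) as.integer(u$seed), integer(1)),
    stage_seconds = stageTimes,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(provenance, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(provenance = provenance)))
}
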