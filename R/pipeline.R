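## end-to-end driver: configuration, staged execution, report emission.

#' Configuration of a full pipeline run
#'
#' Exactly one input mode: \code{"simulate"} (synthetic cohort from
#' \code{simulation}), \code{"coordinates"} (read a coordinate table through
#' \code{mapping}) or \code{"images"} (detect nuclei in per-frame TIFF
#' stacks). Settings may also be loaded from a YAML file with
#' \code{\link{readRunConfig}}.
#'
#' @param mode input mode.
#' @param simulation a \linkS4class{SimulationConfig} (simulate mode).
#' @param detection a \linkS4class{DetectionParams} (images mode).
#' @param cutoff synchrony classification cutoff (> 0).
#' @param seed integer seed; overrides the simulation seed.
#' @param coordinatePath coordinate table path (coordinates mode).
#' @param mapping a \code{\link{coordinateMapping}} (coordinates mode).
#' @param imagePaths character vector of per-frame TIFF paths, time order
#'   (images mode).
#' @param imageSpacing,imageInterval voxel pitch (um) and frame interval (h)
#'   of the image series.
#' @param outcomes optional data.frame (embryo_id, outcome) with born/abort
#'   labels; simulate mode provides its own.
#' @param thirdCVGrid optional per-embryo third-round CV grid (simulate mode).
#' @param outDir optional directory for intermediate tables and the report.
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(mode = c("simulate", "coordinates", "images"),
                      simulation = simulationConfig(),
                      detection = detectionParams(),
                      cutoff = 0.15, seed = NULL,
                      coordinatePath = NULL, mapping = coordinateMapping(),
                      imagePaths = NULL, imageSpacing = c(0.8, 0.8, 2.0),
                      imageInterval = 1 / 6,
                      outcomes = NULL, thirdCVGrid = NULL, outDir = NULL) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (!is.null(seed)) simulation@seed <- as.integer(seed)
  if (mode == "coordinates" && is.null(coordinatePath))
    stop("coordinates mode needs coordinatePath")
  if (mode == "images" && is.null(imagePaths))
    stop("images mode needs imagePaths")
  structure(list(mode = mode, simulation = simulation, detection = detection,
                 cutoff = cutoff, coordinatePath = coordinatePath,
                 mapping = mapping, imagePaths = imagePaths,
                 imageSpacing = imageSpacing, imageInterval = imageInterval,
                 outcomes = outcomes, thirdCVGrid = thirdCVGrid,
                 outDir = outDir),
            class = "RunConfig")
}

#' Load a RunConfig from a YAML file
#'
#' Top-level keys mirror the \code{\link{runConfig}} arguments; the
#' \code{simulation} and \code{detection} blocks hold the fields of
#' \code{\link{simulationConfig}} and \code{\link{detectionParams}}.
#' Arguments passed through \code{...} override file values.
#'
#' @param path YAML file path.
#' @param ... overrides forwarded to \code{\link{runConfig}}.
#' @return a \code{"RunConfig"}.
#' @export
readRunConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$simulation)) args$simulation <- do.call(simulationConfig, y$simulation)
  if (!is.null(y$detection)) args$detection <- do.call(detectionParams, y$detection)
  for (k in c("mode", "cutoff", "seed", "coordinatePath", "imagePaths",
              "imageSpacing", "imageInterval", "thirdCVGrid", "outDir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  over <- list(...)
  args[names(over)] <- over
  do.call(runConfig, args)
}

collectObservations <- function(config) {
  switch(config$mode,
    simulate = {
      coh <- simulateCohort(config$simulation, thirdCVGrid = config$thirdCVGrid)
      list(observations = coh$observations,
           outcomes = coh$truth[, c("embryo_id", "outcome")],
           truth = coh$truth)
    },
    coordinates = list(
      observations = readCoordinates(config$coordinatePath, config$mapping),
      outcomes = config$outcomes, truth = NULL),
    images = {
      obs <- do.call(rbind, lapply(seq_along(config$imagePaths), function(i) {
        vg <- readVolumeTIFF(config$imagePaths[i], config$imageSpacing,
                             time = (i - 1) * config$imageInterval,
                             frameIndex = i)
        detectFrame(vg, config$detection, embryoId = "embryo")
      }))
      list(observations = obs, outcomes = config$outcomes, truth = NULL)
    })
}

#' Run the full analysis pipeline
#'
#' Executes the staged workflow — obtain observations (simulate, read or
#' detect), link lineages, derive count curves, stage durations and
#' synchrony profiles, compute per-frame morphometrics, then the cohort
#' statistics (ROC on the third CV and the high/low cross-tabulation when
#' outcome labels exist). Identical configuration and seed give identical
#' output; when \code{outDir} is set every intermediate table is written
#' there.
#'
#' @param config a \code{\link{runConfig}}.
#' @return a list of class \code{"pipelineRun"}: observations, lineages,
#'   curves, stages, profiles (per-embryo data.frame), morphometrics,
#'   failed (ids of unanalyzable embryos), roc, cohort, truth (simulate
#'   mode), configHash, version.
#' @examples
#' run <- runPipeline(runConfig("simulate",
#'   simulation = simulationConfig(nEmbryos = 3, seed = 11)))
#' run$profiles
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  inp <- collectObservations(config)
  obs <- inp$observations
  ids <- unique(obs$embryo_id)
  lineages <- list(); curves <- list(); stages <- list(); morpho <- list()
  profRows <- list(); failed <- character()
  for (id in ids) {
    eo <- obs[obs$embryo_id == id, , drop = FALSE]
    tr <- linkTracks(eo)
    lineages[[id]] <- tr
    if ("tracking_failure" %in% tr@flags) {
      failed <- c(failed, id)
      next
    }
    curves[[id]] <- countCurve(eo)
    stages[[id]] <- stageDurations(curves[[id]])
    morpho[[id]] <- morphometricSeries(eo)
    pr <- synchronyProfile(tr, config$cutoff)
    profRows[[id]] <- data.frame(embryo_id = id,
                                 second_diff_norm = secondDiffNorm(pr),
                                 third_cv = thirdCV(pr),
                                 fourth_cv = fourthCV(pr),
                                 synchrony_class = synchronyClass(pr))
  }
  profiles <- do.call(rbind, profRows)
  rownames(profiles) <- NULL
  roc <- NULL; cohort <- NULL
  outc <- inp$outcomes
  if (!is.null(outc) && !is.null(profiles)) {
    outc <- outc[outc$embryo_id %in% profiles$embryo_id, , drop = FALSE]
    lab <- outc$outcome[match(profiles$embryo_id, outc$embryo_id)]
    if (length(unique(lab)) == 2L)
      roc <- rocAnalysis(profiles$third_cv, lab)
    cohort <- cohortReport(profiles, outc, config$cutoff)
  }
  run <- list(observations = obs, lineages = lineages, curves = curves,
              stages = stages, profiles = profiles,
              morphometrics = if (length(morpho)) do.call(rbind, morpho) else NULL,
              failed = failed, roc = roc, cohort = cohort,
              truth = inp$truth, cutoff = config$cutoff,
              seed = config$simulation@seed,
              configHash = configHash(paste(deparse(config), collapse = "")),
              version = as.character(utils::packageVersion("EmbryoSynchrony")))
  class(run) <- "pipelineRun"
  if (!is.null(config$outDir)) emitReport(run, config$outDir)
  run
}

#' Emit the run report and intermediate tables
#'
#' Writes the observation, profile and morphometric tables, a
#' machine-readable JSON report and a human-readable text report carrying
#' every statistic with its provenance (config hash, seed, package
#' version). An empty cohort produces a valid report stating zero embryos.
#'
#' @param run a \code{"pipelineRun"}.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
emitReport <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(run$observations) && nrow(run$observations)) {
    paths["observations"] <- file.path(dir, "observations.tsv")
    writeCoordinates(run$observations, paths["observations"])
  }
  nProfiles <- if (is.null(run$profiles)) 0L else nrow(run$profiles)
  if (nProfiles) {
    paths["profiles"] <- file.path(dir, "synchrony_profiles.tsv")
    utils::write.table(run$profiles, paths["profiles"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$morphometrics)) {
    paths["morphometrics"] <- file.path(dir, "morphometrics.tsv")
    utils::write.table(run$morphometrics, paths["morphometrics"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  js <- list(config_hash = run$configHash, seed = run$seed,
             version = run$version, n_embryos = nProfiles,
             failed = run$failed, cutoff = run$cutoff)
  if (!is.null(run$cohort)) js$cohort <- unclass(run$cohort)
  if (!is.null(run$roc))
    js$roc <- list(selected_cutoff = selectedCutoff(run$roc),
                   at_selected = as.list(rocAt(run$roc, selectedCutoff(run$roc))))
  paths["json"] <- file.path(dir, "report.json")
  jsonlite::write_json(js, paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- c(sprintf("EmbryoSynchrony run report (version %s)", run$version),
           sprintf("config %s, seed %d", run$configHash, run$seed),
           sprintf("%d embryo(s) analyzed, %d failed tracking",
                   nProfiles, length(run$failed)))
  if (!is.null(run$cohort))
    txt <- c(txt, utils::capture.output(print(run$cohort)))
  if (!is.null(run$roc))
    txt <- c(txt, utils::capture.output(show(run$roc)))
  paths["text"] <- file.path(dir, "report.txt")
  writeLines(txt, paths["text"])
  invisible(paths)
}

#' @export
print.pipelineRun <- function(x, ...) {
  n <- if (is.null(x$profiles)) 0L else nrow(x$profiles)
  cat(sprintf("pipelineRun: %d embryo(s) analyzed, %d failed (seed %d, config %s)\n",
              n, length(x$failed), x$seed, x$configHash))
  if (!is.null(x$cohort)) print(x$cohort)
  invisible(x)
}
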