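#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations — simulation, preprocessing, model — a
#' master seed and an optional output directory into one validated object.
#' All stage randomness (cohort generation, splits, model training) derives
#' from the master seed through named substreams, so a pipeline run is a
#' pure function of its configuration.
#'
#' @param sim a [simulationConfig()].
#' @param preproc a [preprocConfig()].
#' @param mlp an [mlpConfig()].
#' @param mode `"loso"` or `"pooled"` evaluation protocol.
#' @param minBeats minimum valid beats per analysis window.
#' @param outDir optional directory for the feature table and report JSONs.
#' @param seed master seed.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(sim = simulationConfig(nSubjects = 6,
                                                  sessionsPerSubject = 4,
                                                  sessionDuration = 120),
                           preproc = preprocConfig(), mlp = mlpConfig(),
                           mode = c("loso", "pooled"), minBeats = 5,
                           outDir = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (!inherits(sim, "simulationConfig")) stopf("sim must be a simulationConfig")
  if (!inherits(preproc, "preprocConfig")) stopf("preproc must be a preprocConfig")
  if (!inherits(mlp, "mlpConfig")) stopf("mlp must be an mlpConfig")
  structure(list(sim = sim, preproc = preproc, mlp = mlp, mode = mode,
                 minBeats = minBeats, outDir = outDir, seed = seed),
            class = "pipelineConfig")
}

#' Run the full estimation pipeline
#'
#' Chains the stages: synthesize a cohort, condition every session and
#' extract its window features, then train and evaluate the SBP and DBP
#' models under the configured protocol. Idempotent per (config, seed);
#' stage timings and window counts are collected in the returned `log`.
#'
#' @param config a [pipelineConfig()].
#' @return list with `features` (the window-feature table), `reports`
#'   (per-target `bpEvaluation` objects) and `log` (stage timings/counters).
#' @examples
#' \dontrun{
#' out <- runPipeline(pipelineConfig(seed = 7))
#' out$reports$SBP
#' }
#' @export
runPipeline <- function(config = pipelineConfig()) {
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  sim <- config$sim
  sim$seed <- subSeed(config$seed, "simulate")
  cohort <- generateCohort(sim)
  log$simulate <- list(seconds = tic() - t0,
                       sessions = length(cohort$dataset))

  t0 <- tic()
  features <- datasetFeatures(cohort$dataset, cfg = config$preproc,
                              minBeats = config$minBeats)
  log$features <- list(seconds = tic() - t0,
                       windows = nrow(features),
                       rejectedWindows = sum(!features$valid))

  reports <- list()
  for (target in c("SBP", "DBP")) {
    t0 <- tic()
    reports[[target]] <- if (config$mode == "loso")
      runLosoExperiment(features, target, config$mlp,
                        seed = subSeed(config$seed, "split"))
    else
      runPooledExperiment(features, target, config$mlp,
                          seed = subSeed(config$seed, "split"))
    log[[paste0("model_", target)]] <- list(seconds = tic() - t0)
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(config$outDir, "features.csv"),
                     row.names = FALSE)
    for (target in names(reports))
      writeEvaluationReport(reports[[target]],
                            file.path(config$outDir,
                                      sprintf("report_%s.json", tolower(target))))
  }
  list(features = features, reports = reports, log = log)
}

#' Build a tiny quickstart fixture on disk
#'
#' Writes a 2-subject, 60-s-per-session cohort in the session directory
#' format, with a dataset manifest and the per-session ground truth, for use
#' in documentation and smoke tests.
#'
#' @param outDir output directory.
#' @param seed master seed.
#' @return `invisible(outDir)`.
#' @export
makeQuickstartFixture <- function(outDir, seed = 1) {
  cfg <- simulationConfig(nSubjects = 2, sessionsPerSubject = 2,
                          sessionDuration = 60, seed = seed)
  cohort <- generateCohort(cfg)
  writeDataset(cohort$dataset, outDir)
  for (sid in names(cohort$groundTruths)) {
    gt <- cohort$groundTruths[[sid]]
    writeLines(jsonlite::toJSON(list(session_id = sid, beats = gt$beats,
                                     windows = gt$windows),
                                auto_unbox = TRUE, digits = 10),
               file.path(outDir, sid, "ground_truth.json"))
  }
  invisible(outDir)
}
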