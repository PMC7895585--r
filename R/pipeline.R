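# End-to-end pipeline over the synthetic experiment: simulate trials
# condition by condition, band-pass the mu rhythm, slice the imagery
# window, select one threshold per subject-task condition on the
# trial-averaged correlation matrix, accumulate regional connectivity
# values, then normalise by the pooled resting baseline into CIR features.

.conditionSeed <- function(seed, subject, taskIndex) {
  as.integer((abs(as.numeric(seed)) * 131 + as.numeric(subject) * 17 +
                taskIndex) %% 2147483629)
}

#' Run the synthetic experiment end to end
#'
#' Simulates every subject-task-trial combination of `config`, computes
#' per-trial imagery-window correlation matrices on the mu rhythm, selects
#' one threshold per subject-task condition (on the trial-averaged matrix;
#' or uses `globalDelta` for all conditions), computes the regional
#' connectivity values, and forms CIR features against the pooled resting
#' baseline. With `baselineMode = "silence"` the baseline is the mean
#' imagery-window connectivity of the silence task pooled over all
#' subjects; with `"preparation"` it is the mean preparation-stage (0-3 s)
#' connectivity pooled over all trials of all tasks.
#'
#' @param config a [SimulationConfig-class].
#' @param grid,nReps,seed threshold-selection controls (see
#'   [selectThreshold()]); `seed = NULL` uses the config seed.
#' @param baselineMode `"silence"` or `"preparation"`.
#' @param globalDelta optional fixed threshold overriding per-condition
#'   selection.
#' @param absolute threshold |r| instead of signed r.
#' @param verbose print per-condition progress.
#' @return a [CirPipelineResult-class]; `featureTable()` has one row per
#'   trial with columns subject, task, trial, delta, C_C3/C_C4/C_Cz and
#'   CIR_C3/CIR_C4/CIR_Cz.
#' @export
runExperiment <- function(config = simulationConfig(),
                          grid = seq(0.5, 0.95, by = 0.05),
                          nReps = 100, seed = NULL,
                          baselineMode = c("silence", "preparation"),
                          globalDelta = NULL, absolute = FALSE,
                          verbose = FALSE) {
  baselineMode <- match.arg(baselineMode)
  validObject(config)
  if (is.null(seed)) seed <- config@seed
  tasks <- taskLabels()
  regions <- c("C3", "C4", "Cz")
  refCache <- new.env(parent = emptyenv())
  rows <- list()
  selections <- list()
  for (s in seq_len(config@nSubjects)) {
    for (ti in seq_along(tasks)) {
      task <- tasks[ti]
      Rs <- vector("list", config@nTrialsPerTask)
      Rprep <- vector("list", config@nTrialsPerTask)
      for (tr in seq_len(config@nTrialsPerTask)) {
        mu <- bandpassMu(simulateTrial(config, task, s, tr),
                         config@muBand[1], config@muBand[2])
        Rs[[tr]] <- correlationMatrix(extractStage(mu, "imagery"))
        if (baselineMode == "preparation")
          Rprep[[tr]] <- correlationMatrix(extractStage(mu, "preparation"))
      }
      if (is.null(globalDelta)) {
        sel <- selectThreshold(averageCorrelation(Rs), grid = grid,
                               nReps = nReps,
                               seed = .conditionSeed(seed, s, ti),
                               absolute = absolute, refCache = refCache)
        delta <- sel@chosen
      } else delta <- globalDelta
      selections[[length(selections) + 1]] <-
        data.frame(subject = s, task = task, delta = delta)
      for (tr in seq_len(config@nTrialsPerTask)) {
        cImage <- vapply(regions, function(rg)
          regionalConnectivity(Rs[[tr]], delta, rg, absolute = absolute), 0)
        row <- data.frame(subject = s, task = task, trial = tr,
                          delta = delta, C_C3 = cImage[["C3"]],
                          C_C4 = cImage[["C4"]], C_Cz = cImage[["Cz"]])
        if (baselineMode == "preparation") {
          cPrep <- vapply(regions, function(rg)
            regionalConnectivity(Rprep[[tr]], delta, rg,
                                 absolute = absolute), 0)
          row$Cprep_C3 <- cPrep[["C3"]]
          row$Cprep_C4 <- cPrep[["C4"]]
          row$Cprep_Cz <- cPrep[["Cz"]]
        }
        rows[[length(rows) + 1]] <- row
      }
      if (verbose)
        message(sprintf("subject %d task %-6s delta = %.2f", s, task,
                        delta))
    }
  }
  features <- do.call(rbind, rows)
  baselines <- vapply(regions, function(rg) {
    col <- paste0(if (baselineMode == "silence") "C_" else "Cprep_", rg)
    vals <- if (baselineMode == "silence")
      features[features$task == "S", col] else features[[col]]
    restBaseline(vals)
  }, 0)
  for (rg in regions)
    features[[paste0("CIR_", rg)]] <-
      cirRatio(features[[paste0("C_", rg)]], baselines[[rg]])
  new("CirPipelineResult", features = features, baselines = baselines,
      selections = do.call(rbind, selections),
      baselineMode = baselineMode, config = config)
}
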