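# Synthetic motor-imagery EEG generator. Three latent mu-band sources,
# one per region centre (C3, C4, Cz), are mixed into the 60 channels with
# distance-decaying weights. Task-active sources get an elevated gain
# during the imagery window, so the inter-channel correlation structure
# agglomerates around the task-appropriate electrodes -- the network
# consequence of event-related desynchronisation that the CIR feature
# consumes.

.REGION_CENTERS <- c("C3", "C4", "Cz")

# run expr with a temporary RNG state; restores the caller's stream
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stable per-trial seed
#'
#' Mixes the master seed with subject, task and trial indices by integer
#' arithmetic so every trial gets a reproducible, parallel-safe seed below
#' 2^31 regardless of generation order.
#'
#' @param seed master seed (integer).
#' @param subject subject index.
#' @param task task label (one of [taskLabels()]).
#' @param trial trial index.
#' @return integer seed.
#' @export
trialSeed <- function(seed, subject, task, trial) {
  ti <- match(as.character(task), taskLabels())
  if (is.na(ti)) stop("unknown task '", task, "'")
  v <- (abs(as.numeric(seed)) %% 2^31) * 1000003 +
    as.numeric(subject) * 10007 + ti * 257 + as.numeric(trial)
  as.integer(v %% 2147483629)
}

#' Build a simulation configuration
#'
#' Defaults reproduce the experiment design emulated by the generator:
#' 12 subjects, 7 tasks, 10 trials each (840 trials), 10 s at 250 Hz with
#' stage boundaries 0/3/4/8/10 s. Gains and noise are free generator
#' parameters chosen so the silent state keeps a connected mu-band network
#' while active regions show clearly elevated within-region correlation.
#'
#' @param nSubjects number of subjects.
#' @param nTrialsPerTask trials per subject and task.
#' @param fs sampling rate, Hz.
#' @param trialLength trial duration, seconds.
#' @param stageBounds stage boundaries, seconds.
#' @param taskRegionMap task -> active region centres map.
#' @param couplingGainActive mixing gain of active sources in the imagery
#'   window.
#' @param couplingGainRest baseline mixing gain.
#' @param spatialDecay distance decay constant of mixing weights (montage
#'   grid units).
#' @param noiseSd sd of broadband white channel noise.
#' @param muBand frequency band of the latent sources, Hz.
#' @param seed master seed.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nSubjects = 1, nTrialsPerTask = 2)
#' @export
simulationConfig <- function(nSubjects = 12, nTrialsPerTask = 10,
                             fs = 250, trialLength = 10,
                             stageBounds = c(0, 3, 4, 8, 10),
                             taskRegionMap = defaultTaskRegionMap(),
                             couplingGainActive = 5,
                             couplingGainRest = 2,
                             spatialDecay = 1.5,
                             noiseSd = 3,
                             muBand = c(8, 13),
                             seed = 1L) {
  new("SimulationConfig",
      nSubjects = nSubjects, nTrialsPerTask = nTrialsPerTask, fs = fs,
      trialLength = trialLength, stageBounds = stageBounds,
      taskRegionMap = taskRegionMap,
      couplingGainActive = couplingGainActive,
      couplingGainRest = couplingGainRest, spatialDecay = spatialDecay,
      noiseSd = noiseSd, muBand = muBand, seed = seed)
}

# unit-variance band-limited Gaussian source; 1 s padding on both sides
# absorbs filter edge transients
.muSource <- function(n, fs, band) {
  pad <- round(fs)
  s <- .bandpassVector(rnorm(n + 2 * pad), band[1], band[2], fs, order = 4)
  s <- s[(pad + 1):(pad + n)]
  s / sd(s)
}

#' Simulate one motor-imagery trial
#'
#' Channel c receives `sum_r m_cr(t) s_r(t) + e_c(t)` where `s_r` is a
#' unit-variance 8-13 Hz Gaussian source at region centre r,
#' `m_cr(t) = g_r(t) exp(-d(c, r) / spatialDecay)` with `g_r(t)` equal to
#' the active gain for task-active regions during the imagery window and
#' to the rest gain otherwise, and `e_c` is white noise. Identical
#' arguments reproduce identical trials bit for bit.
#'
#' @param config a [SimulationConfig-class].
#' @param task task label.
#' @param subject subject index.
#' @param trial trial index.
#' @return a [Recording-class] (60 channels x fs * trialLength samples).
#' @examples
#' rec <- simulateTrial(simulationConfig(), "LH", subject = 1, trial = 1)
#' @export
simulateTrial <- function(config, task, subject = 1L, trial = 1L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  task <- as.character(task)
  if (!task %in% names(config@taskRegionMap))
    stop("unknown task '", task, "'; must be one of ",
         paste(taskLabels(), collapse = ", "))
  active <- config@taskRegionMap[[task]]
  if (length(active) > 0 && config@couplingGainActive <= 0)
    warning("task '", task, "' expects activity but couplingGainActive <= 0")

  fs <- config@fs
  nSamp <- round(fs * config@trialLength)
  mont <- makeMontage()
  nChan <- nrow(mont)

  # static distance weights, channels x regions
  W <- vapply(.REGION_CENTERS, function(r) {
    cx <- mont$x[mont$label == r]
    cy <- mont$y[mont$label == r]
    exp(-sqrt((mont$x - cx)^2 + (mont$y - cy)^2) / config@spatialDecay)
  }, numeric(nChan))

  # time-varying gains, regions x samples
  G <- matrix(config@couplingGainRest, nrow = length(.REGION_CENTERS),
              ncol = nSamp, dimnames = list(.REGION_CENTERS, NULL))
  imStart <- floor(config@stageBounds[3] * fs) + 1
  imEnd <- floor(config@stageBounds[4] * fs)
  if (length(active))
    G[active, imStart:imEnd] <- config@couplingGainActive

  seed <- trialSeed(config@seed, subject, task, trial)
  data <- .withSeed(seed, {
    S <- t(vapply(.REGION_CENTERS,
                  function(r) .muSource(nSamp, fs, config@muBand),
                  numeric(nSamp)))
    noise <- matrix(rnorm(nChan * nSamp, sd = config@noiseSd),
                    nrow = nChan)
    W %*% (S * G) + noise
  })

  new("Recording", data = unname(data), labels = mont$label, fs = fs,
      stageBounds = config@stageBounds,
      subject = as.character(subject), task = task,
      trial = as.integer(trial), history = "simulated")
}

#' Simulate the full experiment
#'
#' Generates `nSubjects x 7 tasks x nTrialsPerTask` trials (840 under
#' defaults). With `outDir` the trials are written to disk (one file per
#' trial, CSV or EDF) together with a `manifest.csv` (columns subject,
#' task, trial, path, seed); otherwise the recordings are returned in a
#' list with the manifest attached as attribute `"manifest"`.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir optional output directory.
#' @param format file format when writing, `"csv"` or `"edf"`.
#' @return list of [Recording-class] objects (invisibly when writing),
#'   with attribute `"manifest"`.
#' @export
simulateExperiment <- function(config = simulationConfig(), outDir = NULL,
                               format = c("csv", "edf")) {
  format <- match.arg(format)
  validObject(config)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  tasks <- taskLabels()
  n <- config@nSubjects * length(tasks) * config@nTrialsPerTask
  recs <- vector("list", n)
  manifest <- data.frame(subject = integer(n), task = character(n),
                         trial = integer(n), path = character(n),
                         seed = integer(n), stringsAsFactors = FALSE)
  k <- 0
  for (s in seq_len(config@nSubjects)) {
    for (task in tasks) {
      for (tr in seq_len(config@nTrialsPerTask)) {
        k <- k + 1
        rec <- simulateTrial(config, task, subject = s, trial = tr)
        path <- ""
        if (!is.null(outDir)) {
          safe <- gsub("&", "-", task, fixed = TRUE)
          path <- file.path(outDir, sprintf("s%02d_%s_t%02d.%s",
                                            s, safe, tr, format))
          writeRecording(rec, path, format = format)
        }
        recs[[k]] <- rec
        manifest[k, ] <- list(s, task, tr, path,
                              trialSeed(config@seed, s, task, tr))
      }
    }
  }
  attr(recs, "manifest") <- manifest
  if (!is.null(outDir)) {
    write.csv(manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
    return(invisible(recs))
  }
  recs
}
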