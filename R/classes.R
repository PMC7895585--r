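# Central S4 containers for the pipeline. All matrices are plain base
# matrices with channel labels carried separately so that validity checks
# stay cheap and explicit.

#' Multichannel EEG recording
#'
#' One trial of multichannel EEG: a channels-by-samples numeric matrix with
#' ordered channel labels, the sampling rate, the trial's stage boundaries
#' (preparation / cue / imagery / rest), and bookkeeping metadata. A
#' `history` slot records the processing steps applied (e.g. band-pass,
#' stage extraction), so downstream code can assert the filter-then-slice
#' order.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot labels character, one unique label per channel (row).
#' @slot fs sampling rate in Hz.
#' @slot stageBounds numeric vector of increasing stage boundaries in
#'   seconds (default \code{c(0, 3, 4, 8, 10)}).
#' @slot subject subject identifier.
#' @slot task task label, one of [taskLabels()] (or \code{NA}).
#' @slot trial trial index within the subject-task condition.
#' @slot history character log of processing steps.
#' @export
setClass("Recording",
  representation(
    data = "matrix", labels = "character", fs = "numeric",
    stageBounds = "numeric", subject = "character", task = "character",
    trial = "integer", history = "character"
  ),
  prototype(
    stageBounds = c(0, 3, 4, 8, 10), subject = NA_character_,
    task = NA_character_, trial = NA_integer_, history = character(0)
  )
)

setValidity("Recording", function(object) {
  msg <- character(0)
  if (nrow(object@data) != length(object@labels))
    msg <- c(msg, "number of rows of 'data' must equal length of 'labels'")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@stageBounds) >= 2 && any(diff(object@stageBounds) <= 0))
    msg <- c(msg, "'stageBounds' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Pearson correlation matrix between channels
#'
#' Symmetric N x N matrix of Pearson correlation coefficients between
#' channel signals, with unit diagonal and entries in \[-1, 1\].
#'
#' @slot values numeric N x N matrix.
#' @slot labels character channel labels in matrix order.
#' @export
setClass("CorrelationMatrix",
  representation(values = "matrix", labels = "character")
)

setValidity("CorrelationMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "'values' must be square")
  if (nrow(v) != length(object@labels))
    msg <- c(msg, "dimension of 'values' must match length of 'labels'")
  if (nrow(v) == ncol(v)) {
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "'values' must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
    if (max(abs(v)) > 1 + 1e-12) msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Thresholded brain functional network
#'
#' Binary adjacency obtained by thresholding a correlation matrix, together
#' with the retained correlation weights (r on surviving edges, 0
#' elsewhere) and the threshold used. Self-loops are excluded: the network
#' is defined over distinct electrode pairs.
#'
#' @slot adjacency numeric N x N matrix with entries in \{0, 1\}, symmetric,
#'   zero diagonal.
#' @slot weights numeric N x N matrix; nonzero only where adjacency is 1.
#' @slot labels character node labels.
#' @slot delta threshold used to build the graph (\code{NA} if unknown).
#' @export
setClass("BfnGraph",
  representation(
    adjacency = "matrix", weights = "matrix", labels = "character",
    delta = "numeric"
  ),
  prototype(delta = NA_real_)
)

setValidity("BfnGraph", function(object) {
  a <- object@adjacency
  w <- object@weights
  msg <- character(0)
  if (nrow(a) != ncol(a)) msg <- c(msg, "'adjacency' must be square")
  if (!identical(dim(a), dim(w)))
    msg <- c(msg, "'weights' must have the same dimension as 'adjacency'")
  if (nrow(a) != length(object@labels))
    msg <- c(msg, "dimension must match length of 'labels'")
  if (nrow(a) == ncol(a)) {
    if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0 or 1")
    if (max(abs(a - t(a))) > 0) msg <- c(msg, "'adjacency' must be symmetric")
    if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be 0")
    if (identical(dim(a), dim(w)) && any(w[a == 0] != 0))
      msg <- c(msg, "'weights' must be zero where 'adjacency' is 0")
  }
  if (length(msg)) msg else TRUE
})

#' Small-world indices of a thresholded network
#'
#' Clustering and path-length statistics of a network together with the
#' corresponding averages over a random-reference ensemble with the same
#' number of nodes and edges, and the derived ratios gamma = C_real/C_rand,
#' lambda = L_real/L_rand and the comprehensive index sigma = gamma/lambda.
#' sigma > 1 indicates small-world organisation.
#'
#' @slot CReal mean local clustering coefficient of the network.
#' @slot CRand mean clustering of the random reference ensemble.
#' @slot LReal characteristic path length (mean shortest path over
#'   connected pairs).
#' @slot LRand path length of the random reference ensemble.
#' @slot gamma C_real / C_rand.
#' @slot lambda L_real / L_rand.
#' @slot sigma gamma / lambda.
#' @slot K mean node degree 2E/N.
#' @slot nRandom number of random-reference realizations averaged.
#' @slot connected TRUE if the network is connected.
#' @export
setClass("SmallWorldMetrics",
  representation(
    CReal = "numeric", CRand = "numeric", LReal = "numeric",
    LRand = "numeric", gamma = "numeric", lambda = "numeric",
    sigma = "numeric", K = "numeric", nRandom = "numeric",
    connected = "logical"
  )
)

setValidity("SmallWorldMetrics", function(object) {
  if (is.finite(object@sigma) && is.finite(object@gamma) &&
      is.finite(object@lambda) &&
      abs(object@sigma - object@gamma / object@lambda) > 1e-12)
    return("sigma must equal gamma/lambda")
  TRUE
})

#' Result of the threshold-selection procedure
#'
#' Per-candidate audit table (threshold, mean degree K, small-world
#' metrics, feasibility under K >= ln N) and the chosen threshold: the
#' feasible candidate with maximal sigma, ties broken toward the larger
#' threshold.
#'
#' @slot grid candidate thresholds, ascending.
#' @slot table data.frame with one row per candidate.
#' @slot chosen the selected threshold.
#' @slot bound the connectivity bound ln(N).
#' @slot nReps random-reference realizations per candidate.
#' @slot seed RNG seed used.
#' @export
setClass("ThresholdSelection",
  representation(
    grid = "numeric", table = "data.frame", chosen = "numeric",
    bound = "numeric", nReps = "numeric", seed = "numeric"
  )
)

setValidity("ThresholdSelection", function(object) {
  if (length(object@chosen) == 1 && !is.na(object@chosen) &&
      !any(abs(object@grid - object@chosen) < 1e-9))
    return("'chosen' must be one of the grid candidates")
  TRUE
})

#' Configuration of the synthetic EEG experiment
#'
#' Parameters of the seeded generator emulating the motor-imagery
#' experiment design: 12 subjects x 7 tasks x 10 trials of 10 s at 250 Hz,
#' with stage boundaries 0/3/4/8/10 s. Each region centre (C3, C4, Cz)
#' drives one latent mu-band source; channels receive distance-weighted
#' mixtures whose gain is elevated for task-active regions during the
#' imagery window.
#'
#' @slot nSubjects number of subjects.
#' @slot nTrialsPerTask trials per subject and task.
#' @slot fs sampling rate, Hz.
#' @slot trialLength trial duration, seconds.
#' @slot stageBounds stage boundaries in seconds
#'   (preparation/cue/imagery/rest).
#' @slot taskRegionMap named list mapping each task label to its active
#'   region centres (subset of C3/C4/Cz).
#' @slot couplingGainActive mixing amplitude of active-region sources
#'   during the imagery window.
#' @slot couplingGainRest baseline mixing amplitude.
#' @slot spatialDecay electrode-distance decay constant of mixing weights.
#' @slot noiseSd standard deviation of the broadband channel noise.
#' @slot muBand mu-rhythm band of the latent sources, Hz.
#' @slot seed master RNG seed; per-trial seeds are derived from it.
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "numeric", nTrialsPerTask = "numeric", fs = "numeric",
    trialLength = "numeric", stageBounds = "numeric",
    taskRegionMap = "list", couplingGainActive = "numeric",
    couplingGainRest = "numeric", spatialDecay = "numeric",
    noiseSd = "numeric", muBand = "numeric", seed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (any(diff(object@stageBounds) <= 0))
    msg <- c(msg, "'stageBounds' must be strictly increasing")
  if (object@couplingGainActive < 0 || object@couplingGainRest < 0)
    msg <- c(msg, "coupling gains must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (!all(taskLabels() %in% names(object@taskRegionMap)))
    msg <- c(msg, "'taskRegionMap' must cover all 7 task labels")
  bad <- setdiff(unlist(object@taskRegionMap), c("C3", "C4", "Cz"))
  if (length(bad))
    msg <- c(msg, paste0("unknown region centres in map: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-trial CIR feature vector
#'
#' The three-dimensional feature of one trial: for each region (C3, C4,
#' Cz), the connectivity value C during the imagery window, the pooled
#' resting baseline, and their absolute ratio, the connectivity increment
#' rate CIR = |C_image / C_rest_bar|.
#'
#' @slot subject subject identifier.
#' @slot task task label.
#' @slot trial trial index.
#' @slot delta threshold used.
#' @slot cImage named numeric, imagery-window C per region.
#' @slot cRestBar named numeric, baseline C per region.
#' @slot cir named numeric, CIR per region.
#' @export
setClass("CirFeature",
  representation(
    subject = "character", task = "character", trial = "integer",
    delta = "numeric", cImage = "numeric", cRestBar = "numeric",
    cir = "numeric"
  )
)

setValidity("CirFeature", function(object) {
  if (any(object@cir < 0, na.rm = TRUE)) return("'cir' entries must be >= 0")
  ok <- abs(object@cir - abs(object@cImage / object@cRestBar)) < 1e-9
  if (!all(ok, na.rm = TRUE)) return("'cir' must equal |cImage / cRestBar|")
  TRUE
})

#' Pairwise multivariate test results over tasks
#'
#' Symmetric matrix of p-values for the 21 unordered task pairs, from a
#' two-sample multivariate (Hotelling-type) test on the 3-D feature
#' vectors, with a per-coordinate univariate breakdown alongside.
#'
#' @slot pTable numeric 7 x 7 symmetric matrix, NA diagonal.
#' @slot method character description of the test used.
#' @slot univariate data.frame of per-coordinate p-values per pair.
#' @export
setClass("PairwiseStats",
  representation(pTable = "matrix", method = "character",
                 univariate = "data.frame")
)

setValidity("PairwiseStats", function(object) {
  p <- object@pTable
  if (nrow(p) != ncol(p)) return("'pTable' must be square")
  if (max(abs(p - t(p)), na.rm = TRUE) > 1e-12)
    return("'pTable' must be symmetric")
  if (!all(is.na(diag(p)))) return("diagonal of 'pTable' must be NA")
  TRUE
})

#' One-versus-rest SVM cross-validation result
#'
#' Per-repeat, per-fold, per-task accuracies of the repeated stratified
#' 5-fold cross-validation, a fold x task table averaged over repeats,
#' per-task mean and sd over folds, and the overall mean (mean of per-task
#' means). Accuracies are percentages.
#'
#' @slot accuracy numeric array repeats x folds x tasks.
#' @slot foldTask numeric folds x tasks matrix averaged over repeats.
#' @slot perTaskMean named numeric per-task mean accuracy.
#' @slot perTaskSd named numeric per-task sd over folds.
#' @slot overall overall mean accuracy.
#' @slot folds,repeats CV layout.
#' @slot trainParts,testParts task-parts per rotation.
#' @slot foldAssignments list (one integer vector per repeat) recording
#'   which fold each trial was tested in.
#' @slot seed RNG seed used.
#' @export
setClass("ClassificationResult",
  representation(
    accuracy = "array", foldTask = "matrix", perTaskMean = "numeric",
    perTaskSd = "numeric", overall = "numeric", folds = "numeric",
    repeats = "numeric", trainParts = "numeric", testParts = "numeric",
    foldAssignments = "list", seed = "numeric"
  )
)

setValidity("ClassificationResult", function(object) {
  a <- object@accuracy
  if (any(a < 0 | a > 100, na.rm = TRUE))
    return("accuracies must lie in [0, 100] percent")
  if (abs(object@overall - mean(object@perTaskMean)) > 1e-9)
    return("'overall' must be the mean of per-task means")
  TRUE
})

#' Full synthetic-experiment pipeline result
#'
#' @slot features data.frame with one row per trial: subject, task, trial,
#'   delta, per-region connectivity values and CIRs.
#' @slot baselines named numeric, pooled resting C per region.
#' @slot selections data.frame of per-condition chosen thresholds.
#' @slot baselineMode "silence" or "preparation".
#' @slot config the [SimulationConfig] used.
#' @export
setClass("CirPipelineResult",
  representation(
    features = "data.frame", baselines = "numeric",
    selections = "data.frame", baselineMode = "character",
    config = "SimulationConfig"
  )
)
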