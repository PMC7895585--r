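# Accessors and show methods. Slots are never touched directly by user
# code; these generics are the supported surface.

#' @name accessors
#' @title Accessors for bfncir S4 containers
#' @param object an S4 object from this package.
#' @description Small generic accessors: channel labels, sampling rate,
#'   raw data matrix, correlation values, adjacency, edge weights, counts.
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("recData", function(object) standardGeneric("recData"))
#' @rdname accessors
#' @export
setGeneric("taskLabel", function(object) standardGeneric("taskLabel"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("trialIndex", function(object) standardGeneric("trialIndex"))
#' @rdname accessors
#' @export
setGeneric("stageBounds", function(object) standardGeneric("stageBounds"))
#' @rdname accessors
#' @export
setGeneric("processingHistory",
           function(object) standardGeneric("processingHistory"))
#' @rdname accessors
#' @export
setGeneric("corValues", function(object) standardGeneric("corValues"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))
#' @rdname accessors
#' @export
setGeneric("nodeCount", function(object) standardGeneric("nodeCount"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("graphDelta", function(object) standardGeneric("graphDelta"))
#' @rdname accessors
#' @export
setGeneric("chosenDelta", function(object) standardGeneric("chosenDelta"))
#' @rdname accessors
#' @export
setGeneric("auditTable", function(object) standardGeneric("auditTable"))
#' @rdname accessors
#' @export
setGeneric("cirValues", function(object) standardGeneric("cirValues"))
#' @rdname accessors
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("overallAccuracy",
           function(object) standardGeneric("overallAccuracy"))

#' @rdname accessors
#' @export
setMethod("channelLabels", "Recording", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "CorrelationMatrix",
          function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "BfnGraph", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("recData", "Recording", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("taskLabel", "Recording", function(object) object@task)
#' @rdname accessors
#' @export
setMethod("taskLabel", "CirFeature", function(object) object@task)
#' @rdname accessors
#' @export
setMethod("subjectId", "Recording", function(object) object@subject)
#' @rdname accessors
#' @export
setMethod("trialIndex", "Recording", function(object) object@trial)
#' @rdname accessors
#' @export
setMethod("stageBounds", "Recording", function(object) object@stageBounds)
#' @rdname accessors
#' @export
setMethod("processingHistory", "Recording",
          function(object) object@history)
#' @rdname accessors
#' @export
setMethod("corValues", "CorrelationMatrix", function(object) {
  v <- object@values
  dimnames(v) <- list(object@labels, object@labels)
  v
})
#' @rdname accessors
#' @export
setMethod("adjacency", "BfnGraph", function(object) {
  a <- object@adjacency
  dimnames(a) <- list(object@labels, object@labels)
  a
})
#' @rdname accessors
#' @export
setMethod("edgeWeights", "BfnGraph", function(object) {
  w <- object@weights
  dimnames(w) <- list(object@labels, object@labels)
  w
})
#' @rdname accessors
#' @export
setMethod("nodeCount", "BfnGraph", function(object) length(object@labels))
#' @rdname accessors
#' @export
setMethod("edgeCount", "BfnGraph",
          function(object) sum(object@adjacency) / 2)
#' @rdname accessors
#' @export
setMethod("graphDelta", "BfnGraph", function(object) object@delta)
#' @rdname accessors
#' @export
setMethod("chosenDelta", "ThresholdSelection",
          function(object) object@chosen)
#' @rdname accessors
#' @export
setMethod("auditTable", "ThresholdSelection", function(object) object@table)
#' @rdname accessors
#' @export
setMethod("cirValues", "CirFeature", function(object) object@cir)
#' @rdname accessors
#' @export
setMethod("featureTable", "CirPipelineResult",
          function(object) object@features)
#' @rdname accessors
#' @export
setMethod("pValues", "PairwiseStats", function(object) object@pTable)
#' @rdname accessors
#' @export
setMethod("overallAccuracy", "ClassificationResult",
          function(object) object@overall)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz\n",
              nrow(object@data), ncol(object@data), object@fs))
  cat(sprintf("  subject: %s  task: %s  trial: %s\n",
              object@subject, object@task, object@trial))
  if (length(object@history))
    cat("  history:", paste(object@history, collapse = " -> "), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("CorrelationMatrix: %d x %d, off-diagonal range [%.3f, %.3f]\n",
              nrow(object@values), ncol(object@values),
              min(off), max(off)))
})

setMethod("show", "BfnGraph", function(object) {
  cat(sprintf("BfnGraph: %d nodes, %d edges (delta = %s)\n",
              nodeCount(object), edgeCount(object),
              format(object@delta)))
})

setMethod("show", "SmallWorldMetrics", function(object) {
  cat(sprintf(
    "SmallWorldMetrics: gamma = %.3f, lambda = %.3f, sigma = %.3f, K = %.2f\n",
    object@gamma, object@lambda, object@sigma, object@K))
  cat(sprintf("  C_real = %.4f  C_rand = %.4f  L_real = %.3f  L_rand = %.3f (%d refs)\n",
              object@CReal, object@CRand, object@LReal, object@LRand,
              as.integer(object@nRandom)))
})

setMethod("show", "ThresholdSelection", function(object) {
  cat(sprintf("ThresholdSelection: chosen delta = %.2f (K >= ln N = %.2f)\n",
              object@chosen, object@bound))
  cat(sprintf("  %d candidates, %d feasible\n",
              nrow(object@table), sum(object@table$feasible)))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d subjects x 7 tasks x %d trials, %g s @ %g Hz\n",
    object@nSubjects, object@nTrialsPerTask, object@trialLength, object@fs))
  cat(sprintf("  gains active/rest = %g/%g, decay = %g, noise sd = %g, seed = %d\n",
              object@couplingGainActive, object@couplingGainRest,
              object@spatialDecay, object@noiseSd, as.integer(object@seed)))
})

setMethod("show", "CirFeature", function(object) {
  cat(sprintf("CirFeature: subject %s, task %s, trial %d (delta = %.2f)\n",
              object@subject, object@task, object@trial, object@delta))
  cat(sprintf("  CIR = [%s]\n",
              paste(sprintf("%s: %.3f", names(object@cir), object@cir),
                    collapse = ", ")))
})

setMethod("show", "PairwiseStats", function(object) {
  cat(sprintf("PairwiseStats (%s): %d pairwise comparisons\n",
              object@method, sum(!is.na(object@pTable)) / 2))
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf(
    "ClassificationResult: %d-fold CV x %d repeats, overall accuracy %.2f%%\n",
    as.integer(object@folds), as.integer(object@repeats), object@overall))
})

setMethod("show", "CirPipelineResult", function(object) {
  cat(sprintf("CirPipelineResult: %d trials, baseline mode '%s'\n",
              nrow(object@features), object@baselineMode))
  cat(sprintf("  baselines: %s\n",
              paste(sprintf("%s = %.3f", names(object@baselines),
                            object@baselines), collapse = ", ")))
})
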