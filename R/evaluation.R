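# Pairwise significance analysis of the 3-D feature vectors and
# one-versus-rest SVM classification with repeated stratified k-fold
# cross-validation.

.CIR_COLS <- c("CIR_C3", "CIR_C4", "CIR_Cz")

.featureMatrix <- function(features) {
  stopifnot(is.data.frame(features), all(.CIR_COLS %in% names(features)),
            "task" %in% names(features))
  as.matrix(features[, .CIR_COLS])
}

#' Pairwise multivariate tests over the seven tasks
#'
#' For each of the 21 unordered task pairs, tests whether the 3-D feature
#' vectors differ between the two tasks with a two-sample multivariate
#' analysis of variance (Hotelling-type; Pillai statistic). A univariate
#' per-coordinate breakdown (one-way ANOVA p per CIR coordinate) is
#' reported alongside.
#'
#' @param features data.frame with columns `task` and
#'   `CIR_C3`, `CIR_C4`, `CIR_Cz`.
#' @return a [PairwiseStats-class] with the symmetric 7 x 7 p-value table.
#' @export
pairwiseAnova <- function(features) {
  x <- .featureMatrix(features)
  task <- as.character(features$task)
  tasks <- taskLabels()
  present <- tasks[tasks %in% task]
  counts <- table(task)
  if (any(counts < 2))
    stop("task(s) with fewer than 2 trials: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  p <- matrix(NA_real_, length(tasks), length(tasks),
              dimnames = list(tasks, tasks))
  uni <- list()
  for (i in seq_along(tasks)) {
    for (j in seq_len(length(tasks) - i) + i) {
      a <- tasks[i]
      b <- tasks[j]
      if (!(a %in% present && b %in% present)) next
      sel <- task %in% c(a, b)
      g <- factor(task[sel], levels = c(a, b))
      if (sum(sel) - 2 < ncol(x))
        stop(sprintf("too few trials to test %s vs %s", a, b))
      fit <- manova(x[sel, ] ~ g)
      pv <- summary(fit, test = "Pillai")$stats[1, "Pr(>F)"]
      p[a, b] <- p[b, a] <- pv
      up <- vapply(seq_len(ncol(x)), function(k)
        summary(aov(x[sel, k] ~ g))[[1]][1, "Pr(>F)"], 0)
      uni[[length(uni) + 1]] <- data.frame(
        task1 = a, task2 = b, p = pv,
        p_C3 = up[1], p_C4 = up[2], p_Cz = up[3])
    }
  }
  new("PairwiseStats", pTable = p,
      method = "two-sample MANOVA (Pillai)",
      univariate = do.call(rbind, uni))
}

# one-vs-rest decision scores for a task against the rest
.ovrScore <- function(xtr, isPos, xte, cost) {
  y <- factor(ifelse(isPos, "pos", "neg"), levels = c("pos", "neg"))
  m <- e1071::svm(xtr, y, kernel = "radial", cost = cost, scale = FALSE)
  dv <- attr(predict(m, xte, decision.values = TRUE), "decision.values")
  if (colnames(dv)[1] == "pos/neg") dv[, 1] else -dv[, 1]
}

#' One-versus-rest SVM with repeated stratified cross-validation
#'
#' Per repeat, each task's trials are randomly split into `folds` equal
#' parts; rotation f trains one RBF SVM per task (that task against the
#' rest) on the other parts of every task and tests on the held-out
#' parts, so each rotation uses `7 * (folds - 1)` training and 7 testing
#' task-parts. Features are standardised with training-fold statistics
#' only. Test trials are assigned to the task with the largest decision
#' value; accuracies (percent) are accumulated per task per fold and
#' averaged over repeats.
#'
#' @param features data.frame with columns `task` and the three CIR
#'   coordinates.
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions (default 10).
#' @param seed RNG seed.
#' @param cost SVM regularisation constant.
#' @return a [ClassificationResult-class].
#' @export
ovrSvmCv <- function(features, folds = 5, repeats = 10, seed = 1L,
                     cost = 1) {
  x <- .featureMatrix(features)
  task <- as.character(features$task)
  tasks <- taskLabels()[taskLabels() %in% task]
  counts <- table(task)
  if (any(counts < folds))
    stop("task(s) with fewer trials than folds: ",
         paste(names(counts)[counts < folds], collapse = ", "))
  acc <- array(NA_real_, dim = c(repeats, folds, length(tasks)),
               dimnames = list(NULL, NULL, tasks))
  assignments <- vector("list", repeats)
  .withSeed(seed, {
    for (rep in seq_len(repeats)) {
      foldId <- integer(length(task))
      for (tk in tasks) {
        idx <- sample(which(task == tk))
        foldId[idx] <- rep_len(seq_len(folds), length(idx))
      }
      assignments[[rep]] <- foldId
      for (f in seq_len(folds)) {
        te <- foldId == f
        mu <- colMeans(x[!te, , drop = FALSE])
        sg <- apply(x[!te, , drop = FALSE], 2, sd)
        sg[sg == 0] <- 1
        xtr <- sweep(sweep(x[!te, , drop = FALSE], 2, mu), 2, sg, "/")
        xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sg, "/")
        scores <- vapply(tasks, function(tk)
          .ovrScore(xtr, task[!te] == tk, xte, cost), numeric(sum(te)))
        pred <- tasks[max.col(scores, ties.method = "first")]
        truth <- task[te]
        for (tk in tasks)
          acc[rep, f, tk] <- 100 * mean(pred[truth == tk] == tk)
      }
    }
  })
  foldTask <- apply(acc, c(2, 3), mean)
  perTaskMean <- colMeans(foldTask)
  perTaskSd <- apply(foldTask, 2, sd)
  new("ClassificationResult", accuracy = acc, foldTask = foldTask,
      perTaskMean = perTaskMean, perTaskSd = perTaskSd,
      overall = mean(perTaskMean), folds = folds, repeats = repeats,
      trainParts = length(tasks) * (folds - 1),
      testParts = length(tasks), foldAssignments = assignments,
      seed = as.numeric(seed))
}

#' Assemble a run report
#'
#' Prints (and optionally writes as CSV/text) the pairwise p-value matrix,
#' the fold x task accuracy table with its mean +/- sd row, and the
#' configuration used.
#'
#' @param result a [ClassificationResult-class].
#' @param stats a [PairwiseStats-class] (optional).
#' @param config configuration echoed into the report (optional).
#' @param outDir optional directory for CSV/text output.
#' @return invisible list of the report tables.
#' @export
cirReport <- function(result, stats = NULL, config = NULL,
                      outDir = NULL) {
  stopifnot(is(result, "ClassificationResult"))
  accTab <- rbind(result@foldTask,
                  mean = result@perTaskMean)
  rownames(accTab) <- c(paste0("Fold-", seq_len(result@folds)), "Average")
  cat("Average classification accuracies (%)\n")
  print(round(accTab, 2))
  cat(sprintf("Per-task sd over folds: %s\n",
              paste(sprintf("%s %.2f", names(result@perTaskSd),
                            result@perTaskSd), collapse = ", ")))
  cat(sprintf("Overall mean accuracy: %.2f%%\n", result@overall))
  out <- list(accuracy = accTab, perTaskSd = result@perTaskSd,
              overall = result@overall)
  if (!is.null(stats)) {
    cat("\nPairwise p values\n")
    print(signif(pValues(stats), 3))
    out$pTable <- pValues(stats)
  }
  if (!is.null(config) && is(config, "SimulationConfig")) {
    cat("\nConfiguration:\n")
    show(config)
  }
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.csv(accTab, file.path(outDir, "accuracy.csv"))
    if (!is.null(stats))
      write.csv(pValues(stats), file.path(outDir, "p_values.csv"))
  }
  invisible(out)
}
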