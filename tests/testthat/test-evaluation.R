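# synthetic feature tables: seven task clusters in CIR space with
# controllable separation
clusterFeatures <- function(nPerTask = 30, sdWithin = 0.3, seed = 1) {
  set.seed(seed)
  centers <- rbind(
    "S"     = c(1, 1, 1),
    "LH"    = c(3.1, 5.7, 2.0),
    "RH"    = c(5.9, 3.2, 2.0),
    "LF"    = c(2.3, 2.2, 4.2),
    "LH&RH" = c(6.1, 6.2, 2.1),
    "LH&LF" = c(3.2, 6.0, 4.2),
    "RH&LF" = c(6.0, 3.4, 3.9))
  rows <- lapply(rownames(centers), function(tk) {
    x <- matrix(rnorm(nPerTask * 3, sd = sdWithin), ncol = 3,
                byrow = TRUE)
    data.frame(task = tk, CIR_C3 = centers[tk, 1] + x[, 1],
               CIR_C4 = centers[tk, 2] + x[, 2],
               CIR_Cz = centers[tk, 3] + x[, 3])
  })
  do.call(rbind, rows)
}

test_that("pairwise analysis tests all 21 task pairs symmetrically", {
  f <- clusterFeatures(nPerTask = 10)
  st <- pairwiseAnova(f)
  p <- pValues(st)
  expect_equal(dim(p), c(7, 7))
  expect_equal(sum(!is.na(p)) / 2, 21)
  expect_true(all(is.na(diag(p))))
  expect_equal(p, t(p))
  expect_equal(nrow(st@univariate), 21)
  few <- f[f$task != "S" | seq_len(nrow(f)) %in% which(f$task == "S")[1], ]
  expect_error(pairwiseAnova(few), "fewer than 2")
})

test_that("same-distribution groups give null p, shifted groups reject", {
  set.seed(10)
  null <- data.frame(
    task = rep(c("S", "LH"), each = 60),
    CIR_C3 = rnorm(120), CIR_C4 = rnorm(120), CIR_Cz = rnorm(120))
  pNull <- pValues(pairwiseAnova(null))["S", "LH"]
  expect_gt(pNull, 0.05)
  shifted <- null
  shifted$CIR_C4[shifted$task == "LH"] <-
    shifted$CIR_C4[shifted$task == "LH"] + 3  # 3 pooled sd in one axis
  expect_lt(pValues(pairwiseAnova(shifted))["S", "LH"], 0.01)
})

test_that("the multivariate test holds its nominal size", {
  set.seed(77)
  rejections <- vapply(1:500, function(i) {
    f <- data.frame(task = rep(c("S", "LH"), each = 15),
                    CIR_C3 = rnorm(30), CIR_C4 = rnorm(30),
                    CIR_Cz = rnorm(30))
    pValues(pairwiseAnova(f))["S", "LH"] < 0.05
  }, TRUE)
  expect_lte(mean(rejections), 0.07)
})

test_that("cross-validation partitions each task exactly once per rotation", {
  f <- clusterFeatures(nPerTask = 10)
  res <- ovrSvmCv(f, folds = 5, repeats = 3, seed = 2)
  expect_equal(res@trainParts, 28)
  expect_equal(res@testParts, 7)
  for (foldId in res@foldAssignments) {
    expect_length(foldId, nrow(f))
    expect_true(all(foldId %in% 1:5))
    # within every task each fold holds 2 of the 10 trials
    for (tk in unique(f$task))
      expect_equal(as.vector(table(foldId[f$task == tk])), rep(2L, 5))
  }
  expect_equal(dim(res@accuracy), c(3, 5, 7))
  expect_error(ovrSvmCv(clusterFeatures(nPerTask = 3)), "fewer trials")
})

test_that("separable clusters classify perfectly, permuted labels at chance", {
  f <- clusterFeatures(nPerTask = 15, sdWithin = 0.05, seed = 3)
  res <- ovrSvmCv(f, folds = 5, repeats = 2, seed = 4)
  expect_gt(overallAccuracy(res), 99)
  set.seed(5)
  fPerm <- f
  fPerm$task <- sample(fPerm$task)
  chance <- ovrSvmCv(fPerm, folds = 5, repeats = 10, seed = 6)
  expect_lt(abs(overallAccuracy(chance) - 100 / 7), 5)
})

test_that("results are seeded and the report has the expected shape", {
  f <- clusterFeatures(nPerTask = 10, seed = 7)
  r1 <- ovrSvmCv(f, folds = 5, repeats = 2, seed = 11)
  r2 <- ovrSvmCv(f, folds = 5, repeats = 2, seed = 11)
  expect_identical(r1@accuracy, r2@accuracy)
  expect_equal(overallAccuracy(r1), mean(r1@perTaskMean))

  rOne <- ovrSvmCv(f, folds = 5, repeats = 1, seed = 1)
  expect_true(all(is.finite(rOne@perTaskSd)))  # sd over folds still defined

  st <- pairwiseAnova(f)
  out <- capture.output(tabs <- cirReport(r1, st))
  expect_true(any(grepl("Overall mean accuracy", out)))
  expect_equal(dim(tabs$accuracy), c(6, 7))  # 5 folds + average row
  expect_equal(dim(tabs$pTable), c(7, 7))
  out2 <- capture.output(cirReport(r2, st))
  expect_identical(out, out2)
})
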