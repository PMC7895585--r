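test_that("connectivity value sums surviving weights over pairs", {
  R <- toyCor4()
  G <- thresholdAdjacency(R, 0.5)
  # no edges inside {a, c}
  expect_error(connectivityValue(R, G, "a"), "at least 2")
  expect_equal(connectivityValue(R, G, c("a", "c")), 0)
  # complete 4-node region, all r = 0.9 -> 6 * 0.9
  Rc <- makeCor(matrix(0.9, 4, 4))
  Gc <- thresholdAdjacency(Rc, 0.5)
  expect_equal(connectivityValue(Rc, Gc), 5.4)
  expect_error(connectivityValue(R, G, c("a", "zz")), "zz")
})

test_that("connectivity value matches pair enumeration on a 5-node toy", {
  set.seed(8)
  v <- matrix(runif(25, -0.2, 1), 5, 5)
  R <- makeCor(v)
  G <- thresholdAdjacency(R, 0.8)
  expect_equal(connectivityValue(R, G),
               oracleConnectivity(R@values, adjacency(G), 1:5))
  idx <- c(1, 3, 5)
  expect_equal(connectivityValue(R, G, paste0("ch", idx)),
               oracleConnectivity(R@values, adjacency(G), idx))
})

test_that("restricting to a region before or after thresholding is equivalent", {
  set.seed(12)
  rec <- simulateTrial(simulationConfig(), "LH&LF")
  R <- correlationMatrix(extractStage(bandpassMu(rec), "imagery"))
  for (rg in c("C3", "C4", "Cz")) {
    nodes <- regionNodes(rg)
    before <- connectivityValue(subsetCorrelation(R, nodes),
                                thresholdAdjacency(
                                  subsetCorrelation(R, nodes), 0.7))
    G <- thresholdAdjacency(R, 0.7)
    after <- connectivityValue(R, subgraphBfn(G, nodes))
    expect_equal(before, after)
    expect_equal(regionalConnectivity(R, 0.7, rg), before)
  }
})

test_that("connectivity value is nonincreasing in delta and bounded", {
  set.seed(4)
  data <- matrix(rnorm(10 * 80), nrow = 10)
  R <- correlationMatrix(data)
  nodes <- paste0("ch", 1:6)
  cs <- vapply(seq(0, 1, 0.1), function(d)
    regionalConnectivity(R, d, nodes), 0)
  expect_true(all(diff(cs) <= 1e-12))
  bound <- sum(abs(subsetCorrelation(R, nodes)@values[upper.tri(diag(6))]))
  expect_true(all(cs >= 0 - 1e-12 & cs <= bound + 1e-12))
})

test_that("baseline pooling and the CIR ratio follow their definitions", {
  expect_equal(restBaseline(3.2), 3.2)
  expect_equal(restBaseline(c(2, 4)), 3)
  expect_error(restBaseline(numeric(0)), "no baseline")
  expect_equal(cirRatio(5, 5), 1)
  expect_equal(cirRatio(0, 2), 0)
  expect_equal(cirRatio(-3, 2), 1.5)  # absolute value of the ratio
  expect_error(cirRatio(1, 0), "zero resting baseline")
})

test_that("feature vectors recover the planted regional pattern", {
  cfg <- simulationConfig()
  delta <- 0.65
  # pooled baseline from 12 silent trials
  silC <- vapply(1:12, function(i) {
    s <- (i - 1) %/% 4 + 1
    tr <- (i - 1) %% 4 + 1
    mu <- bandpassMu(simulateTrial(cfg, "S", s, tr))
    R <- correlationMatrix(extractStage(mu, "imagery"))
    vapply(c("C3", "C4", "Cz"), function(rg)
      regionalConnectivity(R, delta, rg), 0)
  }, numeric(3))
  baselines <- rowMeans(silC)
  names(baselines) <- c("C3", "C4", "Cz")

  feats <- function(task) vapply(1:12, function(i) {
    s <- (i - 1) %/% 4 + 1
    tr <- (i - 1) %% 4 + 1
    mu <- bandpassMu(simulateTrial(cfg, task, s, tr))
    cirValues(featureVector(mu, baselines, delta))
  }, numeric(3))

  lh <- feats("LH")
  expect_gt(mean(apply(lh, 2, which.max) == 2), 0.5)  # C4 dominates
  both <- feats("LH&RH")
  expect_gt(mean(both["C3", ] > both["Cz", ] &
                   both["C4", ] > both["Cz", ]), 0.5)

  fv <- featureVector(bandpassMu(simulateTrial(cfg, "LH", 1, 1)),
                      baselines, delta)
  fv2 <- featureVector(bandpassMu(simulateTrial(cfg, "LH", 1, 1)),
                       baselines, delta)
  expect_identical(cirValues(fv), cirValues(fv2))  # deterministic
  expect_equal(unname(cirValues(fv)),
               unname(abs(fv@cImage / fv@cRestBar)))
})

test_that("the pipeline assembles features, baselines and thresholds coherently", {
  cfg <- simulationConfig(nSubjects = 2, nTrialsPerTask = 3, seed = 21L)
  res <- runExperiment(cfg, nReps = 20)
  f <- featureTable(res)
  expect_equal(nrow(f), 2 * 7 * 3)
  expect_equal(nrow(res@selections), 14)
  # baseline equals the oracle mean over the silent-state C values
  for (rg in c("C3", "C4", "Cz")) {
    expect_equal(res@baselines[[rg]],
                 mean(f[f$task == "S", paste0("C_", rg)]))
    expect_equal(f[[paste0("CIR_", rg)]],
                 abs(f[[paste0("C_", rg)]] / res@baselines[[rg]]))
  }
  # per-condition delta is constant within a condition and on the grid
  expect_true(all(f$delta %in% seq(0.5, 0.95, 0.05)))
  merged <- merge(f, res@selections, by = c("subject", "task"))
  expect_true(all(merged$delta.x == merged$delta.y))
})
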