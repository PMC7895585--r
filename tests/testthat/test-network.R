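ringLattice <- function(n, k) {
  a <- matrix(0, n, n)
  for (o in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- (i + o - 1) %% n + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  a
}

test_that("clustering coefficient matches triangle-count oracles", {
  expect_equal(averageClustering(makeGraph(matrix(1, 4, 4))), 1)  # K4
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(averageClustering(makeGraph(star)), 0)
  a <- ringLattice(20, 4)
  expect_equal(averageClustering(makeGraph(a)), oracleClustering(a))
})

test_that("characteristic path length matches the all-pairs BFS oracle", {
  expect_equal(as.numeric(characteristicPathLength(
    makeGraph(matrix(1, 5, 5)))), 1)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(as.numeric(characteristicPathLength(makeGraph(path3))),
               4 / 3)
  a <- randomAdjacency(12, 0.3, seed = 7)
  L <- characteristicPathLength(makeGraph(a))
  expect_equal(as.numeric(L), oraclePathLength(a))
  empty <- makeGraph(matrix(0, 4, 4))
  expect_error(characteristicPathLength(empty), "no edges")
})

test_that("clustering and path length match oracles on random graphs up to N = 12", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(4:12, 1)
    a <- randomAdjacency(n, runif(1, 0.2, 0.7), seed = seed + 100)
    if (sum(a) == 0) next
    G <- makeGraph(a)
    expect_equal(averageClustering(G), oracleClustering(a))
    expect_equal(as.numeric(characteristicPathLength(G)),
                 oraclePathLength(a))
  }
})

test_that("mean degree is 2E/N", {
  expect_equal(meanDegree(makeGraph(matrix(1, 60, 60))), 59)
  expect_equal(meanDegree(makeGraph(matrix(0, 5, 5))), 0)
  G <- thresholdAdjacency(toyCor4(), 0.5)  # 4 nodes, 4 edges
  expect_equal(meanDegree(G), 2)
})

test_that("random reference reproduces known ensemble values", {
  # complete graph is the only realization at E = N(N-1)/2
  ref <- randomReference(6, 15, nReps = 5, seed = 1)
  expect_equal(unname(ref), c(1, 1))
  # sparse uniform graphs: expected clustering ~ edge density
  N <- 60; E <- 150
  dens <- E / (N * (N - 1) / 2)
  ref <- randomReference(N, E, nReps = 100, seed = 2)
  se <- sqrt(dens * (1 - dens) / 100)  # generous scale for 3 SE band
  expect_lt(abs(ref[["CRand"]] - dens), 3 * se + 0.01)
  expect_identical(randomReference(30, 60, nReps = 10, seed = 5),
                   randomReference(30, 60, nReps = 10, seed = 5))
  expect_error(randomReference(10, 100, 10, 1), "out of range")
})

test_that("sigma is about 1 for uniform graphs against their own ensemble", {
  sigmas <- vapply(1:50, function(s) {
    set.seed(s)
    g <- igraph::sample_gnm(30, 90)
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    m <- smallWorld(makeGraph(a), nReps = 30, seed = s + 500)
    m@sigma
  }, 0)
  expect_lt(abs(mean(sigmas) - 1), 0.1)
})

test_that("small-world and lattice constructions score as expected", {
  set.seed(99)
  ws <- igraph::sample_smallworld(1, 60, 3, 0.1)
  a <- as.matrix(igraph::as_adjacency_matrix(ws))
  m <- smallWorld(makeGraph(a), nReps = 100, seed = 1)
  expect_gt(m@sigma, 1)
  expect_equal(m@sigma, m@gamma / m@lambda, tolerance = 1e-12)
  # pure ring lattice: strongly clustered *and* long paths
  lat <- ringLattice(60, 6)
  ml <- smallWorld(makeGraph(lat), nReps = 50, seed = 2)
  expect_equal(ml@CReal, oracleClustering(lat))
  expect_equal(ml@LReal, oraclePathLength(lat))
  expect_gt(ml@gamma, 2)
  expect_gt(ml@lambda, 1.5)
})

test_that("threshold selection enforces K >= ln N and maximises sigma", {
  # constructed three-step scenario: a small-world skeleton at 0.85, too
  # sparse at 0.90, denser but more random at 0.80
  set.seed(42)
  g <- igraph::sample_smallworld(1, 60, 3, 0.1)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  v <- matrix(0.3, 60, 60)
  v[A == 1] <- 0.87
  eidx <- which(upper.tri(A) & A == 1)
  v[sample(eidx, 60)] <- 0.92
  v <- pmax(v, t(v))
  non <- which(upper.tri(A) & A == 0)
  v[sample(non, 120)] <- 0.82
  v <- pmax(v, t(v))
  R <- makeCor(v, makeMontage()$label)

  sel <- selectThreshold(R, nReps = 100, seed = 1)
  tab <- auditTable(sel)
  at <- function(col, d) tab[[col]][abs(tab$delta - d) < 1e-9]
  expect_equal(sel@bound, log(60))
  expect_gte(at("K", 0.85), log(60))
  expect_lt(at("K", 0.90), log(60))
  expect_false(at("feasible", 0.90))
  expect_gt(at("sigma", 0.85), at("sigma", 0.80))
  expect_equal(chosenDelta(sel), 0.85)
  # deterministic given (R, grid, seed)
  sel2 <- selectThreshold(R, nReps = 100, seed = 1)
  expect_identical(auditTable(sel2), tab)
  # K is nonincreasing across the ascending grid
  expect_true(all(diff(tab$K) <= 0))
})

test_that("saturated matrices choose the largest threshold and infeasible ones error", {
  sat <- makeCor(matrix(0.99, 60, 60), makeMontage()$label)
  sel <- selectThreshold(sat, nReps = 5, seed = 1)
  expect_equal(chosenDelta(sel), 0.95)
  expect_true(all(auditTable(sel)$feasible))

  weak <- makeCor(matrix(0.1, 60, 60), makeMontage()$label)
  err <- tryCatch(selectThreshold(weak, nReps = 5, seed = 1),
                  noFeasibleThreshold = function(e) e)
  expect_s3_class(err, "noFeasibleThreshold")
  expect_equal(nrow(err$table), 10)
})
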