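# Small-world metrics and the three-step threshold-selection procedure:
# (1) the network must keep significant connectivity, K >= ln N;
# (2) among feasible thresholds, maximise the comprehensive small-world
#     index sigma = gamma / lambda;
# (3) ties go to the larger threshold (sigma grows with the threshold on
#     these networks).

#' Mean local clustering coefficient
#'
#' Average over nodes of 2 * triangles / (deg * (deg - 1)); nodes of
#' degree < 2 contribute 0.
#'
#' @param G a [BfnGraph-class] with at least 3 nodes.
#' @return numeric.
#' @export
averageClustering <- function(G) {
  stopifnot(is(G, "BfnGraph"), nodeCount(G) >= 3)
  cc <- igraph::transitivity(.asIgraph(G), type = "local",
                             isolates = "zero")
  mean(cc)
}

#' Characteristic path length
#'
#' Mean shortest-path length (unweighted hops) over all connected ordered
#' node pairs; unreachable pairs are ignored. The attribute `"connected"`
#' flags whether the graph is connected.
#'
#' @param G a [BfnGraph-class] with at least one edge.
#' @return numeric with logical attribute `"connected"`.
#' @export
characteristicPathLength <- function(G) {
  stopifnot(is(G, "BfnGraph"), nodeCount(G) >= 2)
  if (edgeCount(G) == 0)
    stop("characteristic path length undefined for a graph with no edges")
  g <- .asIgraph(G)
  L <- igraph::mean_distance(g, unconnected = TRUE)
  attr(L, "connected") <- igraph::is_connected(g)
  L
}

#' Mean node degree
#'
#' K = 2E / N.
#'
#' @param G a [BfnGraph-class].
#' @return numeric.
#' @export
meanDegree <- function(G) {
  stopifnot(is(G, "BfnGraph"))
  2 * edgeCount(G) / nodeCount(G)
}

#' Random-network reference values
#'
#' Mean clustering coefficient and characteristic path length over
#' `nReps` uniform random graphs with exactly `N` nodes and `E` edges
#' (the reference of the same node size and edge count used by the
#' small-world ratios).
#'
#' @param N node count.
#' @param E edge count, 0 < E <= N(N-1)/2.
#' @param nReps realizations to average.
#' @param seed RNG seed.
#' @return named numeric `c(CRand, LRand)`.
#' @export
randomReference <- function(N, E, nReps = 100, seed = 1L) {
  stopifnot(N >= 2, nReps >= 1)
  if (E <= 0 || E > N * (N - 1) / 2)
    stop(sprintf("edge count E = %d out of range (0, %d]", E,
                 N * (N - 1) / 2))
  .withSeed(seed, {
    cs <- numeric(nReps)
    ls <- numeric(nReps)
    for (i in seq_len(nReps)) {
      g <- igraph::sample_gnm(N, E)
      cs[i] <- mean(igraph::transitivity(g, type = "local",
                                         isolates = "zero"))
      ls[i] <- igraph::mean_distance(g, unconnected = TRUE)
    }
    c(CRand = mean(cs), LRand = mean(ls))
  })
}

#' Small-world metrics of a network
#'
#' Computes C_real, L_real, their random-reference counterparts over an
#' ensemble matched in nodes and edges, and the ratios gamma, lambda and
#' sigma = gamma / lambda. sigma > 1 indicates small-world organisation.
#'
#' @param G a [BfnGraph-class] with at least one edge.
#' @param nReps random-reference realizations.
#' @param seed RNG seed.
#' @return a [SmallWorldMetrics-class].
#' @export
smallWorld <- function(G, nReps = 100, seed = 1L) {
  stopifnot(is(G, "BfnGraph"))
  E <- edgeCount(G)
  if (E < 1) stop("small-world metrics need at least one edge")
  CReal <- averageClustering(G)
  LReal <- characteristicPathLength(G)
  ref <- randomReference(nodeCount(G), E, nReps = nReps, seed = seed)
  if (ref[["CRand"]] == 0 || !is.finite(ref[["LRand"]]))
    stop("random reference degenerate (C_rand = 0 or L_rand undefined); sigma undefined")
  gamma <- CReal / ref[["CRand"]]
  lambda <- as.numeric(LReal) / ref[["LRand"]]
  new("SmallWorldMetrics", CReal = CReal, CRand = ref[["CRand"]],
      LReal = as.numeric(LReal), LRand = ref[["LRand"]], gamma = gamma,
      lambda = lambda, sigma = gamma / lambda, K = meanDegree(G),
      nRandom = nReps, connected = attr(LReal, "connected"))
}

# reference seed as a pure function of (seed, E) so cached and uncached
# paths agree
.refSeed <- function(seed, E) {
  as.integer((abs(as.numeric(seed)) * 31 + as.numeric(E) * 7919) %%
               2147483629)
}

#' Select the correlation threshold
#'
#' Sweeps the candidate grid (default 0.50 to 0.95 in steps of 0.05); for
#' each candidate the correlation matrix is thresholded and the mean
#' degree K and small-world index sigma are computed. Candidates are
#' feasible when K >= ln N (significant connectivity); among feasible
#' candidates the one with maximal sigma is chosen, ties broken toward
#' the larger threshold. The full per-candidate audit table is returned.
#'
#' @param R a [CorrelationMatrix-class].
#' @param grid ascending candidate thresholds.
#' @param nReps random-reference realizations per candidate.
#' @param seed RNG seed.
#' @param absolute threshold |r| instead of signed r.
#' @param refCache optional environment caching random-reference values
#'   across calls (keyed by edge count).
#' @return a [ThresholdSelection-class]. If no candidate is feasible an
#'   error of class `"noFeasibleThreshold"` is signalled, carrying the
#'   audit table in its `table` field.
#' @examples
#' rec <- simulateTrial(simulationConfig(), "S")
#' R <- correlationMatrix(extractStage(bandpassMu(rec), "imagery"))
#' sel <- selectThreshold(R, nReps = 20)
#' @export
selectThreshold <- function(R, grid = seq(0.5, 0.95, by = 0.05),
                            nReps = 100, seed = 1L, absolute = FALSE,
                            refCache = NULL) {
  stopifnot(is(R, "CorrelationMatrix"), length(grid) >= 1,
            !is.unsorted(grid))
  N <- length(R@labels)
  bound <- log(N)
  if (is.null(refCache)) refCache <- new.env(parent = emptyenv())
  rows <- lapply(grid, function(delta) {
    G <- thresholdAdjacency(R, delta, absolute = absolute)
    E <- edgeCount(G)
    K <- meanDegree(G)
    feasible <- K >= bound
    CReal <- LReal <- CRand <- LRand <- gamma <- lambda <- sigma <- NA_real_
    connected <- NA
    if (E >= 1) {
      CReal <- averageClustering(G)
      L <- characteristicPathLength(G)
      LReal <- as.numeric(L)
      connected <- attr(L, "connected")
      key <- as.character(E)
      if (is.null(refCache[[key]]))
        refCache[[key]] <- randomReference(N, E, nReps = nReps,
                                           seed = .refSeed(seed, E))
      ref <- refCache[[key]]
      CRand <- ref[["CRand"]]
      LRand <- ref[["LRand"]]
      if (CRand > 0 && is.finite(LRand)) {
        gamma <- CReal / CRand
        lambda <- LReal / LRand
        sigma <- gamma / lambda
      }
    }
    data.frame(delta = delta, E = E, K = K, CReal = CReal, LReal = LReal,
               CRand = CRand, LRand = LRand, gamma = gamma,
               lambda = lambda, sigma = sigma, feasible = feasible,
               connected = connected)
  })
  tab <- do.call(rbind, rows)
  feas <- tab[tab$feasible, , drop = FALSE]
  if (nrow(feas) == 0) {
    cond <- structure(
      class = c("noFeasibleThreshold", "error", "condition"),
      list(message = sprintf(
             "no threshold in [%g, %g] satisfies K >= ln(%d) = %.2f",
             min(grid), max(grid), N, bound),
           call = sys.call(-1), table = tab))
    stop(cond)
  }
  s <- feas$sigma
  s[!is.finite(s)] <- -Inf
  best <- which(s == max(s))
  chosen <- max(feas$delta[best])
  new("ThresholdSelection", grid = as.numeric(grid), table = tab,
      chosen = chosen, bound = bound, nReps = nReps,
      seed = as.numeric(seed))
}
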