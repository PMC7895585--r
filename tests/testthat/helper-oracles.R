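# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the code paths (and packages) they are used to check.

# Pearson correlation by explicit double loop over the defining sum
oraclePearson <- function(data) {
  n <- nrow(data)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xi <- data[i, ] - mean(data[i, ])
      xj <- data[j, ] - mean(data[j, ])
      out[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# mean local clustering by exhaustive triangle counting
oracleClustering <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (p in seq_len(k - 1))
      for (q in seq(p + 1, k))
        tri <- tri + a[nb[p], nb[q]]
    cc[v] <- 2 * tri / (k * (k - 1))
  }
  mean(cc)
}

# mean shortest-path length over connected ordered pairs, all-pairs BFS
oraclePathLength <- function(a) {
  n <- nrow(a)
  total <- 0
  count <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in which(a[v, ] == 1)) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    reach <- dist[-s]
    total <- total + sum(reach[!is.na(reach)])
    count <- count + sum(!is.na(reach))
  }
  total / count
}

# connectivity value by explicit pair enumeration
oracleConnectivity <- function(r, a, idx) {
  C <- 0
  for (p in seq_len(length(idx) - 1))
    for (q in seq(p + 1, length(idx)))
      C <- C + r[idx[p], idx[q]] * a[idx[p], idx[q]]
  C
}

# CorrelationMatrix from a raw symmetric matrix
makeCor <- function(v, labels = paste0("ch", seq_len(nrow(v)))) {
  diag(v) <- 1
  new("CorrelationMatrix", values = (v + t(v)) / 2, labels = labels)
}

# BfnGraph straight from a 0/1 adjacency matrix
makeGraph <- function(a, labels = paste0("n", seq_len(nrow(a)))) {
  a <- (a + t(a) > 0) * 1
  diag(a) <- 0
  new("BfnGraph", adjacency = a, weights = a, labels = labels)
}

# seeded Erdos-Renyi style 0/1 adjacency without igraph
randomAdjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# the paper-style 4-node toy correlation matrix: off-diagonal entries
# (1,2)=.9 (1,3)=.3 (1,4)=.6 (2,3)=.95 (2,4)=.1 (3,4)=.7
toyCor4 <- function() {
  v <- diag(4)
  v[1, 2] <- 0.9; v[1, 3] <- 0.3; v[1, 4] <- 0.6
  v[2, 3] <- 0.95; v[2, 4] <- 0.1; v[3, 4] <- 0.7
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  makeCor(v, c("a", "b", "c", "d"))
}

# small, fast simulation config for unit tests
tinyConfig <- function(...) {
  simulationConfig(nSubjects = 1, nTrialsPerTask = 2, ...)
}
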