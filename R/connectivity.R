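# Pearson correlation matrices between channels and their thresholding
# into binary brain functional networks.

#' Pearson correlation matrix of a recording
#'
#' Computes the Pearson correlation coefficient between every pair of
#' channel signals, giving the N x N symmetric connection-coefficient
#' matrix of the weighted network (r_ij as edge weight).
#'
#' @param rec a [Recording-class], or a channels x samples numeric matrix
#'   with row names as labels.
#' @return a [CorrelationMatrix-class].
#' @examples
#' rec <- simulateTrial(simulationConfig(), "S")
#' R <- correlationMatrix(extractStage(bandpassMu(rec), "imagery"))
#' @export
correlationMatrix <- function(rec) {
  if (is(rec, "Recording")) {
    data <- rec@data
    labels <- rec@labels
  } else if (is.matrix(rec)) {
    data <- rec
    labels <- rownames(rec)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(rec)))
  } else stop("'rec' must be a Recording or a numeric matrix")
  if (ncol(data) < 3) stop("need at least 3 samples per channel")
  sds <- apply(data, 1, sd)
  if (any(sds == 0))
    stop("zero-variance channel(s): ",
         paste(labels[sds == 0], collapse = ", "))
  v <- cor(t(data))
  v <- (v + t(v)) / 2
  diag(v) <- 1
  v[v > 1] <- 1
  v[v < -1] <- -1
  new("CorrelationMatrix", values = unname(v), labels = labels)
}

#' Average correlation matrices across trials
#'
#' Entry-wise mean of correlation matrices sharing the same labels, used
#' to select one threshold per subject-task condition.
#'
#' @param Rs list of [CorrelationMatrix-class] objects.
#' @return a [CorrelationMatrix-class].
#' @export
averageCorrelation <- function(Rs) {
  stopifnot(length(Rs) >= 1, all(vapply(Rs, is, TRUE, "CorrelationMatrix")))
  labels <- Rs[[1]]@labels
  for (R in Rs)
    if (!identical(R@labels, labels))
      stop("all correlation matrices must share the same channel labels")
  v <- Reduce(`+`, lapply(Rs, function(R) R@values)) / length(Rs)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  new("CorrelationMatrix", values = v, labels = labels)
}

#' Restrict a correlation matrix to a node subset
#'
#' @param R a [CorrelationMatrix-class].
#' @param nodes subset of its labels; ordering follows the stored
#'   (montage) order.
#' @return a [CorrelationMatrix-class] over `nodes`.
#' @export
subsetCorrelation <- function(R, nodes) {
  stopifnot(is(R, "CorrelationMatrix"))
  missing <- setdiff(nodes, R@labels)
  if (length(missing))
    stop("unknown node label(s): ", paste(missing, collapse = ", "))
  idx <- which(R@labels %in% nodes)
  new("CorrelationMatrix", values = R@values[idx, idx, drop = FALSE],
      labels = R@labels[idx])
}

#' Threshold a correlation matrix into a binary network
#'
#' Builds the 0-1 adjacency: an edge joins distinct nodes i and j exactly
#' when r_ij >= delta (boundary inclusive). Surviving edges keep r_ij as
#' weight; the diagonal is forced to zero (no self-loops). By default the
#' signed correlation is compared to delta; `absolute = TRUE` thresholds
#' |r_ij| instead.
#'
#' @param R a [CorrelationMatrix-class].
#' @param delta threshold in \[0, 1\].
#' @param absolute threshold |r| instead of signed r.
#' @return a [BfnGraph-class].
#' @examples
#' v <- matrix(c(1, .9, .9, 1), 2); G <- thresholdAdjacency(
#'   new("CorrelationMatrix", values = v, labels = c("a", "b")), 0.85)
#' edgeCount(G)  # 1
#' @export
thresholdAdjacency <- function(R, delta, absolute = FALSE) {
  stopifnot(is(R, "CorrelationMatrix"))
  if (is(delta, "ThresholdSelection")) delta <- delta@chosen
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0, delta <= 1)
  v <- R@values
  base <- if (absolute) abs(v) else v
  a <- (base >= delta) * 1
  diag(a) <- 0
  w <- v * a
  new("BfnGraph", adjacency = a, weights = w, labels = R@labels,
      delta = delta)
}

#' Induced subgraph of a brain functional network
#'
#' Restricts the network to a node subset, keeping edges with both ends
#' inside it. Node ordering follows the graph's stored (montage) order.
#'
#' @param G a [BfnGraph-class].
#' @param nodes subset of its labels.
#' @return a [BfnGraph-class] over `nodes`.
#' @export
subgraphBfn <- function(G, nodes) {
  stopifnot(is(G, "BfnGraph"))
  missing <- setdiff(nodes, G@labels)
  if (length(missing))
    stop("unknown node label(s): ", paste(missing, collapse = ", "))
  idx <- which(G@labels %in% nodes)
  new("BfnGraph", adjacency = G@adjacency[idx, idx, drop = FALSE],
      weights = G@weights[idx, idx, drop = FALSE],
      labels = G@labels[idx], delta = G@delta)
}

# BfnGraph -> igraph (internal)
.asIgraph <- function(G) {
  igraph::graph_from_adjacency_matrix(G@adjacency, mode = "undirected")
}
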