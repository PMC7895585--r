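# The connectivity value C of a regional network and the connectivity
# increment rate (CIR) feature: C summed over surviving edges inside the
# 15-node region, normalised by the pooled resting baseline.

#' Connectivity value of a node set
#'
#' Sum of the retained correlation weights r_ij over unordered pairs
#' \{i, j\} inside `nodes` that are joined in the thresholded network:
#' `C = sum_{i<j in V} r_ij a_ij`.
#'
#' @param R a [CorrelationMatrix-class].
#' @param G a [BfnGraph-class] built from `R` (same labels).
#' @param nodes node subset V (default: all labels of `G`).
#' @return numeric.
#' @examples
#' rec <- simulateTrial(simulationConfig(), "LH")
#' R <- correlationMatrix(extractStage(bandpassMu(rec), "imagery"))
#' G <- thresholdAdjacency(R, 0.8)
#' connectivityValue(R, G, regionNodes("C4"))
#' @export
connectivityValue <- function(R, G, nodes = NULL) {
  stopifnot(is(R, "CorrelationMatrix"), is(G, "BfnGraph"))
  if (is.null(nodes)) nodes <- G@labels
  if (length(nodes) < 2)
    stop("node set must contain at least 2 nodes")
  missing <- setdiff(nodes, G@labels)
  if (length(missing))
    stop("unknown node label(s): ", paste(missing, collapse = ", "))
  ri <- match(G@labels, R@labels)
  if (anyNA(ri)) stop("'R' and 'G' must share labels")
  idx <- which(G@labels %in% nodes)
  a <- G@adjacency[idx, idx, drop = FALSE]
  r <- R@values[ri, ri, drop = FALSE][idx, idx, drop = FALSE]
  sum((r * a)[upper.tri(a)])
}

#' Regional connectivity value of a correlation matrix
#'
#' Convenience wrapper: restrict the correlation matrix to a region's 15
#' nodes, threshold at `delta`, and sum the surviving weights. Because the
#' edge rule is pairwise, restricting before or after thresholding gives
#' the same result.
#'
#' @param R a full [CorrelationMatrix-class].
#' @param delta threshold.
#' @param region region name (C3, C4, Cz) or an explicit node vector.
#' @param absolute threshold |r| instead of signed r.
#' @return numeric connectivity value.
#' @export
regionalConnectivity <- function(R, delta, region, absolute = FALSE) {
  nodes <- if (is.character(region) && length(region) == 1 &&
               region %in% c("C3", "C4", "Cz")) regionNodes(region)
           else region
  Rsub <- subsetCorrelation(R, nodes)
  G <- thresholdAdjacency(Rsub, delta, absolute = absolute)
  connectivityValue(Rsub, G)
}

#' Pooled resting baseline
#'
#' Mean of resting-state connectivity values pooled over the configured
#' baseline segments of all subjects; one scalar per region.
#'
#' @param cRest numeric vector of per-segment connectivity values of one
#'   region.
#' @return numeric scalar.
#' @export
restBaseline <- function(cRest) {
  cRest <- cRest[!is.na(cRest)]
  if (length(cRest) < 1)
    stop("no baseline segments available")
  mean(cRest)
}

#' Connectivity increment rate
#'
#' `CIR = |C_image / C_rest_bar|`: the absolute ratio of the imagery
#' connectivity value to the pooled resting baseline.
#'
#' @param cImage connectivity value during imagery.
#' @param cRestBar pooled resting baseline (nonzero).
#' @return numeric (vectorised over both arguments).
#' @export
cirRatio <- function(cImage, cRestBar) {
  if (any(cRestBar == 0))
    stop("zero resting baseline: CIR undefined")
  abs(cImage / cRestBar)
}

#' CIR feature vector of one trial
#'
#' Computes `[CIR_C3, CIR_C4, CIR_Cz]` for a preprocessed (mu-band) trial:
#' for each region, restrict the imagery-window correlation matrix to the
#' region's 15 nodes, threshold at `delta`, sum the surviving weights, and
#' divide by the region's pooled resting baseline (absolute value).
#'
#' @param rec a mu-band filtered [Recording-class] covering the full trial.
#' @param baselines named numeric `c(C3 = , C4 = , Cz = )` of pooled
#'   resting connectivity values.
#' @param delta threshold (scalar or [ThresholdSelection-class]).
#' @param stage imagery stage name or explicit window, passed to
#'   [extractStage()].
#' @param absolute threshold |r| instead of signed r.
#' @return a [CirFeature-class].
#' @export
featureVector <- function(rec, baselines, delta, stage = "imagery",
                          absolute = FALSE) {
  stopifnot(is(rec, "Recording"))
  if (is(delta, "ThresholdSelection")) delta <- delta@chosen
  regions <- c("C3", "C4", "Cz")
  stopifnot(all(regions %in% names(baselines)))
  seg <- extractStage(rec, stage)
  R <- correlationMatrix(seg)
  cImage <- vapply(regions, function(rg)
    regionalConnectivity(R, delta, rg, absolute = absolute), 0)
  bar <- baselines[regions]
  new("CirFeature", subject = rec@subject, task = rec@task,
      trial = rec@trial, delta = delta, cImage = cImage,
      cRestBar = bar, cir = cirRatio(cImage, bar))
}
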