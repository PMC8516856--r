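#' Functional-connectivity parameters
#'
#' Spike trains are binned (100 ms by default), Pearson spike-count
#' correlations are computed for all channel pairs, and an edge is kept when
#' the correlation is significant (two-sided `P < alpha`) and its absolute
#' value reaches `weightThreshold`.
#'
#' @param binS bin width in seconds.
#' @param alpha significance level for the Pearson correlation.
#' @param weightThreshold absolute correlation threshold (0.35 in the study).
#' @return list of class `connectivityConfig`.
#' @export
connectivityConfig <- function(binS = 0.1, alpha = 0.05,
                               weightThreshold = 0.35) {
  stopifnot(binS > 0, alpha > 0, alpha < 1,
            weightThreshold >= 0, weightThreshold <= 1)
  structure(list(binS = binS, alpha = alpha,
                 weightThreshold = weightThreshold),
            class = "connectivityConfig")
}

#' Build the thresholded significant-correlation graph
#'
#' Nodes are the active channels; an undirected binary edge links channels
#' whose binned spike-count Pearson correlation is significant at `alpha`
#' (two-sided p from the exact t transform with `nBins - 2` degrees of
#' freedom) and has `|r| >= weightThreshold`. Pairs involving a zero-variance
#' count vector get no edge. No multiple-comparison correction is applied
#' (matching the source analysis); see the methods vignette.
#'
#' @param rec an [MEARecording-class].
#' @param cfg a [connectivityConfig()].
#' @param qc a [qcConfig()].
#' @return list with `adjacency` (binary symmetric matrix, zero diagonal,
#'   dimnames = channel ids), `r` (correlation matrix), `p` (p-value matrix)
#'   and `channels`.
#' @export
buildGraph <- function(rec, cfg = connectivityConfig(), qc = qcConfig()) {
  act <- activeChannels(rec, qc)
  n <- length(act)
  dur <- durationS(rec)
  nBins <- floor(dur / cfg$binS)
  counts <- matrix(0L, nBins, n)
  for (k in seq_len(n)) {
    t <- spikeTimes(rec)[[act[k]]]
    t <- t[t < nBins * cfg$binS]
    if (length(t)) {
      counts[, k] <- tabulate(floor(t / cfg$binS) + 1L, nbins = nBins)
    }
  }
  r <- suppressWarnings(stats::cor(counts))  # NA for zero-variance channels
  # two-sided p from t = r * sqrt((n-2) / (1 - r^2)), df = nBins - 2
  tstat <- r * sqrt((nBins - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = nBins - 2)
  p[abs(r) >= 1] <- 0
  adj <- (p < cfg$alpha & abs(r) >= cfg$weightThreshold)
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  adj <- adj * 1L
  dimnames(adj) <- dimnames(r) <- dimnames(p) <- list(act, act)
  list(adjacency = adj, r = r, p = p, channels = act)
}

#' Graph metrics: mean node degree, clustering coefficient, global efficiency
#'
#' `nodeDegree` is the mean degree; `clusteringCoeff` the mean over nodes of
#' the local clustering coefficient (`0` for nodes of degree < 2);
#' `efficiency` the mean over ordered node pairs of the inverse shortest-path
#' length (unweighted), with disconnected pairs contributing 0.
#'
#' @param adjacency binary symmetric adjacency matrix (or the list returned
#'   by [buildGraph()]).
#' @return named list `nodeDegree`, `clusteringCoeff`, `efficiency`
#'   (all `NA` when the graph has fewer than 2 nodes).
#' @examples
#' k3 <- matrix(1, 3, 3) - diag(3)
#' graphMetrics(k3)  # degree 2, clustering 1, efficiency 1
#' @export
graphMetrics <- function(adjacency) {
  if (is.list(adjacency)) adjacency <- adjacency$adjacency
  n <- nrow(adjacency)
  if (is.null(n) || n < 2) {
    return(list(nodeDegree = NA_real_, clusteringCoeff = NA_real_,
                efficiency = NA_real_))
  }
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           diag = FALSE)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0  # degree-1 nodes: no triangle is possible
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  list(nodeDegree = mean(deg),
       clusteringCoeff = mean(cc),
       efficiency = sum(inv) / (n * (n - 1)))
}
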