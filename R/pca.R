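#' PCA of the feature table
#'
#' Columns are scaled to unit variance (z-scored) before the decomposition,
#' so the PCA is on the correlation structure. The contribution of a feature
#' to a component is its squared loading as a share of the component's total
#' squared loadings, in percent; with p features the reference line for a
#' "significant" contribution is `100 / p` percent (5.56% for the 18-feature
#' table, printed as 5.55% at two truncated decimals).
#'
#' @param x numeric matrix or data.frame of features (rows = observations);
#'   non-numeric columns are dropped.
#' @param nComponents number of components to return (default 2).
#' @return list with `scores` (n x nComponents), `explainedPct` (percent of
#'   variance per component, all components), `contributionsPct`
#'   (p x nComponents, percent), `referencePct` (`100/p`) and
#'   `droppedColumns` (zero-variance columns removed with a warning).
#' @export
pcaProject <- function(x, nComponents = 2L) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x <- as.matrix(x[, num, drop = FALSE])
  stopifnot(nrow(x) >= 2, ncol(x) >= 1, !anyNA(x))
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance columns: ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  fit <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  nComponents <- min(nComponents, ncol(fit$rotation))
  expl <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  load2 <- fit$rotation[, seq_len(nComponents), drop = FALSE]^2
  contrib <- 100 * sweep(load2, 2, colSums(load2), "/")
  list(scores = fit$x[, seq_len(nComponents), drop = FALSE],
       explainedPct = expl,
       contributionsPct = contrib,
       referencePct = 100 / ncol(x),
       droppedColumns = dropped)
}
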