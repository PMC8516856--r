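#' SMOTE-style oversampling for regression rows
#'
#' Creates `ratio` synthetic rows per original row: for each synthetic
#' instance a seed row is taken, one of its `kNeighbors` nearest neighbors
#' (Euclidean distance in the joint predictor + target space) is picked at
#' random, and the new row is `row + lambda * (neighbor - row)` with
#' `lambda ~ U(0, 1)` applied jointly to predictors and target, so every
#' synthetic row lies componentwise between its two parents. No class
#' distinction is made: all rows are processed.
#'
#' @param rows numeric matrix (predictors and target as columns).
#' @param kNeighbors neighbors considered (default 20); shrunk to
#'   `nrow(rows) - 1` with a warning when there are too few rows.
#' @param ratio synthetic instances per original instance (default 2).
#' @param seed RNG seed.
#' @return matrix with `nrow(rows) * (1 + ratio)` rows: the originals
#'   followed by the synthetic rows (attribute `parents` records the parent
#'   row indices of each synthetic row).
#' @export
smoteAugment <- function(rows, kNeighbors = 20L, ratio = 2L, seed = 1L) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  stopifnot(n >= 2, ratio >= 0)
  if (kNeighbors >= n) {
    warning(sprintf("kNeighbors reduced from %d to %d (only %d rows)",
                    kNeighbors, n - 1L, n))
    kNeighbors <- n - 1L
  }
  nSyn <- n * ratio
  if (nSyn == 0) return(rows)
  set.seed(seed)
  d <- as.matrix(stats::dist(rows))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(dr) order(dr)[seq_len(kNeighbors)]))
  syn <- matrix(NA_real_, nSyn, ncol(rows))
  parents <- matrix(NA_integer_, nSyn, 2)
  k <- 0L
  for (rep in seq_len(ratio)) {
    for (i in seq_len(n)) {
      k <- k + 1L
      j <- nn[i, sample.int(kNeighbors, 1)]
      lambda <- stats::runif(1)
      syn[k, ] <- rows[i, ] + lambda * (rows[j, ] - rows[i, ])
      parents[k, ] <- c(i, j)
    }
  }
  colnames(syn) <- colnames(rows)
  out <- rbind(rows, syn)
  rownames(out) <- NULL
  attr(out, "parents") <- parents
  out
}
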