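#' Self-organizing-map configuration
#'
#' Defaults follow the study's setup: a 5 x 5 hexagonal competition layer,
#' random initialization from the data, 50 training iterations (full passes
#' over the data). The learning-rate and neighborhood schedules are not
#' fixed by the study and follow common sequential-Kohonen conventions:
#' learning rate decaying linearly 0.05 to 0.01, Gaussian neighborhood with
#' radius decaying linearly from two-thirds of the grid diameter to 1.
#'
#' @param gridDim integer `c(rows, cols)` of the hexagonal lattice.
#' @param nIterations full passes over the data.
#' @param lrStart,lrEnd linear learning-rate schedule.
#' @param radiusStart starting neighborhood radius (`NULL`: 2/3 of the grid
#'   diameter); decays linearly to `radiusEnd`.
#' @param radiusEnd final neighborhood radius.
#' @return list of class `somConfig`.
#' @export
somConfig <- function(gridDim = c(5L, 5L), nIterations = 50L,
                      lrStart = 0.05, lrEnd = 0.01,
                      radiusStart = NULL, radiusEnd = 1) {
  stopifnot(all(gridDim >= 1), nIterations >= 1, lrStart > 0, lrEnd > 0,
            is.null(radiusStart) || radiusStart > 0, radiusEnd > 0)
  structure(list(gridDim = as.integer(gridDim),
                 nIterations = as.integer(nIterations),
                 lrStart = lrStart, lrEnd = lrEnd,
                 radiusStart = radiusStart, radiusEnd = radiusEnd),
            class = "somConfig")
}

# Cartesian coordinates of a hexagonal lattice (odd rows offset by 1/2,
# row spacing sqrt(3)/2): unit distance between adjacent units.
hexCoords <- function(gridDim) {
  rows <- gridDim[1]; cols <- gridDim[2]
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  x <- g$col + ifelse(g$row %% 2 == 0, 0.5, 0)
  y <- g$row * sqrt(3) / 2
  cbind(x = x, y = y)
}

#' Fit a self-organizing map to trajectory vectors
#'
#' Sequential Kohonen training: per step one data row is picked (cycling
#' through a seeded random order each pass), its best-matching unit (BMU) is
#' found by Euclidean distance, and the BMU and its lattice neighbors move
#' toward the row with Gaussian neighborhood weights. Deterministic under
#' `seed`. Inputs are used as given; z-score them upstream (see
#' [trajectoryInputs()]).
#'
#' @param x numeric matrix, rows = dishes (at least 2), no missing values.
#' @param cfg a [somConfig()].
#' @param seed RNG seed.
#' @return an [SOMModel-class].
#' @export
fitSom <- function(x, cfg = somConfig(), seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2, !anyNA(x))
  set.seed(seed)
  coords <- hexCoords(cfg$gridDim)
  nUnits <- nrow(coords)
  codebook <- x[sample.int(nrow(x), nUnits, replace = TRUE), , drop = FALSE]
  diam <- max(stats::dist(coords))
  r0 <- if (is.null(cfg$radiusStart)) 2 / 3 * diam else cfg$radiusStart
  unitD2 <- as.matrix(stats::dist(coords))^2

  nSteps <- cfg$nIterations * nrow(x)
  step <- 0L
  for (it in seq_len(cfg$nIterations)) {
    for (i in sample.int(nrow(x))) {
      frac <- step / max(1L, nSteps - 1L)
      lr <- cfg$lrStart + frac * (cfg$lrEnd - cfg$lrStart)
      radius <- r0 + frac * (cfg$radiusEnd - r0)
      row <- x[i, ]
      d2 <- rowSums(sweep(codebook, 2, row)^2)
      bmu <- which.min(d2)
      h <- lr * exp(-unitD2[bmu, ] / (2 * radius^2))
      codebook <- codebook - h * sweep(codebook, 2, row, `-`)
      step <- step + 1L
    }
  }
  bmu <- apply(x, 1, function(row) {
    which.min(colSums((t(codebook) - row)^2))
  })
  methods::new("SOMModel", codebook = codebook, gridCoords = coords,
               gridDim = cfg$gridDim, bmu = as.integer(bmu),
               data = unname(x),
               dataNames = if (is.null(rownames(x))) character(0)
                           else rownames(x))
}

#' Davies-Bouldin index of a clustering
#'
#' `DB = (1/k) * sum_i max_{j != i} (s_i + s_j) / d(c_i, c_j)` with `s_i`
#' the mean Euclidean distance of cluster members to their centroid and
#' `d` the centroid distance. Lower is better; coincident centroids give
#' `Inf`, so degenerate partitions are never selected.
#'
#' @param x numeric matrix of points.
#' @param labels integer cluster labels (1..k, all clusters non-empty).
#' @return the index (scalar).
#' @export
daviesBouldin <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  cent <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                   numeric(ncol(x))))
  s <- vapply(seq_along(ks), function(i) {
    pts <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  k <- length(ks)
  if (k < 2) return(Inf)
  db <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (d == 0) Inf else (s[i] + s[j]) / d
    }, numeric(1)))
  }, numeric(1))
  mean(db)
}

#' Cluster the SOM codebook with k-means under Davies-Bouldin selection
#'
#' Runs k-means (multiple restarts via `nstart`) on the codebook vectors of
#' the occupied units -- those that are the best-matching unit of at least
#' one input, i.e. the cells associated with input cases -- for each
#' candidate `k`; each dish is labelled by its BMU's cluster and the
#' candidate partitions are scored with the Davies-Bouldin index of the
#' induced partition of the dish trajectories, selecting the minimizing `k`.
#' Unoccupied (interpolating) units carry no input cases and are excluded
#' from the clustering; scoring the dish-level partition (rather than the
#' handful of codebook points) keeps the validity index away from degenerate
#' singleton-unit optima.
#'
#' @param model an [SOMModel-class].
#' @param kRange candidate numbers of clusters.
#' @param seed RNG seed.
#' @param nstart k-means restarts per candidate.
#' @return list of class `clusterResult` with `k`, `labels` (per dish),
#'   `unitLabels` (per occupied unit, named by unit index), `dbScores`
#'   (named by k), `centroids`.
#' @export
clusterSom <- function(model, kRange = 2:6, seed = 1L, nstart = 50L) {
  stopifnot(methods::is(model, "SOMModel"))
  occ <- sort(unique(model@bmu))
  cb <- model@codebook[occ, , drop = FALSE]
  set.seed(seed)
  fits <- list()
  db <- stats::setNames(rep(Inf, length(kRange)), kRange)
  for (k in kRange) {
    if (k > nrow(unique(cb))) next
    fit <- tryCatch(
      stats::kmeans(cb, centers = k, nstart = nstart, iter.max = 100),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("k = %d excluded: k-means failed", k))
      next
    }
    fits[[as.character(k)]] <- fit
    db[as.character(k)] <- daviesBouldin(model@data,
                                         fit$cluster[match(model@bmu, occ)])
  }
  if (all(!is.finite(db))) stop("no candidate k produced a valid partition")
  kBest <- as.integer(names(db)[which.min(db)])
  best <- fits[[as.character(kBest)]]
  labels <- best$cluster[match(model@bmu, occ)]
  if (length(model@dataNames)) names(labels) <- model@dataNames
  unitLabels <- stats::setNames(best$cluster, occ)
  structure(list(k = kBest, labels = labels, unitLabels = unitLabels,
                 dbScores = db, centroids = best$centers),
            class = "clusterResult")
}

#' Build and z-score the SOM input matrix from dish trajectories
#'
#' The clustering inputs are the per-dish trajectories of two representative
#' network features -- number of bursting channels (`ch_bursts`) and mean
#' STTC (`sttc`) -- at each DIV interval: a 6-column matrix for the default
#' three-interval scheme. Dishes with any missing entry are dropped (listed
#' in the `dropped` attribute); columns are z-scored.
#'
#' @param trajectories output of [aggregateTrajectories()].
#' @param features feature columns to use (default `c("ch_bursts", "sttc")`).
#' @return numeric matrix, rows named by dish, with attribute `dropped`.
#' @export
trajectoryInputs <- function(trajectories,
                             features = c("ch_bursts", "sttc")) {
  ivs <- unique(trajectories$interval)
  dishes <- unique(trajectories$dish)
  m <- matrix(NA_real_, length(dishes), length(ivs) * length(features),
              dimnames = list(dishes, paste(rep(ivs, each = length(features)),
                                            features, sep = ".")))
  for (i in seq_along(dishes)) {
    for (j in seq_along(ivs)) {
      row <- trajectories[trajectories$dish == dishes[i] &
                            trajectories$interval == ivs[j], ]
      if (nrow(row) == 1) {
        m[i, (j - 1) * length(features) + seq_along(features)] <-
          unlist(row[features])
      }
    }
  }
  complete <- stats::complete.cases(m)
  out <- scale(m[complete, , drop = FALSE])
  attr(out, "dropped") <- dishes[!complete]
  out
}

#' Summary statistics of the 18 features per cluster and interval
#'
#' @param labels named integer vector of cluster labels (names = dish ids).
#' @param trajectories output of [aggregateTrajectories()].
#' @return data.frame keyed (cluster, interval, feature) with `n`, `mean`,
#'   `median`, `sem` (`NA` for singletons) and `iqr` (type-7 quantiles).
#' @export
summarizeClusters <- function(labels, trajectories) {
  featCols <- intersect(featureNames(), names(trajectories))
  rows <- list()
  for (cl in sort(unique(labels))) {
    dishes <- names(labels)[labels == cl]
    for (iv in unique(trajectories$interval)) {
      sub <- trajectories[trajectories$dish %in% dishes &
                            trajectories$interval == iv, featCols,
                          drop = FALSE]
      for (f in featCols) {
        v <- sub[[f]]
        v <- v[!is.na(v)]
        n <- length(v)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = cl, interval = iv, feature = f, n = n,
          mean = if (n) mean(v) else NA_real_,
          median = if (n) stats::median(v) else NA_real_,
          sem = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
          iqr = if (n) stats::IQR(v, type = 7) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
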