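#' STTC and synchronized-cluster parameters
#'
#' @param dtS tiling half-window Delta t in seconds (default 0.1, i.e. the
#'   study's 100 ms window).
#' @param dbscanEps DBSCAN neighborhood radius on the distance
#'   `1 - STTC` (default 0.2, i.e. highly synchronized pairs have
#'   STTC > 0.8).
#' @param dbscanMinSamples minimum neighborhood size for a core point.
#' @param selfCounting if `TRUE`, a point counts itself among its
#'   `dbscanMinSamples` neighbors (the sklearn convention); default `FALSE`
#'   (a core point needs `dbscanMinSamples` other points within `eps`).
#' @return list of class `sttcConfig`.
#' @export
sttcConfig <- function(dtS = 0.1, dbscanEps = 0.2, dbscanMinSamples = 3L,
                       selfCounting = FALSE) {
  stopifnot(dtS > 0, dbscanEps > 0, dbscanEps < 2, dbscanMinSamples >= 1)
  structure(list(dtS = dtS, dbscanEps = dbscanEps,
                 dbscanMinSamples = as.integer(dbscanMinSamples),
                 selfCounting = isTRUE(selfCounting)),
            class = "sttcConfig")
}

# Length of the union of +/- dt windows around sorted spike times, clipped to
# [0, duration], as a fraction of duration.
tiledFraction <- function(t, dtS, durationS) {
  if (!length(t)) return(0)
  starts <- pmax(0, t - dtS)
  ends <- pmin(durationS, t + dtS)
  prevCover <- c(-Inf, cummax(ends)[-length(ends)])
  sum(pmax(0, ends - pmax(starts, prevCover))) / durationS
}

# Fraction of spikes in `a` lying within dt of some spike in sorted `b`.
nearFraction <- function(a, b, dtS) {
  if (!length(a)) return(0)
  if (!length(b)) return(0)
  idx <- findInterval(a, b)
  dLeft <- rep(Inf, length(a))
  sel <- idx >= 1L
  dLeft[sel] <- a[sel] - b[idx[sel]]
  dRight <- rep(Inf, length(a))
  sel <- idx < length(b)
  dRight[sel] <- b[idx[sel] + 1L] - a[sel]
  mean(dLeft <= dtS | dRight <= dtS)
}

#' Spike time tiling coefficient of a pair of trains
#'
#' `STTC = 1/2 * ((P_A - T_B)/(1 - P_A*T_B) + (P_B - T_A)/(1 - P_B*T_A))`,
#' where `P_A` is the proportion of spikes in train A falling within
#' `dtS` of a spike of train B, and `T_A` the proportion of the total
#' recording time tiled by windows of `+/- dtS` around the spikes of A
#' (exact interval union with boundary clipping). Returns 0 when either
#' train is empty (no measurable correlation). If one term's denominator is
#' exactly zero the other term's value is returned (with a message); if both
#' degenerate the result is 0.
#'
#' @param trainA,trainB sorted numeric spike-time vectors (s).
#' @param dtS tiling half-window (s).
#' @param durationS recording duration (s).
#' @return STTC value in `[-1, 1]`.
#' @examples
#' sttcPair(c(1.0), c(5.0), dtS = 0.1, durationS = 10)  # -0.02
#' @export
sttcPair <- function(trainA, trainB, dtS = 0.1, durationS) {
  stopifnot(durationS > 0, dtS > 0)
  if (!length(trainA) || !length(trainB)) return(0)
  pA <- nearFraction(trainA, trainB, dtS)
  pB <- nearFraction(trainB, trainA, dtS)
  tA <- tiledFraction(trainA, dtS, durationS)
  tB <- tiledFraction(trainB, dtS, durationS)
  dA <- 1 - pA * tB
  dB <- 1 - pB * tA
  termA <- if (dA != 0) (pA - tB) / dA else NA_real_
  termB <- if (dB != 0) (pB - tA) / dB else NA_real_
  if (is.na(termA) && is.na(termB)) {
    message("sttcPair: both denominators zero; returning 0")
    return(0)
  }
  if (is.na(termA)) {
    message("sttcPair: degenerate denominator; returning the other term")
    return(termB)
  }
  if (is.na(termB)) {
    message("sttcPair: degenerate denominator; returning the other term")
    return(termA)
  }
  (termA + termB) / 2
}

#' STTC matrix of a recording
#'
#' Pairwise STTC over the active channels, with diagonal 1 for non-empty
#' trains. The mean STTC is the mean of the strictly-upper-triangle entries.
#'
#' @param rec an [MEARecording-class].
#' @param cfg an [sttcConfig()].
#' @param qc a [qcConfig()].
#' @return list with `matrix` (symmetric, dimnames = channel ids), `channels`
#'   and `meanSttc` (`NA` when fewer than 2 active channels).
#' @export
sttcMatrix <- function(rec, cfg = sttcConfig(), qc = qcConfig()) {
  act <- activeChannels(rec, qc)
  n <- length(act)
  m <- matrix(NA_real_, n, n, dimnames = list(act, act))
  st <- spikeTimes(rec)
  dur <- durationS(rec)
  if (n) {
    # per-channel tiled fractions computed once
    tFrac <- vapply(st[act], tiledFraction, numeric(1), dtS = cfg$dtS,
                    durationS = dur)
    for (i in seq_len(n)) {
      m[i, i] <- if (length(st[[act[i]]])) 1 else 0
      if (i < n) {
        for (j in (i + 1L):n) {
          a <- st[[act[i]]]; b <- st[[act[j]]]
          v <- if (!length(a) || !length(b)) 0 else {
            pA <- nearFraction(a, b, cfg$dtS)
            pB <- nearFraction(b, a, cfg$dtS)
            dA <- 1 - pA * tFrac[j]
            dB <- 1 - pB * tFrac[i]
            if (dA == 0 && dB == 0) 0
            else if (dA == 0) (pB - tFrac[i]) / dB
            else if (dB == 0) (pA - tFrac[j]) / dA
            else ((pA - tFrac[j]) / dA + (pB - tFrac[i]) / dB) / 2
          }
          m[i, j] <- v
          m[j, i] <- v
        }
      }
    }
  }
  meanSttc <- if (n >= 2) mean(m[upper.tri(m)]) else NA_real_
  list(matrix = m, channels = act, meanSttc = meanSttc)
}

# DBSCAN on a precomputed distance matrix. Core point: at least minSamples
# neighbors within eps (excluding itself unless selfCounting). Returns
# integer labels: 0 = noise, 1..k = clusters.
dbscanPrecomputed <- function(d, eps, minSamples, selfCounting = FALSE) {
  n <- nrow(d)
  if (!n) return(integer(0))
  need <- if (selfCounting) minSamples - 1L else minSamples
  nbr <- lapply(seq_len(n), function(i) setdiff(which(d[i, ] <= eps), i))
  core <- vapply(nbr, length, integer(1)) >= need
  labels <- integer(n)  # 0 = unvisited/noise
  k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    k <- k + 1L
    labels[i] <- k
    queue <- nbr[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- k
        if (core[j]) queue <- c(queue, nbr[[j]][labels[nbr[[j]]] == 0L])
      }
    }
  }
  labels
}

#' Count highly synchronized electrode clusters
#'
#' Runs DBSCAN on the precomputed distance `d(i, j) = 1 - STTC(i, j)` with
#' the configured `eps` and minimum-samples rule and returns the number of
#' clusters found (noise electrodes excluded).
#'
#' @param m STTC matrix (symmetric numeric matrix) or the list returned by
#'   [sttcMatrix()].
#' @param cfg an [sttcConfig()].
#' @return integer cluster count.
#' @export
sttcDbscanClusters <- function(m, cfg = sttcConfig()) {
  if (is.list(m)) m <- m$matrix
  if (!nrow(m)) return(0L)
  d <- 1 - m
  diag(d) <- 0
  labels <- dbscanPrecomputed(d, cfg$dbscanEps, cfg$dbscanMinSamples,
                              cfg$selfCounting)
  max(c(0L, labels))
}
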