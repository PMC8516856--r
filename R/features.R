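#' The 18 electrophysiological features
#'
#' Canonical column order of the per-recording feature vector: spike features
#' (`ch_spikes`, `mfr`, `network_spikes`, `isi`), burst features
#' (`ch_bursts`, `mbr`, `burst_duration`, `network_bursts`, `ibi`,
#' `burst_pct_spikes`, `burst_isi`, `burst_peakfreq`, `burst_surprise`),
#' synchrony (`sttc`, `sttc_dbscan`) and connectivity (`node_degree`,
#' `clustering_coeff`, `efficiency`).
#'
#' @return character vector of length 18.
#' @export
featureNames <- function() {
  c("ch_spikes", "mfr", "network_spikes", "isi",
    "ch_bursts", "mbr", "burst_duration", "network_bursts", "ibi",
    "burst_pct_spikes", "burst_isi", "burst_peakfreq", "burst_surprise",
    "sttc", "sttc_dbscan",
    "node_degree", "clustering_coeff", "efficiency")
}

#' Extract the electrophysiological feature vector of one recording
#'
#' Computes the 18 features (or a subset of feature groups, for speed when
#' only a few are needed) from a recording. Features that are undefined for
#' the recording (e.g. burst statistics when no burst was detected) are
#' returned as `NA`; downstream consumers decide how to handle missingness.
#'
#' @param rec an [MEARecording-class].
#' @param groups feature groups to compute: subset of
#'   `c("spikes", "bursts", "synchrony", "connectivity")`.
#' @param burstCfg a [burstConfig()].
#' @param netCfg a [networkEventConfig()].
#' @param sttcCfg an [sttcConfig()].
#' @param connCfg a [connectivityConfig()].
#' @param qc a [qcConfig()].
#' @return named numeric vector over [featureNames()] (uncomputed groups are
#'   `NA`).
#' @export
extractFeatures <- function(rec,
                            groups = c("spikes", "bursts", "synchrony",
                                       "connectivity"),
                            burstCfg = burstConfig(),
                            netCfg = networkEventConfig(),
                            sttcCfg = sttcConfig(),
                            connCfg = connectivityConfig(),
                            qc = qcConfig()) {
  groups <- match.arg(groups, several.ok = TRUE)
  fv <- stats::setNames(rep(NA_real_, 18L), featureNames())
  if ("spikes" %in% groups) {
    sf <- spikeFeatures(rec, qc)
    fv["ch_spikes"] <- sf$ch_spikes
    fv["mfr"] <- sf$mfr
    fv["isi"] <- sf$isi
    fv["network_spikes"] <- networkSpikeRate(rec, netCfg, qc)
  }
  if ("bursts" %in% groups) {
    bf <- burstFeatures(rec, burstCfg, qc)
    for (nm in c("ch_bursts", "mbr", "burst_duration", "ibi",
                 "burst_pct_spikes", "burst_isi", "burst_peakfreq",
                 "burst_surprise")) {
      fv[nm] <- bf[[nm]]
    }
    fv["network_bursts"] <- networkBurstRate(bf$bursts, rec, netCfg)
  }
  if ("synchrony" %in% groups) {
    sm <- sttcMatrix(rec, sttcCfg, qc)
    fv["sttc"] <- sm$meanSttc
    fv["sttc_dbscan"] <- sttcDbscanClusters(sm, sttcCfg)
  }
  if ("connectivity" %in% groups) {
    g <- buildGraph(rec, connCfg, qc)
    gm <- graphMetrics(g)
    fv["node_degree"] <- gm$nodeDegree
    fv["clustering_coeff"] <- gm$clusteringCoeff
    fv["efficiency"] <- gm$efficiency
  }
  fv
}

#' Feature table of a set of recordings
#'
#' @param recs list of [MEARecording-class] or an [MEACohort-class].
#' @inheritParams extractFeatures
#' @return data.frame with `dish`, `div` and one column per feature.
#' @export
featureTable <- function(recs,
                         groups = c("spikes", "bursts", "synchrony",
                                    "connectivity"),
                         burstCfg = burstConfig(),
                         netCfg = networkEventConfig(),
                         sttcCfg = sttcConfig(),
                         connCfg = connectivityConfig(),
                         qc = qcConfig()) {
  if (methods::is(recs, "MEACohort")) recs <- recordings(recs)
  rows <- lapply(recs, function(r) {
    data.frame(dish = dishId(r), div = div(r),
               as.list(extractFeatures(r, groups, burstCfg, netCfg, sttcCfg,
                                       connCfg, qc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
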