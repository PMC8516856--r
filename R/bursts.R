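#' Max-interval burst-detection parameters
#'
#' Defaults are the study's settings: maximum initial ISI to start a burst
#' 0.1 s, maximum ISI to end it 0.2 s, minimum inter-burst interval 0.2 s,
#' minimum burst duration 0.003 s, minimum 3 spikes per burst.
#'
#' @param maxBeginIsiS maximum ISI opening a burst (s).
#' @param maxEndIsiS maximum ISI keeping a burst open (s).
#' @param minIbiS candidate bursts closer than this are merged (s).
#' @param minBurstDurS minimum burst duration (s).
#' @param minSpikes minimum spikes per burst.
#' @return list of class `burstConfig`.
#' @export
burstConfig <- function(maxBeginIsiS = 0.1, maxEndIsiS = 0.2, minIbiS = 0.2,
                        minBurstDurS = 0.003, minSpikes = 3L) {
  stopifnot(maxBeginIsiS > 0, maxEndIsiS > 0, minIbiS > 0, minBurstDurS > 0,
            minSpikes >= 1, maxBeginIsiS <= maxEndIsiS)
  structure(list(maxBeginIsiS = maxBeginIsiS, maxEndIsiS = maxEndIsiS,
                 minIbiS = minIbiS, minBurstDurS = minBurstDurS,
                 minSpikes = as.integer(minSpikes)),
            class = "burstConfig")
}

#' Detect bursts on one spike train (maximum-interval method)
#'
#' Scans inter-spike intervals: a candidate burst opens at the first ISI not
#' exceeding `maxBeginIsiS`, extends while subsequent ISIs stay within
#' `maxEndIsiS`, and closes otherwise. Candidates separated by a gap shorter
#' than `minIbiS` are merged (together with any spikes in the gap), and only
#' then are candidates violating `minSpikes` or `minBurstDurS` discarded.
#'
#' @param spikeTimes sorted numeric spike times (s).
#' @param cfg a [burstConfig()].
#' @return data.frame with one row per burst: `tStart`, `tEnd`, `nSpikes`,
#'   `iStart`, `iEnd` (spike indices); zero rows when no burst is found.
#' @examples
#' detectBursts(c(0, 0.05, 0.10, 1.0))   # one 3-spike burst
#' detectBursts(c(0, 0.5, 1.0, 1.5))     # none: all ISIs > 0.1 s
#' @export
detectBursts <- function(spikeTimes, cfg = burstConfig()) {
  empty <- data.frame(tStart = numeric(0), tEnd = numeric(0),
                      nSpikes = integer(0), iStart = integer(0),
                      iEnd = integer(0))
  n <- length(spikeTimes)
  if (n < 2L) return(empty)
  stopifnot(!is.unsorted(spikeTimes))
  isi <- diff(spikeTimes)

  # candidate bursts as index ranges [iStart, iEnd]
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (isi[i] <= cfg$maxBeginIsiS) {
      j <- i + 1L
      while (j <= n - 1L && isi[j] <= cfg$maxEndIsiS) j <- j + 1L
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(starts)) return(empty)

  # merge candidates separated by a gap < minIbiS (gap spans any loose spikes)
  mS <- starts[1]; mE <- ends[1]
  outS <- integer(0); outE <- integer(0)
  if (length(starts) > 1L) {
    for (k in 2L:length(starts)) {
      if (spikeTimes[starts[k]] - spikeTimes[mE] < cfg$minIbiS) {
        mE <- ends[k]
      } else {
        outS <- c(outS, mS); outE <- c(outE, mE)
        mS <- starts[k]; mE <- ends[k]
      }
    }
  }
  outS <- c(outS, mS); outE <- c(outE, mE)

  keep <- (outE - outS + 1L) >= cfg$minSpikes &
    (spikeTimes[outE] - spikeTimes[outS]) >= cfg$minBurstDurS
  outS <- outS[keep]; outE <- outE[keep]
  data.frame(tStart = spikeTimes[outS], tEnd = spikeTimes[outE],
             nSpikes = outE - outS + 1L, iStart = outS, iEnd = outE)
}

#' Spike-level features of a recording
#'
#' @param rec an [MEARecording-class].
#' @param qc a [qcConfig()] defining channel activity.
#' @return named list: `ch_spikes` (number of active channels), `mfr` (mean
#'   firing rate over active channels, Hz) and `isi` (mean over channels with
#'   at least two spikes of their mean inter-spike interval, s). `mfr` and
#'   `isi` are `NA` when undefined.
#' @export
spikeFeatures <- function(rec, qc = qcConfig()) {
  act <- activeChannels(rec, qc)
  st <- spikeTimes(rec)[act]
  if (!length(act)) {
    return(list(ch_spikes = 0L, mfr = NA_real_, isi = NA_real_))
  }
  rates <- lengths(st) / durationS(rec)
  withIsi <- st[lengths(st) >= 2L]
  isi <- if (length(withIsi)) {
    mean(vapply(withIsi, function(x) mean(diff(x)), numeric(1)))
  } else NA_real_
  list(ch_spikes = length(act), mfr = mean(rates), isi = isi)
}

#' Burst-level features of a recording
#'
#' Bursts are detected per channel with [detectBursts()] on the recording's
#' eligible channels. The burst surprise is the Legendy-style Poisson
#' surprise `-log P(X >= n)` with `X ~ Poisson(rate_ch * duration_burst)`,
#' where `rate_ch` is the channel's overall firing rate; natural log by
#' default.
#'
#' @param rec an [MEARecording-class].
#' @param cfg a [burstConfig()].
#' @param qc a [qcConfig()].
#' @param logBase base of the surprise logarithm (default `exp(1)`).
#' @return named list with `ch_bursts`, `mbr` (bursts/min over bursting
#'   channels), `burst_duration` (s), `ibi` (s), `burst_pct_spikes` (%),
#'   `burst_isi` (s), `burst_peakfreq` (Hz), `burst_surprise`, plus the
#'   per-channel burst tables in `bursts`. Burst features are `NA` when no
#'   burst is detected.
#' @export
burstFeatures <- function(rec, cfg = burstConfig(), qc = qcConfig(),
                          logBase = exp(1)) {
  chans <- eligibleChannels(rec)
  st <- spikeTimes(rec)
  dur <- durationS(rec)
  burstsByCh <- lapply(chans, function(ch) detectBursts(st[[ch]], cfg))
  names(burstsByCh) <- as.character(chans)
  nB <- vapply(burstsByCh, nrow, integer(1))
  bursting <- which(nB > 0)
  act <- activeChannels(rec, qc)

  out <- list(ch_bursts = length(bursting), mbr = NA_real_,
              burst_duration = NA_real_, ibi = NA_real_,
              burst_pct_spikes = NA_real_, burst_isi = NA_real_,
              burst_peakfreq = NA_real_, burst_surprise = NA_real_,
              bursts = burstsByCh)
  if (!length(bursting)) return(out)

  out$mbr <- mean(nB[bursting] / (dur / 60))

  perCh <- lapply(bursting, function(k) {
    ch <- chans[k]
    b <- burstsByCh[[k]]
    train <- st[[ch]]
    rateCh <- length(train) / dur
    di <- diff(train)
    csIsi <- c(0, cumsum(di))
    meanIsi <- (csIsi[b$iEnd] - csIsi[b$iStart]) / (b$nSpikes - 1L)
    minIsi <- vapply(seq_len(nrow(b)), function(r) {
      min(di[b$iStart[r]:(b$iEnd[r] - 1L)])
    }, numeric(1))
    # Poisson tail surprise: P(X >= n) with lambda = rateCh * burst duration
    logTail <- stats::ppois(b$nSpikes - 1L, rateCh * (b$tEnd - b$tStart),
                            lower.tail = FALSE, log.p = TRUE)
    list(durs = b$tEnd - b$tStart, isis = meanIsi, peaks = 1 / minIsi,
         surpr = -logTail / log(logBase),
         ibis = if (nrow(b) >= 2L) b$tStart[-1] - b$tEnd[-nrow(b)]
                else numeric(0),
         nSpikes = sum(b$nSpikes))
  })
  durs <- unlist(lapply(perCh, `[[`, "durs"))
  isis <- unlist(lapply(perCh, `[[`, "isis"))
  peaks <- unlist(lapply(perCh, `[[`, "peaks"))
  surpr <- unlist(lapply(perCh, `[[`, "surpr"))
  ibis <- unlist(lapply(perCh, `[[`, "ibis"))
  spikesInBursts <- sum(vapply(perCh, `[[`, numeric(1), "nSpikes"))
  out$burst_duration <- mean(durs)
  out$burst_isi <- mean(isis)
  out$burst_peakfreq <- mean(peaks)
  out$burst_surprise <- mean(surpr)
  out$ibi <- if (length(ibis)) mean(ibis) else NA_real_
  totalSpikes <- sum(lengths(st[act]))
  out$burst_pct_spikes <- if (totalSpikes > 0) {
    100 * spikesInBursts / totalSpikes
  } else NA_real_
  out
}

#' Network-event detection parameters
#'
#' Network spikes and network bursts quantify near-simultaneous activity
#' across channels. These thresholds are package conventions (the original
#' software's exact definitions are not public) and are configurable.
#'
#' @param nsWindowS bin width for network-spike detection (s).
#' @param nsFrac fraction of active channels that must fire within a bin.
#' @param nbFrac fraction of bursting channels that must burst concurrently.
#' @return list of class `networkEventConfig`.
#' @export
networkEventConfig <- function(nsWindowS = 0.1, nsFrac = 0.25,
                               nbFrac = 0.25) {
  stopifnot(nsWindowS > 0, nsFrac > 0, nsFrac <= 1, nbFrac > 0, nbFrac <= 1)
  structure(list(nsWindowS = nsWindowS, nsFrac = nsFrac, nbFrac = nbFrac),
            class = "networkEventConfig")
}

#' Network spike rate (events/s)
#'
#' Partitions the recording into `nsWindowS` bins; a network spike is a
#' maximal run of bins in which at least `ceiling(nsFrac * nActive)` distinct
#' active channels fire.
#'
#' @param rec an [MEARecording-class].
#' @param cfg a [networkEventConfig()].
#' @param qc a [qcConfig()].
#' @return events per second (0 when no active channel).
#' @export
networkSpikeRate <- function(rec, cfg = networkEventConfig(),
                             qc = qcConfig()) {
  act <- activeChannels(rec, qc)
  if (!length(act)) return(0)
  dur <- durationS(rec)
  nBins <- ceiling(dur / cfg$nsWindowS)
  counts <- integer(nBins)
  for (ch in act) {
    t <- spikeTimes(rec)[[ch]]
    if (!length(t)) next
    bins <- unique(pmin(nBins, floor(t / cfg$nsWindowS) + 1L))
    counts[bins] <- counts[bins] + 1L
  }
  thr <- ceiling(cfg$nsFrac * length(act))
  hits <- counts >= thr
  runs <- sum(hits & !c(FALSE, hits[-nBins]))  # run starts
  runs / dur
}

#' Network burst rate (events/min)
#'
#' Overlays all per-channel burst intervals; a network burst is a maximal
#' time interval during which at least `max(2, ceiling(nbFrac * nBursting))`
#' channels have an ongoing burst.
#'
#' @param burstsByCh named list of per-channel burst tables, as returned in
#'   `burstFeatures()$bursts`.
#' @param rec the [MEARecording-class] the bursts came from.
#' @param cfg a [networkEventConfig()].
#' @return events per minute (0 when no channel bursts).
#' @export
networkBurstRate <- function(burstsByCh, rec, cfg = networkEventConfig()) {
  nB <- vapply(burstsByCh, nrow, integer(1))
  bursting <- sum(nB > 0)
  if (!bursting) return(0)
  thr <- max(2L, ceiling(cfg$nbFrac * bursting))
  starts <- unlist(lapply(burstsByCh, function(b) b$tStart))
  ends <- unlist(lapply(burstsByCh, function(b) b$tEnd))
  ev <- rbind(data.frame(t = starts, d = 1L), data.frame(t = ends, d = -1L))
  ev <- ev[order(ev$t, -ev$d), ]  # starts before ends at equal times
  depth <- cumsum(ev$d)
  above <- depth >= thr
  nEvents <- sum(above & !c(FALSE, above[-length(above)]))
  nEvents / (durationS(rec) / 60)
}
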