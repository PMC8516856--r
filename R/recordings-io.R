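#' Recording-level quality-control configuration
#'
#' Defaults follow the study's acceptance rules for MEA recordings: a channel
#' is active when it fires strictly more than 3 spikes/min; a recording needs
#' 10 or more active channels; a dish is discarded when more than 6 channels
#' are flagged as noise (here: listed on the exclusion list, since spike-time
#' input carries no waveforms) or when network spike activity drops by more
#' than 50% between consecutive second-week recordings.
#'
#' @param minRateSpikesPerMin active-channel rate threshold (strict `>`).
#' @param minActiveChannels minimum active channels per qualifying recording.
#' @param maxNoiseChannels maximum excluded (noisy) channels tolerated.
#' @param maxSecondWeekDrop maximal tolerated fractional drop of the network
#'   spike rate between consecutive second-week (DIV 9-14) recordings.
#' @return list of class `qcConfig`.
#' @export
qcConfig <- function(minRateSpikesPerMin = 3, minActiveChannels = 10,
                     maxNoiseChannels = 6, maxSecondWeekDrop = 0.5) {
  stopifnot(minRateSpikesPerMin >= 0, minActiveChannels >= 0,
            maxNoiseChannels >= 0,
            maxSecondWeekDrop >= 0, maxSecondWeekDrop <= 1)
  structure(list(minRateSpikesPerMin = minRateSpikesPerMin,
                 minActiveChannels = minActiveChannels,
                 maxNoiseChannels = maxNoiseChannels,
                 maxSecondWeekDrop = maxSecondWeekDrop),
            class = "qcConfig")
}

#' Developmental interval scheme
#'
#' The default groups days in vitro into the three intervals used throughout
#' the analysis: 6-8, 9-12 and 13-18 (inclusive on both ends).
#'
#' @param intervals list of length-2 integer vectors (inclusive DIV ranges),
#'   ordered and disjoint.
#' @return list of class `intervalScheme` with `intervals` and `labels`.
#' @export
intervalScheme <- function(intervals = list(c(6L, 8L), c(9L, 12L),
                                            c(13L, 18L))) {
  lo <- vapply(intervals, `[`, numeric(1), 1)
  hi <- vapply(intervals, `[`, numeric(1), 2)
  stopifnot(all(lo <= hi), !is.unsorted(c(rbind(lo, hi)), strictly = TRUE))
  structure(list(intervals = intervals,
                 labels = sprintf("div%d_%d", lo, hi)),
            class = "intervalScheme")
}

intervalOf <- function(div, scheme) {
  for (i in seq_along(scheme$intervals)) {
    r <- scheme$intervals[[i]]
    if (div >= r[1] && div <= r[2]) return(i)
  }
  NA_integer_
}

#' Is a spike train active?
#'
#' A channel counts as active when its firing rate strictly exceeds the QC
#' threshold (default 3 spikes/min).
#'
#' @param spikeTimes numeric spike-time vector (seconds).
#' @param durationS recording duration (seconds).
#' @param qc a [qcConfig()].
#' @return logical scalar.
#' @examples
#' channelIsActive(seq_len(15) * 10, 300)  # 3.0/min: not active (strict >)
#' channelIsActive(seq_len(16) * 10, 300)  # 3.2/min: active
#' @export
channelIsActive <- function(spikeTimes, durationS, qc = qcConfig()) {
  length(spikeTimes) / (durationS / 60) > qc$minRateSpikesPerMin
}

#' Read / write a spike-time table
#'
#' The on-disk format is a TSV with comment metadata lines (`# dish=`,
#' `# div=`, `# duration_s=`, optional `# exclude=` comma-separated channel
#' ids) followed by a `channel<TAB>time_s` header and one row per spike.
#' Writing then reading reproduces the recording exactly (times are stored at
#' full 0.04 ms grid precision).
#'
#' @param path file path.
#' @param nChannels minimum channel count of the returned recording (the
#'   file's maximum channel id is used if larger); default 60.
#' @return `readRecording` returns an [MEARecording-class];
#'   `writeRecording` invisibly returns `path`.
#' @export
readRecording <- function(path, nChannels = 60L) {
  lines <- readLines(path)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[trimws(substr(kv, 1, eq - 1))]] <-
        trimws(substr(kv, eq + 1, nchar(kv)))
    }
    i <- i + 1L
  }
  for (key in c("dish", "div", "duration_s")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("%s: missing metadata line '# %s=...'", path, key))
    }
  }
  if (i > length(lines) || !identical(strsplit(lines[i], "\t")[[1]],
                                      c("channel", "time_s"))) {
    stop(sprintf("%s: line %d: expected header 'channel\\ttime_s'", path, i))
  }
  durationS <- as.numeric(meta$duration_s)
  body <- lines[-seq_len(i)]
  body <- body[nzchar(body)]
  channel <- integer(length(body))
  time <- numeric(length(body))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      stop(sprintf("%s: line %d: expected 2 tab-separated fields",
                   path, i + bad[1]))
    }
    channel <- as.integer(vapply(parts, `[`, character(1), 1))
    time <- as.numeric(vapply(parts, `[`, character(1), 2))
    if (anyNA(channel) || anyNA(time) || any(channel < 1L)) {
      bad <- which(is.na(channel) | is.na(time) | channel < 1L)[1]
      stop(sprintf("%s: line %d: malformed spike row", path, i + bad))
    }
    if (any(time < 0 | time > durationS)) {
      bad <- which(time < 0 | time > durationS)[1]
      stop(sprintf("%s: line %d: spike time %g outside [0, %g]",
                   path, i + bad, time[bad], durationS))
    }
    unsorted <- which(diff(time) < 0 & channel[-1] == channel[-length(channel)])
    if (length(unsorted)) {
      stop(sprintf("%s: line %d: unsorted spike times within channel %d",
                   path, i + unsorted[1] + 1L, channel[unsorted[1] + 1L]))
    }
  }
  nch <- max(nChannels, if (length(channel)) max(channel) else 0L)
  spikes <- rep(list(numeric(0)), nch)
  if (length(channel)) {
    byCh <- split(time, factor(channel, levels = seq_len(nch)))
    spikes <- unname(lapply(byCh, as.numeric))
  }
  excl <- integer()
  if (!is.null(meta$exclude) && nzchar(meta$exclude)) {
    excl <- as.integer(strsplit(meta$exclude, ",")[[1]])
  }
  MEARecording(meta$dish, as.integer(meta$div), durationS, spikes,
               nChannels = nch, excludedChannels = excl)
}

#' @rdname readRecording
#' @param rec an [MEARecording-class].
#' @export
writeRecording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dish=%s", dishId(rec)),
               sprintf("# div=%d", div(rec)),
               sprintf("# duration_s=%g", durationS(rec))), con)
  if (length(excludedChannels(rec))) {
    writeLines(sprintf("# exclude=%s",
                       paste(excludedChannels(rec), collapse = ",")), con)
  }
  writeLines("channel\ttime_s", con)
  st <- spikeTimes(rec)
  for (ch in seq_along(st)) {
    if (length(st[[ch]])) {
      writeLines(sprintf("%d\t%.5f", ch, st[[ch]]), con)
    }
  }
  invisible(path)
}

#' Apply recording-level quality control to one dish
#'
#' A dish is kept when it has at least one recording at DIV 6-8 and at least
#' one at DIV 9-18, each with at least `minActiveChannels` active channels;
#' when no recording lists more than `maxNoiseChannels` excluded channels; and
#' when the network spike rate never drops by more than `maxSecondWeekDrop`
#' between consecutive second-week (DIV 9-14) recordings.
#'
#' @param recs list of [MEARecording-class] sharing one dish id.
#' @param qc a [qcConfig()].
#' @param netCfg a [networkEventConfig()] used for the network-spike-rate
#'   drop rule.
#' @return list with `kept` (the recordings, or an empty list) and `reasons`
#'   (character vector of rejection reasons, empty if kept).
#' @export
applyQc <- function(recs, qc = qcConfig(), netCfg = networkEventConfig()) {
  stopifnot(length(recs) >= 1)
  ids <- unique(vapply(recs, dishId, character(1)))
  if (length(ids) != 1L) stop("applyQc expects recordings of a single dish")
  divs <- vapply(recs, div, integer(1))
  recs <- recs[order(divs)]
  divs <- sort(divs)
  reasons <- character()

  nAct <- vapply(recs, function(r) length(activeChannels(r, qc)), integer(1))
  okFirst <- any(divs >= 6 & divs <= 8 & nAct >= qc$minActiveChannels)
  okLater <- any(divs >= 9 & divs <= 18 & nAct >= qc$minActiveChannels)
  if (!okFirst) {
    reasons <- c(reasons,
      "missing DIV 6-8 recording with enough active channels")
  }
  if (!okLater) {
    reasons <- c(reasons,
      "missing DIV 9-18 recording with enough active channels")
  }

  nNoise <- vapply(recs, function(r) length(excludedChannels(r)), integer(1))
  if (any(nNoise > qc$maxNoiseChannels)) {
    reasons <- c(reasons, sprintf("more than %d noise channels",
                                  qc$maxNoiseChannels))
  }

  # Second-week stability: compare network spike rates of consecutive
  # recordings whose DIVs both fall in 9-14.
  wk2 <- which(divs >= 9 & divs <= 14)
  if (length(wk2) >= 2) {
    rates <- vapply(recs[wk2], networkSpikeRate, numeric(1), cfg = netCfg,
                    qc = qc)
    for (j in seq_len(length(wk2) - 1L)) {
      if (rates[j] > 0 && (rates[j] - rates[j + 1]) / rates[j] >
            qc$maxSecondWeekDrop) {
        reasons <- c(reasons, sprintf(
          "network spike rate dropped %.0f%% between DIV %d and %d",
          100 * (rates[j] - rates[j + 1]) / rates[j],
          divs[wk2[j]], divs[wk2[j + 1]]))
        break
      }
    }
  }

  list(kept = if (length(reasons)) list() else recs, reasons = reasons)
}

#' Quality control over a cohort
#'
#' Groups recordings by dish, applies [applyQc()] per dish, and returns the
#' kept recordings plus a rejection log.
#'
#' @param recs list of [MEARecording-class] (any number of dishes).
#' @inheritParams applyQc
#' @return list with `kept` (flat list of recordings) and `log` (data.frame
#'   dish, kept, reasons).
#' @export
cohortQc <- function(recs, qc = qcConfig(), netCfg = networkEventConfig()) {
  ids <- vapply(recs, dishId, character(1))
  kept <- list()
  logRows <- list()
  for (d in unique(ids)) {
    res <- applyQc(recs[ids == d], qc, netCfg)
    kept <- c(kept, res$kept)
    logRows[[d]] <- data.frame(
      dish = d, kept = length(res$kept) > 0,
      reasons = paste(res$reasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  list(kept = kept, log = do.call(rbind, c(logRows, make.row.names = FALSE)))
}

#' Aggregate per-recording features into per-dish trajectories
#'
#' Computes, for every dish and DIV interval, the arithmetic mean of each
#' feature over the recordings falling in that interval. Intervals without a
#' recording are reported with `NA` features and `nRecordings = 0`.
#'
#' @param featureTable data.frame with columns `dish`, `div` and one column
#'   per feature (see [featureNames()]).
#' @param scheme an [intervalScheme()].
#' @return data.frame keyed by (`dish`, `interval`) with `nRecordings` and
#'   the interval-mean feature columns.
#' @export
aggregateTrajectories <- function(featureTable, scheme = intervalScheme()) {
  featCols <- setdiff(names(featureTable), c("dish", "div"))
  dishes <- unique(featureTable$dish)
  iv <- vapply(featureTable$div, intervalOf, integer(1), scheme = scheme)
  rows <- list()
  for (d in dishes) {
    for (i in seq_along(scheme$intervals)) {
      sel <- featureTable$dish == d & !is.na(iv) & iv == i
      n <- sum(sel)
      means <- if (n > 0) {
        colMeans(featureTable[sel, featCols, drop = FALSE], na.rm = TRUE)
      } else {
        stats::setNames(rep(NA_real_, length(featCols)), featCols)
      }
      means[!is.finite(means)] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        dish = d, interval = scheme$labels[i], nRecordings = n,
        as.list(means), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
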