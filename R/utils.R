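# Internal helpers shared across modules.

# 25 kHz acquisition grid: 0.04 ms.
SAMPLE_STEP_S <- 4e-5

quantizeTimes <- function(t) round(t / SAMPLE_STEP_S) * SAMPLE_STEP_S

# Deterministic substream seeds: mix a base seed with integer counters so
# per-dish / per-recording streams do not depend on iteration order.
# Constants are arbitrary large primes; result stays below 2^31.
deriveSeed <- function(base, ...) {
  ks <- c(...)
  s <- as.double(base) %% 2147483647
  for (k in ks) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}

# Channels eligible for analysis: not on the exclusion list.
eligibleChannels <- function(rec) {
  setdiff(seq_len(nChannels(rec)), excludedChannels(rec))
}

# Ids of active channels under the spike-rate QC rule.
activeChannels <- function(rec, qc = qcConfig()) {
  ch <- eligibleChannels(rec)
  ch[vapply(spikeTimes(rec)[ch], channelIsActive, logical(1),
            durationS = durationS(rec), qc = qc)]
}

# Column-wise mean imputation; returns the matrix and a log of filled cells.
meanImpute <- function(x) {
  filled <- 0L
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) {
      mu <- mean(x[!miss, j])
      if (!is.finite(mu)) mu <- 0
      x[miss, j] <- mu
      filled <- filled + sum(miss)
    }
  }
  attr(x, "imputedCells") <- filled
  x
}
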