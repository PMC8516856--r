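test_that("hand-traced max-interval fixtures reproduce exactly", {
  # single burst: ISI 0.05 opens, 0.05 extends, 0.9 closes
  b <- detectBursts(c(0, 0.05, 0.10, 1.0))
  expect_equal(nrow(b), 1)
  expect_equal(b$tStart, 0)
  expect_equal(b$tEnd, 0.10)
  expect_equal(b$nSpikes, 3L)

  # no burst: all ISIs above the 0.1 s opening threshold
  expect_equal(nrow(detectBursts(c(0, 0.5, 1.0, 1.5))), 0)

  # merge rule: two 3-spike candidates separated by a 0.15 s gap (< 0.2 s)
  b <- detectBursts(c(0, 0.05, 0.10, 0.25, 0.30, 0.35))
  expect_equal(nrow(b), 1)
  expect_equal(b$nSpikes, 6L)
  expect_equal(b$tStart, 0)
  expect_equal(b$tEnd, 0.35)
})

test_that("detected bursts always satisfy the burst invariants", {
  cfg <- burstConfig()
  set.seed(11)
  for (i in 1:300) {
    # mix of background and clustered spikes to exercise all paths
    train <- sort(c(runif(rpois(1, 30), 0, 60),
                    rep(runif(rpois(1, 3), 0, 60), each = 4) +
                      cumsum(rexp(4, 50))))
    train <- unique(round(train, 5))
    b <- detectBursts(train, cfg)
    if (!nrow(b)) next
    expect_true(all(b$nSpikes >= cfg$minSpikes))
    expect_true(all(b$tEnd - b$tStart >= cfg$minBurstDurS))
    for (r in seq_len(nrow(b))) {
      isis <- diff(train[b$iStart[r]:b$iEnd[r]])
      expect_true(all(isis <= cfg$maxEndIsiS))
    }
    # disjoint and ordered
    if (nrow(b) > 1) {
      expect_true(all(b$tStart[-1] > b$tEnd[-nrow(b)]))
    }
  }
})

test_that("burst detection is translation invariant", {
  set.seed(21)
  train <- sort(runif(200, 0, 60))
  b0 <- detectBursts(train)
  b1 <- detectBursts(train + 17.3)
  expect_equal(b1$tStart, b0$tStart + 17.3)
  expect_equal(b1$nSpikes, b0$nSpikes)
})

test_that("spike features match their closed forms", {
  rec <- quickRec(list(seq(0.5, 299.5, by = 1)))  # 300 spikes in 300 s
  sf <- spikeFeatures(rec)
  expect_equal(sf$mfr, 1.0)
  expect_equal(sf$ch_spikes, 1L)

  # channels at 1 and 3 Hz average to 2 Hz
  rec <- quickRec(list(seq(0.5, 299.5, by = 1), seq(0.2, 299.9, length.out = 900)))
  expect_equal(spikeFeatures(rec)$mfr, 2.0, tolerance = 1e-3)

  # mean ISI of [0, 1, 3] is 1.5 (channel active at a permissive threshold)
  rec <- quickRec(list(c(0, 1, 3)), duration = 10)
  sf <- spikeFeatures(rec, qc = qcConfig(minRateSpikesPerMin = 0))
  expect_equal(sf$isi, 1.5)

  # no active channels: flagged missing
  sf <- spikeFeatures(quickRec(list(numeric(0))))
  expect_equal(sf$ch_spikes, 0L)
  expect_true(is.na(sf$mfr))
})

test_that("burst features match hand-computed values", {
  # one channel, one 3-spike burst covering all spikes
  rec <- quickRec(list(c(0, 0.05, 0.10)), duration = 10)
  bf <- burstFeatures(rec, qc = qcConfig(minRateSpikesPerMin = 0))
  expect_equal(bf$ch_bursts, 1L)
  expect_equal(bf$burst_pct_spikes, 100)
  expect_equal(bf$burst_duration, 0.10)

  # burst ISIs {0.05, 0.025}: peak frequency = 40 Hz
  rec <- quickRec(list(c(0, 0.05, 0.075)), duration = 10)
  bf <- burstFeatures(rec, qc = qcConfig(minRateSpikesPerMin = 0))
  expect_equal(bf$burst_peakfreq, 40, tolerance = 1e-6)
  expect_equal(bf$burst_isi, 0.0375, tolerance = 1e-6)

  # no bursts: missing-flagged
  bf <- burstFeatures(quickRec(list(c(0, 1, 2, 3))))
  expect_equal(bf$ch_bursts, 0L)
  expect_true(is.na(bf$mbr))
})

test_that("burst surprise equals the Poisson tail oracle and is monotone", {
  # channel firing ~1 Hz overall with a 10-spike burst inside 0.2 s
  burst <- seq(0, 0.2, length.out = 10)
  rest <- seq(5, 295, length.out = 290)
  rec <- quickRec(list(sort(c(burst, rest))))
  bf <- burstFeatures(rec)
  rate <- 300 / 300
  expected <- -log(brutePoissonTail(10, rate * 0.2))
  expect_equal(bf$burst_surprise, expected, tolerance = 1e-6)
  expect_gt(bf$burst_surprise, 20)

  # more spikes at fixed duration and rate: surprise increases
  tail1 <- -log(brutePoissonTail(10, 0.2))
  tail2 <- -log(brutePoissonTail(15, 0.2))
  expect_gt(tail2, tail1)
})

test_that("network spike rate counts maximal volley runs", {
  expect_equal(networkSpikeRate(quickRec(rep(list(numeric(0)), 10))), 0)

  # 10 channels firing once within 20 ms around t = 5 s: one event
  qc0 <- qcConfig(minRateSpikesPerMin = 0)
  spikes <- lapply(1:10, function(ch) 5.0 + ch * 0.002)
  rate <- networkSpikeRate(quickRec(spikes), qc = qc0)
  expect_equal(rate, 1 / 300)

  # sparse independent firing rarely reaches the 25% threshold
  set.seed(31)
  rates <- vapply(1:10, function(s) {
    spikes <- lapply(1:10, function(ch) randTrain(0.2, 300))
    networkSpikeRate(quickRec(spikes), qc = qc0)
  }, numeric(1))
  expect_lt(mean(rates), 0.02)
})

test_that("network burst rate counts concurrent-burst episodes", {
  mkBursts <- function(starts) {
    lapply(1:8, function(ch) {
      train <- sort(unlist(lapply(starts, function(s) {
        seq(s, s + 0.3, length.out = 6)
      })))
      detectBursts(train)
    })
  }
  rec <- quickRec(rep(list(numeric(0)), 8))
  expect_equal(networkBurstRate(mkBursts(10.0), rec), 0.2)   # 1 per 5 min
  expect_equal(networkBurstRate(mkBursts(c(10, 100)), rec), 0.4)
  expect_equal(networkBurstRate(rep(list(detectBursts(numeric(0))), 8), rec),
               0)
})
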