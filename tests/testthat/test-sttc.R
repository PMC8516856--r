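test_that("STTC reproduces hand-evaluated and degenerate cases", {
  # single distant spikes: both P = 0, T = 0.02, so STTC = -0.02
  expect_equal(sttcPair(1.0, 5.0, dtS = 0.1, durationS = 10), -0.02)
  # identical non-empty trains with partial tiling
  expect_equal(sttcPair(c(1, 2, 3), c(1, 2, 3), 0.1, 10), 1.0)
  # empty-train convention
  expect_equal(sttcPair(numeric(0), c(1, 2), 0.1, 10), 0)
  expect_equal(sttcPair(numeric(0), numeric(0), 0.1, 10), 0)
})

test_that("STTC equals the brute-force oracle, is symmetric and bounded", {
  set.seed(41)
  for (i in 1:60) {
    dur <- 300
    a <- randTrain(runif(1, 0.1, 5), dur)
    b <- randTrain(runif(1, 0.1, 5), dur)
    if (!length(a) || !length(b)) next
    v <- sttcPair(a, b, 0.1, dur)
    expect_equal(v, bruteSttc(a, b, 0.1, dur), tolerance = 1e-10)
    expect_equal(v, sttcPair(b, a, 0.1, dur), tolerance = 1e-12)
    expect_gte(v, -1)
    expect_lte(v, 1)
  }
})

test_that("STTC is invariant under joint time translation", {
  set.seed(43)
  a <- randTrain(1, 100)
  b <- randTrain(1, 100)
  v0 <- sttcPair(a, b, 0.1, 200)
  v1 <- sttcPair(a + 50, b + 50, 0.1, 200)
  expect_equal(v0, v1, tolerance = 1e-9)
})

test_that("the STTC matrix averages the upper triangle over active channels", {
  # two identical active channels: mean 1
  train <- seq(0.5, 299.5, by = 1)
  sm <- sttcMatrix(quickRec(list(train, train)))
  expect_equal(sm$meanSttc, 1.0)
  expect_equal(dim(sm$matrix), c(2, 2))

  # independent sparse channels: mean near zero across seeds
  means <- vapply(1:10, function(s) {
    set.seed(100 + s)
    spikes <- lapply(1:3, function(ch) randTrain(0.5, 300))
    sttcMatrix(quickRec(spikes))$meanSttc
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)

  # fewer than two active channels: flagged missing
  expect_true(is.na(sttcMatrix(quickRec(list(train)))$meanSttc))
})

test_that("the matrix agrees with per-pair evaluation", {
  set.seed(47)
  spikes <- lapply(1:6, function(ch) randTrain(runif(1, 0.5, 3), 300))
  rec <- quickRec(spikes)
  st <- spikeTimes(rec)  # quantized trains, as the matrix sees them
  sm <- sttcMatrix(rec)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(sm$matrix[i, j],
                   sttcPair(st[[i]], st[[j]], 0.1, 300),
                   tolerance = 1e-12)
    }
  }
})

test_that("DBSCAN cluster counts match fixtures", {
  cfg <- sttcConfig()
  ones <- matrix(1, 10, 10)
  expect_equal(sttcDbscanClusters(ones, cfg), 1L)

  zeros <- matrix(0, 10, 10)
  diag(zeros) <- 1
  expect_equal(sttcDbscanClusters(zeros, cfg), 0L)

  # two 5-channel blocks: within 0.9 (distance 0.1 <= eps), between 0.1
  m <- matrix(0.1, 10, 10)
  m[1:5, 1:5] <- 0.9
  m[6:10, 6:10] <- 0.9
  diag(m) <- 1
  expect_equal(sttcDbscanClusters(m, cfg), 2L)
})

test_that("DBSCAN equals the exhaustive reference on random instances", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    # random symmetric "STTC-like" matrix with planted blocks
    m <- matrix(runif(n * n, -0.2, 0.7), n, n)
    nBlocks <- sample(0:3, 1)
    if (nBlocks > 0) {
      cuts <- sort(sample(seq_len(n), nBlocks))
      bounds <- c(0, cuts)
      for (b in seq_len(nBlocks)) {
        idx <- (bounds[b] + 1):bounds[b + 1]
        m[idx, idx] <- runif(1, 0.82, 0.99)
      }
    }
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 1
    d <- 1 - m
    diag(d) <- 0
    for (selfCount in c(FALSE, TRUE)) {
      got <- max(c(0L, meadev:::dbscanPrecomputed(d, 0.2, 3L, selfCount)))
      want <- bruteDbscanCount(d, 0.2, 3L, selfCount)
      expect_equal(got, want,
                   info = sprintf("case %d selfCounting=%s", i, selfCount))
    }
  }
})

test_that("the min-samples convention changes the smallest core size", {
  # 4 mutually close points: core needs 3 other neighbors (default) -> all
  # core; with 3 close points only the self-counting convention clusters
  d3 <- matrix(0.1, 3, 3); diag(d3) <- 0
  d4 <- matrix(0.1, 4, 4); diag(d4) <- 0
  cfgStrict <- sttcConfig(selfCounting = FALSE)
  cfgSelf <- sttcConfig(selfCounting = TRUE)
  expect_equal(sttcDbscanClusters(1 - d3, cfgStrict), 0L)
  expect_equal(sttcDbscanClusters(1 - d3, cfgSelf), 1L)
  expect_equal(sttcDbscanClusters(1 - d4, cfgStrict), 1L)
})

test_that("mean STTC does not decrease with recruitment probability", {
  pars <- function(p) list(lambdaBg = 0.3, nuNb = 6, pPart = p,
                           nActive = 20, burstLen = 8, intraIsiMs = 20,
                           jitterMs = 10)
  meanFor <- function(p) {
    mean(vapply(1:5, function(s) {
      rec <- simulateRecording(pars(p), div = 10, durationS = 120,
                               nChannels = 20, seed = 600 + s)
      sttcMatrix(rec)$meanSttc
    }, numeric(1)))
  }
  ms <- vapply(c(0.2, 0.5, 0.9), meanFor, numeric(1))
  expect_true(all(diff(ms) > -0.02))
  expect_gt(ms[3], ms[1])
})
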