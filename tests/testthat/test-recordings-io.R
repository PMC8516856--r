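test_that("spike-time TSV round-trips a recording exactly", {
  rec <- simulateRecording(defaultArchetypes()[[1]], div = 7, seed = 3,
                           durationS = 60, nChannels = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRecording(rec, path)
  back <- readRecording(path, nChannels = 20)
  expect_equal(dishId(back), dishId(rec))
  expect_equal(div(back), div(rec))
  expect_equal(durationS(back), durationS(rec))
  expect_equal(spikeTimes(back), spikeTimes(rec), tolerance = 1e-9)
})

test_that("a minimal file parses into the expected recording", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# dish=d1", "# div=7", "# duration_s=300",
               "channel\ttime_s", "1\t0.1", "1\t0.2"), path)
  rec <- readRecording(path, nChannels = 1)
  expect_equal(sum(lengths(spikeTimes(rec))), 2)
  expect_equal(spikeTimes(rec)[[1]], c(0.1, 0.2))
})

test_that("malformed files fail with the offending line named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# dish=d1", "# div=7", "# duration_s=300",
               "channel\ttime_s", "1\t301.0"), path)
  expect_error(readRecording(path), "line 5.*outside")

  writeLines(c("# dish=d1", "# div=7", "# duration_s=300",
               "channel\ttime_s", "1\t0.5", "1\t0.2"), path)
  expect_error(readRecording(path), "unsorted")

  writeLines(c("# dish=d1", "# div=7", "# duration_s=300",
               "wrong\theader"), path)
  expect_error(readRecording(path), "expected header")

  writeLines(c("# div=7", "# duration_s=300", "channel\ttime_s"), path)
  expect_error(readRecording(path), "dish")
})

test_that("excluded channels survive the round trip and never count", {
  rec <- MEARecording("d1", 8, 300,
                      c(list(seq(0.5, 299, by = 0.5)),
                        rep(list(seq(1, 299, by = 1)), 11)),
                      excludedChannels = 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeRecording(rec, path)
  back <- readRecording(path, nChannels = 12)
  expect_equal(excludedChannels(back), 1L)
  expect_false(1L %in% meadev:::activeChannels(back))
})

test_that("recording validity rejects out-of-range and unsorted spikes", {
  expect_error(methods::validObject(
    methods::new("MEARecording", dishId = "d", div = 5L, durationS = 10,
                 spikes = list(c(0.5, 11)), excludedChannels = integer())),
    "lie in")
  expect_error(methods::validObject(
    methods::new("MEARecording", dishId = "d", div = 5L, durationS = 10,
                 spikes = list(c(2, 1)), excludedChannels = integer())),
    "increasing")
})

test_that("channel activity uses the strict 3 spikes/min rule", {
  expect_false(channelIsActive(seq_len(15) * 10 - 5, 300))  # exactly 3.0/min
  expect_true(channelIsActive(seq_len(16) * 10 - 5, 300))   # 3.2/min
  expect_false(channelIsActive(numeric(0), 300))
})

test_that("QC keeps dishes with both intervals and enough active channels", {
  mkRec <- function(div, nAct, dish = "d1") {
    spikes <- rep(list(seq(0.3, 299, by = 0.7)), nAct)
    MEARecording(dish, div, 300, spikes, nChannels = 60)
  }
  res <- applyQc(list(mkRec(7, 12), mkRec(14, 15)))
  expect_length(res$kept, 2)
  expect_length(res$reasons, 0)

  res <- applyQc(list(mkRec(7, 12)))
  expect_length(res$kept, 0)
  expect_match(res$reasons, "DIV 9-18", all = FALSE)

  # active channels present but too few
  res <- applyQc(list(mkRec(7, 12), mkRec(14, 5)))
  expect_length(res$kept, 0)
})

test_that("QC is idempotent", {
  mkRec <- function(div, nAct) {
    MEARecording("d1", div, 300, rep(list(seq(0.3, 299, by = 0.7)), nAct),
                 nChannels = 60)
  }
  recs <- list(mkRec(7, 12), mkRec(14, 15))
  once <- applyQc(recs)
  twice <- applyQc(once$kept)
  expect_equal(length(once$kept), length(twice$kept))
  expect_equal(twice$reasons, character(0))
})

test_that("a >50% drop of network spike activity in week two rejects", {
  # 20 channels; at DIV 10 they fire 16 synchronized volleys; at DIV 12 the
  # same channels fire 16 spikes each but asynchronously (no volleys)
  sync <- lapply(1:20, function(ch) seq(5, 290, length.out = 16) + ch * 1e-4)
  async <- lapply(1:20, function(ch) {
    seq(0.11 * ch, 290, length.out = 16)
  })
  recSync <- MEARecording("d2", 10, 300, sync, nChannels = 60)
  recAsync <- MEARecording("d2", 12, 300, async, nChannels = 60)
  early <- MEARecording("d2", 7, 300, sync, nChannels = 60)

  kept <- applyQc(list(early, recSync,
                       MEARecording("d2", 12, 300, sync, nChannels = 60)))
  expect_length(kept$kept, 3)

  res <- applyQc(list(early, recSync, recAsync))
  expect_length(res$kept, 0)
  expect_match(res$reasons, "dropped", all = FALSE)
})

test_that("trajectory aggregation takes per-interval means", {
  ft <- data.frame(dish = "d1", div = c(13L, 13L, 18L), mfr = c(1, 2, 3),
                   sttc = c(0.1, 0.2, 0.3))
  tr <- aggregateTrajectories(ft)
  late <- tr[tr$interval == "div13_18", ]
  expect_equal(late$mfr, 2)
  expect_equal(late$sttc, 0.2)
  expect_equal(late$nRecordings, 3)
  # absent interval flagged, others filled
  expect_equal(tr[tr$interval == "div9_12", ]$nRecordings, 0)
  expect_true(is.na(tr[tr$interval == "div9_12", ]$mfr))
})

test_that("aggregation is invariant to recording order", {
  set.seed(9)
  ft <- data.frame(dish = rep(c("a", "b"), each = 4),
                   div = rep(c(7L, 7L, 10L, 15L), 2),
                   mfr = runif(8), sttc = runif(8))
  t1 <- aggregateTrajectories(ft)
  perm <- sample(nrow(ft))
  t2 <- aggregateTrajectories(ft[perm, ])
  t2 <- t2[order(match(t2$dish, t1$dish), match(t2$interval, t1$interval)), ]
  rownames(t2) <- NULL
  expect_equal(t1, t2)
})
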