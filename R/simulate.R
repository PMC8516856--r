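#' Developmental archetype parameters
#'
#' An archetype describes how one class of dishes develops: every generative
#' parameter is a function of the day in vitro (DIV), obtained by linear
#' interpolation between an anchor value at DIV 6 and one at DIV 18.
#' The three built-in archetypes emulate the developmental patterns seen in
#' dense cortical cultures: (1) early-synchronized, high-bursting networks,
#' (2) networks whose synchrony emerges late, and (3) persistently sparse
#' networks.
#'
#' @param label archetype id (integer).
#' @param lambdaBg length-2 anchors (DIV 6, DIV 18) of the background firing
#'   rate per channel, Hz; must be non-decreasing.
#' @param nuNb anchors of the network-burst event rate, events/min.
#' @param pPart anchors of the per-channel recruitment probability per
#'   network event, in `[0, 1]`.
#' @param nActive anchors of the number of active channels.
#' @param burstLen mean within-burst spike count.
#' @param intraIsiMs mean intra-burst inter-spike interval, ms.
#' @param jitterMs s.d. of per-channel burst-onset jitter, ms.
#' @param syncGroups anchors of the number of tightly-synchronized electrode
#'   groups (electrodes recording near-identical activity, as around a shared
#'   hub or unit); each group comprises 5 channels firing a common source
#'   train with sub-millisecond spike jitter, so its pairwise STTC exceeds
#'   the 0.8 high-synchrony threshold.
#' @param refractoryMs minimal intra-burst inter-spike interval, ms.
#' @return list of class `archetypeParams`.
#' @export
archetypeParams <- function(label, lambdaBg, nuNb, pPart, nActive,
                            burstLen = 8, intraIsiMs = 20, jitterMs = 10,
                            syncGroups = c(0, 0), refractoryMs = 2) {
  stopifnot(length(lambdaBg) == 2, length(nuNb) == 2, length(pPart) == 2,
            length(nActive) == 2, length(syncGroups) == 2,
            all(lambdaBg >= 0), all(nuNb >= 0),
            all(pPart >= 0), all(pPart <= 1), all(nActive >= 0),
            lambdaBg[1] <= lambdaBg[2], all(syncGroups >= 0),
            burstLen > 0, intraIsiMs > 0, jitterMs >= 0,
            refractoryMs >= 0, refractoryMs < intraIsiMs)
  structure(list(label = as.integer(label), lambdaBg = lambdaBg, nuNb = nuNb,
                 pPart = pPart, nActive = nActive, burstLen = burstLen,
                 intraIsiMs = intraIsiMs, jitterMs = jitterMs,
                 syncGroups = syncGroups, refractoryMs = refractoryMs),
            class = "archetypeParams")
}

#' @rdname archetypeParams
#' @export
defaultArchetypes <- function() {
  list(
    # early-synchronized, high-bursting
    archetypeParams(1L, lambdaBg = c(0.8, 1.6), nuNb = c(8, 14),
                    pPart = c(0.60, 0.90), nActive = c(45, 55),
                    burstLen = 8, intraIsiMs = 20, jitterMs = 10,
                    syncGroups = c(1, 3)),
    # late-emerging synchrony: starts sparse, converges toward archetype 1
    archetypeParams(2L, lambdaBg = c(0.5, 1.3), nuNb = c(1, 12),
                    pPart = c(0.15, 0.85), nActive = c(32, 52),
                    burstLen = 7, intraIsiMs = 20, jitterMs = 15,
                    syncGroups = c(0, 2)),
    # persistently sparse
    archetypeParams(3L, lambdaBg = c(0.25, 0.45), nuNb = c(0.5, 1.5),
                    pPart = c(0.15, 0.25), nActive = c(20, 28),
                    burstLen = 5, intraIsiMs = 25, jitterMs = 20,
                    syncGroups = c(0, 0))
  )
}

# Interpolate an anchor pair (DIV 6, DIV 18) at an arbitrary DIV.
anchorAt <- function(anchors, div) {
  w <- min(1, max(0, (div - 6) / 12))
  anchors[1] + w * (anchors[2] - anchors[1])
}

# Concrete generative parameters of one archetype at one DIV, optionally
# scaled by a dish-level factor (rates multiplicative, recruitment on the
# log-odds scale, channel count proportional).
paramsAt <- function(arch, div, factor = 1, nChannels = 60L) {
  p0 <- anchorAt(arch$pPart, div)
  pScaled <- if (p0 <= 0 || p0 >= 1) p0 else {
    stats::plogis(stats::qlogis(p0) + log(factor))
  }
  list(lambdaBg = anchorAt(arch$lambdaBg, div) * factor,
       nuNb = anchorAt(arch$nuNb, div) * factor,
       pPart = pScaled,
       nActive = min(nChannels,
                     max(1L, as.integer(round(anchorAt(arch$nActive, div) *
                                                factor)))),
       burstLen = arch$burstLen,
       intraIsiMs = arch$intraIsiMs,
       jitterMs = arch$jitterMs,
       nSyncGroups = as.integer(round(anchorAt(arch$syncGroups, div))),
       refractoryMs = arch$refractoryMs)
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults emulate the study's recording conditions: 60-channel arrays,
#' 300 s of spontaneous activity, and one recording in each of the three DIV
#' intervals (the default schedule DIV 7, 10, 15 matches the study's density
#' of roughly three recordings per dish across DIV 6-18).
#'
#' @param nDishes number of dishes.
#' @param nChannels channels per array (default 60).
#' @param durationS recording length in seconds (default 300).
#' @param divSchedule integer days in vitro at which each dish is recorded.
#' @param archetypeMix proportions over the archetypes (must sum to 1);
#'   dishes are assigned deterministically in proportion.
#' @param archetypes list of [archetypeParams()].
#' @param dishSd s.d. of the lognormal dish-level scaling factor.
#' @param noiseLink s.d. of the Gaussian noise (log scale) added when the
#'   late-stage dish factor is derived from the early-stage factor; 0 makes
#'   third-week parameters an exact function of first-week parameters.
#' @param seed RNG seed.
#' @return list of class `cohortConfig`.
#' @export
cohortConfig <- function(nDishes = 60L, nChannels = 60L, durationS = 300,
                         divSchedule = c(7L, 10L, 15L),
                         archetypeMix = c(1, 1, 1) / 3,
                         archetypes = defaultArchetypes(),
                         dishSd = 0.15, noiseLink = 0.10, seed = 1L) {
  stopifnot(nDishes >= 1, nChannels >= 1, durationS > 0,
            length(divSchedule) >= 1,
            length(archetypeMix) == length(archetypes),
            abs(sum(archetypeMix) - 1) < 1e-8,
            dishSd >= 0, noiseLink >= 0)
  structure(list(nDishes = as.integer(nDishes),
                 nChannels = as.integer(nChannels),
                 durationS = durationS,
                 divSchedule = sort(as.integer(divSchedule)),
                 archetypeMix = archetypeMix,
                 archetypes = archetypes,
                 dishSd = dishSd, noiseLink = noiseLink,
                 seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Simulate one MEA recording
#'
#' Generation model: each of the `nActive` active channels fires homogeneous
#' Poisson background spikes at `lambdaBg` Hz; network events arrive as a
#' Poisson process at `nuNb` events/min; each event independently recruits
#' each active channel with probability `pPart`; a recruited channel emits a
#' burst of about `burstLen` spikes with exponential intra-burst ISIs (mean
#' `intraIsiMs`) starting at the event time plus Gaussian onset jitter
#' (`jitterMs`). Inactive channels stay silent. Spike times are quantized to
#' the 0.04 ms acquisition grid and clipped to the recording.
#'
#' @param arch an [archetypeParams()] (or the plain parameter list produced
#'   internally for one DIV).
#' @param div day in vitro to simulate.
#' @param durationS recording duration (s).
#' @param nChannels number of channels.
#' @param seed RNG seed for this recording.
#' @param dishId dish identifier stored in the recording.
#' @param factor dish-level scaling factor applied to the archetype (see
#'   [cohortConfig()]).
#' @return an [MEARecording-class].
#' @export
simulateRecording <- function(arch, div, durationS = 300, nChannels = 60L,
                              seed = 1L, dishId = "sim", factor = 1) {
  stopifnot(durationS > 0, nChannels >= 1)
  pars <- if (inherits(arch, "archetypeParams")) {
    paramsAt(arch, div, factor, nChannels)
  } else {
    arch
  }
  stopifnot(pars$lambdaBg >= 0, pars$nuNb >= 0,
            pars$pPart >= 0, pars$pPart <= 1, pars$nActive <= nChannels)
  nSync <- if (is.null(pars$nSyncGroups)) 0L else pars$nSyncGroups
  refr <- if (is.null(pars$refractoryMs)) 2 else pars$refractoryMs
  set.seed(seed)
  active <- sort(sample.int(nChannels, pars$nActive))
  spikes <- rep(list(numeric(0)), nChannels)

  # intra-burst ISIs: refractory floor plus exponential tail, mean intraIsiMs
  burstTrain <- function(onset, nSp) {
    isis <- refr / 1000 +
      stats::rexp(nSp - 1L, rate = 1000 / max(pars$intraIsiMs - refr, 1e-3))
    onset + c(0, cumsum(isis))
  }

  # background Poisson spikes on active channels
  for (ch in active) {
    nBg <- stats::rpois(1, pars$lambdaBg * durationS)
    if (nBg > 0) spikes[[ch]] <- sort(stats::runif(nBg, 0, durationS))
  }

  # network events recruiting channels into bursts
  nEv <- stats::rpois(1, pars$nuNb / 60 * durationS)
  evTimes <- if (nEv > 0) sort(stats::runif(nEv, 0, durationS)) else numeric(0)
  for (ev in evTimes) {
    recruited <- active[stats::runif(length(active)) < pars$pPart]
    for (ch in recruited) {
      onset <- ev + stats::rnorm(1, 0, pars$jitterMs / 1000)
      nSp <- max(2L, stats::rpois(1, pars$burstLen))
      spikes[[ch]] <- c(spikes[[ch]], burstTrain(onset, nSp))
    }
  }

  # tightly-synchronized electrode groups: disjoint sets of 5 channels fire
  # one shared source train (background + a burst at every network event)
  # with sub-millisecond per-spike jitter
  groupSize <- 5L
  nSync <- min(nSync, length(active) %/% groupSize)
  if (nSync > 0) {
    pool <- sample(active)
    for (g in seq_len(nSync)) {
      members <- pool[(g - 1L) * groupSize + seq_len(groupSize)]
      nBg <- stats::rpois(1, pars$lambdaBg * durationS)
      source <- sort(stats::runif(nBg, 0, durationS))
      for (ev in evTimes) {
        onset <- ev + stats::rnorm(1, 0, pars$jitterMs / 1000)
        nSp <- max(2L, stats::rpois(1, pars$burstLen))
        source <- c(source, burstTrain(onset, nSp))
      }
      for (ch in members) {
        spikes[[ch]] <- source + stats::rnorm(length(source), 0, 5e-4)
      }
    }
  }

  spikes <- lapply(spikes, function(t) sort(t[t >= 0 & t <= durationS]))
  MEARecording(dishId, div, durationS, spikes, nChannels = nChannels)
}

#' Simulate a cohort of developing dishes
#'
#' Dishes are assigned to archetypes deterministically in proportion to
#' `archetypeMix`. Each dish receives a lognormal scaling factor
#' `fEarly = exp(dishSd * z1)` applied to its first-week parameters; its
#' third-week factor is the fixed monotone map `fLate = fEarly *
#' exp(noiseLink * z2)` (log-linear interpolation in between), so third-week
#' ground truth is a noisy monotone function of first-week ground truth by
#' construction. Per-recording RNG substreams are derived from the cohort
#' seed and dish/DIV counters, so the output is reproducible independently
#' of iteration order.
#'
#' @param cfg a [cohortConfig()].
#' @return an [MEACohort-class]; its truth table has one row per dish and
#'   DIV with the archetype label, dish factors and the realized generative
#'   parameters.
#' @export
simulateCohort <- function(cfg = cohortConfig()) {
  stopifnot(inherits(cfg, "cohortConfig"))
  nA <- length(cfg$archetypes)
  # deterministic proportional assignment
  countPer <- floor(cfg$archetypeMix * cfg$nDishes)
  rem <- cfg$nDishes - sum(countPer)
  if (rem > 0) {
    frac <- cfg$archetypeMix * cfg$nDishes - countPer
    countPer[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      countPer[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  assign <- rep(seq_len(nA), countPer)

  recs <- vector("list", cfg$nDishes * length(cfg$divSchedule))
  truthRows <- list()
  k <- 0L
  for (d in seq_len(cfg$nDishes)) {
    id <- sprintf("dish%03d", d)
    arch <- cfg$archetypes[[assign[d]]]
    set.seed(deriveSeed(cfg$seed, d, 0L))
    z1 <- stats::rnorm(1)
    z2 <- stats::rnorm(1)
    fEarly <- exp(cfg$dishSd * z1)
    fLate <- fEarly * exp(cfg$noiseLink * z2)
    for (j in seq_along(cfg$divSchedule)) {
      dv <- cfg$divSchedule[j]
      # log-linear interpolation of the dish factor between DIV 8 and 13
      w <- min(1, max(0, (dv - 8) / 5))
      f <- exp((1 - w) * log(fEarly) + w * log(fLate))
      pars <- paramsAt(arch, dv, f, cfg$nChannels)
      k <- k + 1L
      recs[[k]] <- simulateRecording(pars, dv, cfg$durationS, cfg$nChannels,
                                     seed = deriveSeed(cfg$seed, d, j),
                                     dishId = id)
      truthRows[[k]] <- data.frame(
        dish = id, archetype = arch$label, div = dv,
        factorEarly = fEarly, factorLate = fLate, factor = f,
        lambdaBg = pars$lambdaBg, nuNb = pars$nuNb, pPart = pars$pPart,
        nActive = pars$nActive, nSyncGroups = pars$nSyncGroups,
        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  methods::new("MEACohort", recordings = recs, truth = truth,
               config = unclass(cfg))
}

#' Write a simulated cohort to disk
#'
#' Writes one spike-time TSV per recording (named `<dish>_div<div>.tsv`),
#' the ground-truth table as `truth.csv`, and the generating configuration
#' as `config.json` (plain JSON written without external dependencies).
#'
#' @param cohort an [MEACohort-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in recordings(cohort)) {
    writeRecording(rec, file.path(dir, sprintf("%s_div%02d.tsv",
                                               dishId(rec), div(rec))))
  }
  utils::write.csv(cohortTruth(cohort), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- cohort@config
  scalar <- vapply(cfg, function(x) is.atomic(x) && length(x) >= 1,
                   logical(1))
  fields <- vapply(names(cfg)[scalar], function(nm) {
    v <- cfg[[nm]]
    val <- if (is.character(v)) sprintf("\"%s\"", v) else format(v)
    if (length(val) > 1) val <- sprintf("[%s]", paste(val, collapse = ", "))
    sprintf("  \"%s\": %s", nm, val)
  }, character(1))
  writeLines(c("{", paste(fields, collapse = ",\n"), "}"),
             file.path(dir, "config.json"))
  invisible(dir)
}
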