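#' MEARecording: one dish on one day in vitro
#'
#' Container for a single microelectrode-array recording: per-channel sorted
#' spike-time vectors (seconds) plus dish metadata. Spike times are quantized
#' to the 0.04 ms grid of a 25 kHz acquisition system; duplicate times within
#' a channel are coalesced at construction.
#'
#' @slot dishId character scalar identifying the culture dish.
#' @slot div integer day in vitro of the recording.
#' @slot durationS recording length in seconds.
#' @slot spikes list of numeric vectors, one per channel (1-based channel
#'   ids), each strictly increasing within `[0, durationS]`.
#' @slot excludedChannels integer vector of channel ids excluded upstream
#'   (e.g. electrodes flagged as noisy); these never count as active.
#'
#' @seealso [MEARecording()], [readRecording()], [simulateRecording()]
#' @export
setClass("MEARecording",
  representation(
    dishId = "character",
    div = "integer",
    durationS = "numeric",
    spikes = "list",
    excludedChannels = "integer"
  )
)

setValidity("MEARecording", function(object) {
  msgs <- character()
  if (length(object@dishId) != 1L || is.na(object@dishId)) {
    msgs <- c(msgs, "dishId must be a single non-missing string")
  }
  if (length(object@div) != 1L || is.na(object@div) || object@div < 0L) {
    msgs <- c(msgs, "div must be a single non-negative integer")
  }
  if (length(object@durationS) != 1L || !is.finite(object@durationS) ||
      object@durationS <= 0) {
    msgs <- c(msgs, "durationS must be a single positive number")
  }
  for (ch in seq_along(object@spikes)) {
    st <- object@spikes[[ch]]
    if (!is.numeric(st)) {
      msgs <- c(msgs, sprintf("channel %d: spike times must be numeric", ch))
      next
    }
    if (length(st)) {
      if (anyNA(st) || min(st) < 0 || max(st) > object@durationS) {
        msgs <- c(msgs, sprintf(
          "channel %d: spike times must lie in [0, %g]", ch, object@durationS))
      }
      if (is.unsorted(st, strictly = TRUE)) {
        msgs <- c(msgs, sprintf(
          "channel %d: spike times must be strictly increasing", ch))
      }
    }
  }
  bad <- object@excludedChannels < 1L |
    object@excludedChannels > length(object@spikes)
  if (any(bad)) msgs <- c(msgs, "excludedChannels out of channel range")
  if (length(msgs)) msgs else TRUE
})

#' Construct an MEARecording
#'
#' Spike times are rounded onto the 0.04 ms sampling grid (25 kHz) and
#' duplicates within a channel coalesced before validation.
#'
#' @param dishId dish identifier.
#' @param div day in vitro (non-negative integer).
#' @param durationS recording duration in seconds.
#' @param spikes list of numeric spike-time vectors (seconds), one per
#'   channel; channel ids are the list positions (1-based).
#' @param nChannels total number of channels; `spikes` is padded with empty
#'   channels up to this count (default: `length(spikes)`).
#' @param excludedChannels integer channel ids to exclude from analysis.
#' @return An [MEARecording-class] object.
#' @examples
#' rec <- MEARecording("d1", 7, 300, list(c(0.1, 0.2), numeric(0)))
#' nChannels(rec)
#' @export
MEARecording <- function(dishId, div, durationS, spikes,
                         nChannels = length(spikes),
                         excludedChannels = integer()) {
  stopifnot(nChannels >= length(spikes))
  spikes <- lapply(spikes, function(st) {
    st <- sort(as.numeric(st))
    unique(quantizeTimes(st))
  })
  if (nChannels > length(spikes)) {
    spikes <- c(spikes, rep(list(numeric(0)), nChannels - length(spikes)))
  }
  methods::new("MEARecording",
    dishId = as.character(dishId), div = as.integer(div),
    durationS = as.numeric(durationS), spikes = spikes,
    excludedChannels = as.integer(excludedChannels))
}

#' MEACohort: a simulated or assembled set of recordings
#'
#' Bundles the recordings of a cohort of dishes with the ground-truth
#' parameter table (for synthetic cohorts) and the generating configuration.
#'
#' @slot recordings list of [MEARecording-class] objects.
#' @slot truth data.frame with one row per dish and day in vitro carrying the
#'   generating parameters (empty for assembled real-data cohorts).
#' @slot config list: the configuration the cohort was generated from.
#' @seealso [simulateCohort()]
#' @export
setClass("MEACohort",
  representation(recordings = "list", truth = "data.frame", config = "list")
)

setValidity("MEACohort", function(object) {
  ok <- vapply(object@recordings, methods::is, logical(1), "MEARecording")
  if (!all(ok)) "all elements of recordings must be MEARecording" else TRUE
})

#' SOMModel: a trained self-organizing map
#'
#' Result of sequential Kohonen training on per-dish trajectory vectors.
#'
#' @slot codebook numeric matrix, one row per map unit, in input space.
#' @slot gridCoords two-column matrix of unit positions on the hexagonal
#'   lattice (Cartesian coordinates of axial hex layout).
#' @slot gridDim integer vector `c(nrow, ncol)` of the lattice.
#' @slot bmu integer vector: best-matching unit of each training row.
#' @slot data the training matrix (rows = dishes), kept for cluster-validity
#'   scoring of induced partitions.
#' @slot dataNames row names of the training data (dish ids).
#' @export
setClass("SOMModel",
  representation(
    codebook = "matrix",
    gridCoords = "matrix",
    gridDim = "integer",
    bmu = "integer",
    data = "matrix",
    dataNames = "character"
  )
)

setValidity("SOMModel", function(object) {
  msgs <- character()
  if (!all(is.finite(object@codebook))) {
    msgs <- c(msgs, "codebook must be finite")
  }
  if (nrow(object@gridCoords) != nrow(object@codebook)) {
    msgs <- c(msgs, "gridCoords and codebook must have matching rows")
  }
  if (length(object@bmu) &&
      (min(object@bmu) < 1L || max(object@bmu) > nrow(object@codebook))) {
    msgs <- c(msgs, "bmu indices out of codebook range")
  }
  if (nrow(object@data) != length(object@bmu)) {
    msgs <- c(msgs, "data rows and bmu length must match")
  }
  if (length(msgs)) msgs else TRUE
})
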