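#' @name accessors
#' @title Accessors for MEA data classes
#' @param x an object.
#' @return `dishId`, `div`, `durationS`, `nChannels` return scalars;
#'   `spikeTimes` the list of per-channel spike-time vectors;
#'   `excludedChannels` an integer vector; `recordings` the recording list of
#'   a cohort; `cohortTruth` the ground-truth parameter table.
NULL

#' @rdname accessors
#' @export
setGeneric("dishId", function(x) standardGeneric("dishId"))
#' @rdname accessors
#' @export
setGeneric("div", function(x) standardGeneric("div"))
#' @rdname accessors
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("excludedChannels", function(x) standardGeneric("excludedChannels"))
#' @rdname accessors
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname accessors
#' @export
setMethod("dishId", "MEARecording", function(x) x@dishId)
#' @rdname accessors
#' @export
setMethod("div", "MEARecording", function(x) x@div)
#' @rdname accessors
#' @export
setMethod("durationS", "MEARecording", function(x) x@durationS)
#' @rdname accessors
#' @export
setMethod("spikeTimes", "MEARecording", function(x) x@spikes)
#' @rdname accessors
#' @export
setMethod("nChannels", "MEARecording", function(x) length(x@spikes))
#' @rdname accessors
#' @export
setMethod("excludedChannels", "MEARecording", function(x) x@excludedChannels)
#' @rdname accessors
#' @export
setMethod("recordings", "MEACohort", function(x) x@recordings)
#' @rdname accessors
#' @export
setMethod("cohortTruth", "MEACohort", function(x) x@truth)

setMethod("show", "MEARecording", function(object) {
  n <- sum(lengths(object@spikes))
  cat(sprintf(
    "MEARecording: dish %s, DIV %d, %.0f s, %d channels, %d spikes\n",
    object@dishId, object@div, object@durationS,
    length(object@spikes), n))
  if (length(object@excludedChannels)) {
    cat("  excluded channels:",
        paste(object@excludedChannels, collapse = ", "), "\n")
  }
})

setMethod("show", "MEACohort", function(object) {
  dishes <- unique(vapply(object@recordings, dishId, character(1)))
  divs <- sort(unique(vapply(object@recordings, div, integer(1))))
  cat(sprintf("MEACohort: %d recordings, %d dishes, DIV %s\n",
              length(object@recordings), length(dishes),
              paste(divs, collapse = ", ")))
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %dx%d hexagonal grid, %d inputs of dimension %d\n",
              object@gridDim[1], object@gridDim[2],
              length(object@bmu), ncol(object@codebook)))
})
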