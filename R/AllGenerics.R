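#' Accessors for leverseq classes
#'
#' Accessor generics for the core containers: `events()` returns the event
#' `data.frame` of a [Session-class], `spikeTimes()` the spike-time vector
#' of a [SpikeTrain-class], `rateValues()`/`rateTimes()` the samples of a
#' [RateTrace-class], `rateMatrix()`/`binOffsets()` the matrix and bin grid
#' of an [AlignedRates-class], and `sessionProtocol()` the optogenetic
#' protocol of a session.
#'
#' @param x an object of the documented class.
#' @return the slot value (see details per class).
#' @name accessors
#' @aliases events spikeTimes rateValues rateTimes rateMatrix binOffsets
#'   sessionProtocol unitId
NULL

#' @rdname accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("rateValues", function(x) standardGeneric("rateValues"))
#' @rdname accessors
#' @export
setGeneric("rateTimes", function(x) standardGeneric("rateTimes"))
#' @rdname accessors
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))
#' @rdname accessors
#' @export
setGeneric("binOffsets", function(x) standardGeneric("binOffsets"))
#' @rdname accessors
#' @export
setGeneric("sessionProtocol", function(x) standardGeneric("sessionProtocol"))
#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))

#' @rdname accessors
setMethod("events", "Session", function(x) x@events)
#' @rdname accessors
setMethod("sessionProtocol", "Session", function(x) x@protocol)
#' @rdname accessors
setMethod("spikeTimes", "SpikeTrain", function(x) x@spike_times)
#' @rdname accessors
setMethod("unitId", "SpikeTrain", function(x) x@unit_id)
#' @rdname accessors
setMethod("rateValues", "RateTrace", function(x) x@values)
#' @rdname accessors
setMethod("rateTimes", "RateTrace",
          function(x) x@t0 + (seq_along(x@values) - 1L) * x@dt)
#' @rdname accessors
setMethod("rateMatrix", "AlignedRates", function(x) x@matrix)
#' @rdname accessors
setMethod("binOffsets", "AlignedRates", function(x) x@offsets)
#' @rdname accessors
setMethod("unitId", "AlignedRates", function(x) x@unit_id)

#' Known event codes
#'
#' The closed vocabulary of behavioral/stimulation event codes, in the
#' canonical tie-break order applied to simultaneous events.
#' @return character vector of event codes.
#' @export
eventCodes <- function() EVENT_CODES

setMethod("show", "Session", function(object) {
  ev <- object@events
  cat(sprintf("Session '%s' (group %s, day %d, protocol %s)\n",
              object@animal_id, object@group, object@day, object@protocol))
  cat(sprintf("  %d events", nrow(ev)))
  if (nrow(ev))
    cat(sprintf(" spanning %.2f-%.2f s; %d rewards",
                min(ev$time), max(ev$time), sum(ev$code == "REWARD")))
  cat("\n")
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s' (%s): %d spikes", object@unit_id,
              object@region, length(object@spike_times)))
  if (length(object@spike_times))
    cat(sprintf(" over %.2f-%.2f s", min(object@spike_times),
                max(object@spike_times)))
  if (length(object@waveform_behavioral)) cat("; waveforms attached")
  if (!is.na(object@pid)) cat(sprintf("; PID %s", object@pid))
  cat("\n")
})

setMethod("show", "RateTrace", function(object) {
  cat(sprintf("RateTrace: %d samples at %.0f Hz from t0 = %.2f s (kernel sigma %.3f s)\n",
              length(object@values), 1 / object@dt, object@t0,
              object@kernel_sigma))
})

setMethod("show", "AlignedRates", function(object) {
  cat(sprintf("AlignedRates '%s' @ %s: %d trials x %d bins [%s], window -%g/+%g s, %d dropped\n",
              object@unit_id, object@anchor, nrow(object@matrix),
              ncol(object@matrix), object@units, object@window[1],
              object@window[2], object@n_dropped))
})

setMethod("show", "ModulationProfile", function(object) {
  cat(sprintf("ModulationProfile '%s' @ %s: %d bins, %d significant (p < 0.05, %d permutations)\n",
              object@unit_id, object@anchor, length(object@bin_centers),
              sum(object@significant), object@n_perm))
})
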