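#' @import methods
NULL

## Canonical event vocabulary. Position in this vector is the tie-break
## priority when several events share a timestamp: block markers sort first,
## then the beam crossing, presses, magazine entry, reward, light edges.
EVENT_CODES <- c(
  "BLOCK_FORCED_START", "BLOCK_SELF_START", "TIMEOUT_START",
  "BEAM_OUT", "LP1", "LP2", "MAG_IN", "REWARD",
  "LIGHT_ON", "LIGHT_OFF", "SESSION_END"
)

GROUPS    <- c("ARCH_M2", "ARCH_M1", "ARCH_LS", "EYFP_CONTROL")
PROTOCOLS <- c("NONE", "BEFORE", "EXECUTION", "TRANSITION")
REGIONS   <- c("M2", "M1", "LS")

TIME_RESOLUTION <- 0.01  # s; all event times are quantized to this grid

#' Session of timestamped behavioral events
#'
#' Container for one behavioral session: animal metadata, the optogenetic
#' protocol in force (at most one per session), and the ordered event
#' stream. Event times are quantized to the 10-ms acquisition grid and
#' simultaneous events are ordered by a fixed code priority so parsing is
#' deterministic.
#'
#' @slot animal_id single character identifier.
#' @slot group experimental group, one of `ARCH_M2`, `ARCH_M1`, `ARCH_LS`,
#'   `EYFP_CONTROL`.
#' @slot day integer training/recording day.
#' @slot protocol optogenetic trigger protocol, one of `NONE`, `BEFORE`,
#'   `EXECUTION`, `TRANSITION`.
#' @slot events `data.frame` with columns `time` (seconds, multiples of
#'   0.01), `code` (see [eventCodes()]) and `payload` (character, verbatim
#'   annotation, `""` when absent).
#' @exportClass Session
setClass("Session",
  representation(
    animal_id = "character",
    group     = "character",
    day       = "integer",
    protocol  = "character",
    events    = "data.frame"
  ),
  prototype(
    animal_id = "unknown", group = "EYFP_CONTROL", day = 1L,
    protocol = "NONE",
    events = data.frame(time = numeric(0), code = character(0),
                        payload = character(0))
  )
)

setValidity("Session", function(object) {
  ev <- object@events
  msg <- character(0)
  if (length(object@animal_id) != 1L) msg <- c(msg, "animal_id must be length 1")
  if (!object@group %in% GROUPS)
    msg <- c(msg, sprintf("unknown group '%s'", object@group))
  if (!object@protocol %in% PROTOCOLS)
    msg <- c(msg, sprintf("unknown protocol '%s'", object@protocol))
  if (!all(c("time", "code", "payload") %in% names(ev)))
    msg <- c(msg, "events needs columns time, code, payload")
  else {
    bad <- setdiff(unique(ev$code), EVENT_CODES)
    if (length(bad))
      msg <- c(msg, sprintf("unknown event code(s): %s",
                            paste(bad, collapse = ", ")))
    if (nrow(ev)) {
      if (any(ev$time < 0)) msg <- c(msg, "event times must be non-negative")
      if (any(abs(ev$time - round(ev$time / TIME_RESOLUTION) * TIME_RESOLUTION)
              > 1e-9))
        msg <- c(msg, "event times must be multiples of 0.01 s")
      if (is.unsorted(ev$time)) msg <- c(msg, "events must be time-ordered")
      lt <- ev$code[ev$code %in% c("LIGHT_ON", "LIGHT_OFF")]
      if (length(lt)) {
        expected <- rep(c("LIGHT_ON", "LIGHT_OFF"), length.out = length(lt))
        if (!identical(lt, expected))
          msg <- c(msg, "LIGHT_ON/LIGHT_OFF must strictly alternate")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Spike train of one sorted unit
#'
#' @slot unit_id single character identifier.
#' @slot region recording region (`M2`, `M1` or `LS`).
#' @slot spike_times sorted, non-negative spike times in seconds.
#' @slot waveform_behavioral,waveform_light optional mean waveforms
#'   (microvolts per sample; `numeric(0)` when absent).
#' @slot pid logical; `NA` until photo-identification has been run.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    unit_id = "character",
    region  = "character",
    spike_times = "numeric",
    waveform_behavioral = "numeric",
    waveform_light = "numeric",
    pid = "logical"
  ),
  prototype(unit_id = "u0", region = "M2", spike_times = numeric(0),
            waveform_behavioral = numeric(0), waveform_light = numeric(0),
            pid = NA)
)

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (!object@region %in% REGIONS)
    msg <- c(msg, sprintf("unknown region '%s'", object@region))
  st <- object@spike_times
  if (length(st)) {
    if (any(st < 0)) msg <- c(msg, "spike times must be non-negative")
    if (is.unsorted(st)) msg <- c(msg, "spike times must be sorted")
  }
  if (length(msg)) msg else TRUE
})

#' Instantaneous firing-rate trace
#'
#' Kernel-smoothed rate on a regular 100-Hz grid. The smoothing kernel is a
#' unit-area Gaussian (sigma 25 ms) truncated at +/- 4 sigma and
#' renormalized, so the integral of the trace equals the spike count when
#' the span fully supports every kernel.
#'
#' @slot t0 time (s) of the first sample.
#' @slot dt sample interval, fixed at 0.01 s.
#' @slot values rate values in Hz.
#' @slot kernel_sigma Gaussian kernel sigma (s).
#' @exportClass RateTrace
setClass("RateTrace",
  representation(t0 = "numeric", dt = "numeric", values = "numeric",
                 kernel_sigma = "numeric"),
  prototype(t0 = 0, dt = 0.01, values = numeric(0), kernel_sigma = 0.025)
)

setValidity("RateTrace", function(object) {
  msg <- character(0)
  if (abs(object@dt - 0.01) > 1e-12) msg <- c(msg, "dt must be 0.01 s")
  if (length(object@values) && any(object@values < -1e-9))
    msg <- c(msg, "rate values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Event-aligned rate matrix
#'
#' One row per trial (anchor occurrence), columns on a common bin grid
#' relative to the anchor. Values are Hz, or z units after [zscoreRows()].
#'
#' @slot unit_id unit identifier.
#' @slot anchor anchor event name (e.g. `"P1_S1"`).
#' @slot window numeric length 2: seconds before and after the anchor
#'   (both positive).
#' @slot offsets bin-center offsets (s) relative to the anchor.
#' @slot matrix trials x bins matrix.
#' @slot units `"hz"` or `"z"`.
#' @slot n_dropped anchors dropped for lacking full window support.
#' @slot baseline_mean,baseline_sd pooled baseline statistics recorded by
#'   [zscoreRows()] (`NA` before z-scoring).
#' @slot flagged `TRUE` when the unit was excluded from z analyses
#'   (degenerate baseline).
#' @exportClass AlignedRates
setClass("AlignedRates",
  representation(unit_id = "character", anchor = "character",
                 window = "numeric", offsets = "numeric", matrix = "matrix",
                 units = "character", n_dropped = "integer",
                 baseline_mean = "numeric", baseline_sd = "numeric",
                 flagged = "logical"),
  prototype(unit_id = "u0", anchor = "P1_S1", window = c(4.5, 5),
            offsets = numeric(0), matrix = matrix(0, 0, 0), units = "hz",
            n_dropped = 0L, baseline_mean = NA_real_, baseline_sd = NA_real_,
            flagged = FALSE)
)

setValidity("AlignedRates", function(object) {
  msg <- character(0)
  if (length(object@window) != 2L || any(object@window < 0))
    msg <- c(msg, "window must be two non-negative numbers (pre, post)")
  if (ncol(object@matrix) != length(object@offsets))
    msg <- c(msg, "ncol(matrix) must match length(offsets)")
  if (!object@units %in% c("hz", "z")) msg <- c(msg, "units must be 'hz' or 'z'")
  if (length(msg)) msg else TRUE
})

#' Sliding-window AUROC modulation profile
#'
#' Per-bin AUROC of trial firing rates against baseline, with permutation
#' p values and a significance mask (p < 0.05, uncorrected, matching the
#' per-bin binary-matrix convention used for recruitment summaries).
#'
#' @slot unit_id unit identifier.
#' @slot anchor anchor event name.
#' @slot bin_centers bin-center offsets (s) relative to the anchor.
#' @slot auroc per-bin AUROC in \[0, 1\].
#' @slot p_perm per-bin permutation p values.
#' @slot significant per-bin logical, `p_perm < 0.05`.
#' @slot n_perm number of permutations used.
#' @exportClass ModulationProfile
setClass("ModulationProfile",
  representation(unit_id = "character", anchor = "character",
                 bin_centers = "numeric", auroc = "numeric",
                 p_perm = "numeric", significant = "logical",
                 n_perm = "integer"),
  prototype(unit_id = "u0", anchor = "P1_S1", bin_centers = numeric(0),
            auroc = numeric(0), p_perm = numeric(0), significant = logical(0),
            n_perm = 1000L)
)

setValidity("ModulationProfile", function(object) {
  msg <- character(0)
  n <- length(object@bin_centers)
  if (length(object@auroc) != n || length(object@p_perm) != n ||
      length(object@significant) != n)
    msg <- c(msg, "auroc, p_perm, significant must match bin_centers")
  if (length(object@auroc) &&
      (any(object@auroc < -1e-9) || any(object@auroc > 1 + 1e-9)))
    msg <- c(msg, "auroc values must lie in [0, 1]")
  if (any(object@significant & !(object@p_perm < 0.05)))
    msg <- c(msg, "significant bins must have p_perm < 0.05")
  if (length(msg)) msg else TRUE
})
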