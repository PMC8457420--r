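#' Antidromic response latency to light pulses
#'
#' For each pulse, the latency of the first spike inside the response
#' window (default 0-10 ms after pulse onset, equal to the acceptance
#' bound; later spikes are ignored). Summarized by the median over
#' responding pulses.
#'
#' @param spikes a [SpikeTrain-class] or numeric spike times.
#' @param pulse_onsets pulse onset times (s), at least 10 pulses.
#' @param window response window (s) relative to pulse onset.
#' @return list with `median_latency`, `latency_sd`, `latencies` (one per
#'   responding pulse), `follow_fraction`, `n_pulses`.
#' @export
antidromicLatency <- function(spikes, pulse_onsets, window = c(0, 0.010)) {
  st <- if (is(spikes, "SpikeTrain")) spikes@spike_times else sort(spikes)
  stopIfNot(length(pulse_onsets) >= 10L, "need at least 10 pulses")
  lat <- vapply(pulse_onsets, function(p) {
    hit <- st[st > p + window[1] & st <= p + window[2]]
    if (length(hit)) hit[1] - p else NA_real_
  }, numeric(1))
  lat <- lat[!is.na(lat)]
  list(median_latency = if (length(lat)) stats::median(lat) else NA_real_,
       latency_sd = if (length(lat) > 1L) stats::sd(lat) else NA_real_,
       latencies = lat,
       follow_fraction = length(lat) / length(pulse_onsets),
       n_pulses = length(pulse_onsets))
}

#' Pearson correlation between behavioral and light-evoked waveforms
#'
#' @param behavioral_wf,light_wf mean waveforms, equal length >= 8 samples.
#' @return Pearson r, or `NA` when either waveform has zero variance
#'   (rejected downstream).
#' @export
waveformCorrelation <- function(behavioral_wf, light_wf) {
  stopIfNot(length(behavioral_wf) == length(light_wf),
            "waveforms must have equal length")
  stopIfNot(length(behavioral_wf) >= 8L, "waveforms need at least 8 samples")
  if (stats::sd(behavioral_wf) == 0 || stats::sd(light_wf) == 0)
    return(NA_real_)
  stats::cor(behavioral_wf, light_wf)
}

#' Antidromic photo-identification decision
#'
#' A unit is accepted as a cortico-striatal projection neuron when the
#' median antidromic latency is below `latency_max` (10 ms) and the
#' correlation between its behavioral and light-evoked mean waveforms
#' exceeds `r_min` (0.9). Units with no response in the window, or with a
#' degenerate waveform, are rejected with the reason recorded.
#'
#' @param unit a [SpikeTrain-class] carrying both waveforms.
#' @param pulse_onsets pulse onset times (s), e.g. [pulseTrain()].
#' @param latency_max latency acceptance bound (s), default 0.010.
#' @param r_min waveform-correlation acceptance bound, default 0.9.
#' @return `data.frame` row: `unit_id`, `median_latency`, `latency_sd`,
#'   `waveform_r`, `follow_fraction`, `accepted`, `reason`.
#' @export
identifyPid <- function(unit, pulse_onsets, latency_max = 0.010,
                        r_min = 0.9) {
  lat <- antidromicLatency(unit, pulse_onsets, window = c(0, latency_max))
  r <- if (length(unit@waveform_behavioral) && length(unit@waveform_light))
    waveformCorrelation(unit@waveform_behavioral, unit@waveform_light)
    else NA_real_
  reason <- ""
  if (!length(lat$latencies)) reason <- "no response"
  else if (is.na(r)) reason <- "no waveforms"
  accepted <- length(lat$latencies) > 0L && !is.na(r) &&
    lat$median_latency < latency_max && r > r_min
  if (!accepted && reason == "") {
    if (!is.na(r) && r <= r_min) reason <- "waveform correlation below 0.9"
    if (length(lat$latencies) && lat$median_latency >= latency_max)
      reason <- paste0(reason, if (nzchar(reason)) "; ",
                       "latency at or above bound")
  }
  data.frame(unit_id = unit@unit_id, median_latency = lat$median_latency,
             latency_sd = lat$latency_sd, waveform_r = r,
             follow_fraction = lat$follow_fraction, accepted = accepted,
             reason = reason, stringsAsFactors = FALSE)
}
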