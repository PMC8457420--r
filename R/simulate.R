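#' Behavioral performer model
#'
#' Generative parameters for a simulated animal performing the serial-order
#' task (>= 4 presses on lever 1, then >= 4 on lever 2, rewarded at the
#' magazine). Error probabilities are per self-paced trial; in forced blocks
#' only the two break categories can occur because the apparatus presents
#' one lever at a time. Defaults emulate a late-training performer: the
#' break probabilities give about 83% correct forced trials and, with the
#' incorrect-start and premature-switch probabilities added, about 61%
#' correct self-paced trials; timing means follow the reported late-training
#' scale (latency about 1.5 s, inter-press interval about 0.5 s, transition
#' about 1 s, mean self-paced S1 length about 6 presses).
#'
#' @param p_incorrect_start probability the first press lands on lever 2
#'   (self-paced only).
#' @param p_break_s1 probability of abandoning S1 (< 4 lever-1 presses, then
#'   magazine).
#' @param p_premature_switch probability of switching to lever 2 before four
#'   lever-1 presses (self-paced only).
#' @param p_break_s2 probability of abandoning S2 (1-3 lever-2 presses, then
#'   magazine).
#' @param latency_mean,latency_sd beam-to-first-press latency (s).
#' @param ipi_mean,ipi_sd within-subsequence inter-press interval (s).
#' @param transition_mean,transition_sd last-S1-press to first-S2-press gap (s).
#' @param s1_extra_press_geometric_p geometric success probability for the
#'   number of S1 presses beyond four on correct self-paced trials (smaller
#'   values give longer Long-S1 sequences).
#' @param s2_extra_press_geometric_p same for S2 (default 1: exactly four).
#' @param magazine_delay_mean,magazine_delay_sd last-event to magazine-entry
#'   delay (s).
#' @param iti_mean,iti_sd magazine-entry to next beam-crossing interval (s).
#' @param p_return probability that a beam crossing is followed by a return
#'   to the magazine with no press (a return-to-start record).
#' @param opto_effects named list of additive deltas applied to the
#'   generative parameters on light-on trials: `latency_add`,
#'   `transition_add`, `ipi_add`, `p_incorrect_start_add`, `p_break_s1_add`,
#'   `p_premature_switch_add`, `p_break_s2_add`, `p_return_add`. Effects are
#'   applied to the stages at or after the protocol's trigger, so downstream
#'   recovery is a genuine end-to-end test.
#' @return a validated list of class `PerformerModel`.
#' @export
performerModel <- function(p_incorrect_start = 0.05, p_break_s1 = 0.09,
                           p_premature_switch = 0.17, p_break_s2 = 0.08,
                           latency_mean = 1.5, latency_sd = 0.5,
                           ipi_mean = 0.5, ipi_sd = 0.15,
                           transition_mean = 1.0, transition_sd = 0.3,
                           s1_extra_press_geometric_p = 0.33,
                           s2_extra_press_geometric_p = 1,
                           magazine_delay_mean = 1.0, magazine_delay_sd = 0.3,
                           iti_mean = 2.0, iti_sd = 0.5,
                           p_return = 0.01,
                           opto_effects = list()) {
  m <- list(
    p_incorrect_start = p_incorrect_start, p_break_s1 = p_break_s1,
    p_premature_switch = p_premature_switch, p_break_s2 = p_break_s2,
    latency_mean = latency_mean, latency_sd = latency_sd,
    ipi_mean = ipi_mean, ipi_sd = ipi_sd,
    transition_mean = transition_mean, transition_sd = transition_sd,
    s1_extra_press_geometric_p = s1_extra_press_geometric_p,
    s2_extra_press_geometric_p = s2_extra_press_geometric_p,
    magazine_delay_mean = magazine_delay_mean,
    magazine_delay_sd = magazine_delay_sd,
    iti_mean = iti_mean, iti_sd = iti_sd, p_return = p_return,
    opto_effects = optoEffectDefaults(opto_effects)
  )
  pr <- c(m$p_incorrect_start, m$p_break_s1, m$p_premature_switch,
          m$p_break_s2, m$p_return, m$s1_extra_press_geometric_p,
          m$s2_extra_press_geometric_p)
  stopIfNot(all(pr >= 0 & pr <= 1), "probabilities must lie in [0, 1]")
  stopIfNot(m$p_incorrect_start + m$p_break_s1 + m$p_premature_switch +
              m$p_break_s2 <= 1, "error probabilities must sum to at most 1")
  stopIfNot(all(c(m$latency_mean, m$ipi_mean, m$transition_mean,
                  m$magazine_delay_mean, m$iti_mean) > 0),
            "timing means must be positive")
  class(m) <- "PerformerModel"
  m
}

optoEffectDefaults <- function(x) {
  d <- list(latency_add = 0, transition_add = 0, ipi_add = 0,
            p_incorrect_start_add = 0, p_break_s1_add = 0,
            p_premature_switch_add = 0, p_break_s2_add = 0,
            p_return_add = 0)
  bad <- setdiff(names(x), names(d))
  stopIfNot(!length(bad), "unknown opto effect(s): %s",
            paste(bad, collapse = ", "))
  d[names(x)] <- x
  d
}

#' Simulate one behavioral session
#'
#' Generates an event stream obeying the task state machine: blocks start
#' forced (one lever at a time, only break errors possible) and switch to
#' self-paced (both levers, all four error categories) after five
#' consecutive correct trials, and back; each error is followed by a 10-s
#' timeout; the session ends at `n_rewards_target` rewards (or at
#' `n_trials_target` classified trials when given). Under an optogenetic
#' protocol a random 50% of attempts are assigned light, emitted for
#' `light_duration` seconds at the protocol trigger: the beam crossing
#' (`BEFORE`), the first press (`EXECUTION`), or the press before the
#' penultimate S1 press (`TRANSITION`; with exactly four S1 presses this is
#' the third press, the penultimate). Light-on trials have the model's
#' `opto_effects` applied to the generative stages at or after the trigger.
#'
#' @param model a [performerModel()].
#' @param n_rewards_target session ends after this many rewards (default 70,
#'   half earned in each block type under alternating blocks).
#' @param protocol one of `"NONE"`, `"BEFORE"`, `"EXECUTION"`,
#'   `"TRANSITION"`.
#' @param seed integer seed (mandatory for reproducibility).
#' @param n_trials_target optional; stop after this many classified trials
#'   instead of counting rewards.
#' @param block_mode `"alternating"` (default), `"forced_only"` or
#'   `"self_only"`.
#' @param block_switch consecutive correct trials required to switch blocks.
#' @param timeout timeout duration after an error (s).
#' @param light_duration light pulse duration (s).
#' @param light_fraction probability an attempt is assigned light (Bernoulli
#'   per attempt; the realized fraction is recorded in the session payload).
#' @param animal_id,group,day session metadata.
#' @return a [Session-class].
#' @export
simulateSession <- function(model, n_rewards_target = 70,
                            protocol = c("NONE", "BEFORE", "EXECUTION",
                                         "TRANSITION"),
                            seed = 1L, n_trials_target = NULL,
                            block_mode = c("alternating", "forced_only",
                                           "self_only"),
                            block_switch = 5L, timeout = 10,
                            light_duration = 2, light_fraction = 0.5,
                            animal_id = "sim", group = "ARCH_M2", day = 1L) {
  stopIfNot(inherits(model, "PerformerModel"), "model must be a performerModel()")
  protocol <- match.arg(protocol)
  block_mode <- match.arg(block_mode)
  if (protocol == "TRANSITION" && model$s1_extra_press_geometric_p <= 0)
    stop("TRANSITION protocol requires trials with at least 3 S1 presses",
         call. = FALSE)
  withSeed(seed, {
    tt <- numeric(0); cc <- character(0); pp <- character(0)
    emit <- function(time, code, payload = "") {
      tt <<- c(tt, time); cc <<- c(cc, code)
      pp <<- c(pp, rep(payload, length(time))[seq_along(time)])
    }
    block <- switch(block_mode, alternating = "FORCED",
                    forced_only = "FORCED", self_only = "SELF_PACED")
    emit(0, if (block == "FORCED") "BLOCK_FORCED_START" else
           "BLOCK_SELF_START")
    t <- 0.5
    rewards <- 0L; trials <- 0L; consec <- 0L
    last_light_off <- -Inf
    n_assigned <- 0L; n_attempts <- 0L
    max_attempts <- 40L * max(n_rewards_target,
                              if (is.null(n_trials_target)) 0 else
                                n_trials_target) + 200L
    while (n_attempts < max_attempts) {
      if (!is.null(n_trials_target)) {
        if (trials >= n_trials_target) break
      } else if (rewards >= n_rewards_target) break
      n_attempts <- n_attempts + 1L
      lit <- protocol != "NONE" && stats::runif(1) < light_fraction
      if (lit) n_assigned <- n_assigned + 1L
      trial <- simTrialEvents(model, block, protocol, lit, timeout)
      t_beam <- t + rtnorm(1, model$iti_mean, model$iti_sd)
      ## keep LIGHT_ON strictly after the previous LIGHT_OFF
      if (lit && !is.na(trial$trigger_rel) &&
          t_beam + trial$trigger_rel <= last_light_off + TIME_RESOLUTION)
        t_beam <- last_light_off + TIME_RESOLUTION * 2 - trial$trigger_rel
      emit(t_beam + trial$rel_times, trial$codes)
      if (lit && !is.na(trial$trigger_rel)) {
        t_on <- t_beam + trial$trigger_rel
        emit(t_on, "LIGHT_ON", protocol)
        emit(t_on + light_duration, "LIGHT_OFF")
        last_light_off <- t_on + light_duration
      }
      t <- t_beam + trial$end_rel
      if (!trial$return_to_start) {
        trials <- trials + 1L
        if (trial$correct) {
          rewards <- rewards + 1L
          consec <- consec + 1L
        } else consec <- 0L
        if (block_mode == "alternating" && consec >= block_switch &&
            (is.null(n_trials_target) && rewards < n_rewards_target ||
             !is.null(n_trials_target) && trials < n_trials_target)) {
          if (block == "SELF_PACED") t <- t + 3  # levers retracted 3 s
          block <- if (block == "FORCED") "SELF_PACED" else "FORCED"
          emit(t, if (block == "FORCED") "BLOCK_FORCED_START" else
                 "BLOCK_SELF_START")
          consec <- 0L
        }
      }
    }
    emit(t + 1, "SESSION_END",
         sprintf("light_assigned=%d/%d", n_assigned, n_attempts))
    ev <- orderEvents(newEvents(tt, cc, pp))
    rownames(ev) <- NULL
    new("Session", animal_id = animal_id, group = group,
        day = as.integer(day), protocol = protocol, events = ev)
  })
}

## One attempt, in times relative to the beam crossing. Returns the event
## codes/times, the relative trigger time for the session's protocol (NA if
## the trigger press is never reached), and bookkeeping flags.
simTrialEvents <- function(model, block, protocol, lit, timeout) {
  oe <- model$opto_effects
  ## effects gated on the stage being at or after the protocol trigger
  eff <- function(name, stage_on) {
    if (lit && protocol %in% stage_on) oe[[name]] else 0
  }
  p_ret <- min(1, max(0, model$p_return + eff("p_return_add", "BEFORE")))
  if (stats::runif(1) < p_ret) {
    t_mag <- rtnorm(1, model$magazine_delay_mean, model$magazine_delay_sd)
    return(list(rel_times = c(0, t_mag), codes = c("BEAM_OUT", "MAG_IN"),
                trigger_rel = if (protocol == "BEFORE") 0 else NA_real_,
                end_rel = t_mag, return_to_start = TRUE, correct = FALSE))
  }
  p_is <- if (block == "SELF_PACED")
    min(1, max(0, model$p_incorrect_start +
                 eff("p_incorrect_start_add", "BEFORE"))) else 0
  p_b1 <- min(1, max(0, model$p_break_s1 +
                       eff("p_break_s1_add", c("BEFORE", "EXECUTION"))))
  p_ps <- if (block == "SELF_PACED")
    min(1, max(0, model$p_premature_switch +
                 eff("p_premature_switch_add", c("BEFORE", "EXECUTION"))))
    else 0
  p_b2 <- min(1, max(0, model$p_break_s2 +
                       eff("p_break_s2_add", c("BEFORE", "EXECUTION"))))
  probs <- c(p_is, p_b1, p_ps, p_b2)
  psum <- sum(probs)
  if (psum > 1) probs <- probs / psum
  cat_ <- sample(c("INCORRECT_START", "BREAK_S1", "PREMATURE_SWITCH",
                   "BREAK_S2", "CORRECT"), 1L,
                 prob = c(probs, max(0, 1 - sum(probs))))
  latency <- rtnorm(1, model$latency_mean + eff("latency_add", "BEFORE"),
                    model$latency_sd)
  ipi_m <- model$ipi_mean + eff("ipi_add", c("BEFORE", "EXECUTION"))
  trans_m <- model$transition_mean +
    eff("transition_add", c("BEFORE", "EXECUTION", "TRANSITION"))
  drawIpis <- function(n) if (n > 0) rtnorm(n, ipi_m, model$ipi_sd) else numeric(0)
  n1 <- n2 <- 0L
  if (cat_ == "CORRECT") {
    n1 <- if (block == "FORCED") 4L else
      4L + stats::rgeom(1, model$s1_extra_press_geometric_p)
    n2 <- if (block == "FORCED") 4L else
      4L + stats::rgeom(1, model$s2_extra_press_geometric_p)
  } else if (cat_ == "INCORRECT_START") {
    n2 <- sample(1:3, 1L)
  } else if (cat_ == "BREAK_S1") {
    n1 <- sample(1:3, 1L)
  } else if (cat_ == "PREMATURE_SWITCH") {
    n1 <- sample(1:3, 1L); n2 <- sample(1:4, 1L)
  } else {  # BREAK_S2
    n1 <- if (block == "FORCED") 4L else
      4L + stats::rgeom(1, model$s1_extra_press_geometric_p)
    n2 <- sample(1:3, 1L)
  }
  t1 <- if (n1 > 0) latency + c(0, cumsum(drawIpis(n1 - 1L))) else numeric(0)
  if (n2 > 0) {
    start2 <- if (n1 > 0) t1[n1] + rtnorm(1, trans_m, model$transition_sd)
      else latency
    t2 <- start2 + c(0, cumsum(drawIpis(n2 - 1L)))
  } else t2 <- numeric(0)
  last_press <- max(c(t1, t2))
  rel <- c(0, t1, t2)
  codes <- c("BEAM_OUT", rep("LP1", n1), rep("LP2", n2))
  correct <- cat_ == "CORRECT"
  if (correct) { rel <- c(rel, last_press); codes <- c(codes, "REWARD") }
  t_mag <- last_press + rtnorm(1, model$magazine_delay_mean,
                               model$magazine_delay_sd)
  rel <- c(rel, t_mag); codes <- c(codes, "MAG_IN")
  end_rel <- t_mag
  if (!correct) {
    rel <- c(rel, t_mag + TIME_RESOLUTION)
    codes <- c(codes, "TIMEOUT_START")
    end_rel <- t_mag + timeout
  }
  trigger_rel <- switch(protocol,
    NONE = NA_real_,
    BEFORE = 0,
    EXECUTION = if (n1 + n2 > 0) min(c(t1, t2)) else NA_real_,
    TRANSITION = if (n1 >= 3L) t1[n1 - 2L] else NA_real_)
  list(rel_times = rel, codes = codes, trigger_rel = trigger_rel,
       end_rel = end_rel, return_to_start = FALSE, correct = correct)
}

#' Spike-train modulation specification
#'
#' Describes the inhomogeneous Poisson intensity of a simulated unit:
#' a constant baseline plus event-locked kernels plus an optional
#' duration-coding term that adds `duration_gain` x (trial sequence
#' duration) Hz over each correct trial (from 1 s before its first press to
#' its last press), for regression-recovery tests. The intensity is clipped
#' at zero.
#'
#' @param baseline_rate baseline intensity (Hz), > 0.
#' @param kernels list of kernels; each a list with `anchor` (one of
#'   `"first_press"`, `"s1_press"`, `"transition"` (last S1 press),
#'   `"s2_press"`, `"reward"`), `shape` (`"boxcar"`, `"ramp"` or
#'   `"gaussian"`), `amplitude` (Hz, may be negative), `onset` and `offset`
#'   (s relative to the anchor, onset < offset). A ramp rises linearly from
#'   0 at onset to `amplitude` at offset; a gaussian is centered mid-window
#'   with sigma a quarter of the window.
#' @param duration_gain Hz per second of sequence duration.
#' @return a list of class `ModulationSpec`.
#' @export
modulationSpec <- function(baseline_rate = 10, kernels = list(),
                           duration_gain = 0) {
  stopIfNot(baseline_rate > 0, "baseline_rate must be > 0")
  for (k in kernels) {
    stopIfNot(all(c("anchor", "shape", "amplitude", "onset", "offset") %in%
                    names(k)), "kernel missing fields")
    stopIfNot(k$anchor %in% c("first_press", "s1_press", "transition",
                              "s2_press", "reward"),
              "unknown kernel anchor '%s'", k$anchor)
    stopIfNot(k$shape %in% c("boxcar", "ramp", "gaussian"),
              "unknown kernel shape '%s'", k$shape)
    stopIfNot(k$onset < k$offset, "kernel onset must precede offset")
  }
  structure(list(baseline_rate = baseline_rate, kernels = kernels,
                 duration_gain = duration_gain), class = "ModulationSpec")
}

## Anchor times for each kernel anchor name, from parsed trials.
kernelAnchorTimes <- function(trials, anchor) {
  tr <- trials[!trials$return_to_start, , drop = FALSE]
  switch(anchor,
    first_press = vapply(seq_len(nrow(tr)), function(i) {
      a <- c(tr$s1_times[[i]], tr$s2_times[[i]])
      if (length(a)) min(a) else NA_real_
    }, numeric(1)),
    s1_press = unlist(tr$s1_times),
    transition = vapply(tr$s1_times, function(x)
      if (length(x)) max(x) else NA_real_, numeric(1)),
    s2_press = unlist(tr$s2_times),
    reward = tr$magazine_time[tr$classification == "CORRECT"])
}

#' Evaluate the modulation intensity of a unit
#'
#' Returns the inhomogeneous Poisson intensity (Hz) of `spec` over a
#' session at the requested times. Exposed so the spike-count conservation
#' of [simulateUnit()] can be checked against the intensity integral.
#'
#' @param session a [Session-class] (must parse without error).
#' @param spec a [modulationSpec()].
#' @param t times (s) at which to evaluate.
#' @return numeric vector of intensities (Hz), clipped at zero.
#' @export
unitIntensity <- function(session, spec, t) {
  trials <- parseTrials(session)
  lam <- rep(spec$baseline_rate, length(t))
  ord <- order(t)
  ts <- t[ord]
  add <- numeric(length(ts))
  for (k in spec$kernels) {
    anchors <- kernelAnchorTimes(trials, k$anchor)
    anchors <- anchors[!is.na(anchors)]
    for (a in anchors) {
      lo <- a + k$onset; hi <- a + k$offset
      i1 <- findInterval(lo, ts, left.open = TRUE) + 1L
      i2 <- findInterval(hi, ts)
      if (i1 > i2) next
      idx <- i1:i2
      tau <- ts[idx] - a
      add[idx] <- add[idx] + switch(k$shape,
        boxcar = k$amplitude,
        ramp = k$amplitude * (tau - k$onset) / (k$offset - k$onset),
        gaussian = {
          ctr <- (k$onset + k$offset) / 2
          sdv <- (k$offset - k$onset) / 4
          k$amplitude * exp(-0.5 * ((tau - ctr) / sdv)^2)
        })
    }
  }
  if (spec$duration_gain != 0) {
    ok <- which(trials$classification %in% "CORRECT" &
                  !is.na(trials$duration))
    for (i in ok) {
      first <- min(trials$s1_times[[i]])
      last <- max(trials$s2_times[[i]])
      i1 <- findInterval(first - 1, ts, left.open = TRUE) + 1L
      i2 <- findInterval(last, ts)
      if (i1 <= i2)
        add[i1:i2] <- add[i1:i2] + spec$duration_gain * trials$duration[i]
    }
  }
  out <- numeric(length(t))
  out[ord] <- pmax(lam[ord] + add, 0)
  out
}

#' Simulate a unit's spike train over a session
#'
#' Draws spikes from the inhomogeneous Poisson process defined by
#' [modulationSpec()] using thinning: candidates are drawn homogeneously at
#' an upper bound on the intensity and accepted with probability
#' intensity/bound, so the expected count over any window equals the
#' intensity integral.
#'
#' @param session a [Session-class].
#' @param spec a [modulationSpec()].
#' @param seed integer seed.
#' @param unit_id,region identity of the simulated unit.
#' @return a [SpikeTrain-class].
#' @export
simulateUnit <- function(session, spec, seed = 1L, unit_id = "sim_u1",
                         region = "M2") {
  stopIfNot(inherits(spec, "ModulationSpec"), "spec must be a modulationSpec()")
  ev <- session@events
  t_end <- max(ev$time)
  trials <- parseTrials(session)
  max_dur <- if (any(trials$classification %in% "CORRECT"))
    max(trials$duration[trials$classification %in% "CORRECT"], na.rm = TRUE)
    else 0
  lam_max <- spec$baseline_rate +
    sum(vapply(spec$kernels, function(k) max(0, k$amplitude), numeric(1))) +
    max(0, spec$duration_gain * max_dur)
  withSeed(seed, {
    n_cand <- stats::rpois(1, lam_max * t_end)
    cand <- sort(stats::runif(n_cand, 0, t_end))
    lam <- unitIntensity(session, spec, cand)
    keep <- stats::runif(n_cand) < lam / lam_max
    new("SpikeTrain", unit_id = unit_id, region = region,
        spike_times = cand[keep], waveform_behavioral = numeric(0),
        waveform_light = numeric(0), pid = NA)
  })
}

#' Photo-identification response specification
#'
#' @param antidromic_latency fixed antidromic latency (s), > 0.
#' @param latency_jitter_sd per-pulse latency jitter sd (s).
#' @param follow_fidelity probability a pulse evokes a spike, in \[0, 1\].
#' @param waveform_correlation target Pearson correlation between the
#'   behavioral and light-evoked mean waveforms, in \[-1, 1\] (achieved
#'   exactly by construction).
#' @return a list of class `PidSpec`.
#' @export
pidSpec <- function(antidromic_latency = 0.005, latency_jitter_sd = 0.0005,
                    follow_fidelity = 0.9, waveform_correlation = 0.97) {
  stopIfNot(antidromic_latency > 0, "antidromic_latency must be > 0")
  stopIfNot(follow_fidelity >= 0 && follow_fidelity <= 1,
            "follow_fidelity must lie in [0, 1]")
  stopIfNot(abs(waveform_correlation) <= 1,
            "waveform_correlation must lie in [-1, 1]")
  structure(list(antidromic_latency = antidromic_latency,
                 latency_jitter_sd = latency_jitter_sd,
                 follow_fidelity = follow_fidelity,
                 waveform_correlation = waveform_correlation),
            class = "PidSpec")
}

#' Pulse-train onsets for photo-identification
#'
#' Onset times of 10-Hz trains of brief light pulses (the
#' photo-identification stimulation geometry: 1-s trains of 10-ms pulses).
#'
#' @param train_starts start times (s) of each 1-s train.
#' @param n_pulses pulses per train.
#' @param hz pulse rate within a train.
#' @return sorted vector of pulse onset times (s).
#' @export
pulseTrain <- function(train_starts, n_pulses = 10L, hz = 10) {
  sort(as.vector(outer(seq_len(n_pulses) - 1L, train_starts,
                       function(i, s) s + i / hz)))
}

#' Add light-evoked spikes and waveforms to a unit
#'
#' For each pulse, an antidromic spike is emitted with probability
#' `follow_fidelity` at the specified latency plus Gaussian jitter. A pair
#' of mean waveforms (behavioral, light-evoked) is attached with exactly
#' the requested Pearson correlation (the light waveform is built from the
#' standardized behavioral waveform plus an orthogonalized noise component).
#'
#' @param unit a [SpikeTrain-class].
#' @param pid a [pidSpec()].
#' @param pulse_times pulse onset times (s), e.g. from [pulseTrain()].
#' @param seed integer seed.
#' @param n_samples waveform length in samples.
#' @return the unit with evoked spikes merged in and waveforms attached.
#' @export
simulatePhotoid <- function(unit, pid, pulse_times, seed = 1L,
                            n_samples = 32L) {
  stopIfNot(inherits(pid, "PidSpec"), "pid must be a pidSpec()")
  withSeed(seed, {
    fire <- stats::runif(length(pulse_times)) < pid$follow_fidelity
    lat <- pid$antidromic_latency +
      stats::rnorm(sum(fire), 0, pid$latency_jitter_sd)
    lat <- pmax(lat, 1e-4)
    evoked <- pulse_times[fire] + lat
    i <- seq_len(n_samples)
    wb <- unit@waveform_behavioral
    if (!length(wb))
      wb <- 100 * (-exp(-0.5 * ((i - n_samples * 0.3) / (n_samples * 0.06))^2) +
                     0.35 * exp(-0.5 * ((i - n_samples * 0.6) /
                                          (n_samples * 0.12))^2))
    z1 <- as.vector(scale(wb))
    e <- stats::rnorm(n_samples)
    e <- stats::residuals(stats::lm(e ~ z1))
    z2 <- as.vector(scale(e))
    r <- pid$waveform_correlation
    wl <- (r * z1 + sqrt(max(0, 1 - r^2)) * z2) * stats::sd(wb) + mean(wb)
    new("SpikeTrain", unit_id = unit@unit_id, region = unit@region,
        spike_times = sort(c(unit@spike_times, evoked)),
        waveform_behavioral = wb, waveform_light = wl, pid = NA)
  })
}
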