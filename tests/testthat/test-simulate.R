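test_that("a perfect performer is 100% correct in both block types", {
  m <- performerModel(p_incorrect_start = 0, p_break_s1 = 0,
                      p_premature_switch = 0, p_break_s2 = 0, p_return = 0)
  s <- simulateSession(m, n_rewards_target = 40, seed = 1)
  tr <- parseTrials(s)
  expect_equal(percentCorrect(tr, "FORCED"), 100)
  expect_equal(percentCorrect(tr, "SELF_PACED"), 100)
  expect_equal(sum(events(s)$code == "REWARD"), 40L)
})

test_that("parsed error fractions recover the programmed probabilities", {
  m <- performerModel(p_incorrect_start = 0, p_break_s1 = 0,
                      p_premature_switch = 0.3, p_break_s2 = 0,
                      p_return = 0)
  s <- simulateSession(m, n_trials_target = 500, seed = 4,
                       block_mode = "self_only")
  tr <- parseTrials(s)
  tr <- tr[!tr$return_to_start, ]
  frac <- mean(tr$classification == "PREMATURE_SWITCH")
  se <- sqrt(0.3 * 0.7 / nrow(tr))
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("a programmed light latency effect is recovered from parsed trials", {
  m <- performerModel(opto_effects = list(latency_add = 1.0))
  s <- simulateSession(m, n_trials_target = 400, protocol = "BEFORE",
                       seed = 6, block_mode = "self_only")
  tr <- parseTrials(s)
  tr <- tr[!tr$return_to_start & !is.na(tr$latency), ]
  d <- mean(tr$latency[tr$light == "ON"]) - mean(tr$latency[tr$light == "OFF"])
  se <- sqrt(var(tr$latency[tr$light == "ON"]) / sum(tr$light == "ON") +
               var(tr$latency[tr$light == "OFF"]) / sum(tr$light == "OFF"))
  expect_lt(abs(d - 1.0), 3 * se)
})

test_that("light events alternate strictly and fire at the protocol trigger", {
  m <- performerModel()
  for (prot in c("BEFORE", "EXECUTION", "TRANSITION")) {
    s <- simulateSession(m, n_rewards_target = 25, protocol = prot, seed = 10)
    ev <- events(s)
    lt <- ev$code[ev$code %in% c("LIGHT_ON", "LIGHT_OFF")]
    expect_identical(lt, rep(c("LIGHT_ON", "LIGHT_OFF"),
                             length.out = length(lt)))
    ons <- ev$time[ev$code == "LIGHT_ON"]
    offs <- ev$time[ev$code == "LIGHT_OFF"]
    expect_equal(offs - ons, rep(2, length(ons)))
    if (prot == "BEFORE")
      expect_true(all(ons %in% ev$time[ev$code == "BEAM_OUT"]))
    else
      expect_true(all(ons %in% ev$time[ev$code %in% c("LP1", "LP2")]))
  }
})

test_that("a fixed seed reproduces the event log and spike table byte-identically", {
  m <- performerModel()
  s1 <- simulateSession(m, n_rewards_target = 15, seed = 21)
  s2 <- simulateSession(m, n_rewards_target = 15, seed = 21)
  expect_identical(events(s1), events(s2))
  f1 <- tempfile(); f2 <- tempfile()
  writeEventLog(s1, f1); writeEventLog(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  spec <- modulationSpec(baseline_rate = 8)
  u1 <- simulateUnit(s1, spec, seed = 5)
  u2 <- simulateUnit(s2, spec, seed = 5)
  expect_identical(spikeTimes(u1), spikeTimes(u2))
})

test_that("spike counts match the intensity integral within Poisson error", {
  s <- quietSession(seed = 3)
  t_end <- max(events(s)$time)
  spec <- modulationSpec(baseline_rate = 10, kernels = list(
    list(anchor = "first_press", shape = "boxcar", amplitude = 15,
         onset = -1, offset = 0),
    list(anchor = "s2_press", shape = "gaussian", amplitude = -6,
         onset = -0.2, offset = 0.2)))
  grid <- seq(0, t_end, by = 0.002)
  integral <- sum(unitIntensity(s, spec, grid)) * 0.002
  z <- vapply(1:30, function(seed) {
    n <- length(spikeTimes(simulateUnit(s, spec, seed = seed)))
    (n - integral) / sqrt(integral)
  }, numeric(1))
  expect_true(all(abs(z) < 4.5))
  expect_lt(abs(mean(z)), 3 / sqrt(30))
})

test_that("a flat 10-Hz unit over a session yields about rate x time spikes", {
  s <- quietSession(seed = 12, n_rewards = 10)
  t_end <- max(events(s)$time)
  spec <- modulationSpec(baseline_rate = 10)
  n <- length(spikeTimes(simulateUnit(s, spec, seed = 31)))
  expect_lt(abs(n - 10 * t_end), 3 * sqrt(10 * t_end))
})

test_that("duration-coded units carry the programmed rate offset", {
  m <- performerModel(p_incorrect_start = 0, p_break_s1 = 0,
                      p_premature_switch = 0, p_break_s2 = 0)
  s <- simulateSession(m, n_trials_target = 30, seed = 13,
                       block_mode = "self_only")
  tr <- parseTrials(s)
  spec <- modulationSpec(baseline_rate = 10, duration_gain = 5)
  ok <- which(tr$classification == "CORRECT")
  mid <- vapply(ok, function(i) mean(range(tr$s1_times[[i]])), numeric(1))
  lam <- unitIntensity(s, spec, mid)
  expect_equal(lam, 10 + 5 * tr$duration[ok], tolerance = 1e-9)
})

test_that("photo-id simulation controls latency, fidelity and waveform r", {
  pulses <- pulseTrain(c(10, 20, 30))
  expect_length(pulses, 30L)
  expect_equal(diff(pulses)[1:9], rep(0.1, 9))
  base <- new("SpikeTrain", unit_id = "u1", region = "M2",
              spike_times = sort(runif(50, 0, 9)),
              waveform_behavioral = numeric(0),
              waveform_light = numeric(0), pid = NA)
  u <- simulatePhotoid(base, pidSpec(antidromic_latency = 0.005,
                                     latency_jitter_sd = 0,
                                     follow_fidelity = 1,
                                     waveform_correlation = 0.99),
                       pulses, seed = 2)
  lat <- antidromicLatency(u, pulses)
  expect_equal(lat$median_latency, 0.005, tolerance = 1e-9)
  expect_equal(lat$follow_fraction, 1)
  expect_equal(waveformCorrelation(u@waveform_behavioral, u@waveform_light),
               0.99, tolerance = 1e-9)
})

test_that("model validation rejects impossible parameter sets", {
  expect_error(performerModel(p_break_s1 = 1.2), "\\[0, 1\\]")
  expect_error(performerModel(p_incorrect_start = 0.5, p_break_s1 = 0.5,
                              p_premature_switch = 0.5), "sum")
  expect_error(performerModel(ipi_mean = -1), "positive")
  expect_error(modulationSpec(baseline_rate = 0), "baseline_rate")
  expect_error(modulationSpec(kernels = list(list(anchor = "nope",
    shape = "boxcar", amplitude = 1, onset = 0, offset = 1))), "anchor")
})
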