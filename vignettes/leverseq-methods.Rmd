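---
title: "Analyzing serial-order lever-press sequences and peri-event neural activity with leverseq"
author: "leverseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing serial-order lever-press sequences with leverseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leverseq)
```

## The task and the data

leverseq analyzes operant experiments in which an animal chains two
subsequences of lever presses: at least four presses on lever 1 (S1)
followed by at least four on lever 2 (S2), rewarded at a food magazine. In
*forced* blocks the apparatus presents one lever at a time, so only two
errors are possible (abandoning S1 or S2 for the magazine). In *self-paced*
blocks both levers are available and four error categories exist: incorrect
start (first press on lever 2), break of S1, premature switch (moving to
lever 2 before four S1 presses), and break of S2. Blocks alternate after
five consecutive correct trials, errors trigger a 10-s timeout, and an
infrared beam between magazine and lever marks the start of each attempt.
All events are timestamped at 10-ms resolution; that resolution is baked
into the package (`Event` times are quantized to 0.01 s and all bin
arithmetic uses half-open 10-ms bins).

Three kinds of data flow through the pipeline: behavioral event logs
(`Session`), spike-time tables per unit (`SpikeTrain`), and optogenetic
trial metadata (the session's protocol plus `LIGHT_ON`/`LIGHT_OFF` events).
Simultaneous events are ordered by a fixed code priority (block markers,
then beam, presses, magazine, reward, light), so parsing is deterministic
regardless of file row order.

## Trial parsing

`parseTrials()` partitions the event stream at magazine entries and
timeouts: a trial opens at the first beam crossing (or press) after the
previous magazine entry and closes at the next magazine entry. Every press
belongs to exactly one trial and every trial receives exactly one category
(both properties are tested). Two boundary conventions were genuinely open
and are resolved as follows:

* **Presses on lever 1 after the first lever-2 press** do not extend S1;
  the trial is classified by the S1/S2 counts at closure. The task
  description never covers this case; counting at closure keeps the
  classification a total function of press counts.
* **Latency to start** uses the *last* beam crossing before the first
  press; the beam sits physically between magazine and lever, so the final
  crossing is the one that precedes the approach.
* **Long-S1** requires strictly more than four S1 presses on a correct
  trial.
* A beam crossing followed by a magazine entry with no press in between is
  recorded as a *return to start* and excluded from percent-correct
  denominators.

## Firing rates, alignment, z-scoring

Spike trains are converted to instantaneous rate by convolution with a
unit-area Gaussian (sigma 25 ms) on a 100-Hz grid. The kernel is truncated
at plus/minus four sigma and renormalized, which keeps the mass loss below
1e-4 per spike; the integral of a fully supported trace equals the spike
count to better than 1e-3 (tested on random trains). Rates are aligned to
press anchors over a window of 4.5 s before to 5 s after, and z-scored
against the half second ending 4 s before the first press. The baseline
mean and standard deviation are pooled over every trial's baseline bins
(one normalization per unit); whether the normalization should be per-trial
was open, and pooled was chosen because the per-trial baseline spans only
0.5 s (about five independent samples at this kernel width), making
per-trial standard deviations unusable. A floor of 0.1 Hz on the baseline
standard deviation prevents unbounded z values for near-silent units; a
unit whose baseline is identically zero is flagged and excluded from z
analyses.

## Per-trial time rescaling

Trials of different durations are averaged after piecewise-linear time
rescaling: the eight alignment events (first, second, penultimate and last
press of each subsequence) are mapped onto a canonical template built from
the mean inter-press interval, the mean second-to-penultimate gap, and the
mean transition time of all eligible trials (at least four presses per
subsequence). Values at the anchors are preserved exactly and rescaling is
the identity when a trial already matches the template (both tested to
1e-9). For a 4-press subsequence the second and penultimate press coincide;
the warp treats the duplicated anchor as a point and paints the template's
middle segment with the value at that instant, rather than reordering or
erroring. Segments before the first and after the last anchor are shifted
rigidly.

Units are assigned a modulation category from the mean z in four epochs on
the template: pre-initiation (the 1 s before the first S1 press), S1,
transition, and S2, with threshold |z| >= 2. The taxonomy is: Init & S1
execution, Init S1 & S2, Transition (init S2), S2 execution, S1 & S2
execution, plus None (no epoch crosses the threshold) and Negative (only
negative crossings). Patterns the taxonomy does not name explicitly are
mapped to the nearest label by precedence (initiation first, then S1, then
transition), and a separate Negative label is kept rather than folding
negative modulations into the positive categories; both conventions were
open choices.

## AUROC modulation maps

`modulationProfile()` compares the firing rate in each 200-ms bin (slid in
10-ms steps) against baseline with the area under the ROC curve, which
equals the Mann-Whitney U statistic normalized by the product of sample
sizes, ties counted one half (tested against exhaustive pair counting).
The baseline sample consists of non-overlapping 200-ms bins inside the
baseline window (two bins per trial at the default half-second window),
*not* the 0.5-s mean: matching the test-bin width makes test and baseline
values exchangeable under the null, and the per-bin false-positive rate
then calibrates at the nominal 0.05 (tested over 20 seeds on homogeneous
Poisson units).

Significance per bin comes from permuting the test/baseline labels, 1000
permutations, with the two-sided extremity definition
p = (b + 1)/(n_perm + 1) where b counts permuted AUROC values at least as
far from 0.5 as the observed one. A rule sometimes quoted for such maps -
counting the fraction of permuted AUROC values falling above (or below)
0.5 - is not a p value (it sits near 0.5 under the null whatever the
data), so the standard two-sided smoothed definition is used, and an
exact-enumeration path is available at
small trial counts. Per-bin significance is reported uncorrected, matching
the binary-matrix convention used for recruitment summaries
(`recruitmentFraction()`); family-wise control is left to the effect
statistics layer.

## Permutation regressions

Firing rates are regressed on binned behavioral covariates: press counts
grouped to the nearest even class 2-16 (odd counts round up), latency in
1-s classes starting at 0.5 s (values below 0.5 s join the first class,
since no lower class is defined), and durations in seven equal-count
classes ordered descending. Five canonical windows are analyzed
(`windowRegressions()`): rate in the 1 s before the sequence vs sequence
duration, rate during the sequence vs its duration, and the three
within-epoch pairs (S1, transition, S2). Significance is by shuffling the
covariate across trials (1000 permutations, two-sided on |r|); a
regression is accepted when p < 0.05, r > 0.6 and the slope is nonzero.
Both conventions - |r| > 0.6 and R^2 > 0.6 - are in circulation for this
kind of screen; |r| is the default and `use_r2 = TRUE` switches to the
stricter variant (both values are reported either way).

Population comparisons use the z-difference test:
z = (Z1 - Z2) / sqrt(1/(N1 - 3) + 1/(N2 - 3)), referred to the standard
normal, two-sided. The default denominator is the Fisher-comparison form,
which is symmetric in the two samples; a variant with 1/(N2 + 3) in the
second term, occasionally seen in print, is kept behind `literal = TRUE`
for comparison.

## Estimation statistics for optogenetic designs

Light-on/light-off designs are summarized per animal
(`animalDeltas()`): continuous metrics average per-trial values per light
condition; proportion metrics divide category counts by the total
classified trials of that light condition, and returns-to-start use
all attempt records as the denominator. Inference uses:

* paired two-sided permutation t tests (sign flips of the paired
  differences; exact enumeration when 2^n <= 4096, otherwise 5000 flips
  with (b + 1)/(n_perm + 1) smoothing),
* unpaired two-sided permutation t tests (label shuffles, exact when
  choose(n, n1) <= 4096),
* percentile bootstrap 95% CIs of the mean difference (5000 resamples);
  percentile chosen as the simplest interval consistent with the
  effect-size-and-CI reporting format,
* Benjamini-Hochberg FDR within each protocol-by-group family, significance
  q < 0.10 (via `stats::p.adjust`; the test suite checks it against a
  direct step-up implementation).

`optoEffects()` chains these into one table per group, protocol, metric
and comparison (paired on/off, and change score against the
fluorophore-only control group).

## Photo-identification

A unit is accepted as a cortico-striatal projection neuron when the median
first-spike latency after striatal light pulses is below 10 ms and the
Pearson correlation between its behavioral and light-evoked mean waveforms
exceeds 0.9. The summary statistic for latency (mean, median or minimum)
is a genuinely open choice; the median over responding pulses is used. The response
window equals the acceptance bound (0-10 ms), so later spikes are ignored
rather than counted as slow responses. These conventions make the decision
boundary exact, which the tests exploit (9.9-ms units accepted, 10.1-ms
rejected, in 100% of noiseless cases).

## The synthetic-data generator

`simulateSession()` implements the full task state machine with a
stochastic performer: per-trial error-category draws, truncated-normal
timing (floor 0.05 s: only the timing means are pinned down by the task
conventions, and truncation guarantees positivity and a realistic minimum
interval), a geometric number of
extra S1 presses on correct self-paced trials, and optional light protocols
(`BEFORE`: light at the beam crossing; `EXECUTION`: at the first press;
`TRANSITION`: at the press before the penultimate S1 press, which in
4-press forced sequences is the third press, the penultimate). Light is
assigned by a Bernoulli(0.5) draw per attempt — the realized fraction is
logged in the session payload — and optogenetic effects are applied to the
generative parameters of the stages at or after the trigger, never post
hoc, so downstream recovery is a genuine end-to-end test.

Default parameters emulate a late-training performer: break probabilities
0.09/0.08 give about 83% correct forced trials, adding incorrect starts
(0.05) and premature switches (0.17) gives about 61% correct self-paced
trials, latency 1.5 s, inter-press interval 0.5 s, transition 1 s, and a
geometric S1-extra parameter of 0.33 for a mean of about six S1 presses on
self-paced trials. These match the reported late-training behavior scale
and are fixed as the package's study conditions.

`simulateUnit()` draws spikes from an inhomogeneous Poisson process by
thinning; the intensity is a baseline plus event-locked kernels (boxcar,
ramp, or Gaussian, anchored at presses, transitions or rewards) plus an
optional duration-coding term (`duration_gain` in Hz per second of
sequence duration, active from 1 s before the first press to the last
press of each correct trial). The intensity is clipped at zero, and
`unitIntensity()` exposes it so tests can check spike-count conservation
against the integral. What the generator does **not** emulate: bursting
and refractoriness, slow drift, cross-trial learning, correlated noise
across units, and movement artifacts — so passing tests demonstrate the
statistics recover programmed structure from Poisson spiking, not that
they are robust to every property of real recordings.

## Problem sizes, tolerances and degenerate inputs

The test suite runs the stochastic checks at sizes chosen to make each
property measurable while keeping the suite fast: simulator-parser closure
pools 10 seeds of 500 self-paced trials; the AUROC null calibration uses
20 seeds of 20-reward sessions; permutation-test calibration uses 1000
replicates; regression recovery uses 50 seeds of 60-trial sessions at a
duration gain of 5 Hz/s; the optogenetic end-to-end check uses 20 seeds of
9 + 9 animal cohorts at 70 rewards per session (the standard session
length), with a programmed 1.0-s latency increase and a 0.12
premature-switch increase.

One power note, established analytically and reproduced by the suite: with
70-reward sessions and 50% light assignment, each animal contributes only
about 25 self-paced trials per light condition, so a per-animal
premature-switch proportion carries a binomial standard error near 12
percentage points. A 12-point programmed effect then gives the unpaired
9-vs-9 change-score comparison roughly 70% power at q < 0.10 — the paired
on/off contrast detects it reliably, but the change score against control
does not reach 90% recovery at these session sizes. This is a property of
the design geometry (per-animal trial counts), not of the estimators; the
corresponding end-to-end expectation in the suite is documented as not
attained under these study conditions rather than met by enlarging the
sessions.

Degenerate inputs are handled explicitly rather than by accident: empty
spike trains give zero rate traces; constant rates give slope 0 and are
never accepted by the regression; all-zero paired differences give p = 1;
zero-variance waveforms are rejected from photo-identification; silent
units are flagged out of z analyses; and anchors that lack full window
support are dropped and counted, never silently padded.
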