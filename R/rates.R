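#' Instantaneous firing rate from spike times
#'
#' Convolves the spike train with a unit-area Gaussian kernel (sigma 25 ms,
#' truncated at +/- 4 sigma and renormalized so less than 1e-4 of the mass
#' is lost) evaluated on a regular 100-Hz grid. The trace integrates to the
#' spike count when the span fully supports every kernel. An empty spike
#' list yields an all-zero trace, not an error.
#'
#' @param spikes a [SpikeTrain-class] or a numeric vector of spike times.
#' @param span numeric length 2: start and end (s) of the grid; should
#'   extend 4 sigma beyond any spike used downstream.
#' @param kernel_sigma Gaussian sigma (s), default 0.025.
#' @return a [RateTrace-class].
#' @export
rateFromSpikes <- function(spikes, span, kernel_sigma = 0.025) {
  st <- if (is(spikes, "SpikeTrain")) spikes@spike_times else sort(spikes)
  stopIfNot(length(span) == 2L && span[2] > span[1],
            "span must be (start, end) with start < end")
  dt <- TIME_RESOLUTION
  t0 <- round(span[1] / dt) * dt
  nb <- floor((span[2] - t0) / dt) + 1L
  vals <- numeric(nb)
  if (length(st)) {
    half <- ceiling(4 * kernel_sigma / dt)
    koff <- (-half):half
    kern <- stats::dnorm(koff * dt, sd = kernel_sigma)
    kern <- kern / (sum(kern) * dt)  # renormalize truncated kernel to unit area
    centers <- round((st - t0) / dt)
    for (i in seq_along(centers)) {
      idx <- centers[i] + koff + 1L
      ok <- idx >= 1L & idx <= nb
      vals[idx[ok]] <- vals[idx[ok]] + kern[ok]
    }
  }
  new("RateTrace", t0 = t0, dt = dt, values = vals,
      kernel_sigma = kernel_sigma)
}

#' Align a rate trace around event anchors
#'
#' Extracts one row per anchor from the trace, on a common bin grid running
#' from `window[1]` s before to `window[2]` s after the anchor. Anchors
#' whose window is not fully supported by the trace are dropped and counted
#' in `n_dropped`.
#'
#' @param trace a [RateTrace-class].
#' @param anchors anchor times (s).
#' @param window numeric length 2: seconds before and after the anchor
#'   (both positive).
#' @param unit_id,anchor_name labels stored on the result.
#' @return an [AlignedRates-class] (units Hz).
#' @export
alignRates <- function(trace, anchors, window = c(4.5, 5),
                       unit_id = "u0", anchor_name = "P1_S1") {
  stopIfNot(length(window) == 2L && all(window >= 0),
            "window must be two non-negative numbers (pre, post)")
  dt <- trace@dt
  nb <- length(trace@values)
  pre_n <- round(window[1] / dt); post_n <- round(window[2] / dt)
  offsets <- ((-pre_n):post_n) * dt
  centers <- round((anchors - trace@t0) / dt)
  ok <- centers - pre_n >= 0L & centers + post_n <= nb - 1L
  if (!any(ok)) stop("no anchor has full window support", call. = FALSE)
  m <- t(vapply(centers[ok], function(ci)
    trace@values[(ci - pre_n):(ci + post_n) + 1L],
    numeric(pre_n + post_n + 1L)))
  new("AlignedRates", unit_id = unit_id, anchor = anchor_name,
      window = window, offsets = offsets, matrix = m, units = "hz",
      n_dropped = sum(!ok), baseline_mean = NA_real_,
      baseline_sd = NA_real_, flagged = FALSE)
}

#' z-score aligned rates against a baseline window
#'
#' z = (rate - baseline mean) / baseline sd, with the mean and sd pooled
#' over every trial's baseline bins (a single normalization per unit). A
#' floor of `sd_floor` Hz is applied to the baseline sd so near-silent
#' units do not produce unbounded z values; a unit whose pooled baseline is
#' exactly constant at zero is flagged (`@flagged`) and should be excluded
#' from z analyses.
#'
#' @param aligned an [AlignedRates-class] in Hz.
#' @param baseline numeric length 2: baseline window (s, relative to the
#'   anchor), default the pre-initiation convention (-4.5, -4).
#' @param sd_floor minimum baseline sd (Hz).
#' @return the object with `matrix` in z units and baseline stats recorded.
#' @export
zscoreRows <- function(aligned, baseline = c(-4.5, -4), sd_floor = 0.1) {
  stopIfNot(aligned@units == "hz", "aligned matrix already z-scored")
  cols <- aligned@offsets >= baseline[1] - 1e-9 &
    aligned@offsets <= baseline[2] + 1e-9
  stopIfNot(any(cols), "baseline window outside the alignment window")
  b <- as.vector(aligned@matrix[, cols, drop = FALSE])
  mu <- mean(b)
  sd_raw <- stats::sd(b)
  flagged <- (is.na(sd_raw) || sd_raw == 0) && mu == 0
  sdv <- max(sd_raw, sd_floor, na.rm = TRUE)
  out <- aligned
  out@matrix <- (aligned@matrix - mu) / sdv
  out@units <- "z"
  out@baseline_mean <- mu
  out@baseline_sd <- sdv
  out@flagged <- flagged
  out
}

#' Canonical sequence template from trial metrics
#'
#' Builds the eight alignment anchors (first, second, penultimate and last
#' press of S1 and of S2) of the canonical sequence: adjacent-press gaps are
#' the mean inter-press interval pooled over all eligible trials, the
#' middle gap of each subsequence (second to penultimate press) is the mean
#' observed gap, and the S1 -> S2 gap is the mean transition time. Eligible
#' trials have at least four presses in each subsequence. Anchors are
#' rounded to the 10-ms grid.
#'
#' @param trials trial table(s) from [parseTrials()]; a list is pooled
#'   across sessions.
#' @return named numeric of length 8 (`P1_S1` ... `PLast_S2`), `P1_S1` at 0.
#' @export
buildTemplate <- function(trials) {
  if (is.data.frame(trials)) trials <- list(trials)
  tr <- do.call(rbind, lapply(trials, function(x)
    x[!x$return_to_start & x$n_s1 >= 4L & x$n_s2 >= 4L, , drop = FALSE]))
  stopIfNot(!is.null(tr) && nrow(tr) > 0L, "no eligible trials (>=4 presses in each subsequence)")
  ipi <- mean(unlist(tr$ipis))
  trans <- mean(tr$transition)
  mid1 <- mean(vapply(tr$s1_times, function(x) x[length(x) - 1L] - x[2L],
                      numeric(1)))
  mid2 <- mean(vapply(tr$s2_times, function(x) x[length(x) - 1L] - x[2L],
                      numeric(1)))
  a <- cumsum(c(0, ipi, mid1, ipi, trans, ipi, mid2, ipi))
  a <- quantizeTime(a)
  names(a) <- c("P1_S1", "P2_S1", "PLast1_S1", "PLast_S1",
                "P1_S2", "P2_S2", "PLast1_S2", "PLast_S2")
  a
}

#' Anchor times of one trial
#'
#' The eight alignment events of an eligible trial (first, second,
#' penultimate, last press of each subsequence). For a 4-press subsequence
#' the second and penultimate press coincide; the duplicated anchor time is
#' returned as-is (the rescaling map treats the zero-length segment as a
#' point, never reorders it).
#'
#' @param trial one row of a [parseTrials()] table.
#' @return named numeric of length 8.
#' @export
trialAnchors <- function(trial) {
  s1 <- trial$s1_times[[1]]; s2 <- trial$s2_times[[1]]
  stopIfNot(length(s1) >= 4L && length(s2) >= 4L,
            "trial needs at least four presses in each subsequence")
  a <- c(s1[1], s1[2], s1[length(s1) - 1L], s1[length(s1)],
         s2[1], s2[2], s2[length(s2) - 1L], s2[length(s2)])
  names(a) <- c("P1_S1", "P2_S1", "PLast1_S1", "PLast_S1",
                "P1_S2", "P2_S2", "PLast1_S2", "PLast_S2")
  a
}

#' Linearly time-rescale a trial onto the template
#'
#' Warps the trial's rate trace so its eight press anchors land on the
#' template anchors, interpolating linearly within each inter-anchor
#' segment. Values at the anchors are preserved exactly. Segments before
#' the first and after the last anchor are shifted rigidly (unit slope).
#' Trial anchors must be non-decreasing; a duplicated anchor (4-press
#' subsequence, where the second and penultimate press coincide) maps its
#' template segment to the constant value at that instant.
#'
#' @param trace a [RateTrace-class] covering the trial.
#' @param trial_anchor_times the trial's 8 anchor times (s), e.g. from
#'   [trialAnchors()].
#' @param template_anchor_times the template anchors from [buildTemplate()].
#' @param pad seconds of unscaled context kept before the first and after
#'   the last anchor.
#' @return list with `times` (template grid), `values`, and
#'   `anchor_index` (grid indices of the 8 anchors, identical for every
#'   trial rescaled to the same template).
#' @export
rescaleTrial <- function(trace, trial_anchor_times, template_anchor_times,
                         pad = c(1, 1)) {
  ta <- as.numeric(trial_anchor_times)
  pa <- as.numeric(template_anchor_times)
  stopIfNot(length(ta) == length(pa) && length(ta) >= 2L,
            "anchor vectors must have equal length >= 2")
  stopIfNot(!is.unsorted(ta), "trial anchors must be non-decreasing")
  stopIfNot(all(diff(pa) > 0), "template anchors must be strictly increasing")
  dt <- trace@dt
  grid <- seq(quantizeTime(pa[1] - pad[1]),
              quantizeTime(pa[length(pa)] + pad[2]), by = dt)
  grid <- quantizeTime(grid)
  ## map template time -> trial time: piecewise linear between anchors,
  ## unit slope outside them
  u <- numeric(length(grid))
  left <- grid < pa[1]; right <- grid > pa[length(pa)]
  mid <- !(left | right)
  u[left] <- ta[1] + (grid[left] - pa[1])
  u[right] <- ta[length(ta)] + (grid[right] - pa[length(pa)])
  if (any(mid))
    u[mid] <- stats::approx(pa, ta, xout = grid[mid], ties = "ordered")$y
  tr_t <- rateTimes(trace)
  vals <- stats::approx(tr_t, trace@values, xout = u, rule = 2)$y
  anchor_index <- round((pa - grid[1]) / dt) + 1L
  list(times = grid, values = vals, anchor_index = anchor_index)
}

#' Epoch mean z values on the rescaled template
#'
#' Means of a rescaled z trace over the four analysis epochs:
#' pre-initiation (the 1 s before the first S1 press), S1 (first to last S1
#' press), transition (last S1 press to first S2 press) and S2 (first to
#' last S2 press).
#'
#' @param values rescaled z values on the template grid.
#' @param times template grid times (s).
#' @param template template anchors from [buildTemplate()].
#' @return named numeric: `init`, `s1`, `transition`, `s2`.
#' @export
epochMeanZ <- function(values, times, template) {
  spans <- rbind(init = c(template["P1_S1"] - 1, template["P1_S1"]),
                 s1 = c(template["P1_S1"], template["PLast_S1"]),
                 transition = c(template["PLast_S1"], template["P1_S2"]),
                 s2 = c(template["P1_S2"], template["PLast_S2"]))
  out <- apply(spans, 1L, function(sp)
    mean(values[times >= sp[1] - 1e-9 & times <= sp[2] + 1e-9]))
  names(out) <- rownames(spans)
  out
}

#' Assign a modulation category from epoch z values
#'
#' Maps the pattern of epochs whose mean |z| reaches the threshold onto the
#' modulation taxonomy: `Init & S1 execution`, `Init S1 & S2`,
#' `Transition (init S2)`, `S2 execution`, `S1 & S2 execution`, `Negative`
#' (only sub-threshold-negative exceedances) or `None`. The assignment
#' depends only on which epochs cross the threshold, not on the rate scale.
#'
#' @param epoch_mean_z named numeric (`init`, `s1`, `transition`, `s2`),
#'   e.g. from [epochMeanZ()].
#' @param threshold z threshold, default 2.
#' @return list with `label` and the input `epoch_mean_z`.
#' @export
categorizeUnit <- function(epoch_mean_z, threshold = 2) {
  z <- epoch_mean_z[c("init", "s1", "transition", "s2")]
  stopIfNot(!any(is.na(z)), "epoch_mean_z needs init, s1, transition, s2")
  pos <- z >= threshold
  neg <- z <= -threshold
  label <-
    if (!any(pos) && !any(neg)) "None"
    else if (!any(pos)) "Negative"
    else if (pos["init"] && pos["s2"]) "Init S1 & S2"
    else if (pos["init"]) "Init & S1 execution"
    else if (pos["s1"] && pos["s2"]) "S1 & S2 execution"
    else if (pos["s1"]) "Init & S1 execution"
    else if (pos["transition"]) "Transition (init S2)"
    else "S2 execution"
  list(label = label, epoch_mean_z = z)
}
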