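#' Parse an event stream into serial-order trials
#'
#' Segments the session's event stream into candidate sequence trials and
#' classifies each one. A trial opens at the first beam crossing (or press)
#' after the previous magazine entry and closes at the next magazine entry
#' or timeout. Classification, per block type:
#' \itemize{
#'   \item self-paced: first press on lever 2 -> `INCORRECT_START`; fewer
#'     than 4 lever-1 presses then magazine with no lever-2 press ->
#'     `BREAK_S1`; fewer than 4 lever-1 presses then any lever-2 press ->
#'     `PREMATURE_SWITCH`; at least 4 lever-1 presses then fewer than 4
#'     lever-2 presses -> `BREAK_S2`; at least 4 and at least 4 ->
#'     `CORRECT`.
#'   \item forced: only break errors are possible (one lever is presented at
#'     a time); correct requires exactly 4 and 4.
#' }
#' A beam crossing followed by a magazine entry with no press in between
#' yields a return-to-start record (`return_to_start = TRUE`,
#' classification `NA`), excluded from percent-correct denominators.
#'
#' Lever-1 presses that occur after the first lever-2 press are not counted
#' into S1; the trial is classified by the S1/S2 counts at closure. The
#' latency uses the last beam crossing before the first press.
#'
#' @param session a [Session-class].
#' @param label_light when `TRUE` (default) and the session has an
#'   optogenetic protocol, [labelOpto()] is applied before returning.
#' @return a `data.frame` with one row per trial or return record: `trial`,
#'   `block`, `classification`, `n_s1`, `n_s2`, `n_presses`, `latency`,
#'   `duration`, `transition`, `ipi_mean`, `long_s1`, `reward`,
#'   `beam_out_time`, `magazine_time`, `t_open`, `t_close`, `light`,
#'   `trigger_press_index`, `return_to_start`, plus list columns
#'   `s1_times`, `s2_times`, `ipis`.
#' @export
parseTrials <- function(session, label_light = TRUE) {
  validObject(session)
  ev <- session@events
  n <- nrow(ev)
  if (!n) return(emptyTrials())
  block_marker <- ifelse(ev$code == "BLOCK_FORCED_START", "FORCED",
                  ifelse(ev$code == "BLOCK_SELF_START", "SELF_PACED", NA))
  block_at <- fillForward(block_marker)
  is_press <- ev$code %in% c("LP1", "LP2")
  if (any(is_press & is.na(block_at)))
    stop("press events outside any block", call. = FALSE)
  closes <- ev$code %in% c("MAG_IN", "TIMEOUT_START")
  seg <- cumsum(c(0L, utils::head(as.integer(closes), -1L)))
  rows <- list()
  trial_no <- 0L
  for (s in split(seq_len(n), seg)) {
    e <- ev[s, , drop = FALSE]
    press <- e[e$code %in% c("LP1", "LP2"), , drop = FALSE]
    beams <- e$time[e$code == "BEAM_OUT"]
    mag <- e$time[e$code == "MAG_IN"]
    mag <- if (length(mag)) mag[1] else NA_real_
    if (!nrow(press)) {
      if (length(beams) && !is.na(mag)) {
        trial_no <- trial_no + 1L
        rows[[length(rows) + 1L]] <- trialRow(
          trial = trial_no, block = block_at[s[1]][1],
          classification = NA_character_, s1 = numeric(0), s2 = numeric(0),
          n_presses = 0L, beam = beams[length(beams)], mag = mag,
          reward = FALSE, t_open = beams[1], t_close = mag,
          return_to_start = TRUE)
      }
      next
    }
    block <- block_at[s[which(is_press[s])[1]]]
    first_lp2 <- suppressWarnings(min(press$time[press$code == "LP2"]))
    s1 <- press$time[press$code == "LP1" & press$time < first_lp2]
    s2 <- press$time[press$code == "LP2"]
    first_press <- press$time[1]
    first_code <- press$code[1]
    cls <- classifyCounts(block, first_code, length(s1), length(s2))
    beam_before <- beams[beams <= first_press]
    beam <- if (length(beam_before)) beam_before[length(beam_before)]
      else NA_real_
    t_open <- min(c(beams, press$time))
    t_close <- if (!is.na(mag)) mag else max(e$time)
    trial_no <- trial_no + 1L
    rows[[length(rows) + 1L]] <- trialRow(
      trial = trial_no, block = block, classification = cls, s1 = s1,
      s2 = s2, n_presses = nrow(press), beam = beam, mag = mag,
      reward = any(e$code == "REWARD"), t_open = t_open, t_close = t_close,
      return_to_start = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else emptyTrials()
  rownames(out) <- NULL
  if (label_light && session@protocol != "NONE")
    out <- labelOpto(out, session)
  out
}

fillForward <- function(x) {
  i <- seq_along(x)
  has <- !is.na(x)
  idx <- cummax(ifelse(has, i, 0L))
  out <- rep(NA_character_, length(x))
  out[idx > 0L] <- x[idx[idx > 0L]]
  out
}

classifyCounts <- function(block, first_code, n1, n2) {
  if (block == "SELF_PACED") {
    if (first_code == "LP2") return("INCORRECT_START")
    if (n1 < 4L && n2 == 0L) return("BREAK_S1")
    if (n1 < 4L) return("PREMATURE_SWITCH")
    if (n2 < 4L) return("BREAK_S2")
    return("CORRECT")
  }
  ## forced: lever availability forbids incorrect starts and switches
  if (n1 < 4L) return("BREAK_S1")
  if (n1 == 4L && n2 == 4L) return("CORRECT")
  "BREAK_S2"
}

trialRow <- function(trial, block, classification, s1, s2, n_presses, beam,
                     mag, reward, t_open, t_close, return_to_start) {
  n1 <- length(s1); n2 <- length(s2)
  first_press <- if (n1 + n2) min(c(s1, s2)) else NA_real_
  latency <- if (!is.na(beam) && !is.na(first_press)) first_press - beam
    else NA_real_
  corr <- isTRUE(classification == "CORRECT")
  duration <- if (corr) max(s2) - min(s1) else NA_real_
  transition <- if (n1 > 0L && n2 > 0L) min(s2) - max(s1) else NA_real_
  ipis <- c(if (n1 > 1L) diff(s1), if (n2 > 1L) diff(s2))
  df <- data.frame(
    trial = trial, block = block, classification = classification,
    n_s1 = n1, n_s2 = n2, n_presses = n_presses, latency = latency,
    duration = duration, transition = transition,
    ipi_mean = if (length(ipis)) mean(ipis) else NA_real_,
    long_s1 = corr && n1 > 4L, reward = reward,
    beam_out_time = beam, magazine_time = mag, t_open = t_open,
    t_close = t_close, light = "NONE",
    trigger_press_index = NA_integer_, return_to_start = return_to_start,
    stringsAsFactors = FALSE)
  df$s1_times <- I(list(s1)); df$s2_times <- I(list(s2))
  df$ipis <- I(list(ipis))
  df
}

emptyTrials <- function() {
  df <- trialRow(1L, "SELF_PACED", NA_character_, numeric(0), numeric(0),
                 0L, NA, NA, FALSE, NA, NA, TRUE)
  df[0L, , drop = FALSE]
}

#' Percent correct sequences
#'
#' 100 x correct / (correct + errors) among classified trials of a block
#' type; return-to-start records are excluded from the denominator.
#'
#' @param trials trial table from [parseTrials()].
#' @param block `"SELF_PACED"`, `"FORCED"` or `"ALL"`.
#' @return percentage in \[0, 100\].
#' @export
percentCorrect <- function(trials, block = c("SELF_PACED", "FORCED", "ALL")) {
  block <- match.arg(block)
  tr <- trials[!trials$return_to_start, , drop = FALSE]
  if (block != "ALL") tr <- tr[tr$block == block, , drop = FALSE]
  stopIfNot(nrow(tr) > 0L, "percent correct undefined: no classified %s trials",
            block)
  100 * mean(tr$classification == "CORRECT")
}

#' Per-trial timing metrics
#'
#' Extracts the timing metrics of each classified trial: latency to start
#' (beam crossing to first press), sequence duration (first S1 press to
#' last S2 press, correct trials only), transition time (last S1 press to
#' first S2 press; flagged undefined when either subsequence is empty),
#' mean inter-press interval, and press counts.
#'
#' @param trials trial table from [parseTrials()].
#' @return `data.frame` with one row per classified trial and a
#'   `transition_defined` flag.
#' @export
trialMetrics <- function(trials) {
  tr <- trials[!trials$return_to_start, , drop = FALSE]
  data.frame(trial = tr$trial, block = tr$block,
             classification = tr$classification, latency = tr$latency,
             duration = tr$duration, transition = tr$transition,
             transition_defined = !is.na(tr$transition),
             ipi_mean = tr$ipi_mean, n_presses = tr$n_presses,
             n_s1 = tr$n_s1, n_s2 = tr$n_s2, long_s1 = tr$long_s1,
             stringsAsFactors = FALSE)
}

#' Label trials with their light condition
#'
#' Marks each trial (and return record) `ON` if a `LIGHT_ON` event falls
#' within its span, `OFF` otherwise. Under the `TRANSITION` protocol the
#' trigger press index is recorded as the press count from the end of S1
#' (the last S1 press is index 0, so the press before the penultimate press
#' is -2). `LIGHT_ON` events not attributable to any trial raise a warning,
#' not an error.
#'
#' @param trials trial table from [parseTrials()].
#' @param session the [Session-class] the trials came from.
#' @return the trial table with `light` and `trigger_press_index` filled.
#' @export
labelOpto <- function(trials, session) {
  stopIfNot(session@protocol != "NONE",
            "labelOpto requires a session with an optogenetic protocol")
  ons <- session@events$time[session@events$code == "LIGHT_ON"]
  trials$light <- "OFF"
  attributed <- rep(FALSE, length(ons))
  for (i in seq_len(nrow(trials))) {
    hit <- which(ons >= trials$t_open[i] - 1e-9 &
                   ons <= trials$t_close[i] + 1e-9)
    if (length(hit)) {
      trials$light[i] <- "ON"
      attributed[hit] <- TRUE
      if (session@protocol == "TRANSITION") {
        s1 <- trials$s1_times[[i]]
        j <- which(abs(s1 - ons[hit[1]]) < 0.015)
        if (length(j))
          trials$trigger_press_index[i] <- as.integer(j[1] - length(s1))
      }
    }
  }
  if (any(!attributed))
    warning(sprintf("%d LIGHT_ON event(s) not attributable to any trial",
                    sum(!attributed)), call. = FALSE)
  trials
}
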