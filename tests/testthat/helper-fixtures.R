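## Shared builders for the test suite.

## Session from vectors, through the exported constructor path.
makeSession <- function(time, code, payload = rep("", length(time)),
                        protocol = "NONE", group = "EYFP_CONTROL",
                        animal_id = "test", day = 1L) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeLines(c(sprintf("# animal_id: %s", animal_id),
               sprintf("# group: %s", group),
               sprintf("# day: %d", day),
               sprintf("# protocol: %s", protocol),
               "time_s\tcode\tpayload",
               sprintf("%.2f\t%s\t%s", time, code, payload)), f)
  readEventLog(f)
}

## A single self-paced trial's events appended after a block marker.
selfPacedTrialEvents <- function(beam, lp1, lp2, reward = FALSE,
                                 mag = NULL) {
  time <- c(beam, lp1, lp2)
  code <- c("BEAM_OUT", rep("LP1", length(lp1)), rep("LP2", length(lp2)))
  if (reward) { time <- c(time, max(c(lp1, lp2))); code <- c(code, "REWARD") }
  if (is.null(mag)) mag <- max(time) + 1
  list(time = c(time, mag), code = c(code, "MAG_IN"))
}

fixturePath <- function() {
  system.file("extdata", "self_forced_12trials.tsv", package = "leverseq",
              mustWork = TRUE)
}

## Default session+unit pair used by several spike tests.
quietSession <- function(seed = 3L, n_rewards = 15) {
  simulateSession(performerModel(), n_rewards_target = n_rewards,
                  seed = seed, block_mode = "self_only")
}
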