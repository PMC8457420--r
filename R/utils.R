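## Internal helpers (not exported).

quantizeTime <- function(t) round(t / TIME_RESOLUTION) * TIME_RESOLUTION

## Canonical ordering: time, then fixed code priority for ties.
orderEvents <- function(ev) {
  ev[order(ev$time, match(ev$code, EVENT_CODES)), , drop = FALSE]
}

newEvents <- function(time = numeric(0), code = character(0),
                      payload = character(0)) {
  if (!length(payload)) payload <- rep("", length(time))
  data.frame(time = quantizeTime(time), code = code, payload = payload,
             stringsAsFactors = FALSE)
}

## Truncated-normal draw by resampling, with a hard floor (default 0.05 s)
## so intervals stay positive and distinguishable at the 10-ms grid.
rtnorm <- function(n, mean, sd, lower = 0.05) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower
  tries <- 0L
  while (any(bad) && tries < 50L) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower
    tries <- tries + 1L
  }
  x[x < lower] <- lower
  x
}

## Seed handling: functions taking `seed` set it locally and restore the
## caller's RNG state, so pipelines are reproducible without side effects.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE)
  }
  set.seed(seed)
  expr
}

## Moving average of width w samples along rows of a matrix (centered,
## "valid" region only). Returns list(values, keep) where keep indexes the
## retained column centers.
movingMeanRows <- function(m, w) {
  nb <- ncol(m)
  if (w <= 1L) return(list(values = m, keep = seq_len(nb)))
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  starts <- seq_len(nb - w + 1L)
  vals <- (cs[, starts + w, drop = FALSE] - cs[, starts, drop = FALSE]) / w
  keep <- starts + (w %/% 2L)
  list(values = vals, keep = keep)
}

stopIfNot <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}
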