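test_that("the rate kernel conserves spike mass", {
  tr1 <- rateFromSpikes(5.0, c(0, 10))
  expect_equal(sum(rateValues(tr1)) * 0.01, 1.0, tolerance = 1e-6)
  set.seed(2)
  spikes <- sort(runif(100, 2, 8))
  tr100 <- rateFromSpikes(spikes, c(0, 10))
  expect_equal(sum(rateValues(tr100)) * 0.01, 100, tolerance = 0.01)
  expect_equal(length(rateValues(rateFromSpikes(numeric(0), c(0, 1)))), 101L)
  expect_true(all(rateValues(rateFromSpikes(numeric(0), c(0, 1))) == 0))
})

test_that("regular 10-Hz spiking averages 10 Hz and matches the comb sum", {
  spikes <- seq(0.05, 9.95, by = 0.1)
  tr <- rateFromSpikes(spikes, c(-1, 11))
  tt <- rateTimes(tr)
  mid <- tt > 2 & tt < 8
  expect_equal(mean(rateValues(tr)[mid]), 10, tolerance = 0.01)
  ## pointwise: closed-form comb of (untruncated) Gaussian kernels
  comb <- vapply(tt[mid], function(t0) sum(dnorm(t0 - spikes, sd = 0.025)),
                 numeric(1))
  expect_equal(rateValues(tr)[mid], comb, tolerance = 1e-3)
})

test_that("alignment extracts a common grid and drops unsupported anchors", {
  tr <- rateFromSpikes(numeric(0), c(0, 20))
  tr@values <- rep(5, length(tr@values))
  al <- alignRates(tr, c(5, 10, 15), window = c(2, 3))
  expect_equal(dim(rateMatrix(al)), c(3L, 501L))
  expect_true(all(rateMatrix(al) == 5))
  al2 <- alignRates(tr, c(0.5, 10), window = c(2, 3))
  expect_equal(nrow(rateMatrix(al2)), 1L)
  expect_equal(al2@n_dropped, 1L)
  expect_error(alignRates(tr, 0.1, window = c(2, 3)), "no anchor")
  ## a rate bump lands at the right offset
  trb <- rateFromSpikes(rep(10.5, 25), c(0, 20))
  alb <- alignRates(trb, 10, window = c(2, 3))
  expect_equal(binOffsets(alb)[which.max(rateMatrix(alb)[1, ])], 0.5)
})

test_that("z-scoring matches its definition and inverts exactly", {
  tr <- rateFromSpikes(numeric(0), c(0, 30))
  set.seed(7)
  tr@values <- abs(rnorm(length(tr@values), 10, 2))
  al <- alignRates(tr, c(10, 20), window = c(4.5, 5))
  z <- zscoreRows(al, baseline = c(-4.5, -4))
  expect_identical(z@units, "z")
  back <- z@matrix * z@baseline_sd + z@baseline_mean
  expect_equal(back, al@matrix, tolerance = 1e-9)
  bl <- as.vector(al@matrix[, al@offsets >= -4.5 & al@offsets <= -4])
  expect_equal(z@baseline_mean, mean(bl))
  expect_equal(z@baseline_sd, sd(bl))
  ## rows identical to the baseline level give z about 0
  trc <- tr; trc@values <- rep(10, length(tr@values))
  alc <- alignRates(trc, c(10, 20), window = c(4.5, 5))
  zc <- zscoreRows(alc)
  expect_true(all(abs(zc@matrix) < 1e-9))
  expect_equal(zc@baseline_sd, 0.1)  # sd floor engaged
  ## silent unit flagged
  trs <- tr; trs@values <- rep(0, length(tr@values))
  zs <- zscoreRows(alignRates(trs, c(10, 20), window = c(4.5, 5)))
  expect_true(zs@flagged)
})

test_that("the template averages IPIs, middle gaps and transitions", {
  mkTrial <- function(offset, ipi, trans) {
    ev <- selfPacedTrialEvents(offset, offset + 1 + ipi * (0:3),
                               offset + 1 + ipi * 3 + trans + ipi * (0:3),
                               reward = TRUE)
    ev
  }
  a <- mkTrial(0, 0.4, 1.0); b <- mkTrial(30, 0.6, 1.0)
  s <- makeSession(c(0, a$time, b$time),
                   c("BLOCK_SELF_START", a$code, b$code))
  tr <- parseTrials(s)
  tmpl <- buildTemplate(tr)
  expect_equal(unname(tmpl["P2_S1"] - tmpl["P1_S1"]), 0.5)
  expect_equal(unname(tmpl["P1_S2"] - tmpl["PLast_S1"]), 1.0)
  ## all trials identical: template equals that trial's anchors (shifted to 0)
  s1 <- makeSession(c(0, a$time), c("BLOCK_SELF_START", a$code))
  tr1 <- parseTrials(s1)
  t1 <- buildTemplate(tr1)
  expect_equal(unname(t1), unname(trialAnchors(tr1[1, ]) -
                                    trialAnchors(tr1[1, ])[1]))
})

test_that("rescaling is the identity on the template and preserves anchors", {
  set.seed(11)
  tmpl <- c(0, 0.5, 1.0, 1.5, 2.5, 3.0, 3.5, 4.0)
  names(tmpl) <- c("P1_S1", "P2_S1", "PLast1_S1", "PLast_S1",
                   "P1_S2", "P2_S2", "PLast1_S2", "PLast_S2")
  tr <- rateFromSpikes(numeric(0), c(-3, 9))
  tr@values <- abs(rnorm(length(tr@values), 5, 1))
  idn <- rescaleTrial(tr, tmpl, tmpl)
  tt <- rateTimes(tr)
  expected <- approx(tt, tr@values, xout = idn$times)$y
  expect_lt(max(abs(idn$values - expected)), 1e-9)
  for (rep_i in 1:25) {
    gaps <- runif(7, 0.2, 1.0)
    anchors <- cumsum(c(runif(1, -1, 1), gaps))
    rs <- rescaleTrial(tr, anchors, tmpl)
    at_anchor <- rs$values[rs$anchor_index]
    expect_equal(at_anchor, approx(tt, tr@values, xout = anchors)$y,
                 tolerance = 1e-9)
    expect_identical(rs$anchor_index, idn$anchor_index)
  }
})

test_that("linear segments stay linear under stretching", {
  tr <- rateFromSpikes(numeric(0), c(-2, 12))
  tt <- rateTimes(tr)
  tr@values <- pmax(tt, 0)  # ramp with slope 1
  tmpl <- c(0, 2); trial <- c(0, 1)  # segment stretched x2
  rs <- rescaleTrial(tr, trial, tmpl, pad = c(0.5, 0.5))
  seg <- rs$times >= 0 & rs$times <= 2
  v <- rs$values[seg]; x <- rs$times[seg]
  fit <- lm(v ~ x)
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 1e-6)
  expect_equal(v[1], 0, tolerance = 1e-9)
  expect_equal(v[length(v)], 1, tolerance = 1e-9)
  ## duplicated trial anchor (4-press case) maps to a constant segment
  rs2 <- rescaleTrial(tr, c(0, 1, 1, 2), c(0, 1, 1.5, 2.5),
                      pad = c(0.2, 0.2))
  const <- rs2$values[rs2$times >= 1 & rs2$times <= 1.5]
  expect_true(all(abs(const - 1) < 1e-9))
  expect_error(rescaleTrial(tr, c(0, 2, 1, 3), c(0, 1, 2, 3)),
               "non-decreasing")
})

test_that("epoch z patterns map onto the modulation taxonomy", {
  lab <- function(z) categorizeUnit(stats::setNames(
    z, c("init", "s1", "transition", "s2")))$label
  expect_identical(lab(c(2.5, 2.5, 0, 0)), "Init & S1 execution")
  expect_identical(lab(c(0, 0, 0, 0)), "None")
  expect_identical(lab(c(0, 2.1, 0, 2.1)), "S1 & S2 execution")
  expect_identical(lab(c(2.2, 2.2, 0, 2.2)), "Init S1 & S2")
  expect_identical(lab(c(0, 0, 2.4, 0)), "Transition (init S2)")
  expect_identical(lab(c(0, 0, 0, 3)), "S2 execution")
  expect_identical(lab(c(0, -2.5, 0, 0)), "Negative")
  ## scale invariance above threshold: only the crossing pattern matters
  expect_identical(lab(c(8, 9, 0, 0)), lab(c(2.1, 2.2, 0, 0)))
})

test_that("epoch means are taken over the template spans", {
  tmpl <- c(P1_S1 = 0, P2_S1 = 0.5, PLast1_S1 = 1, PLast_S1 = 1.5,
            P1_S2 = 2.5, P2_S2 = 3, PLast1_S2 = 3.5, PLast_S2 = 4)
  times <- seq(-1.5, 4.5, by = 0.01)
  vals <- ifelse(times < 0, 1, ifelse(times <= 1.5, 2,
                                      ifelse(times < 2.5, 3, 4)))
  z <- epochMeanZ(vals, times, tmpl)
  expect_equal(unname(z["init"]), 1, tolerance = 0.02)
  expect_equal(unname(z["s1"]), 2, tolerance = 0.02)
  expect_equal(unname(z["transition"]), 3, tolerance = 0.02)
  expect_equal(unname(z["s2"]), 4, tolerance = 0.02)
})
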