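## Independent oracle: AUROC as the exhaustive pairwise win fraction
## (ties count one half).
aurocBruteForce <- function(test, baseline) {
  wins <- 0
  for (a in test) for (b in baseline)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(test) * length(baseline))
}

test_that("aurocValue equals the exhaustive pairwise win fraction", {
  expect_equal(aurocValue(c(3, 4), c(1, 2)), 1.0)
  expect_equal(aurocValue(c(1, 2), c(3, 4)), 0.0)
  ## exhaustive count over the 4 pairs: one win (3 > 2), three losses
  expect_equal(aurocValue(c(1, 3), c(2, 4)), 0.25)
  expect_equal(aurocValue(c(2, 2), c(2, 2)), 0.5)
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2), 1)  # force some ties
    expect_equal(aurocValue(x, y), aurocBruteForce(x, y))
  }
})

test_that("a boxcar rate increase is detected at the right bins", {
  s <- quietSession(seed = 3, n_rewards = 15)
  spec <- modulationSpec(baseline_rate = 10, kernels = list(
    list(anchor = "first_press", shape = "boxcar", amplitude = 20,
         onset = 0, offset = 0.5)))
  u <- simulateUnit(s, spec, seed = 5)
  tr <- parseTrials(s)
  firsts <- vapply(tr$s1_times[tr$classification %in% "CORRECT"], min,
                   numeric(1))
  rt <- rateFromSpikes(u, c(0, max(events(s)$time) + 1))
  al <- alignRates(rt, firsts, window = c(4.5, 2))
  prof <- modulationProfile(al, seed = 9)
  inside <- prof@bin_centers >= 0.1 & prof@bin_centers <= 0.4
  far <- prof@bin_centers <= -2
  expect_true(all(prof@significant[inside]))
  expect_true(all(prof@auroc[inside] > 0.5))
  expect_lt(mean(prof@significant[far]), 0.2)
})

test_that("few-trial units are excluded with a reason", {
  tr <- rateFromSpikes(numeric(0), c(0, 40))
  tr@values <- rep(3, length(tr@values))
  al <- alignRates(tr, c(10, 20, 30), window = c(4.5, 1))
  expect_error(modulationProfile(al), "excluded")
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration at tiny n", {
  set.seed(8)
  tr <- rateFromSpikes(sort(runif(150, 0, 60)), c(0, 60))
  al <- alignRates(tr, c(10, 25, 40, 52), window = c(4.5, 0.5))
  pe <- modulationProfile(al, min_trials = 4, exact = TRUE)
  pm <- modulationProfile(al, min_trials = 4, n_perm = 4000, seed = 1)
  expect_lt(max(abs(pe@p_perm - pm@p_perm)), 2 / sqrt(4000) + 1 / 4001)
  expect_equal(pe@auroc, pm@auroc)
})

test_that("recruitment fractions are per-bin percentages of significant units", {
  mk <- function(sig) new("ModulationProfile", unit_id = "u",
                          anchor = "P1_S1", bin_centers = c(0, 0.1, 0.2),
                          auroc = rep(0.7, 3), p_perm = ifelse(sig, 0.01, 0.5),
                          significant = sig, n_perm = 1000L)
  profs <- list(mk(c(TRUE, TRUE, FALSE)), mk(c(TRUE, FALSE, FALSE)),
                mk(c(TRUE, FALSE, FALSE)))
  expect_equal(unname(recruitmentFraction(profs)), c(100, 100 / 3, 0))
  expect_error(recruitmentFraction(list()), "no profiles")
})

test_that("covariates bin by the stated grouping rules", {
  tr <- parseTrials(readEventLog(fixturePath()))
  cls_tr <- tr[!tr$return_to_start, ]
  bp <- binCovariate(tr, "n_presses")
  ## odd counts round up to the next even class (9 presses -> class 10)
  expect_equal(bp$value[match(c(8, 3, 9), cls_tr$n_presses[bp$keep])][1:3],
               c(8, 4, 10))
  ## presses {4,5,6} -> classes {4,6,6}; extremes clamp to 2 and 16
  tr3 <- data.frame(n_presses = c(4, 5, 6, 1, 20), return_to_start = FALSE)
  expect_equal(binCovariate(tr3, "n_presses")$value, c(4, 6, 6, 2, 16))
  bl <- binCovariate(tr, "latency")
  expect_equal(bl$n_dropped, 0L)  # latency defined on every classified trial
  ## 0.0 s sits below the 0.5-s start and joins the first class (midpoint 1.0)
  lat_kept <- cls_tr$latency[bl$keep]
  expect_equal(bl$class[lat_kept == 0.0][1], 1L)
  expect_equal(bl$value[lat_kept == 0.0][1], 1.0)
  expect_true(all(bl$class[lat_kept < 1.5] == 1L))
  expect_true(all(bl$class[lat_kept >= 1.5] == 2L))
  ## duration classes: equal counts, descending
  tr14 <- data.frame(duration = seq(14, 1), return_to_start = FALSE)
  tr14$s1_times <- I(as.list(rep(NA, 14))); tr14$s2_times <- tr14$s1_times
  tr14$n_presses <- 8L; tr14$transition <- 1; tr14$latency <- 1
  bd <- binCovariate(tr14, "sequence_duration")
  expect_equal(as.integer(table(bd$class)), rep(2L, 7))
  expect_equal(bd$class[1], 1L)   # longest duration in class 1
  expect_equal(bd$class[14], 7L)  # shortest in the last class
  ## dropped trials are counted
  tr$duration[1] <- NA
  expect_gt(binCovariate(tr, "sequence_duration")$n_dropped, 0L)
})

test_that("noiseless regressions recover the slope and are accepted", {
  dur <- rep(c(2, 3, 4, 5, 6), each = 4)
  rate <- 2 + 3 * dur
  res <- permutationRegression(rate, dur, seed = 2)
  expect_equal(res$beta, 3, tolerance = 1e-9)
  expect_equal(res$r, 1, tolerance = 1e-9)
  expect_true(res$accepted)
  expect_lt(res$p_perm, 0.05)
  ## constant rates: slope zero, never accepted
  res0 <- permutationRegression(rep(5, 20), dur, seed = 2)
  expect_equal(res0$beta, 0)
  expect_false(res0$accepted)
})

test_that("regression Monte-Carlo p matches full enumeration at n = 6", {
  set.seed(5)
  for (i in 1:5) {
    rate <- rnorm(6); cls <- c(1, 1, 2, 2, 3, 3)
    pe <- permutationRegression(rate, cls, exact = TRUE)$p_perm
    pm <- permutationRegression(rate, cls, n_perm = 4000, seed = i)$p_perm
    expect_lt(abs(pe - pm), 2 / sqrt(4000) + 1 / 4001)
  }
})

test_that("null regressions respect the joint acceptance bound", {
  set.seed(31)
  acc <- vapply(1:150, function(i) {
    cls <- rep(1:6, length.out = 24)
    permutationRegression(rnorm(24, 10, 2), cls, n_perm = 300,
                          seed = i)$accepted
  }, logical(1))
  expect_lte(mean(acc), 0.05)  # bounded by p < 0.05 and r > 0.6 jointly
})

test_that("window regressions recover a programmed duration code", {
  m <- performerModel(p_incorrect_start = 0, p_break_s1 = 0,
                      p_premature_switch = 0, p_break_s2 = 0)
  s <- simulateSession(m, n_trials_target = 60, seed = 14,
                       block_mode = "self_only")
  u <- simulateUnit(s, modulationSpec(baseline_rate = 10, duration_gain = 5),
                    seed = 15)
  wr <- windowRegressions(parseTrials(s), u, seed = 16)
  expect_equal(nrow(wr), 5L)
  seq_row <- wr[wr$window == "sequence", ]
  expect_true(seq_row$accepted)
  expect_gt(seq_row$beta, 0)
})

test_that("the z-difference test matches the normal-CDF closed form", {
  res <- zDifferenceTest(1.0, 0.0, 12, 12)
  expect_equal(res$z_diff, 1 / sqrt(2 / 9), tolerance = 1e-9)
  expect_equal(res$z_diff, 2.121, tolerance = 1e-3)
  expect_equal(res$p, 2 * pnorm(-1 / sqrt(2 / 9)), tolerance = 1e-12)
  expect_lt(abs(res$p - 0.034), 0.001)
  ## symmetry and antisymmetry
  expect_equal(zDifferenceTest(1.3, 1.3, 10, 20)$z_diff, 0)
  expect_equal(zDifferenceTest(1.3, 1.3, 10, 20)$p, 1)
  swapped <- zDifferenceTest(0.0, 1.0, 12, 12)
  expect_equal(swapped$z_diff, -res$z_diff)
  expect_equal(swapped$p, res$p)
  expect_error(zDifferenceTest(1, 0, 3, 12), "exceed 3")
  ## the literal denominator variant is available but differs
  expect_false(isTRUE(all.equal(
    zDifferenceTest(1, 0, 12, 12, literal = TRUE)$z_diff, res$z_diff)))
})
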