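#' AUROC of test samples against baseline samples
#'
#' Area under the ROC curve comparing the two samples, computed as the
#' Mann-Whitney U statistic normalized by n1 x n2 with ties counted 0.5.
#' Identical samples give 0.5; values above 0.5 mean the test sample tends
#' to exceed baseline.
#'
#' @param test,baseline numeric samples (at least 2 values each).
#' @return value in \[0, 1\].
#' @export
aurocValue <- function(test, baseline) {
  n1 <- length(test); n2 <- length(baseline)
  stopIfNot(n1 >= 2L && n2 >= 2L, "need at least 2 samples per side")
  r <- rank(c(test, baseline))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

## AUROC for many permutations at once, from the ranks of the combined
## sample: each row of `idx` selects which of the n1+n2 values play "test".
aurocFromRanks <- function(r, idx, n1, n2) {
  (rowSums(matrix(r[idx], nrow = nrow(idx))) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Sliding-window AUROC modulation map with permutation significance
#'
#' For each 200-ms bin (slid in 10-ms steps) of an event-aligned rate
#' matrix, compares the per-trial bin rates against per-trial baseline
#' rates with [aurocValue()] and assesses significance by permuting the
#' test/baseline labels. The permutation p value is two-sided on the
#' distance from 0.5 with (b + 1)/(n_perm + 1) smoothing; `exact = TRUE`
#' enumerates all assignments instead (only feasible at very small trial
#' counts). The per-bin significance mask (p < 0.05, uncorrected) is the
#' unit's row of the binary matrix used by [recruitmentFraction()].
#'
#' @param aligned an [AlignedRates-class] in Hz whose window covers
#'   `baseline_window`.
#' @param baseline_window window (s relative to the anchor) whose per-trial
#'   mean rate is the baseline sample; default (-4.5, -4), the half second
#'   ending 4 s before the first press.
#' @param bin sliding-bin width (s), default 0.2.
#' @param step bin step (s), fixed by the 100-Hz grid at 0.01.
#' @param n_perm permutations per bin, default 1000.
#' @param seed integer seed.
#' @param min_trials minimum eligible trials, default 5.
#' @param exact enumerate all label assignments instead of sampling.
#' @return a [ModulationProfile-class].
#' @export
modulationProfile <- function(aligned, baseline_window = c(-4.5, -4),
                              bin = 0.2, step = 0.01, n_perm = 1000L,
                              seed = 1L, min_trials = 5L, exact = FALSE) {
  stopIfNot(aligned@units == "hz", "modulationProfile expects rates in Hz")
  m <- aligned@matrix
  nt <- nrow(m)
  stopIfNot(nt >= min_trials,
            "unit excluded: %d trials (< %d required)", nt, min_trials)
  ## baseline sample: non-overlapping bins of the same width as the test
  ## bins, inside the baseline window, pooled across trials (matching the
  ## test-bin variance so the null is exchangeable)
  w <- max(1L, round(bin / step))
  bidx <- which(aligned@offsets >= baseline_window[1] - 1e-9 &
                  aligned@offsets <= baseline_window[2] + 1e-9)
  stopIfNot(length(bidx) > 0L, "baseline window outside the alignment window")
  k <- max(1L, length(bidx) %/% w)
  base <- as.vector(vapply(seq_len(k), function(j) {
    cols <- bidx[((j - 1L) * w + 1L):min(j * w, length(bidx))]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nt)))
  mm <- movingMeanRows(m, w)
  B <- mm$values
  centers <- aligned@offsets[mm$keep]
  n1 <- nt; n2 <- length(base); ntot <- n1 + n2
  withSeed(seed, {
    if (exact) {
      sel <- utils::combn(ntot, n1)
      idx <- t(sel)
    } else {
      idx <- t(vapply(seq_len(n_perm), function(i) sample.int(ntot, n1),
                      integer(n1)))
    }
    nb <- ncol(B)
    auroc <- p <- numeric(nb)
    for (j in seq_len(nb)) {
      comb <- c(B[, j], base)
      r <- rank(comb)
      obs <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
      perm <- aurocFromRanks(r, idx, n1, n2)
      b <- sum(abs(perm - 0.5) >= abs(obs - 0.5) - 1e-12)
      auroc[j] <- obs
      p[j] <- if (exact) b / nrow(idx) else (b + 1) / (nrow(idx) + 1)
    }
    new("ModulationProfile", unit_id = aligned@unit_id,
        anchor = aligned@anchor, bin_centers = centers, auroc = auroc,
        p_perm = p, significant = p < 0.05,
        n_perm = as.integer(nrow(idx)))
  })
}

#' Fraction of units significantly modulated per bin
#'
#' 100 x (number of units significant) / (number of units) per bin, from a
#' list of [ModulationProfile-class] objects sharing a bin grid.
#'
#' @param profiles list of [ModulationProfile-class] objects.
#' @return numeric vector of percentages, one per bin, with the bin centers
#'   as names.
#' @export
recruitmentFraction <- function(profiles) {
  stopIfNot(length(profiles) > 0L, "no profiles supplied")
  grids <- lapply(profiles, function(p) p@bin_centers)
  stopIfNot(all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])),
                       logical(1))), "profiles must share a bin grid")
  sig <- vapply(profiles, function(p) p@significant,
                logical(length(grids[[1]])))
  out <- 100 * rowMeans(matrix(sig, ncol = length(profiles)))
  names(out) <- format(grids[[1]])
  out
}

#' Bin a behavioral covariate into the regression classes
#'
#' Groups trials by the covariate the way the regressions expect:
#' \itemize{
#'   \item `n_presses`: nearest even class 2, 4, ..., 16 (clamped);
#'   \item `latency`: 1-s classes starting at 0.5 s (values below 0.5 s
#'     join the first class); the class value is the class midpoint;
#'   \item durations (`sequence_duration`, `s1_duration`,
#'     `transition_time`, `s2_duration`): seven equal-count classes in
#'     descending order; the class value is the class mean.
#' }
#' Trials on which the covariate is undefined are dropped and counted.
#'
#' @param trials trial table from [parseTrials()].
#' @param covariate one of `n_presses`, `sequence_duration`, `s1_duration`,
#'   `transition_time`, `s2_duration`, `latency`.
#' @param n_classes classes for duration covariates, default 7.
#' @return list with `value` (numeric class value per kept trial), `class`
#'   (integer class label), `keep` (row indices kept), `n_dropped`.
#' @export
binCovariate <- function(trials, covariate = c("n_presses",
                                               "sequence_duration",
                                               "s1_duration",
                                               "transition_time",
                                               "s2_duration", "latency"),
                         n_classes = 7L) {
  covariate <- match.arg(covariate)
  tr <- trials[!trials$return_to_start, , drop = FALSE]
  raw <- switch(covariate,
    n_presses = as.numeric(tr$n_presses),
    sequence_duration = tr$duration,
    s1_duration = vapply(tr$s1_times, function(x)
      if (length(x) >= 2L) max(x) - min(x) else NA_real_, numeric(1)),
    transition_time = tr$transition,
    s2_duration = vapply(tr$s2_times, function(x)
      if (length(x) >= 2L) max(x) - min(x) else NA_real_, numeric(1)),
    latency = tr$latency)
  keep <- which(!is.na(raw))
  x <- raw[keep]
  if (covariate == "n_presses") {
    ## nearest even class; odd counts round up (5 -> 6)
    value <- pmin(16, pmax(2, 2 * floor(x / 2 + 0.5)))
    cls <- as.integer(value / 2)
  } else if (covariate == "latency") {
    cls <- pmax(1L, floor((x - 0.5) / 1) + 1L)
    value <- 0.5 + (cls - 1) + 0.5  # class midpoint
  } else {
    ## equal-count classes, descending: class 1 holds the longest values
    ord <- order(x, decreasing = TRUE)
    k <- min(n_classes, length(x))
    cls_sorted <- as.integer(cut(seq_along(ord), breaks = k, labels = FALSE))
    cls <- integer(length(x)); cls[ord] <- cls_sorted
    value <- stats::ave(x, cls, FUN = mean)
  }
  list(value = value, class = cls, keep = keep,
       n_dropped = length(raw) - length(keep))
}

## All permutations of 1..n (n <= 8), for exact regression p values.
permutationsOf <- function(n) {
  stopIfNot(n <= 8L, "exact enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- (1:n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Permutation-test regression of firing rate on a binned covariate
#'
#' Ordinary least squares of per-trial firing rate on the covariate class
#' value, with significance from shuffling the covariate across trials:
#' p = fraction of permutations whose |r| is at least the observed |r|
#' (with (b + 1)/(n_perm + 1) smoothing when sampling; exact when all n!
#' orderings are enumerated). The regression is `accepted` when p < 0.05,
#' the correlation criterion holds (r > `r_threshold`, or r^2 when
#' `use_r2 = TRUE`), and the slope is nonzero.
#'
#' @param rates per-trial firing rates (Hz).
#' @param covariate_values per-trial covariate class values, e.g. from
#'   [binCovariate()].
#' @param n_perm permutations, default 1000.
#' @param seed integer seed.
#' @param r_threshold correlation criterion, default 0.6.
#' @param use_r2 apply the criterion to r^2 instead of |r|.
#' @param exact enumerate all orderings (n <= 8) instead of sampling.
#' @return list with `beta`, `intercept`, `r`, `p_perm`, `n_perm`,
#'   `accepted`, `n`.
#' @export
permutationRegression <- function(rates, covariate_values, n_perm = 1000L,
                                  seed = 1L, r_threshold = 0.6,
                                  use_r2 = FALSE, exact = FALSE) {
  n <- length(rates)
  stopIfNot(n == length(covariate_values), "rates and covariate lengths differ")
  stopIfNot(n >= 6L || exact, "need at least 6 trials")
  stopIfNot(length(unique(covariate_values)) >= 2L,
            "need at least 2 distinct covariate classes")
  if (stats::sd(rates) == 0) {
    return(list(beta = 0, intercept = mean(rates), r = 0, p_perm = 1,
                n_perm = 0L, accepted = FALSE, n = n))
  }
  fit <- stats::lm.fit(cbind(1, covariate_values), rates)
  beta <- unname(fit$coefficients[2])
  r_obs <- abs(stats::cor(rates, covariate_values))
  withSeed(seed, {
    if (exact) {
      perms <- permutationsOf(n)
      rp <- abs(apply(perms, 1L, function(ix)
        stats::cor(rates, covariate_values[ix])))
      p <- mean(rp >= r_obs - 1e-12)
      np <- nrow(perms)
    } else {
      rp <- vapply(seq_len(n_perm), function(i)
        abs(stats::cor(rates, sample(covariate_values))), numeric(1))
      b <- sum(rp >= r_obs - 1e-12)
      p <- (b + 1) / (n_perm + 1)
      np <- n_perm
    }
    crit <- if (use_r2) r_obs^2 > r_threshold else r_obs > r_threshold
    list(beta = beta, intercept = unname(fit$coefficients[1]), r = r_obs,
         p_perm = p, n_perm = as.integer(np),
         accepted = p < 0.05 && crit && beta != 0, n = n)
  })
}

#' Window regressions of firing rate on sequence timing
#'
#' Runs [permutationRegression()] for the five canonical windows: mean
#' firing rate 1 s before the sequence start against sequence duration;
#' rate during the whole sequence against its duration; rate during S1
#' against S1 duration; rate during the transition against transition time;
#' and rate during S2 against S2 duration. Rates are spike counts divided
#' by window length, on correct trials with at least four presses per
#' subsequence.
#'
#' @param trials trial table from [parseTrials()].
#' @param spikes a [SpikeTrain-class] (or numeric spike times).
#' @param n_perm,seed,r_threshold,use_r2 passed to
#'   [permutationRegression()].
#' @return `data.frame` with one row per window: `window`, `covariate`,
#'   `beta`, `r`, `p_perm`, `accepted`, `n`.
#' @export
windowRegressions <- function(trials, spikes, n_perm = 1000L, seed = 1L,
                              r_threshold = 0.6, use_r2 = FALSE) {
  st <- if (is(spikes, "SpikeTrain")) spikes@spike_times else sort(spikes)
  tr <- trials[!trials$return_to_start &
                 trials$classification %in% "CORRECT" &
                 trials$n_s1 >= 4L & trials$n_s2 >= 4L, , drop = FALSE]
  stopIfNot(nrow(tr) >= 6L, "need at least 6 eligible correct trials")
  frIn <- function(a, b) {
    w <- pmax(b - a, 1e-6)
    vapply(seq_along(a), function(i)
      sum(st >= a[i] & st < b[i]) / w[i], numeric(1))
  }
  first <- vapply(tr$s1_times, min, numeric(1))
  last1 <- vapply(tr$s1_times, max, numeric(1))
  first2 <- vapply(tr$s2_times, min, numeric(1))
  last2 <- vapply(tr$s2_times, max, numeric(1))
  specs <- list(
    list(window = "pre_1s", rate = frIn(first - 1, first),
         covariate = "sequence_duration"),
    list(window = "sequence", rate = frIn(first, last2),
         covariate = "sequence_duration"),
    list(window = "s1", rate = frIn(first, last1),
         covariate = "s1_duration"),
    list(window = "transition", rate = frIn(last1, first2),
         covariate = "transition_time"),
    list(window = "s2", rate = frIn(first2, last2),
         covariate = "s2_duration"))
  out <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    bc <- binCovariate(tr, sp$covariate)
    res <- permutationRegression(sp$rate[bc$keep], bc$value,
                                 n_perm = n_perm, seed = seed + i,
                                 r_threshold = r_threshold, use_r2 = use_r2)
    data.frame(window = sp$window, covariate = sp$covariate,
               beta = res$beta, r = res$r, p_perm = res$p_perm,
               accepted = res$accepted, n = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' z-difference test between two unit populations
#'
#' Compares the mean normalized (z-scored) activity of two populations of
#' units: z_diff = (Z1 - Z2) / sqrt(1/(N1 - 3) + 1/(N2 - 3)), referred to
#' the standard normal for a two-sided p value. Antisymmetric under
#' swapping the populations. `literal = TRUE` uses 1/(N2 + 3) in the second
#' term instead (a variant kept for comparison; the default is the
#' Fisher-comparison form).
#'
#' @param Z1,Z2 mean normalized activity of each population.
#' @param N1,N2 unit counts (both must exceed 3).
#' @param literal use the `N2 + 3` denominator variant.
#' @return list with `Z1`, `Z2`, `N1`, `N2`, `z_diff`, `p`.
#' @export
zDifferenceTest <- function(Z1, Z2, N1, N2, literal = FALSE) {
  stopIfNot(N1 > 3 && N2 > 3, "unit counts must exceed 3")
  denom <- if (literal) sqrt(1 / (N1 - 3) + 1 / (N2 + 3))
    else sqrt(1 / (N1 - 3) + 1 / (N2 - 3))
  z <- (Z1 - Z2) / denom
  list(Z1 = Z1, Z2 = Z2, N1 = N1, N2 = N2, z_diff = z,
       p = 2 * stats::pnorm(-abs(z)))
}
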