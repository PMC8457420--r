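#' Paired two-sided permutation t test
#'
#' Statistic: mean of the paired differences. The null is generated by
#' independent sign flips of the differences; all 2^n flips are enumerated
#' when 2^n <= 4096 (exact p, no smoothing), otherwise `n_perm` random
#' flips with (b + 1)/(n_perm + 1) smoothing. All-zero differences give
#' p = 1.
#'
#' @param x,y paired samples of equal length (>= 3).
#' @param n_perm Monte-Carlo permutations, default 5000.
#' @param seed integer seed.
#' @param exact `"auto"` (default), `"always"` or `"never"`.
#' @return list with `statistic` (mean difference), `p`, `n_perm`, `exact`.
#' @export
pairedPermutationTest <- function(x, y, n_perm = 5000L, seed = 1L,
                                  exact = c("auto", "always", "never")) {
  exact <- match.arg(exact)
  stopIfNot(length(x) == length(y), "x and y must be paired (equal length)")
  n <- length(x)
  stopIfNot(n >= 3L, "need at least 3 pairs")
  d <- x - y
  if (all(d == 0))
    return(list(statistic = 0, p = 1, n_perm = 0L, exact = TRUE))
  obs <- mean(d)
  use_exact <- exact == "always" || (exact == "auto" && 2^n <= 4096)
  if (use_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stat <- as.vector(signs %*% d) / n
    p <- mean(abs(stat) >= abs(obs) - 1e-12)
    return(list(statistic = obs, p = p, n_perm = as.integer(nrow(signs)),
                exact = TRUE))
  }
  withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    stat <- as.vector(signs %*% d) / n
    b <- sum(abs(stat) >= abs(obs) - 1e-12)
    list(statistic = obs, p = (b + 1) / (n_perm + 1),
         n_perm = as.integer(n_perm), exact = FALSE)
  })
}

#' Unpaired two-sided permutation t test
#'
#' Statistic: difference of group means. The null is generated by shuffling
#' the group labels; all assignments are enumerated when choose(n, nx) <=
#' 4096 (exact p), otherwise `n_perm` random shuffles with smoothing.
#'
#' @param x,y samples (each >= 3 values).
#' @param n_perm Monte-Carlo permutations, default 5000.
#' @param seed integer seed.
#' @param exact `"auto"` (default), `"always"` or `"never"`.
#' @return list with `statistic` (mean(x) - mean(y)), `p`, `n_perm`,
#'   `exact`.
#' @export
unpairedPermutationTest <- function(x, y, n_perm = 5000L, seed = 1L,
                                    exact = c("auto", "always", "never")) {
  exact <- match.arg(exact)
  nx <- length(x); ny <- length(y)
  stopIfNot(nx >= 3L && ny >= 3L, "need at least 3 values per group")
  comb <- c(x, y)
  if (stats::sd(comb) == 0)
    return(list(statistic = 0, p = 1, n_perm = 0L, exact = TRUE))
  obs <- mean(x) - mean(y)
  tot <- sum(comb); n <- nx + ny
  ## mean(x*) - mean(y*) is affine in sum(x*): compute from group-x sums
  statFromSum <- function(sx) sx / nx - (tot - sx) / ny
  use_exact <- exact == "always" ||
    (exact == "auto" && choose(n, nx) <= 4096)
  if (use_exact) {
    sel <- utils::combn(n, nx)
    sx <- colSums(matrix(comb[sel], nrow = nx))
    stat <- statFromSum(sx)
    p <- mean(abs(stat) >= abs(obs) - 1e-12)
    return(list(statistic = obs, p = p, n_perm = as.integer(ncol(sel)),
                exact = TRUE))
  }
  withSeed(seed, {
    sx <- vapply(seq_len(n_perm), function(i)
      sum(comb[sample.int(n, nx)]), numeric(1))
    stat <- statFromSum(sx)
    b <- sum(abs(stat) >= abs(obs) - 1e-12)
    list(statistic = obs, p = (b + 1) / (n_perm + 1),
         n_perm = as.integer(n_perm), exact = FALSE)
  })
}

#' Bootstrap estimate of a mean difference
#'
#' Point estimate and percentile-bootstrap 95% CI of the paired or unpaired
#' mean difference, with a two-sided permutation p value from the matching
#' permutation test. Effect sizes are reported as
#' `point [ci_low; ci_high]`.
#'
#' @param x,y samples (paired: equal length).
#' @param design `"UNPAIRED"` or `"PAIRED"`.
#' @param n_boot bootstrap samples, default 5000.
#' @param n_perm permutations for the p value, default 5000.
#' @param seed integer seed.
#' @param conf confidence level, default 0.95.
#' @return list of class `EffectEstimate`: `design`, `point`, `ci_low`,
#'   `ci_high`, `n_boot`, `p_perm`, `n_perm`, `q` (NA until a family FDR is
#'   applied), `significant` (NA).
#' @export
bootstrapMeanDifference <- function(x, y, design = c("UNPAIRED", "PAIRED"),
                                    n_boot = 5000L, n_perm = 5000L,
                                    seed = 1L, conf = 0.95) {
  design <- match.arg(design)
  stopIfNot(length(x) >= 3L && length(y) >= 3L, "need at least 3 values per group")
  alpha <- (1 - conf) / 2
  withSeed(seed, {
    if (design == "PAIRED") {
      stopIfNot(length(x) == length(y), "paired design needs equal lengths")
      d <- x - y
      point <- mean(d)
      idx <- matrix(sample.int(length(d), n_boot * length(d), replace = TRUE),
                    n_boot)
      boots <- rowMeans(matrix(d[idx], n_boot))
      test <- pairedPermutationTest(x, y, n_perm = n_perm, seed = seed + 1L)
    } else {
      point <- mean(x) - mean(y)
      ix <- matrix(sample.int(length(x), n_boot * length(x), replace = TRUE),
                   n_boot)
      iy <- matrix(sample.int(length(y), n_boot * length(y), replace = TRUE),
                   n_boot)
      boots <- rowMeans(matrix(x[ix], n_boot)) -
        rowMeans(matrix(y[iy], n_boot))
      test <- unpairedPermutationTest(x, y, n_perm = n_perm, seed = seed + 1L)
    }
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
    structure(list(design = design, point = point, ci_low = ci[1],
                   ci_high = ci[2], n_boot = as.integer(n_boot),
                   p_perm = test$p, n_perm = test$n_perm, q = NA_real_,
                   significant = NA), class = "EffectEstimate")
  })
}

#' @export
print.EffectEstimate <- function(x, ...) {
  cat(sprintf("%s mean difference %.4g [%.4g; %.4g], p = %.4g%s\n",
              tolower(x$design), x$point, x$ci_low, x$ci_high, x$p_perm,
              if (!is.na(x$q)) sprintf(", q = %.4g", x$q) else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q values (via [stats::p.adjust()]) with the significance
#' threshold used throughout the optogenetic analyses: q < 0.10,
#' two-sided.
#'
#' @param p_values numeric p values in \[0, 1\].
#' @param q_threshold significance threshold on q, default 0.10.
#' @return list with `q` and logical `significant`.
#' @export
bhFdr <- function(p_values, q_threshold = 0.10) {
  stopIfNot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
            "p values must lie in [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, significant = q < q_threshold)
}

#' Per-animal on/off metric summaries
#'
#' For each animal, the metric mean is computed separately over light-on
#' and light-off trials, and the change score delta = mean(on) - mean(off).
#' Continuous metrics (`latency`, `duration`, `transition`, `ipi_mean`,
#' `n_presses`) average the per-trial values; proportion metrics
#' (`pct_incorrect_start`, `pct_break_s1`, `pct_premature_switch`,
#' `pct_break_s2`, `pct_correct`) are category count / total classified
#' trials of that light condition x 100, and `pct_return` is return records
#' / total records (trials + returns) of that condition x 100. Animals with
#' zero on or zero off trials are excluded with a warning.
#'
#' @param trials trial table with columns `animal_id`, `group`, `protocol`
#'   and `light` (e.g. rbind of labeled [parseTrials()] outputs with the
#'   session metadata columns added, as returned by [cohortTrials()]).
#' @param metric metric name (see Details).
#' @return `data.frame` with one row per animal: `animal_id`, `group`,
#'   `protocol`, `metric`, `mean_off`, `mean_on`, `delta`.
#' @export
animalDeltas <- function(trials, metric) {
  stopIfNot(all(c("animal_id", "group", "protocol", "light") %in%
                  names(trials)), "trials need animal_id, group, protocol, light")
  prop_metrics <- c(pct_incorrect_start = "INCORRECT_START",
                    pct_break_s1 = "BREAK_S1",
                    pct_premature_switch = "PREMATURE_SWITCH",
                    pct_break_s2 = "BREAK_S2", pct_correct = "CORRECT")
  rows <- lapply(split(trials, trials$animal_id), function(tr) {
    valueFor <- function(cond) {
      sub <- tr[tr$light == cond, , drop = FALSE]
      cls <- sub[!sub$return_to_start, , drop = FALSE]
      if (metric == "pct_return") {
        if (!nrow(sub)) return(NA_real_)
        return(100 * mean(sub$return_to_start))
      }
      if (metric %in% names(prop_metrics)) {
        if (!nrow(cls)) return(NA_real_)
        return(100 * mean(cls$classification == prop_metrics[[metric]]))
      }
      stopIfNot(metric %in% names(cls), "unknown metric '%s'", metric)
      v <- cls[[metric]]
      if (!sum(!is.na(v))) return(NA_real_)
      mean(v, na.rm = TRUE)
    }
    m_on <- valueFor("ON"); m_off <- valueFor("OFF")
    data.frame(animal_id = tr$animal_id[1], group = tr$group[1],
               protocol = tr$protocol[1], metric = metric,
               mean_off = m_off, mean_on = m_on, delta = m_on - m_off,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- is.na(out$delta)
  if (any(bad)) {
    warning(sprintf("excluding %d animal(s) lacking on or off trials",
                    sum(bad)), call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Change scores of an experimental group against the control group
#'
#' Unpaired bootstrap CI and permutation test on the per-animal
#' delta(on - off) values of the experimental versus control group.
#'
#' @param deltas_exp,deltas_ctrl [animalDeltas()] tables (or numeric delta
#'   vectors) for the experimental and control group.
#' @param n_boot,n_perm,seed passed to [bootstrapMeanDifference()].
#' @return an `EffectEstimate`.
#' @export
changeScoreVsControl <- function(deltas_exp, deltas_ctrl, n_boot = 5000L,
                                 n_perm = 5000L, seed = 1L) {
  de <- if (is.data.frame(deltas_exp)) deltas_exp$delta else deltas_exp
  dc <- if (is.data.frame(deltas_ctrl)) deltas_ctrl$delta else deltas_ctrl
  stopIfNot(length(dc) >= 3L, "control group needs at least 3 animals")
  stopIfNot(length(de) >= 3L, "experimental group needs at least 3 animals")
  bootstrapMeanDifference(de, dc, design = "UNPAIRED", n_boot = n_boot,
                          n_perm = n_perm, seed = seed)
}

#' Pool labeled trials across a simulated or recorded cohort
#'
#' Convenience: parses each session, labels light conditions, and binds the
#' trial tables with the session metadata attached, producing the input
#' expected by [animalDeltas()] and [optoEffects()].
#'
#' @param sessions list of [Session-class] objects.
#' @return combined trial `data.frame`.
#' @export
cohortTrials <- function(sessions) {
  out <- lapply(sessions, function(s) {
    tr <- parseTrials(s)
    tr$animal_id <- s@animal_id
    tr$group <- s@group
    tr$protocol <- s@protocol
    tr
  })
  do.call(rbind, out)
}

#' Estimation statistics table for an optogenetic cohort
#'
#' For every experimental group x protocol x metric: the paired on/off
#' effect across animals (paired permutation t test + bootstrap CI of the
#' mean delta) and the change score against the control group (unpaired).
#' p values are BH-FDR adjusted within each protocol x group x comparison
#' family; significance is q < `q_threshold`.
#'
#' @param trials combined trial table (see [cohortTrials()]).
#' @param metrics metric names for [animalDeltas()].
#' @param control_group group name of the fluorophore-only control.
#' @param n_boot,n_perm,seed resampling controls.
#' @param q_threshold FDR significance threshold, default 0.10.
#' @return `data.frame`, one row per (group, protocol, metric, comparison)
#'   with `point`, `ci_low`, `ci_high`, `p`, `q`, `significant`, `n`.
#' @export
optoEffects <- function(trials, metrics = c("latency", "transition",
                                            "n_presses",
                                            "pct_premature_switch",
                                            "pct_return"),
                        control_group = "EYFP_CONTROL", n_boot = 5000L,
                        n_perm = 5000L, seed = 1L, q_threshold = 0.10) {
  groups <- setdiff(unique(trials$group), control_group)
  stopIfNot(control_group %in% trials$group,
            "control group '%s' absent from trials", control_group)
  rows <- list()
  si <- 0L
  for (g in groups) {
    for (prot in unique(trials$protocol[trials$group == g])) {
      sub <- trials[trials$protocol == prot &
                      trials$group %in% c(g, control_group), , drop = FALSE]
      for (cmp in c("paired_on_off", "change_vs_control")) {
        fam <- list()
        for (m in metrics) {
          si <- si + 1L
          dx <- animalDeltas(sub[sub$group == g, , drop = FALSE], m)
          if (cmp == "paired_on_off") {
            if (nrow(dx) < 3L) next
            est <- bootstrapMeanDifference(dx$mean_on, dx$mean_off,
                                           design = "PAIRED",
                                           n_boot = n_boot, n_perm = n_perm,
                                           seed = seed + si)
          } else {
            dc <- animalDeltas(sub[sub$group == control_group, ,
                                   drop = FALSE], m)
            if (nrow(dx) < 3L || nrow(dc) < 3L) next
            est <- changeScoreVsControl(dx, dc, n_boot = n_boot,
                                        n_perm = n_perm, seed = seed + si)
          }
          fam[[m]] <- data.frame(group = g, protocol = prot, metric = m,
                                 comparison = cmp, point = est$point,
                                 ci_low = est$ci_low, ci_high = est$ci_high,
                                 p = est$p_perm, n = nrow(dx),
                                 stringsAsFactors = FALSE)
        }
        if (length(fam)) {
          famdf <- do.call(rbind, fam)
          adj <- bhFdr(famdf$p, q_threshold)
          famdf$q <- adj$q
          famdf$significant <- adj$significant
          rows[[length(rows) + 1L]] <- famdf
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Routine nonparametric tests
#'
#' Thin wrappers around the standard implementations so pipeline reports
#' can include the conventional tests: Mann-Whitney U (exact two-sided
#' where possible), Wilcoxon signed-rank (paired), chi-square on a count
#' table, and Friedman across repeated sessions.
#'
#' @param x first sample, or the count matrix (`chisq`), or the
#'   subjects x conditions matrix (`friedman`).
#' @param y second sample where applicable.
#' @param test which test to run.
#' @param ... passed to the underlying stats function.
#' @return the p value.
#' @export
routineTest <- function(x, y = NULL,
                        test = c("mann-whitney", "wilcoxon", "chisq",
                                 "friedman"), ...) {
  test <- match.arg(test)
  switch(test,
    `mann-whitney` = stats::wilcox.test(x, y, ...)$p.value,
    wilcoxon = {
      if (all(x - y == 0)) 1  # no nonzero differences: no evidence
      else stats::wilcox.test(x, y, paired = TRUE, ...)$p.value
    },
    chisq = stats::chisq.test(x, ...)$p.value,
    friedman = {
      m <- as.matrix(x)
      if (all(apply(m, 1L, function(r) length(unique(r)) == 1L))) 1
      else stats::friedman.test(m, ...)$p.value
    })
}
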