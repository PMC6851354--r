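#' Label a recording as active epilepsy or seizure-free
#'
#' All presurgical recordings count as active epilepsy. Postsurgical
#' recordings are seizure-free with ILAE outcome class 1 and active with
#' ILAE > 1; when no ILAE class is available, the recording is active iff
#' its seizure frequency is positive.
#'
#' @param summary one row of the clinical table (needs `stage`, and for
#'   post recordings `ilae` and/or `seizure_freq`)
#' @return `"active"` or `"seizure_free"`
#' @export
label_activity <- function(summary) {
  stage <- summary$stage
  if (!stage %in% c("pre", "post")) stop("invalid-argument: bad stage")
  if (stage == "pre") return("active")
  ilae <- summary$ilae
  if (!is.null(ilae) && length(ilae) == 1L && !is.na(ilae))
    return(if (ilae == 1) "seizure_free" else "active")
  sf <- summary$seizure_freq
  if (is.null(sf) || length(sf) != 1L || is.na(sf))
    stop("missing-label: post recording needs ilae or seizure_freq")
  if (sf > 0) "active" else "seizure_free"
}

#' Classify a recording as HFO-positive
#'
#' A patient "shows HFO" when the affected-hemisphere rate strictly
#' exceeds the rate threshold; a rate exactly at the threshold is
#' negative.
#'
#' @param rate HFO rate in events/min (>= 0)
#' @param threshold rate threshold in events/min
#' @return logical
#' @export
classify_positive <- function(rate, threshold) {
  stopifnot(all(rate >= 0))
  rate > threshold
}

#' Optimal rate threshold by ROC analysis
#'
#' Sweeps the observed rate values as candidate thresholds and picks the
#' one maximizing classification accuracy under strict-greater
#' classification. Accuracy ties are broken by the larger Youden index
#' (sensitivity + specificity - 1), then by the smaller threshold.
#'
#' @param rates affected-hemisphere rates
#' @param labels `"active"`/`"seizure_free"` (or logical, TRUE = active)
#' @return the selected threshold in events/min
#' @export
optimal_threshold_roc <- function(rates, labels) {
  active <- as_active(labels)
  if (length(unique(active)) < 2L)
    stop("degenerate-labels: need both classes")
  stopifnot(length(rates) == length(active))
  cand <- sort(unique(rates))
  stats <- vapply(cand, function(th) {
    pos <- classify_positive(rates, th)
    acc <- mean(pos == active)
    sens <- sum(pos & active) / sum(active)
    spec <- sum(!pos & !active) / sum(!active)
    c(acc = acc, j = sens + spec - 1)
  }, c(acc = 0, j = 0))
  best <- which(stats["acc", ] == max(stats["acc", ]))
  best <- best[stats["j", best] == max(stats["j", best])]
  cand[min(best)]
}

as_active <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% c("active", "seizure_free")))
    stop("invalid-argument: labels must be active/seizure_free")
  labels == "active"
}

#' Confusion matrix of the HFO classification
#'
#' TP = positive and active, FP = positive and seizure-free, FN =
#' negative and active, TN = negative and seizure-free.
#'
#' @param rates affected-hemisphere rates
#' @param labels activity labels (see [optimal_threshold_roc])
#' @param threshold rate threshold
#' @return list of class `confusion_matrix`: `tp`, `fp`, `fn`, `tn`
#' @export
confusion_matrix <- function(rates, labels, threshold) {
  active <- as_active(labels)
  if (length(rates) != length(active))
    stop("invalid-argument: rates and labels differ in length")
  pos <- classify_positive(rates, threshold)
  structure(list(tp = sum(pos & active), fp = sum(pos & !active),
                 fn = sum(!pos & active), tn = sum(!pos & !active)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Predictive values and accuracy
#'
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), accuracy = (TP+TN)/N, at full
#' precision (round to percent only when reporting).
#'
#' @param cm a [confusion_matrix]
#' @return list with `ppv`, `npv`, `accuracy` as proportions; a
#'   zero-denominator component is `NA` with a warning
#' @export
predictive_values <- function(cm) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("undefined-metric: ", what, " has zero denominator")
      return(NA_real_)
    }
    num / den
  }
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  list(ppv = ratio(cm$tp, cm$tp + cm$fp, "PPV"),
       npv = ratio(cm$tn, cm$tn + cm$fn, "NPV"),
       accuracy = ratio(cm$tp + cm$tn, n, "accuracy"))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Closed-form score interval; better small-sample coverage than the
#' Wald interval and never outside [0, 1].
#'
#' @param successes number of successes (0..n)
#' @param n number of trials (>= 1)
#' @param level confidence level
#' @return list of class `binomial_interval`: `lower`, `upper`, `level`,
#'   `estimate`
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  if (n < 1) stop("invalid-argument: n must be >= 1")
  if (successes < 0 || successes > n)
    stop("invalid-argument: successes must be in 0..n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  structure(list(lower = (centre - half) / denom,
                 upper = (centre + half) / denom,
                 level = level, estimate = p),
            class = "binomial_interval")
}

#' @export
print.binomial_interval <- function(x, ...) {
  cat(sprintf("<binomial_interval> %.3f [%0.3f, %0.3f] at %g%%\n",
              x$estimate, x$lower, x$upper, 100 * x$level))
  invisible(x)
}

#' Severity regression: HFO rate versus seizure frequency
#'
#' Ordinary least squares of `log10(affected_rate)` on
#' `log10(seizure_freq)` across recordings; seizure-free recordings
#' (frequency 0 or `NA`) enter at the `freedom_proxy` (0.05
#' seizures/month by convention). `log_scale = FALSE` fits the raw-scale
#' alternative for sensitivity analysis.
#'
#' @param summaries data frame with columns `affected_rate` and
#'   `seizure_freq`
#' @param freedom_proxy seizures/month standing in for seizure freedom
#' @param log_scale fit on log10-log10 axes (default) or raw axes
#' @return list of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `log_scale`
#' @export
severity_regression <- function(summaries, freedom_proxy = 0.05,
                                log_scale = TRUE) {
  stopifnot(freedom_proxy > 0)
  rate <- summaries$affected_rate
  sf <- summaries$seizure_freq
  sf[is.na(sf) | sf <= 0] <- freedom_proxy
  if (length(rate) < 3) stop("invalid-argument: need >= 3 recordings")
  if (log_scale && any(rate <= 0))
    stop("invalid-argument: nonpositive rate; log undefined")
  fit <- if (log_scale) stats::lm(log10(rate) ~ log10(sf))
  else stats::lm(rate ~ sf)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2L, 4L]),
                 n = length(rate), log_scale = log_scale),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> %s: slope %.3f, intercept %.3f, R^2 %.3f, p %.2g, n %d\n",
    if (x$log_scale) "log10-log10" else "raw", x$slope, x$intercept,
    x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Paired hemisphere comparison (Wilcoxon signed-rank)
#'
#' Two-sided signed-rank test of affected versus non-affected hemisphere
#' rates; normal approximation without continuity correction for n > 12,
#' exact distribution otherwise.
#'
#' @param affected_rates,nonaffected_rates paired rate vectors (n >= 5)
#' @return two-sided p value
#' @export
paired_hemisphere_test <- function(affected_rates, nonaffected_rates) {
  stopifnot(length(affected_rates) == length(nonaffected_rates),
            length(affected_rates) >= 5)
  d <- affected_rates - nonaffected_rates
  if (all(d == 0)) return(1)
  n <- sum(d != 0)
  suppressWarnings(stats::wilcox.test(
    affected_rates, nonaffected_rates, paired = TRUE,
    exact = n <= 12, correct = FALSE))$p.value
}

#' Group comparison of rates (Wilcoxon rank-sum)
#'
#' Two-sided rank-sum test of active versus seizure-free recordings;
#' exact for combined n <= 12 without ties, normal approximation without
#' continuity correction otherwise.
#'
#' @param active_rates,free_rates rate vectors
#' @return two-sided p value
#' @export
group_rate_test <- function(active_rates, free_rates) {
  stopifnot(length(active_rates) >= 1, length(free_rates) >= 1)
  if (length(active_rates) == 1L && length(free_rates) == 1L &&
      active_rates == free_rates) return(1)
  n <- length(active_rates) + length(free_rates)
  suppressWarnings(stats::wilcox.test(
    active_rates, free_rates, exact = n <= 12, correct = FALSE))$p.value
}

#' Concordance of pre/post direction of change (chi-squared)
#'
#' 1-df chi-squared, without continuity correction, on the 2x2 table of
#' direction of HFO-rate change versus direction of seizure-frequency
#' change (decrease vs non-decrease) across pre/post case pairs. For a
#' fully concordant table `[[a, 0], [0, b]]` the statistic equals
#' `a + b`, the number of cases.
#'
#' @param pre_post_pairs data frame with logical columns `hfo_decrease`
#'   and `sf_decrease`, one row per case, or a 2x2 count matrix
#' @return list with `chi2` and `p_value`
#' @export
concordance_chi2 <- function(pre_post_pairs) {
  if (is.matrix(pre_post_pairs)) {
    tab <- pre_post_pairs
  } else {
    tab <- table(factor(pre_post_pairs$hfo_decrease, c(TRUE, FALSE)),
                 factor(pre_post_pairs$sf_decrease, c(TRUE, FALSE)))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("undefined-statistic: zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p_value = res$p.value)
}

#' Compare two event sets (e.g. two amplifiers on the same signal)
#'
#' Events match when they are on the same channel and their intervals,
#' padded by `overlap_tol_s`, overlap. The shared fraction is relative to
#' the first set.
#'
#' @param events_a,events_b event data frames (accepted events only are
#'   compared)
#' @param overlap_tol_s symmetric tolerance padding in seconds
#' @return list with `n_a`, `n_b`, `n_shared`, `shared_fraction`
#' @export
compare_event_sets <- function(events_a, events_b, overlap_tol_s = 0.05) {
  a <- events_a[events_a$status == "accepted", , drop = FALSE]
  b <- events_b[events_b$status == "accepted", , drop = FALSE]
  shared <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    shared[i] <- any(b$channel == a$channel[i] &
                       iv_overlaps(a$start_s[i] - overlap_tol_s,
                                   a$end_s[i] + overlap_tol_s,
                                   b$start_s, b$end_s))
  }
  list(n_a = nrow(a), n_b = nrow(b), n_shared = sum(shared),
       shared_fraction = if (nrow(a)) sum(shared) / nrow(a) else NA_real_)
}
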