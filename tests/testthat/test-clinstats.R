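t1 <- load_clinical_table()

test_that("activity labelling follows stage, ILAE and seizure frequency", {
  expect_identical(label_activity(list(stage = "pre")), "active")
  expect_identical(label_activity(list(stage = "post", ilae = 1)),
                   "seizure_free")
  expect_identical(label_activity(list(stage = "post", ilae = 3)), "active")
  expect_identical(label_activity(list(stage = "post", ilae = NA,
                                       seizure_freq = 0.35)), "active")
  expect_identical(label_activity(list(stage = "post", ilae = NA,
                                       seizure_freq = 0)), "seizure_free")
  expect_error(label_activity(list(stage = "post", ilae = NA,
                                   seizure_freq = NA)), "missing-label")
  expect_identical(sum(t1$active), 13L)
})

test_that("classification at the rate threshold is strictly greater-than", {
  expect_true(classify_positive(0.26, 0.25))
  expect_false(classify_positive(0.25, 0.25))
  expect_false(classify_positive(0, 0.25))
  expect_identical(sum(classify_positive(t1$affected_rate, 0.25)), 14L)
})

test_that("ROC threshold selection maximizes accuracy with stable ties", {
  expect_equal(optimal_threshold_roc(t1$affected_rate, t1$active), 0.25)

  # perfectly separated toy set
  expect_equal(optimal_threshold_roc(c(0.1, 0.2, 1, 2),
                                     c(FALSE, FALSE, TRUE, TRUE)), 0.2)

  expect_error(optimal_threshold_roc(1:3, rep(TRUE, 3)),
               "degenerate-labels")

  # exhaustive sweep oracle on random small sets
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    rates <- round(runif(n, 0, 3), 2)
    lab <- runif(n) < 0.5
    if (length(unique(lab)) < 2) next
    got <- optimal_threshold_roc(rates, lab)
    cand <- sort(unique(rates))
    acc <- vapply(cand, function(th) mean((rates > th) == lab), 0)
    j <- vapply(cand, function(th)
      sum(rates > th & lab) / sum(lab) +
        sum(rates <= th & !lab) / sum(!lab) - 1, 0)
    best <- which(acc == max(acc))
    best <- best[j[best] == max(j[best])]
    expect_equal(got, cand[min(best)])
    expect_gte(mean((rates > got) == lab), max(acc) - 1e-12)
  }
})

test_that("confusion matrix and predictive values match the fixture", {
  cm <- confusion_matrix(t1$affected_rate, t1$active, 0.25)
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(12L, 2L, 1L, 4L))
  pv <- predictive_values(cm)
  expect_identical(round(100 * c(pv$ppv, pv$npv, pv$accuracy)),
                   c(86, 80, 84))

  pv2 <- predictive_values(confusion_matrix(c(2, 0.1), c(TRUE, FALSE), 1))
  expect_identical(c(pv2$ppv, pv2$npv, pv2$accuracy), c(1, 1, 1))

  # direct-formula oracle on random matrices + order invariance
  set.seed(3)
  for (rep in 1:10) {
    n <- 25L
    rates <- runif(n, 0, 2)
    lab <- runif(n) < 0.6
    th <- runif(1, 0, 2)
    cm3 <- confusion_matrix(rates, lab, th)
    expect_identical(cm3$tp + cm3$fp + cm3$fn + cm3$tn, n)
    pv3 <- suppressWarnings(predictive_values(cm3))  # a class may be empty
    expect_equal(pv3$accuracy, mean((rates > th) == lab))
    perm <- sample(n)
    cm4 <- confusion_matrix(rates[perm], lab[perm], th)
    expect_identical(unclass(cm3), unclass(cm4))
  }
  expect_warning(predictive_values(
    structure(list(tp = 0, fp = 0, fn = 1, tn = 1),
              class = "confusion_matrix")), "undefined-metric")
  expect_error(confusion_matrix(1:3, c(TRUE, FALSE), 1),
               "invalid-argument")
})

test_that("Wilson interval matches the score-test inversion", {
  ci <- wilson_interval(16, 19)
  expect_identical(round(100 * c(ci$lower, ci$upper)), c(62, 94))
  expect_equal(wilson_interval(0, 10)$lower, 0)
  expect_error(wilson_interval(3, 0), "invalid-argument")

  # root-finding oracle: endpoints solve (phat-p)^2 = z^2 p(1-p)/n
  z <- qnorm(0.975)
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    ci <- wilson_interval(k, n)
    g <- function(p) (k / n - p)^2 - z^2 * p * (1 - p) / n
    for (edge in c(ci$lower, ci$upper))
      if (edge > 0 && edge < 1) expect_lt(abs(g(edge)), 1e-8)
    expect_gte(k / n, ci$lower)
    expect_lte(k / n, ci$upper)
  }
})

test_that("Wilson interval keeps near-nominal coverage at n = 19", {
  set.seed(2024)
  p <- 0.84
  k <- rbinom(10000, 19, p)
  z <- qnorm(0.975)
  ph <- k / 19
  centre <- ph + z^2 / 38
  half <- z * sqrt(ph * (1 - ph) / 19 + z^2 / (4 * 19^2))
  denom <- 1 + z^2 / 19
  cover <- mean((centre - half) / denom <= p & p <= (centre + half) / denom)
  # exact coverage oracle: sum the binomial mass of the covering k values
  kk <- 0:19
  pe <- kk / 19
  ce <- pe + z^2 / 38
  he <- z * sqrt(pe * (1 - pe) / 19 + z^2 / (4 * 19^2))
  inside <- (ce - he) / denom <= p & p <= (ce + he) / denom
  exact <- sum(dbinom(kk, 19, p)[inside])
  expect_equal(cover, exact, tolerance = 0.01)
  expect_gte(cover, 0.93)
})

test_that("severity regression reproduces the fixture and its oracle", {
  fit <- severity_regression(t1)
  expect_equal(fit$r_squared, 0.80, tolerance = 0.10 / 0.80)
  expect_lt(fit$p_value, 0.001)
  expect_identical(fit$n, 19L)

  # closed-form oracle: R^2 equals squared sample correlation
  set.seed(21)
  for (rep in 1:5) {
    co <- make_cohort(cohort_spec(n_recordings = 40, seed = 300 + rep))
    df <- data.frame(affected_rate = co$affected_rate,
                     seizure_freq = co$seizure_freq_per_month)
    f <- severity_regression(df)
    expect_equal(f$r_squared,
                 cor(log10(df$affected_rate), log10(df$seizure_freq))^2)
  }
  expect_error(severity_regression(
    data.frame(affected_rate = c(0, 1, 2), seizure_freq = 1:3)),
    "invalid-argument")
})

test_that("hemisphere and group tests match the printed regime and oracles", {
  expect_equal(paired_hemisphere_test(1:6, 1:6), 1)
  p_hemi <- paired_hemisphere_test(t1$affected_rate, t1$nonaffected_rate)
  expect_gt(p_hemi, 0.0003 / 2)
  expect_lt(p_hemi, 0.0003 * 2)

  p_grp <- group_rate_test(t1$affected_rate[t1$active],
                           t1$affected_rate[!t1$active])
  expect_gt(p_grp, 0.003)
  expect_lt(p_grp, 0.012)

  # signed-rank enumeration oracle over all 2^8 sign assignments
  set.seed(14)
  x <- runif(8, 1, 2)
  y <- x - runif(8, -0.3, 0.6)
  got <- paired_hemisphere_test(x, y)
  d <- x - y
  rk <- rank(abs(d))
  t_obs <- sum(rk[d > 0])
  M <- sum(rk)
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  t_all <- as.matrix(signs) %*% rk
  p_enum <- mean(pmin(t_all, M - t_all) <= min(t_obs, M - t_obs))
  expect_equal(got, p_enum, tolerance = 1e-10)

  # rank-sum permutation oracle
  set.seed(15)
  a <- runif(5); b <- runif(4) + 0.2
  got2 <- group_rate_test(a, b)
  pool <- c(a, b)
  rks <- rank(pool)
  w_obs <- sum(rks[1:5]) - 5 * 6 / 2
  combs <- combn(9, 5)
  w_all <- apply(combs, 2, function(i) sum(rks[i])) - 15
  mid <- 5 * 4 / 2
  p_perm <- mean(abs(w_all - mid) >= abs(w_obs - mid) - 1e-9)
  expect_equal(got2, p_perm, tolerance = 1e-10)
})

test_that("concordance chi-squared equals the textbook formula", {
  fully <- matrix(c(7, 0, 0, 1), 2, byrow = TRUE)
  res <- concordance_chi2(fully)
  expect_equal(res$chi2, 8)
  expect_lt(res$p_value, 0.005)

  expect_error(concordance_chi2(matrix(c(8, 0, 0, 0), 2)),
               "undefined-statistic")

  set.seed(16)
  for (rep in 1:10) {
    tab <- matrix(sample(1:9, 4, replace = TRUE), 2)
    got <- concordance_chi2(tab)
    n <- sum(tab)
    want <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
      prod(rowSums(tab), colSums(tab))
    expect_equal(got$chi2, want)
  }

  # data-frame interface: 7 concordant decreases + 1 concordant increase
  pairs <- data.frame(hfo_decrease = c(rep(TRUE, 7), FALSE),
                      sf_decrease = c(rep(TRUE, 7), FALSE))
  expect_equal(concordance_chi2(pairs)$chi2, 8)
})

test_that("event-set comparison counts shared detections correctly", {
  ev <- data.frame(channel = c("A", "A", "B"), start_s = c(1, 5, 2),
                   end_s = c(1.1, 5.1, 2.1), status = "accepted")
  same <- compare_event_sets(ev, ev)
  expect_equal(same$shared_fraction, 1)
  far <- ev; far$start_s <- far$start_s + 100; far$end_s <- far$end_s + 100
  expect_equal(compare_event_sets(ev, far)$n_shared, 0)

  # brute-force interval-intersection oracle on random sets
  set.seed(17)
  mk <- function(n) {
    d <- data.frame(channel = sample(c("A", "B"), n, TRUE),
                    start_s = runif(n, 0, 20), status = "accepted")
    d$end_s <- d$start_s + 0.08
    d
  }
  a <- mk(15); b <- mk(15)
  got <- compare_event_sets(a, b, overlap_tol_s = 0.05)
  want <- sum(vapply(seq_len(15), function(i)
    any(b$channel == a$channel[i] & b$start_s < a$end_s[i] + 0.05 &
          a$start_s[i] - 0.05 < b$end_s), TRUE))
  expect_identical(got$n_shared, want)
})
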