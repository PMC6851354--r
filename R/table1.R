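#' Load the packaged 19-recording clinical table
#'
#' The packaged fixture transcribes the study cohort: 19 scalp EEG
#' recordings from 11 children (8 presurgical, 11 postsurgical; the first
#' postsurgical recording of the twice-operated patient doubles as the
#' second presurgical one and is counted once), with affected- and
#' non-affected-hemisphere HFO rates (ripple band, events/min), seizure
#' frequency per month at recording time, and ILAE outcome class where
#' available.
#'
#' @param path CSV path; defaults to the packaged fixture
#' @return data frame with an added `active` label column
#' @export
load_clinical_table <- function(path = system.file("extdata", "table1.csv",
                                                   package = "scalphfo")) {
  t1 <- utils::read.csv(path, stringsAsFactors = FALSE)
  t1$active <- vapply(seq_len(nrow(t1)), function(i)
    label_activity(t1[i, ]) == "active", logical(1L))
  t1
}

#' Recompute all clinical-table statistics in one call
#'
#' Runs the full clinical-validation layer on the packaged 19-recording
#' table: ROC rate threshold, positives count, confusion matrix with
#' PPV/NPV/accuracy and the Wilson 95% CI on accuracy, the severity
#' regression on log10-log10 axes (plus the raw-scale sensitivity fit),
#' the paired hemisphere Wilcoxon test, and the active-vs-free rank-sum
#' test.
#'
#' @param table clinical table as from [load_clinical_table]
#' @param freedom_proxy seizures/month standing in for seizure freedom
#' @param out optional path; when given, the metrics are written there as
#'   JSON
#' @return a list of class `table1_metrics`
#' @export
reproduce_table1 <- function(table = load_clinical_table(),
                             freedom_proxy = 0.05, out = NULL) {
  rates <- table$affected_rate
  active <- table$active
  threshold <- optimal_threshold_roc(rates, active)
  cm <- confusion_matrix(rates, active, threshold)
  pv <- predictive_values(cm)
  ci <- wilson_interval(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn)
  res <- list(
    n_recordings = length(rates),
    threshold = threshold,
    n_positive = sum(classify_positive(rates, threshold)),
    confusion = list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
    ppv_percent = round(100 * pv$ppv),
    npv_percent = round(100 * pv$npv),
    accuracy_percent = round(100 * pv$accuracy),
    accuracy_ci_percent = c(round(100 * ci$lower), round(100 * ci$upper)),
    regression_log = unclass(severity_regression(table, freedom_proxy)),
    regression_raw = unclass(severity_regression(table, freedom_proxy,
                                                 log_scale = FALSE)),
    p_hemisphere = paired_hemisphere_test(table$affected_rate,
                                          table$nonaffected_rate),
    p_active_vs_free = group_rate_test(rates[active], rates[!active]))
  if (!is.null(out))
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  class(res) <- "table1_metrics"
  res
}

#' @export
print.table1_metrics <- function(x, ...) {
  cat(sprintf("Clinical table metrics (n = %d recordings)\n",
              x$n_recordings))
  cat(sprintf("  ROC rate threshold : %.2f HFO/min (%d positive)\n",
              x$threshold, x$n_positive))
  cat(sprintf("  confusion          : TP %d  FP %d  FN %d  TN %d\n",
              x$confusion$tp, x$confusion$fp, x$confusion$fn,
              x$confusion$tn))
  cat(sprintf("  PPV / NPV / acc    : %d%% / %d%% / %d%% CI [%d%% %d%%]\n",
              x$ppv_percent, x$npv_percent, x$accuracy_percent,
              x$accuracy_ci_percent[1L], x$accuracy_ci_percent[2L]))
  cat(sprintf("  severity regression: R^2 = %.2f (log10-log10, p = %.2g)",
              x$regression_log$r_squared, x$regression_log$p_value),
      sprintf("[raw-scale R^2 = %.2f]\n", x$regression_raw$r_squared))
  cat(sprintf("  hemisphere test    : p = %.4f (signed rank)\n",
              x$p_hemisphere))
  cat(sprintf("  active vs free     : p = %.4f (rank sum)\n",
              x$p_active_vs_free))
  invisible(x)
}
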