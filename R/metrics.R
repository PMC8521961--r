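# Posterior-derived metrics: hard classification, TST, confidence-based
# uncertainty percentages, sleep-wake transition percentage, the OSA
# screening decision rule, ROC threshold selection and agreement
# statistics.

#' Hard sleep-wake labels from posteriors
#'
#' An epoch is Wake iff `p_wake >= threshold` (boundary goes to Wake).
#'
#' @param p A `posterior_series` (or numeric `p_wake` vector).
#' @param threshold Decision threshold, default 0.5.
#' @return Integer 0/1 labels; `NA` for invalid epochs.
#' @export
classify_epochs <- function(p, threshold = 0.5) {
  pw <- if (is.data.frame(p)) ifelse(p$valid, p$p_wake, NA_real_) else p
  as.integer(pw >= threshold)
}

#' Fit sleep/wake confidence thresholds on a reference cohort
#'
#' Pooling epochs across subjects, the wake confidence threshold is the
#' median `p(Wake)` of wake-predicted epochs minus its SD; the sleep
#' confidence threshold is the median `p(Sleep)` of sleep-predicted epochs
#' minus its SD.
#'
#' @param p_wake Numeric vector of valid-epoch wake posteriors pooled over
#'   the reference cohort (or a `posterior_series`).
#' @param threshold Hard decision threshold, default 0.5.
#' @return List with `t_s` and `t_w`.
#' @export
fit_confidence_thresholds <- function(p_wake, threshold = 0.5) {
  if (is.data.frame(p_wake)) p_wake <- p_wake$p_wake[p_wake$valid]
  p_wake <- p_wake[!is.na(p_wake)]
  wake <- p_wake >= threshold
  cs_assert(any(wake) && any(!wake),
            "both predicted classes must be non-empty to fit thresholds",
            "threshold_error")
  pw <- p_wake[wake]
  ps <- 1 - p_wake[!wake]
  list(t_s = stats::median(ps) - sd_pop(ps),
       t_w = stats::median(pw) - sd_pop(pw))
}

#' Percentage of uncertain sleep and wake predictions
#'
#' An epoch is an uncertain sleep prediction iff it is predicted Sleep
#' with `p(Sleep)` below `t_s`; an uncertain wake prediction iff predicted
#' Wake with `p(Wake)` below `t_w`. Each percentage is taken over all
#' valid predicted epochs.
#'
#' @param p A `posterior_series` or numeric vector of valid `p_wake`.
#' @param thresholds List with `t_s`, `t_w` from
#'   [fit_confidence_thresholds()].
#' @param threshold Hard decision threshold.
#' @return List with `pct_use` and `pct_uwe` (percent).
#' @export
uncertainty_metrics <- function(p, thresholds, threshold = 0.5) {
  pw <- if (is.data.frame(p)) p$p_wake[p$valid] else p
  pw <- pw[!is.na(pw)]
  n <- length(pw)
  cs_assert(n > 0L, "no valid predicted epochs", "empty_recording_error")
  wake <- pw >= threshold
  list(pct_use = 100 * sum(!wake & (1 - pw) < thresholds$t_s) / n,
       pct_uwe = 100 * sum(wake & pw < thresholds$t_w) / n)
}

#' Percentage of sleep-wake transitions in a predicted architecture
#'
#' Invalid epochs are removed, the remaining labels are laid out in
#' temporal order, adjacent unequal pairs are counted and divided by the
#' number of valid epochs.
#'
#' @param labels Integer 0/1 predicted labels in temporal order (`NA` or
#'   `valid = FALSE` marks removed epochs).
#' @param valid Optional logical vector.
#' @return Transition percentage in `[0, 100)`.
#' @export
transition_metric <- function(labels, valid = NULL) {
  if (!is.null(valid)) labels <- labels[valid]
  labels <- labels[!is.na(labels)]
  cs_assert(length(labels) >= 2L,
            "need at least two valid epochs", "empty_recording_error")
  100 * sum(diff(labels) != 0) / length(labels)
}

#' Estimate total sleep time from predicted labels
#'
#' Each valid epoch predicted Sleep contributes half a minute. An
#' extrapolated estimate rescaled by the total/valid epoch ratio is also
#' returned (clearly labelled; discarded epochs carry no prediction).
#'
#' @param labels Integer 0/1 predicted labels (`NA` = invalid).
#' @param valid Optional logical vector.
#' @param n_total Total epochs on the grid (defaults to `length(labels)`).
#' @return List with `tst_min` and `tst_extrapolated_min`.
#' @export
estimate_tst <- function(labels, valid = NULL, n_total = length(labels)) {
  if (!is.null(valid)) labels[!valid] <- NA_integer_
  ok <- !is.na(labels)
  cs_assert(any(ok), "no valid epochs", "empty_recording_error")
  tst <- 0.5 * sum(labels[ok] == 0L)
  list(tst_min = tst,
       tst_extrapolated_min = tst * n_total / sum(ok))
}

#' Summarize one patient's predicted sleep architecture
#'
#' @param p A `posterior_series` for one patient.
#' @param thresholds Confidence thresholds from
#'   [fit_confidence_thresholds()].
#' @param threshold Hard decision threshold.
#' @return A `patient_summary` list: `tst_min`, `tst_extrapolated_min`,
#'   `pct_use`, `pct_uwe`, `pct_swt`, `n_valid_epochs`.
#' @export
patient_summary <- function(p, thresholds, threshold = 0.5) {
  stopifnot(is.data.frame(p))
  labels <- classify_epochs(p, threshold)
  un <- uncertainty_metrics(p, thresholds, threshold)
  tst <- estimate_tst(labels, n_total = nrow(p))
  structure(list(tst_min = tst$tst_min,
                 tst_extrapolated_min = tst$tst_extrapolated_min,
                 pct_use = un$pct_use, pct_uwe = un$pct_uwe,
                 pct_swt = transition_metric(labels),
                 n_valid_epochs = sum(p$valid)),
            class = "patient_summary")
}

#' @export
print.patient_summary <- function(x, ...) {
  cat(sprintf(paste0("TST %.1f min (extrapolated %.1f); %%USE %.1f, ",
                     "%%UWE %.1f, %%SWT %.1f over %d valid epochs\n"),
              x$tst_min, x$tst_extrapolated_min, x$pct_use, x$pct_uwe,
              x$pct_swt, x$n_valid_epochs))
  invisible(x)
}

#' OSA screening decision from a patient summary
#'
#' A patient is flagged as high-risk iff the percentage of uncertain sleep
#' epochs strictly exceeds `thr_use` or the percentage of sleep-wake
#' transitions strictly exceeds `thr_swt` (defaults 64% and 24%).
#'
#' @param s A [patient_summary()] (or any list with `pct_use`, `pct_swt`).
#' @param thr_use,thr_swt Decision thresholds in percent.
#' @return Logical: `TRUE` if flagged.
#' @export
detect_osa <- function(s, thr_use = 64, thr_swt = 24) {
  isTRUE(s$pct_use > thr_use) || isTRUE(s$pct_swt > thr_swt)
}

#' Choose a detection threshold on the ROC curve
#'
#' Candidate thresholds are midpoints between sorted unique metric values;
#' a patient is detected iff its metric strictly exceeds the threshold.
#' Among candidates attaining at least the specificity floor, the one with
#' maximal sensitivity (ties: higher specificity, then lower threshold)
#' is returned. If no candidate reaches the floor, the most specific
#' threshold is returned with `floor_attained = FALSE`. AUROC is the
#' trapezoid area under the empirical curve.
#'
#' @param metric_values Per-patient metric values.
#' @param osa_labels Logical or 0/1 indicator of the positive class.
#' @param min_specificity Specificity floor (default 0.95).
#' @return List: `threshold`, `sensitivity`, `specificity`, `auroc`,
#'   `floor_attained`, `roc` (data frame of threshold/sens/spec).
#' @export
select_threshold_roc <- function(metric_values, osa_labels,
                                 min_specificity = 0.95) {
  y <- as.logical(osa_labels)
  cs_assert(any(y) && any(!y), "both label groups must be non-empty",
            "cohort_error")
  u <- sort(unique(metric_values))
  cand <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else u
  cand <- c(min(u) - 1, cand, max(u) + 1)   # extremes anchor (0,0)/(1,1)
  sens <- vapply(cand, function(t) mean(metric_values[y] > t), 0)
  spec <- vapply(cand, function(t) mean(metric_values[!y] <= t), 0)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auroc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  roc <- data.frame(threshold = cand, sensitivity = sens,
                    specificity = spec)
  feas <- spec >= min_specificity
  if (any(feas)) {
    k <- which(feas)[order(-sens[feas], -spec[feas], cand[feas])[1L]]
    floor_attained <- TRUE
  } else {
    k <- order(-spec, -sens)[1L]
    floor_attained <- FALSE
    warning("no threshold attains the specificity floor; returning the most specific")
  }
  list(threshold = cand[k], sensitivity = sens[k], specificity = spec[k],
       auroc = auroc, floor_attained = floor_attained, roc = roc)
}

#' Cohen's kappa for two label vectors
#'
#' Chance-corrected agreement: observed minus chance agreement over one
#' minus chance agreement, computed from the confusion matrix.
#'
#' @param pred,truth Label vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(pred, truth) {
  cs_assert(length(pred) == length(truth),
            "label vectors differ in length", "parameter_error")
  lev <- sort(unique(c(pred, truth)))
  cm <- table(factor(pred, lev), factor(truth, lev))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Evaluate predictions against reference labels and TST
#'
#' @param pred_labels,truth_labels Aligned valid-epoch 0/1 labels.
#' @param tst_est,tst_ref Optional per-patient TST estimates and
#'   references in minutes (for bias and Pearson correlation).
#' @param detect_pred,detect_truth Optional per-patient logical detection
#'   decisions and OSA status.
#' @return An `evaluation_report` list with `kappa`, `accuracy_epoch`,
#'   and, when inputs are given, `tst_bias_mean`, `tst_bias_sd`,
#'   `pearson_rho`, `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate <- function(pred_labels, truth_labels, tst_est = NULL,
                     tst_ref = NULL, detect_pred = NULL,
                     detect_truth = NULL) {
  out <- list(kappa = cohen_kappa(pred_labels, truth_labels),
              accuracy_epoch = mean(pred_labels == truth_labels))
  if (!is.null(tst_est)) {
    d <- tst_est - tst_ref
    out$tst_bias_mean <- mean(d)
    out$tst_bias_sd <- stats::sd(d)
    if (stats::sd(tst_est) == 0 || stats::sd(tst_ref) == 0)
      cs_error("TST vectors are constant; correlation undefined",
               "parameter_error")
    out$pearson_rho <- stats::cor(tst_est, tst_ref)
  }
  if (!is.null(detect_pred)) {
    dp <- as.logical(detect_pred); dt <- as.logical(detect_truth)
    out$sensitivity <- mean(dp[dt])
    out$specificity <- mean(!dp[!dt])
    out$accuracy <- mean(dp == dt)
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("epoch kappa %.3f, accuracy %.3f\n", x$kappa,
              x$accuracy_epoch))
  if (!is.null(x$tst_bias_mean))
    cat(sprintf("TST bias %.1f (+/- %.1f) min, rho %.2f\n",
                x$tst_bias_mean, x$tst_bias_sd, x$pearson_rho))
  if (!is.null(x$sensitivity))
    cat(sprintf("detection sens %.2f, spec %.2f, acc %.2f\n",
                x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}
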