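# End-to-end conveniences tying the modules together for cohort-scale
# runs (simulation or manifest-driven), used by the worked examples and
# the reproducibility script.

#' Preprocess a list of synthetic patients into one labelled dataset
#'
#' @param patients List of `synthetic_patient` objects.
#' @param config Pipeline configuration.
#' @return A combined [epoch_dataset].
#' @export
process_cohort <- function(patients, config = cardiosleep_config()) {
  cs_assert(length(patients) >= 1L, "empty cohort", "cohort_error")
  bind_datasets(lapply(patients, process_patient, config = config))
}

#' Cohort table of a synthetic patient list
#' @param patients List of `synthetic_patient` objects.
#' @return Data frame with `patient_id`, `ahi` (true simulated AHI) and
#'   `severity` when available.
#' @export
cohort_table <- function(patients) {
  data.frame(patient_id = vapply(patients, `[[`, "", "patient_id"),
             ahi = vapply(patients, `[[`, 0, "true_ahi"),
             severity = vapply(patients, function(p)
               if (is.null(p$severity)) NA_character_ else p$severity, ""),
             stringsAsFactors = FALSE)
}

#' Per-patient architecture summaries for a cohort
#'
#' Applies a fitted classifier to each patient's epochs, derives posterior
#' series and summarizes uncertainty, transition and TST metrics.
#'
#' @param fit A fitted [sleepwake_cnn()].
#' @param ds A combined [epoch_dataset] covering the cohort.
#' @param thresholds Confidence thresholds from
#'   [fit_confidence_thresholds()].
#' @return Data frame with one row per patient: `patient_id`, `tst_min`,
#'   `tst_extrapolated_min`, `pct_use`, `pct_uwe`, `pct_swt`,
#'   `n_valid_epochs`, `detected`.
#' @export
summarize_cohort <- function(fit, ds, thresholds) {
  ids <- unique(ds$meta$patient_id)
  rows <- lapply(ids, function(id) {
    ps <- predict(fit, subset_dataset(ds, patients = id))
    s <- patient_summary(ps, thresholds)
    data.frame(patient_id = id, tst_min = s$tst_min,
               tst_extrapolated_min = s$tst_extrapolated_min,
               pct_use = s$pct_use, pct_uwe = s$pct_uwe,
               pct_swt = s$pct_swt, n_valid_epochs = s$n_valid_epochs,
               detected = detect_osa(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference total sleep time of a dataset, per patient
#'
#' Counts only valid epochs, mirroring the estimator's denominator.
#'
#' @param ds An [epoch_dataset].
#' @return Named numeric vector of reference TST in minutes.
#' @export
reference_tst <- function(ds) {
  ids <- unique(ds$meta$patient_id)
  out <- vapply(ids, function(id) {
    m <- ds$meta[ds$meta$patient_id == id & ds$meta$valid, ]
    0.5 * sum(m$label == 0L)
  }, 0)
  names(out) <- ids
  out
}
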