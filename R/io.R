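STAGE_LEVELS <- c("W", "N1", "N2", "N3", "REM")
EPOCH_LEN_S <- 30

#' Construct a two-channel PSG recording
#'
#' @param patient_id Patient identifier.
#' @param ecg,rip Numeric sample vectors; both channels start at the same
#'   instant.
#' @param ecg_rate,rip_rate Sampling rates in Hz (must be positive).
#' @param ahi_reference Optional reference apnea-hypopnea index (events per
#'   hour of sleep), used for evaluation only.
#' @return An object of class `psg_recording`.
#' @export
recording <- function(patient_id, ecg, ecg_rate, rip, rip_rate,
                      ahi_reference = NA_real_) {
  cs_assert(ecg_rate > 0 && rip_rate > 0, "sample rates must be positive",
            "parameter_error")
  structure(list(patient_id = as.character(patient_id),
                 ecg = list(x = as.numeric(ecg), rate = ecg_rate),
                 rip = list(x = as.numeric(rip), rate = rip_rate),
                 ahi_reference = ahi_reference),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("PSG recording '%s': %.1f h, ECG %g Hz, RIP %g Hz\n",
              x$patient_id, recording_duration(x) / 3600,
              x$ecg$rate, x$rip$rate))
  if (!is.na(x$ahi_reference))
    cat(sprintf("  reference AHI: %.1f events/h\n", x$ahi_reference))
  invisible(x)
}

#' Common duration of a recording in seconds
#' @param rec A [recording].
#' @return Duration in seconds (shorter of the two channels).
#' @export
recording_duration <- function(rec) {
  min(length(rec$ecg$x) / rec$ecg$rate, length(rec$rip$x) / rec$rip$rate)
}

#' Number of whole 30 s epochs covering a duration
#'
#' Epochs are 0-based and half-open: epoch `i` covers `[30 i, 30 (i+1))`
#' seconds from recording start; a trailing partial window is dropped.
#'
#' @param duration_s Duration in seconds (or a [recording]).
#' @return Integer epoch count, `floor(duration_s / 30)`.
#' @export
n_epochs <- function(duration_s) {
  if (inherits(duration_s, "psg_recording"))
    duration_s <- recording_duration(duration_s)
  as.integer(floor(duration_s / EPOCH_LEN_S))
}

#' Construct a hypnogram
#'
#' @param stages Character vector or factor of per-epoch stages in
#'   `W, N1, N2, N3, REM` (`R` accepted as a synonym for `REM`,
#'   case-insensitively).
#' @param apnea_events Data frame with columns `start_s`, `end_s` giving
#'   half-open annotated respiratory event intervals in seconds.
#' @param epoch_len_s Epoch length; fixed at 30 s.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, apnea_events = NULL, epoch_len_s = EPOCH_LEN_S) {
  stages <- toupper(trimws(as.character(stages)))
  stages[stages == "R"] <- "REM"
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  if (length(bad))
    cs_error(sprintf("unknown sleep stage code(s): %s",
                     paste(bad, collapse = ", ")), "vocabulary_error")
  if (is.null(apnea_events))
    apnea_events <- data.frame(start_s = numeric(), end_s = numeric())
  cs_assert(all(c("start_s", "end_s") %in% names(apnea_events)),
            "apnea_events needs columns start_s, end_s", "grid_error")
  span <- length(stages) * epoch_len_s
  ok <- apnea_events$end_s > apnea_events$start_s &
    apnea_events$start_s >= 0 & apnea_events$end_s <= span
  if (nrow(apnea_events) && !all(ok))
    cs_error("apnea event intervals must be non-empty and inside the recording span",
             "grid_error")
  structure(list(stages = factor(stages, levels = STAGE_LEVELS),
                 apnea_events = apnea_events[, c("start_s", "end_s")],
                 epoch_len_s = epoch_len_s),
            class = "hypnogram")
}

#' Read a hypnogram (and optionally apnea events) from delimited text
#'
#' The stage file must have columns `epoch_index` (0-based) and `stage`;
#' the optional event file columns `start_s`, `end_s`.
#'
#' @param path Stage CSV path.
#' @param n_epochs Expected number of epochs (the recording's grid).
#' @param events_path Optional apnea-event CSV path.
#' @return A [hypnogram].
#' @export
read_hypnogram <- function(path, n_epochs, events_path = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cs_assert(all(c("epoch_index", "stage") %in% names(d)),
            "hypnogram file needs columns epoch_index, stage", "format_error")
  d <- d[order(d$epoch_index), ]
  if (nrow(d) != n_epochs || !identical(as.integer(d$epoch_index),
                                        seq_len(nrow(d)) - 1L))
    cs_error(sprintf("hypnogram has %d rows; expected %d consecutive epochs",
                     nrow(d), n_epochs), "grid_error")
  ev <- if (!is.null(events_path)) utils::read.csv(events_path) else NULL
  hypnogram(d$stage, ev)
}

#' Write hypnogram stages (and events) as CSV
#' @param h A [hypnogram].
#' @param path Stage CSV output path.
#' @param events_path Optional events CSV output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path, events_path = NULL) {
  utils::write.csv(data.frame(epoch_index = seq_along(h$stages) - 1L,
                              stage = as.character(h$stages)),
                   path, row.names = FALSE)
  if (!is.null(events_path))
    utils::write.csv(h$apnea_events, events_path, row.names = FALSE)
  invisible(path)
}

#' Collapse a five-stage hypnogram to sleep/wake labels
#'
#' Class 0 is Sleep (N1, N2, N3, REM) and class 1 is Wake, matching the
#' classifier's output convention.
#'
#' @param h A [hypnogram].
#' @return Integer vector of per-epoch labels in `{0, 1}`.
#' @export
collapse_to_sleep_wake <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  as.integer(h$stages == "W")
}

#' Flag epochs overlapping an annotated apnea event
#'
#' An epoch overlaps iff any event interval intersects its half-open
#' 30 s window.
#'
#' @param h A [hypnogram].
#' @return Logical vector, one entry per epoch.
#' @export
apnea_overlap <- function(h) {
  n <- length(h$stages)
  out <- logical(n)
  if (nrow(h$apnea_events)) {
    s <- (seq_len(n) - 1L) * h$epoch_len_s
    for (k in seq_len(nrow(h$apnea_events))) {
      ev <- h$apnea_events[k, ]
      out <- out | (ev$start_s < s + h$epoch_len_s & ev$end_s > s)
    }
  }
  out
}

#' Read a cohort manifest
#'
#' A manifest lists one patient per row with columns `patient_id`,
#' `edf_path`, `hypnogram_path`, `events_path`, `ahi`.
#'
#' @param path Manifest CSV path.
#' @return Data frame with the columns above.
#' @export
read_manifest <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "edf_path", "hypnogram_path", "events_path", "ahi")
  cs_assert(all(need %in% names(d)),
            paste("manifest needs columns:", paste(need, collapse = ", ")),
            "format_error")
  d
}
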