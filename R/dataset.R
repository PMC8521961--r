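# Epoch-level dataset assembly: pairing preprocessed epochs with labels,
# patient-disjoint cohort splits, and class-balanced batch sampling.

#' Construct an epoch dataset
#'
#' @param ihr `n x 120` matrix of centered IHR epochs.
#' @param rip `n x 120` matrix of normalized RIP epochs.
#' @param meta Data frame with one row per epoch: `patient_id`, `epoch`
#'   (0-based index in the night), `stage`, `label` (0 sleep / 1 wake),
#'   `valid`, `apnea_overlap`.
#' @return Object of class `epoch_dataset`.
#' @export
epoch_dataset <- function(ihr, rip, meta) {
  cs_assert(nrow(ihr) == nrow(rip) && nrow(ihr) == nrow(meta),
            "ihr, rip and meta must have one row per epoch", "grid_error")
  need <- c("patient_id", "epoch", "stage", "label", "valid", "apnea_overlap")
  cs_assert(all(need %in% names(meta)),
            paste("meta needs columns:", paste(need, collapse = ", ")),
            "grid_error")
  structure(list(ihr = ihr, rip = rip, meta = meta), class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  v <- x$meta$valid
  cat(sprintf("epoch_dataset: %d epochs (%d valid) from %d patient(s); %.1f%% wake\n",
              nrow(x$meta), sum(v), length(unique(x$meta$patient_id)),
              100 * mean(x$meta$label[v] == 1L)))
  invisible(x)
}

#' Assemble a labelled dataset from preprocessed epochs and a hypnogram
#'
#' @param patient_id Patient identifier.
#' @param ecg_out Result of [preprocess_ecg()].
#' @param rip_out Result of [preprocess_rip()].
#' @param hyp A [hypnogram] on the same epoch grid.
#' @return An [epoch_dataset] for one patient.
#' @export
assemble_patient <- function(patient_id, ecg_out, rip_out, hyp) {
  ne <- length(ecg_out$valid)
  cs_assert(length(hyp$stages) == ne,
            "hypnogram and signal epoch grids differ", "grid_error")
  valid <- propagate_discards(rip_out$valid, ecg_out$valid)
  meta <- data.frame(patient_id = rep(patient_id, ne),
                     epoch = seq_len(ne) - 1L,
                     stage = as.character(hyp$stages),
                     label = collapse_to_sleep_wake(hyp),
                     valid = valid,
                     apnea_overlap = apnea_overlap(hyp),
                     stringsAsFactors = FALSE)
  epoch_dataset(ecg_out$values, rip_out$values, meta)
}

#' Concatenate epoch datasets across patients
#' @param ... `epoch_dataset` objects (or one list of them).
#' @return A single [epoch_dataset].
#' @export
bind_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && !inherits(dss[[1]], "epoch_dataset"))
    dss <- dss[[1]]
  epoch_dataset(do.call(rbind, lapply(dss, `[[`, "ihr")),
                do.call(rbind, lapply(dss, `[[`, "rip")),
                do.call(rbind, lapply(dss, `[[`, "meta")))
}

#' Subset an epoch dataset by patient ids or epoch index
#' @param ds An [epoch_dataset].
#' @param patients Character vector of patient ids to keep (or `NULL`).
#' @param rows Integer row index (or `NULL`).
#' @param valid_only Keep only valid epoch pairs.
#' @return An [epoch_dataset].
#' @export
subset_dataset <- function(ds, patients = NULL, rows = NULL,
                           valid_only = FALSE) {
  keep <- rep(TRUE, nrow(ds$meta))
  if (!is.null(patients)) keep <- keep & ds$meta$patient_id %in% patients
  if (valid_only) keep <- keep & ds$meta$valid
  idx <- which(keep)
  if (!is.null(rows)) idx <- intersect(idx, rows)
  epoch_dataset(ds$ihr[idx, , drop = FALSE], ds$rip[idx, , drop = FALSE],
                ds$meta[idx, , drop = FALSE])
}

#' Patient-disjoint 70/30 training split among low-AHI patients
#'
#' Only patients with AHI below the eligibility bound (default 10) enter
#' the training pool; they are split 70% for weight training and 30% for
#' validation, randomly by patient and deterministically for a given seed.
#'
#' @param cohort Data frame with columns `patient_id` and `ahi`.
#' @param seed Integer randomization seed.
#' @param test_ids Patient ids reserved for the fixed test set; excluded
#'   from the pool.
#' @param config Pipeline configuration (`split` section).
#' @return List with `train_ids`, `val_ids`, `test_ids`, `seed`.
#' @export
make_split <- function(cohort, seed, test_ids = character(),
                       config = cardiosleep_config()) {
  pool <- cohort[!(cohort$patient_id %in% test_ids) &
                   cohort$ahi < config$split$ahi_eligible, ]
  n <- nrow(pool)
  cs_assert(n >= 2L, "need at least two eligible (low-AHI) patients",
            "cohort_error")
  n_train <- round(config$split$train_frac * n)
  ids <- with_seed(seed, sample(pool$patient_id))
  list(train_ids = sort(ids[seq_len(n_train)]),
       val_ids = sort(ids[(n_train + 1L):n]),
       test_ids = test_ids, seed = seed)
}

#' Class-balanced batch index stream
#'
#' Draws epochs with equal per-class probability (the minority class is
#' over-sampled with replacement), in temporal-order-free fashion, and
#' returns shuffled batches of fixed size; a trailing partial batch is
#' never emitted.
#'
#' @param labels Integer 0/1 labels of the (valid) epochs to sample from.
#' @param n_batches Number of batches to emit.
#' @param batch_size Epochs per batch (default 16).
#' @param seed Integer seed; the stream is reproducible given
#'   `(labels, seed)`.
#' @return List of `n_batches` integer index vectors of length
#'   `batch_size`.
#' @export
balanced_batches <- function(labels, n_batches, batch_size = 16L, seed = 1L) {
  idx0 <- which(labels == 0L)
  idx1 <- which(labels == 1L)
  cs_assert(length(idx0) > 0L && length(idx1) > 0L,
            "both classes must be present to balance batches",
            "balance_error")
  with_seed(seed, {
    lapply(seq_len(n_batches), function(b) {
      cls <- stats::rbinom(batch_size, 1L, 0.5)
      i0 <- sample(idx0, sum(cls == 0L), replace = TRUE)
      i1 <- sample(idx1, sum(cls == 1L), replace = TRUE)
      sample(c(i0, i1))
    })
  })
}
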