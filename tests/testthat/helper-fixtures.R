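# Shared fixtures, generated in code at test time.

# Gaussian-pulse ECG segment with known beat times
pulse_train <- function(beat_times, rate, dur_s = 30, width_s = 0.01,
                        noise_sd = 0) {
  n <- dur_s * rate
  x <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  t <- (seq_len(n) - 1) / rate
  for (b in beat_times) x <- x + exp(-0.5 * ((t - b) / width_s)^2)
  x
}

# valid ihr epoch with given values
make_epoch <- function(values) {
  e <- cardiosleep:::ihr_epoch()
  e$values <- values
  e$valid <- TRUE
  e$nan_mask <- rep(FALSE, length(values))
  e
}

# small labelled dataset with linearly separable modality patterns:
# wake epochs ride a positive IHR offset and a high-variance RIP pattern
separable_dataset <- function(n_per_class = 120L, n_patients = 4L,
                              seed = 42L, offset = 12) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    n <- 2L * n_per_class
    lab <- rep(c(0L, 1L), each = n_per_class)
    t <- (0:119) / 4
    ihr <- t(sapply(seq_len(n), function(i) {
      base <- if (lab[i] == 1L) offset else 0
      base + 2 * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi)) +
        rnorm(120, 0, 1)
    }))
    rip <- t(sapply(seq_len(n), function(i) {
      amp <- if (lab[i] == 1L) runif(1, 0.2, 2) else 1
      amp * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi)) +
        rnorm(120, 0, 0.1)
    }))
    meta <- data.frame(
      patient_id = rep(sprintf("p%d", seq_len(n_patients)),
                       length.out = n),
      epoch = seq_len(n) - 1L,
      stage = ifelse(lab == 1L, "W", "N2"),
      label = lab, valid = TRUE, apnea_overlap = FALSE,
      stringsAsFactors = FALSE)
    epoch_dataset(ihr, rip, meta)
  })
}

# quiet, fast simulator settings for unit tests
fast_sim_config <- function(...) {
  args <- utils::modifyList(list(epochs_per_night = 120L, ecg_rate = 128,
                                 rip_rate = 16,
                                 artifact_rate_per_hour = 0),
                            list(...))
  do.call(sim_config, args)
}
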