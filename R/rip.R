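# Respiratory-effort (RIP) epoch pipeline. Filtering is per 30 s segment
# with reflected borders so that a single epoch never depends on its
# neighbours; discards found on the ECG side are propagated afterwards.

#' Band-pass filter and resample one 30 s RIP segment to the 4 Hz grid
#'
#' Zero-phase band-pass over 0.04-2 Hz with a Butterworth magnitude
#' response of the configured order, applied in the frequency domain (a
#' real symmetric transfer function is zero-phase by construction and
#' numerically robust at the very low normalized high-pass corner).
#' 5 s of the segment are reflected at each border before filtering, then
#' the result is evaluated on the 4 Hz epoch grid by cubic-spline
#' interpolation.
#'
#' @param segment Numeric vector of `30 * rate` samples.
#' @param rate Sampling rate in Hz; must exceed 4.
#' @param config Pipeline configuration.
#' @return Numeric vector of 120 samples.
#' @export
filter_resample <- function(segment, rate, config = cardiosleep_config()) {
  cs_assert(rate > 4, "RIP sampling rate must exceed 4 Hz", "parameter_error")
  rip_filter_segments(matrix(segment, ncol = 1L), rate, config)[, 1L]
}

# filter + resample a matrix of segments (one per column) to the 4 Hz grid
rip_filter_segments <- function(X, rate, config) {
  band <- config$rip$band
  f <- fft_bandpass(X, rate, band[1], band[2], config$rip$order,
                    pad_s = config$rip$pad_s)
  tin <- (seq_len(nrow(X)) - 1L) / rate
  g <- (seq_len(config$grid$epoch_len_s * config$grid$fs_out) - 1L) /
    config$grid$fs_out
  apply(f, 2L, function(col)
    stats::spline(tin, col, xout = g, method = "fmm")$y)
}

#' Normalize all RIP epochs of one recording
#'
#' Let `M` be the 50th percentile of per-epoch medians and `S` the 50th
#' percentile of per-epoch SDs (population formula) over all candidate
#' epochs. Every sample is mapped to `(x - M) / S`, after which each
#' epoch's own median is subtracted, so every output epoch has median
#' exactly zero. The statistics are computed before any discard
#' propagation.
#'
#' @param values `n_epochs x 120` matrix of filtered, resampled segments.
#' @return Matrix of the same shape, normalized.
#' @export
normalize_recording <- function(values) {
  cs_assert(is.matrix(values) && nrow(values) >= 1L,
            "need at least one candidate epoch", "empty_recording_error")
  meds <- apply(values, 1L, stats::median)
  sds <- apply(values, 1L, sd_pop)
  M <- stats::median(meds)
  S <- stats::median(sds)
  if (!is.finite(S) || S == 0)
    cs_error("all RIP epochs are constant; cannot normalize",
             "degenerate_recording_error")
  out <- (values - M) / S
  out - apply(out, 1L, stats::median)
}

#' Propagate ECG-side discards to the RIP epochs
#'
#' The network consumes epoch pairs, so an epoch discarded during ECG
#' preprocessing is discarded from the RIP stream as well.
#'
#' @param rip_valid,ihr_valid Logical validity vectors on the same epoch
#'   grid.
#' @return Logical vector: elementwise AND.
#' @export
propagate_discards <- function(rip_valid, ihr_valid) {
  cs_assert(length(rip_valid) == length(ihr_valid),
            "validity vectors are on different epoch grids", "grid_error")
  rip_valid & ihr_valid
}

#' Run the full RIP pipeline over a recording
#'
#' @param rip Numeric RIP sample vector.
#' @param rate Sampling rate in Hz.
#' @param ihr_valid Logical validity from the ECG pipeline (same grid).
#' @param config Pipeline configuration.
#' @return List with `values` (n_epochs x 120 normalized matrix) and
#'   `valid` (logical, after discard propagation).
#' @export
preprocess_rip <- function(rip, rate, ihr_valid,
                           config = cardiosleep_config()) {
  spe <- config$grid$epoch_len_s * rate
  ne <- floor(length(rip) / spe)
  cs_assert(ne == length(ihr_valid),
            "ECG and RIP epoch grids differ", "grid_error")
  cs_assert(rate > 4, "RIP sampling rate must exceed 4 Hz",
            "parameter_error")
  segs <- matrix(rip[seq_len(ne * spe)], nrow = spe)
  m <- t(rip_filter_segments(segs, rate, config))
  m <- normalize_recording(m)
  list(values = m, valid = propagate_discards(rep(TRUE, ne), ihr_valid))
}
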