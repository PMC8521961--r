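# ECG -> instantaneous-heart-rate (IHR) epoch pipeline. Every operation is
# strictly per 30 s segment until the final per-subject median centering, so
# that epoch validity never depends on neighbouring data quality.

ihr_epoch <- function(values = rep(NA_real_, 120L), valid = FALSE,
                      nan_mask = rep(FALSE, 120L)) {
  structure(list(values = values, valid = valid, nan_mask = nan_mask),
            class = "ihr_epoch")
}

#' Detect R peaks in one 30 s ECG segment
#'
#' Pan-Tompkins-style detector: zero-phase band-pass (5-15 Hz), squared
#' derivative, moving-window integration, adaptive threshold at a fraction
#' of the integrated maximum, 250 ms refractory period, then peak refinement
#' on the band-passed energy.
#'
#' @param segment Numeric vector of `30 * rate` ECG samples.
#' @param rate Sampling rate in Hz (> 0).
#' @param config Pipeline configuration, see [cardiosleep_config()].
#' @return Ascending numeric vector of peak times in seconds within
#'   `[0, 30)`; possibly empty.
#' @export
detect_r_peaks <- function(segment, rate, config = cardiosleep_config()) {
  cs_assert(rate > 0, "sampling rate must be positive", "parameter_error")
  det <- config$ecg$detector
  n <- length(segment)
  if (n < 4L || all(segment == segment[1])) return(numeric())
  bp <- ecg_bandpass(matrix(segment, ncol = 1L), rate, det)[, 1L]
  find_r_peaks_core(bp, rate, det)
}

# detection band-pass for a matrix of segments (one per column)
ecg_bandpass <- function(X, rate, det) {
  hi <- min(det$band[2], 0.45 * rate)
  fft_bandpass(sweep(X, 2L, colMeans(X)), rate, det$band[1], hi,
               det$order, pad_s = 1)
}

# squared-derivative energy, moving-window integration, adaptive
# threshold, refractory pruning, peak refinement on band-passed energy
find_r_peaks_core <- function(bp, rate, det) {
  n <- length(bp)
  en <- c(0, diff(bp))^2
  w <- max(1L, round(det$integrate_s * rate))
  integ <- moving_avg(en, w)
  thr <- det$threshold_frac * max(integ)
  if (thr <= 0) return(numeric())
  above <- integ > thr
  if (!any(above)) return(numeric())
  r <- rle(as.vector(above))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  half <- max(1L, round(0.1 * rate))
  cand <- vapply(seq_len(nrow(regions)), function(k) {
    a <- max(1L, regions[k, 1] - half)
    b <- min(n, regions[k, 2] + half)
    a - 1L + which.max(bp[a:b]^2)
  }, 0)
  cand <- sort(unique(cand))
  # refractory period: keep strongest peaks first
  ord <- cand[order(bp[cand]^2, decreasing = TRUE)]
  kept <- integer(0)
  refr <- det$refractory_s * rate
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) > refr)) kept <- c(kept, i)
  }
  times <- sort(kept - 1L) / rate
  times[times < 30]
}

#' Build a 120-sample IHR epoch from detected beats
#'
#' Segments with fewer than 15 beats are invalidated. Otherwise the first
#' and last beat times are shifted outward (first beat to the second beat
#' time minus the mean of the 2nd and 3rd interbeat intervals; last beat
#' symmetrically) to avoid border extrapolation, the IHR (60 / interbeat
#' interval, bpm) is assigned at beat times, and a shape-preserving
#' piecewise-cubic interpolant is evaluated on the 4 Hz grid.
#'
#' @param beat_times_s Ascending beat times in seconds within one segment.
#' @param config Pipeline configuration.
#' @return An `ihr_epoch` (120 samples; `valid = FALSE` if discarded).
#' @export
make_ihr_epoch <- function(beat_times_s, config = cardiosleep_config()) {
  t <- as.numeric(beat_times_s)
  cs_assert(!is.unsorted(t, strictly = TRUE),
            "beat times must be strictly increasing", "parameter_error")
  if (length(t) < config$ecg$min_beats) return(ihr_epoch())
  ibi <- diff(t)
  n <- length(t)
  t[1] <- t[2] - mean(ibi[2:3])
  t[n] <- t[n - 1L] + mean(ibi[(n - 3L):(n - 2L)])
  d <- diff(t)
  y <- 60 / c(d[1], d)
  g <- (seq_len(config$grid$epoch_len_s * config$grid$fs_out) - 1L) /
    config$grid$fs_out
  gi <- pmin(pmax(g, t[1]), t[n])           # constant-hold beyond beat span
  vals <- signal::pchip(t, y, gi)
  ihr_epoch(values = as.numeric(vals), valid = TRUE)
}

#' Flag IHR outliers
#'
#' A sample is an outlier iff it lies outside 40-180 bpm, or more than
#' 20 bpm from the segment median, or more than 3 segment SDs from the
#' segment median. Median and SD (population formula) are computed over the
#' 120 samples before any flagging; the three rules are applied jointly in
#' one pass.
#'
#' @param e An `ihr_epoch`.
#' @param config Pipeline configuration.
#' @return The epoch with outliers replaced by `NA` and `nan_mask` set.
#' @export
flag_outliers <- function(e, config = cardiosleep_config()) {
  if (!e$valid) return(e)
  v <- e$values
  med <- stats::median(v)
  sdv <- sd_pop(v)
  mask <- v < config$ecg$hr_bounds[1] | v > config$ecg$hr_bounds[2] |
    abs(v - med) > config$ecg$median_margin |
    abs(v - med) > config$ecg$sd_margin * sdv
  v[mask] <- NA_real_
  e$values <- v
  e$nan_mask <- mask
  e
}

#' Fill short missing runs by mirroring
#'
#' Each maximal missing run of length `L <= 10` samples (2.5 s at 4 Hz) is
#' replaced by the `L` samples immediately preceding it in reverse order.
#' Longer runs, or runs without enough preceding samples (including any run
#' starting at the first sample), invalidate the epoch. Runs are processed
#' left to right, so earlier fills can feed later mirrors.
#'
#' @param e An `ihr_epoch` with `nan_mask` populated.
#' @param config Pipeline configuration.
#' @return The epoch, gap-free if still valid.
#' @export
fill_nan_gaps <- function(e, config = cardiosleep_config()) {
  if (!e$valid) return(e)
  v <- e$values
  isna <- is.na(v)
  if (!any(isna)) return(e)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    L <- r$lengths[k]
    s <- starts[k]
    if (L > config$ecg$max_gap || s - 1L < L ||
        anyNA(v[(s - L):(s - 1L)])) {
      e$valid <- FALSE
      return(e)
    }
    v[s:(s + L - 1L)] <- v[(s - 1L):(s - L)]
  }
  e$values <- v
  e$nan_mask <- rep(FALSE, length(v))
  e
}

#' Median-center all IHR epochs of one subject
#'
#' Subtracts the median over all samples of all valid epochs from every
#' valid epoch, removing inter-subject heart-rate level while keeping
#' inter-stage variability. Invalid epochs are untouched.
#'
#' @param epochs List of `ihr_epoch` objects from one recording.
#' @return List of centered epochs.
#' @export
center_subject <- function(epochs) {
  valid <- vapply(epochs, function(e) e$valid, TRUE)
  if (!any(valid))
    cs_error("no valid IHR epochs in recording", "empty_recording_error")
  med <- stats::median(unlist(lapply(epochs[valid], function(e) e$values)))
  lapply(epochs, function(e) {
    if (e$valid) e$values <- e$values - med
    e
  })
}

#' Run the full ECG pipeline over a recording
#'
#' Segments the channel into 30 s epochs, detects beats, builds, flags,
#' gap-fills and median-centers IHR epochs.
#'
#' @param ecg Numeric ECG sample vector.
#' @param rate Sampling rate in Hz.
#' @param config Pipeline configuration.
#' @return List with `values` (n_epochs x 120 matrix, `NA` rows for invalid
#'   epochs) and `valid` (logical vector).
#' @export
preprocess_ecg <- function(ecg, rate, config = cardiosleep_config()) {
  spe <- config$grid$epoch_len_s * rate
  ne <- floor(length(ecg) / spe)
  det <- config$ecg$detector
  segs <- matrix(ecg[seq_len(ne * spe)], nrow = spe)
  flat <- apply(segs, 2L, function(s) all(s == s[1]))
  bp <- matrix(0, spe, ne)
  if (any(!flat))
    bp[, !flat] <- ecg_bandpass(segs[, !flat, drop = FALSE], rate, det)
  epochs <- vector("list", ne)
  for (i in seq_len(ne)) {
    beats <- if (flat[i]) numeric() else
      find_r_peaks_core(bp[, i], rate, det)
    e <- make_ihr_epoch(beats, config)
    if (e$valid) e <- fill_nan_gaps(flag_outliers(e, config), config)
    epochs[[i]] <- e
  }
  valid <- vapply(epochs, function(e) e$valid, TRUE)
  if (any(valid)) epochs <- center_subject(epochs)
  m <- do.call(rbind, lapply(epochs, function(e)
    if (e$valid) e$values else rep(NA_real_, 120L)))
  list(values = m, valid = valid)
}
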