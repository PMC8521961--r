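#' Default pipeline configuration
#'
#' All tunable preprocessing, network and decision parameters in one nested
#' list. Values follow the published processing rules: 4 Hz epoch grid,
#' minimum of 15 detected beats per 30 s segment, physiological heart-rate
#' bounds 40-180 bpm, median +/- 20 bpm and median +/- 3 SD outlier rules,
#' maximum 10-sample (2.5 s) mirror-filled gap, RIP passband 0.04-2 Hz, and
#' screening thresholds of 64% uncertain sleep epochs / 24% sleep-wake
#' transitions.
#'
#' @param ... Named overrides merged (shallowly, per top-level section) into
#'   the defaults.
#' @return Nested list of parameters.
#' @export
cardiosleep_config <- function(...) {
  cfg <- list(
    grid = list(epoch_len_s = 30, fs_out = 4),           # 120 samples/epoch
    ecg = list(
      min_beats = 15L,
      hr_bounds = c(40, 180),                             # bpm
      median_margin = 20,                                 # bpm
      sd_margin = 3,                                      # x segment SD
      max_gap = 10L,                                      # samples at 4 Hz
      detector = list(band = c(5, 15), order = 3L,
                      refractory_s = 0.25, integrate_s = 0.15,
                      threshold_frac = 0.25)
    ),
    rip = list(band = c(0.04, 2), order = 4L, pad_s = 5),
    cnn = list(spec = NULL,                               # default_layer_spec()
               threshold = 0.5),
    detection = list(thr_use = 64, thr_swt = 24, min_specificity = 0.95),
    split = list(train_frac = 0.7, ahi_eligible = 10)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% names(cfg) && is.list(dots[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}
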