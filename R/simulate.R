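# Synthetic PSG cohort generator. Produces stage-labelled ECG and RIP
# waveforms whose statistical structure matches what the pipeline assumes:
# stage-dependent heart rate and breathing with respiratory sinus
# arrhythmia, apnea events that suppress respiratory effort and trigger a
# transient wake-like heart-rate surge, and movement artifacts. Stage
# parameter defaults are chosen for physiological plausibility and class
# separability; they are modelling choices, not measured clinical facts.

#' Simulator configuration
#'
#' @param epochs_per_night Number of 30 s epochs per simulated night.
#' @param ecg_rate,rip_rate Waveform sampling rates in Hz.
#' @param stage_prob Target stationary stage probabilities
#'   (W, N1, N2, N3, REM); the default mirrors a typical clinical
#'   low-AHI training cohort (W 17%, N1 4%, N2 40%, N3 22%, REM 17%).
#' @param stickiness Probability of remaining governed by the current
#'   stage at each epoch transition (sticky Markov chain; the remainder
#'   redraws from `stage_prob`, which is then the exact stationary law).
#' @param ihr_mean,ihr_sd Per-stage mean and slow-variability SD of the
#'   instantaneous heart rate (bpm), ordered Wake > REM = N1 > N2 > N3.
#' @param rsa_amp Per-stage respiratory sinus arrhythmia amplitude (bpm).
#' @param resp_rate,resp_rate_jitter Per-stage breathing rate (Hz) and its
#'   per-epoch jitter SD.
#' @param resp_amp,resp_amp_jitter Per-stage respiratory-effort amplitude
#'   (arbitrary units) and per-epoch jitter SD.
#' @param apnea_rate_per_hour Apnea events per hour of sleep.
#' @param apnea_duration_s Event duration range in seconds (within
#'   10-120 s; scored events last at least 10 s).
#' @param resp_intra_jitter,amp_intra_jitter Per-stage within-epoch
#'   (breath-to-breath) log-scale SD of breathing rate and effort
#'   amplitude; wakefulness breathes irregularly inside an epoch, deep
#'   sleep does not.
#' @param hr_intra_jitter Per-stage within-epoch heart-rate fluctuation
#'   SD (bpm).
#' @param effort_reduction Fractional reduction of respiratory effort
#'   during an event.
#' @param hr_surge_bpm Peak post-event heart-rate surge toward wake-like
#'   values.
#' @param event_brady_bpm Heart-rate dip during the obstructed interval
#'   (the bradycardia half of the brady-tachycardia swing).
#' @param surge_duration_s Duration of the post-event arousal response
#'   (heart-rate surge and recovery breathing).
#' @param recovery_gain Amplitude overshoot of the recovery
#'   (hyperpneic) breaths after an event.
#' @param artifact_rate_per_hour Movement-artifact rate.
#' @param artifact_duration_s Artifact duration range (s).
#' @param ecg_noise_sd,rip_noise_sd Additive white noise SDs (QRS pulse
#'   amplitude is 1).
#' @param beat_jitter_s Per-beat timing jitter SD (s).
#' @param qrs_width_s Gaussian QRS pulse SD (s).
#' @return A `sim_config` list.
#' @export
sim_config <- function(epochs_per_night = 960L, ecg_rate = 256,
                       rip_rate = 32,
                       stage_prob = c(W = 0.17, N1 = 0.04, N2 = 0.40,
                                      N3 = 0.22, REM = 0.17),
                       stickiness = 0.9,
                       ihr_mean = c(W = 73, N1 = 66, N2 = 60, N3 = 55,
                                    REM = 67),
                       ihr_sd = c(W = 6, N1 = 3, N2 = 2, N3 = 1.5,
                                  REM = 4),
                       rsa_amp = c(W = 1, N1 = 2, N2 = 2.5, N3 = 3,
                                   REM = 1.5),
                       resp_rate = c(W = 0.28, N1 = 0.26, N2 = 0.25,
                                     N3 = 0.22, REM = 0.30),
                       resp_rate_jitter = c(W = 0.08, N1 = 0.02,
                                            N2 = 0.01, N3 = 0.005,
                                            REM = 0.05),
                       resp_amp = c(W = 1, N1 = 1, N2 = 1, N3 = 1,
                                    REM = 1),
                       resp_amp_jitter = c(W = 0.15, N1 = 0.1, N2 = 0.05,
                                           N3 = 0.05, REM = 0.1),
                       resp_intra_jitter = c(W = 0.30, N1 = 0.15,
                                             N2 = 0.04, N3 = 0.03,
                                             REM = 0.20),
                       amp_intra_jitter = c(W = 0.45, N1 = 0.12,
                                            N2 = 0.05, N3 = 0.04,
                                            REM = 0.25),
                       hr_intra_jitter = c(W = 4, N1 = 1.5, N2 = 1,
                                           N3 = 0.8, REM = 3),
                       apnea_rate_per_hour = 10,
                       apnea_duration_s = c(10, 40),
                       effort_reduction = 0.7, hr_surge_bpm = 18,
                       event_brady_bpm = 8,
                       surge_duration_s = 15, recovery_gain = 1.5,
                       artifact_rate_per_hour = 1,
                       artifact_duration_s = c(10, 60),
                       ecg_noise_sd = 0.05, rip_noise_sd = 0.05,
                       beat_jitter_s = 0.01, qrs_width_s = 0.01) {
  cs_assert(abs(sum(stage_prob) - 1) < 1e-8,
            "stage probabilities must sum to 1", "parameter_error")
  cs_assert(apnea_duration_s[1] >= 10 && apnea_duration_s[2] <= 120,
            "apnea durations must lie within [10, 120] s",
            "parameter_error")
  cs_assert(apnea_rate_per_hour >= 0 && artifact_rate_per_hour >= 0,
            "rates must be non-negative", "parameter_error")
  as.list(environment())
}

#' Transition matrix of the simulated stage chain
#'
#' Sticky first-order Markov chain: with probability `stickiness` the
#' stage persists, otherwise the next stage is redrawn from the target
#' stationary distribution, which is therefore exact.
#'
#' @param cfg A [sim_config()].
#' @return Row-stochastic 5x5 matrix over W, N1, N2, N3, REM.
#' @export
stage_transition_matrix <- function(cfg) {
  p <- cfg$stage_prob
  P <- cfg$stickiness * diag(length(p)) +
    (1 - cfg$stickiness) * matrix(p, length(p), length(p), byrow = TRUE)
  dimnames(P) <- list(names(p), names(p))
  P
}

#' Simulate a per-epoch hypnogram stage sequence
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the sequence is deterministic given the seed.
#' @param transition Optional 5x5 row-stochastic matrix overriding the
#'   default sticky chain.
#' @param init Initial stage (default `"W"`; nights start awake).
#' @return Character vector of stages of length `epochs_per_night`.
#' @export
simulate_hypnogram <- function(cfg = sim_config(), seed = 1L,
                               transition = NULL, init = "W") {
  P <- if (is.null(transition)) stage_transition_matrix(cfg) else transition
  cs_assert(all(abs(rowSums(P) - 1) < 1e-8),
            "transition matrix rows must sum to 1", "parameter_error")
  lev <- rownames(P)
  n <- cfg$epochs_per_night
  with_seed(seed, {
    s <- character(n)
    cur <- init
    for (i in seq_len(n)) {
      cur <- sample(lev, 1L, prob = P[cur, ])
      s[i] <- cur
    }
    s
  })
}

#' Place apnea events within the sleep epochs of a night
#'
#' The event count is Poisson with mean `rate x sleep hours`; starts fall
#' uniformly inside randomly chosen sleep epochs, durations are uniform in
#' the configured range, and overlapping events are dropped.
#'
#' @param stages Character stage vector (one per epoch).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame with `start_s`, `end_s`.
#' @export
place_apnea_events <- function(stages, cfg = sim_config(), seed = 1L) {
  sleep_epochs <- which(stages != "W")
  span <- length(stages) * EPOCH_LEN_S
  if (!length(sleep_epochs) || cfg$apnea_rate_per_hour == 0)
    return(data.frame(start_s = numeric(), end_s = numeric()))
  sleep_h <- length(sleep_epochs) * EPOCH_LEN_S / 3600
  with_seed(seed, {
    n_target <- stats::rpois(1L, cfg$apnea_rate_per_hour * sleep_h)
    starts <- numeric(0)
    ends <- numeric(0)
    attempts <- 0L
    # rejection placement: event onsets fall in sleep epochs and events
    # never overlap, so the realized count tracks the Poisson target
    while (length(starts) < n_target && attempts < 20L * n_target + 20L) {
      attempts <- attempts + 1L
      ep <- sleep_epochs[sample.int(length(sleep_epochs), 1L)]
      s <- (ep - 1L) * EPOCH_LEN_S + stats::runif(1L, 0, EPOCH_LEN_S)
      d <- stats::runif(1L, cfg$apnea_duration_s[1],
                        cfg$apnea_duration_s[2])
      e <- s + d
      if (e > span) next
      if (length(starts) && any(s < ends & e > starts)) next
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
    o <- order(starts)
    data.frame(start_s = starts[o], end_s = ends[o])
  })
}

# piecewise-constant per-epoch value expanded to a sample grid
expand_epochwise <- function(per_epoch, rate) {
  rep(per_epoch, each = EPOCH_LEN_S * rate)
}

# stationary AR(1) random walk with time constant tau_s; stationary SD
# `sd` modulated per sample (vector-valued sd allowed)
ar1_walk <- function(n, sd, rate, tau_s = 3) {
  a <- exp(-1 / (tau_s * rate))
  innov <- stats::rnorm(n, 0, sqrt(1 - a^2))
  x <- stats::filter(innov, a, method = "recursive")
  as.numeric(x) * sd
}

#' Render ECG and RIP waveforms for a staged night
#'
#' Beat times arise from an integrate-and-fire process on a
#' stage-dependent instantaneous rate with respiratory sinus arrhythmia
#' coupling and post-apnea surges; the ECG is a train of Gaussian
#' QRS-like pulses at those times. The RIP channel is an amplitude- and
#' rate-modulated oscillation, with effort reduced during apnea events.
#'
#' @param stages Character stage vector.
#' @param events Apnea event data frame (`start_s`, `end_s`).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `ecg`, `rip` (numeric vectors), `beat_times`
#'   (seconds) and the modulation grids used.
#' @export
render_signals <- function(stages, events, cfg = sim_config(), seed = 1L) {
  n_ep <- length(stages)
  T <- n_ep * EPOCH_LEN_S
  fs_mod <- 4                                 # modulation grid
  tm <- (seq_len(T * fs_mod) - 1L) / fs_mod
  with_seed(seed, {
    # instantaneous base heart rate: stage mean + per-epoch AR(1) wander
    mu <- cfg$ihr_mean[stages]
    sdv <- cfg$ihr_sd[stages]
    wander <- numeric(n_ep)
    for (i in seq_len(n_ep)) {
      prev <- if (i > 1L) wander[i - 1L] else 0
      wander[i] <- 0.7 * prev + stats::rnorm(1L, 0, sdv[i])
    }
    hr_epoch <- mu + wander
    hr_grid <- stats::approx(seq_len(n_ep) * EPOCH_LEN_S - 15, hr_epoch,
                             xout = tm, rule = 2)$y
    # post-event arousal weight: 1 at event end, decaying linearly over
    # surge_duration_s; sympathetic activation makes the post-apnea
    # cardiorespiratory dynamics wake-like during continued sleep
    arousal_at <- function(t_grid) {
      w <- numeric(length(t_grid))
      if (nrow(events)) for (k in seq_len(nrow(events))) {
        e <- events$end_s[k]
        idx <- which(t_grid >= e & t_grid < e + cfg$surge_duration_s)
        w[idx] <- pmax(w[idx], 1 - (t_grid[idx] - e) /
                         cfg$surge_duration_s)
      }
      w
    }
    aw_mod <- arousal_at(tm)
    # within-epoch heart-rate fluctuation: large awake and during
    # arousals, small in deep sleep
    hr_sd <- expand_epochwise(cfg$hr_intra_jitter[stages], fs_mod)
    hr_sd <- pmax(hr_sd, aw_mod * 1.2 * cfg$hr_intra_jitter["W"])
    in_event_mod <- rep(FALSE, length(tm))
    if (nrow(events)) for (k in seq_len(nrow(events)))
      in_event_mod <- in_event_mod | (tm >= events$start_s[k] &
                                        tm < events$end_s[k])
    hr_grid <- hr_grid + ar1_walk(length(tm), hr_sd, fs_mod, tau_s = 5) +
      aw_mod * cfg$hr_surge_bpm - in_event_mod * cfg$event_brady_bpm
    # breathing rate/amplitude: per-epoch level plus within-epoch
    # (breath-to-breath) log-scale random walks; arousal imposes
    # wake-grade irregularity and recovery (hyperpneic) breaths
    f_ep <- pmax(0.08, cfg$resp_rate[stages] +
                   stats::rnorm(n_ep, 0, cfg$resp_rate_jitter[stages]))
    a_ep <- pmax(0.1, cfg$resp_amp[stages] +
                   stats::rnorm(n_ep, 0, cfg$resp_amp_jitter[stages]))
    rip_t <- (seq_len(T * cfg$rip_rate) - 1L) / cfg$rip_rate
    nr <- length(rip_t)
    aw_rip <- arousal_at(rip_t)
    f_sd <- pmax(expand_epochwise(cfg$resp_intra_jitter[stages],
                                  cfg$rip_rate),
                 aw_rip * 1.2 * cfg$resp_intra_jitter["W"])
    a_sd <- pmax(expand_epochwise(cfg$amp_intra_jitter[stages],
                                  cfg$rip_rate),
                 aw_rip * 1.2 * cfg$amp_intra_jitter["W"])
    f_rip <- expand_epochwise(f_ep, cfg$rip_rate) *
      exp(ar1_walk(nr, f_sd, cfg$rip_rate)) *
      (1 + 0.2 * aw_rip)
    a_rip <- expand_epochwise(a_ep, cfg$rip_rate) *
      exp(ar1_walk(nr, a_sd, cfg$rip_rate)) *
      (1 + (cfg$recovery_gain - 1) * aw_rip)
    in_event <- rep(FALSE, nr)
    if (nrow(events)) for (k in seq_len(nrow(events)))
      in_event <- in_event | (rip_t >= events$start_s[k] &
                                rip_t < events$end_s[k])
    a_rip[in_event] <- a_rip[in_event] * (1 - cfg$effort_reduction)
    phase <- 2 * pi * cumsum(f_rip) / cfg$rip_rate
    rip <- a_rip * sin(phase) +
      stats::rnorm(nr, 0, cfg$rip_noise_sd)
    # respiratory phase on the modulation grid for RSA coupling
    f_mod <- expand_epochwise(f_ep, fs_mod)
    phase_mod <- 2 * pi * cumsum(f_mod) / fs_mod
    rsa_mod <- expand_epochwise(cfg$rsa_amp[stages], fs_mod)
    # integrate-and-fire beat generation
    beats <- numeric(ceiling(T * 4))
    nb <- 0L
    t <- stats::runif(1L, 0, 1)
    while (t < T) {
      i <- min(length(tm), floor(t * fs_mod) + 1L)
      r <- hr_grid[i] + rsa_mod[i] * sin(phase_mod[i])
      ibi <- 60 / max(r, 20) + stats::rnorm(1L, 0, cfg$beat_jitter_s)
      t <- t + max(ibi, 0.25)
      if (t < T) {
        nb <- nb + 1L
        beats[nb] <- t
      }
    }
    beats <- beats[seq_len(nb)]
    # ECG: Gaussian pulses at beat samples + white noise
    n_ecg <- T * cfg$ecg_rate
    ecg <- stats::rnorm(n_ecg, 0, cfg$ecg_noise_sd)
    w <- ceiling(3 * cfg$qrs_width_s * cfg$ecg_rate)
    pulse <- exp(-0.5 * ((-w:w) / (cfg$qrs_width_s * cfg$ecg_rate))^2)
    ctr <- round(beats * cfg$ecg_rate) + 1L
    ok <- ctr > w & ctr <= n_ecg - w
    idx <- outer(ctr[ok], -w:w, "+")
    ecg[idx] <- ecg[idx] + rep(pulse, each = sum(ok))
    list(ecg = ecg, rip = rip, beat_times = beats, hr_grid = hr_grid,
         grid_t = tm)
  })
}

#' Inject movement artifacts into a recording
#'
#' Inserts bursts of high-amplitude noise (or flat spans, alternating) on
#' both channels at the configured rate. Ground-truth artifact intervals
#' are attached as an attribute.
#'
#' @param rec A [recording].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return The corrupted recording with attribute `artifact_intervals`.
#' @export
inject_artifacts <- function(rec, cfg = sim_config(), seed = 1L) {
  T <- recording_duration(rec)
  if (cfg$artifact_rate_per_hour == 0) {
    attr(rec, "artifact_intervals") <- data.frame(start_s = numeric(),
                                                  end_s = numeric())
    return(rec)
  }
  with_seed(seed, {
    n_a <- stats::rpois(1L, cfg$artifact_rate_per_hour * T / 3600)
    iv <- data.frame(start_s = numeric(), end_s = numeric())
    if (n_a > 0L) {
      start <- sort(stats::runif(n_a, 0, T))
      dur <- stats::runif(n_a, cfg$artifact_duration_s[1],
                          cfg$artifact_duration_s[2])
      iv <- data.frame(start_s = start, end_s = pmin(start + dur, T))
      for (k in seq_len(n_a)) {
        ei <- max(1L, floor(iv$start_s[k] * rec$ecg$rate) + 1L):
          min(length(rec$ecg$x), ceiling(iv$end_s[k] * rec$ecg$rate))
        ri <- max(1L, floor(iv$start_s[k] * rec$rip$rate) + 1L):
          min(length(rec$rip$x), ceiling(iv$end_s[k] * rec$rip$rate))
        if (k %% 2L == 1L) {                 # movement noise burst
          rec$ecg$x[ei] <- stats::rnorm(length(ei), 0, 2)
          rec$rip$x[ri] <- stats::rnorm(length(ri), 0, 5)
        } else {                             # sensor saturation / flatline
          rec$ecg$x[ei] <- 0
          rec$rip$x[ri] <- 0
        }
      }
    }
    attr(rec, "artifact_intervals") <- iv
    rec
  })
}

#' Simulate one synthetic patient
#'
#' @param patient_id Identifier.
#' @param cfg A [sim_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A `synthetic_patient`: `recording`, `hypnogram`, `beat_times`,
#'   `true_ahi` (events per true sleep hour) and `config`.
#' @export
simulate_patient <- function(patient_id, cfg = sim_config(), seed = 1L) {
  stages <- simulate_hypnogram(cfg, seed = seed)
  events <- place_apnea_events(stages, cfg, seed = seed + 1L)
  sig <- render_signals(stages, events, cfg, seed = seed + 2L)
  sleep_h <- sum(stages != "W") * EPOCH_LEN_S / 3600
  rec <- recording(patient_id, sig$ecg, cfg$ecg_rate, sig$rip,
                   cfg$rip_rate,
                   ahi_reference = nrow(events) / sleep_h)
  rec <- inject_artifacts(rec, cfg, seed = seed + 3L)
  structure(list(recording = rec,
                 hypnogram = hypnogram(stages, events),
                 beat_times = sig$beat_times,
                 true_ahi = nrow(events) / sleep_h,
                 config = cfg, seed = seed,
                 patient_id = as.character(patient_id)),
            class = "synthetic_patient")
}

#' Simulate a severity-spanning cohort
#'
#' Patients are generated in four OSA severity classes with configured
#' apnea rates (defaults 2, 10, 20 and 60 events per sleep hour for
#' none / mild / moderate / severe).
#'
#' @param n_per_class Integer count per class (scalar or length 4).
#' @param cfg Base [sim_config()]; the apnea rate is overridden per class.
#' @param seed Integer seed.
#' @param class_rates Events/hour per severity class.
#' @return List of `synthetic_patient` objects with a `severity` field.
#' @export
simulate_cohort <- function(n_per_class, cfg = sim_config(), seed = 1L,
                            class_rates = c(none = 2, mild = 10,
                                            moderate = 20, severe = 60)) {
  if (length(n_per_class) == 1L)
    n_per_class <- rep(n_per_class, length(class_rates))
  out <- list()
  k <- 0L
  for (ci in seq_along(class_rates)) {
    cfg_c <- cfg
    cfg_c$apnea_rate_per_hour <- class_rates[[ci]]
    for (j in seq_len(n_per_class[ci])) {
      k <- k + 1L
      p <- simulate_patient(sprintf("%s_%02d", names(class_rates)[ci], j),
                            cfg_c, seed = seed + 137L * k)
      p$severity <- names(class_rates)[ci]
      out[[k]] <- p
    }
  }
  out
}

#' Preprocess a synthetic patient into a labelled epoch dataset
#'
#' Runs the full ECG and RIP pipelines on the rendered waveforms and pairs
#' them with the simulated hypnogram.
#'
#' @param patient A `synthetic_patient`.
#' @param config Pipeline configuration.
#' @return An [epoch_dataset].
#' @export
process_patient <- function(patient, config = cardiosleep_config()) {
  rec <- patient$recording
  ne <- n_epochs(rec)
  ecg_out <- preprocess_ecg(rec$ecg$x[seq_len(ne * 30 * rec$ecg$rate)],
                            rec$ecg$rate, config)
  rip_out <- preprocess_rip(rec$rip$x[seq_len(ne * 30 * rec$rip$rate)],
                            rec$rip$rate, ecg_out$valid, config)
  hyp <- patient$hypnogram
  if (length(hyp$stages) > ne)
    hyp <- hypnogram(as.character(hyp$stages)[seq_len(ne)],
                     hyp$apnea_events[hyp$apnea_events$end_s <= ne * 30, ])
  assemble_patient(patient$patient_id, ecg_out, rip_out, hyp)
}
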