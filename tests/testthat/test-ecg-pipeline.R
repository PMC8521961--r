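test_that("R-peak detector recovers a clean 1 Hz pulse train exactly", {
  rate <- 128
  truth <- seq(0.5, 29.5, by = 1)
  x <- pulse_train(truth, rate)
  got <- detect_r_peaks(x, rate)
  expect_length(got, 30)
  expect_lt(max(abs(got - truth)), 1 / rate + 1e-9)
})

test_that("detector returns an empty series on flat input and rejects bad rates", {
  expect_length(detect_r_peaks(numeric(30 * 64), 64), 0)
  expect_error(detect_r_peaks(rnorm(10), 0), class = "parameter_error")
  expect_error(detect_r_peaks(rnorm(10), -5), class = "parameter_error")
})

test_that("detector tolerates white noise at 20 dB SNR", {
  set.seed(7)
  rate <- 128
  truth <- seq(0.5, 29.5, by = 1)          # 60 bpm
  x <- pulse_train(truth, rate, noise_sd = 0.1)
  got <- detect_r_peaks(x, rate)
  matched <- sum(vapply(truth, function(b) any(abs(got - b) < 0.05), TRUE))
  expect_gte(matched, 28)
})

test_that("segments with fewer than 15 beats are discarded", {
  e14 <- make_ihr_epoch(seq(1, 27, by = 2))     # 14 beats
  expect_false(e14$valid)
  e15 <- make_ihr_epoch(seq(0.5, 28.5, by = 2)) # 15 beats
  expect_true(e15$valid)
})

test_that("a perfectly regular rhythm maps to a constant 60 bpm epoch", {
  e <- make_ihr_epoch(seq(0.5, 29.5, by = 1))
  expect_true(e$valid)
  expect_length(e$values, 120)
  expect_equal(e$values, rep(60, 120), tolerance = 1e-12)
})

test_that("border-shifted shape-preserving interpolation does not overshoot", {
  # alternating 0.8/1.0 s interbeat intervals: IHR alternates 60 and 75
  ibis <- rep(c(0.8, 1.0), 17)
  beats <- cumsum(c(0.3, ibis))
  beats <- beats[beats < 30]
  e <- make_ihr_epoch(beats)
  expect_true(e$valid)
  expect_gte(min(e$values), 60 - 1e-9)
  expect_lte(max(e$values), 75 + 1e-9)
})

test_that("the interpolant agrees with an independent PCHIP oracle", {
  skip_if_not_installed("pracma")
  set.seed(11)
  t <- sort(runif(20, 0, 30))
  y <- 60 + 10 * sin(t / 3) + rnorm(20)
  xi <- seq(min(t), max(t), length.out = 500)
  expect_equal(signal::pchip(t, y, xi), pracma::pchip(t, y, xi),
               tolerance = 1e-9)
})

test_that("outlier rules flag range, median-margin and SD violations jointly", {
  e <- flag_outliers(make_epoch(rep(60, 120)))
  expect_false(any(e$nan_mask))

  v <- rep(60, 120); v[50] <- 39             # physiological range rule
  e <- flag_outliers(make_epoch(v))
  expect_identical(which(e$nan_mask), 50L)
  expect_true(is.na(e$values[50]))

  v <- rep(100, 120); v[10] <- 121           # median +/- 20 inside 40-180
  e <- flag_outliers(make_epoch(v))
  expect_identical(which(e$nan_mask), 10L)

  v <- 60 + rep(c(-1, 1), 60); v[30] <- 75   # 3 x SD rule only
  med <- median(v)
  expect_lte(abs(75 - med), 20)              # not caught by the +/-20 rule
  e <- flag_outliers(make_epoch(v))
  expect_true(e$nan_mask[30])
})

test_that("gaps up to 10 samples are mirror-filled; longer ones invalidate", {
  v <- as.numeric(1:120)
  v[51:60] <- NA                             # run of 10
  e <- fill_nan_gaps(make_epoch(v))
  expect_true(e$valid)
  expect_equal(e$values[51:60], as.numeric(50:41))  # mirrored
  expect_false(anyNA(e$values))

  v <- as.numeric(1:120); v[51:61] <- NA     # run of 11
  expect_false(fill_nan_gaps(make_epoch(v))$valid)

  v <- as.numeric(1:120); v[1:3] <- NA       # no preceding samples
  expect_false(fill_nan_gaps(make_epoch(v))$valid)

  v <- as.numeric(1:120); v[4:6] <- NA       # exactly enough preceding
  e <- fill_nan_gaps(make_epoch(v))
  expect_true(e$valid)
  expect_equal(e$values[4:6], c(3, 2, 1))

  v <- as.numeric(1:120); v[3:6] <- NA       # fewer preceding than run
  expect_false(fill_nan_gaps(make_epoch(v))$valid)

  e <- fill_nan_gaps(make_epoch(as.numeric(1:120)))
  expect_equal(e$values, as.numeric(1:120))  # identity without gaps
})

test_that("subject centering zeroes the pooled median and removes baselines", {
  es <- list(make_epoch(rep(72, 120)), make_epoch(rep(72, 120)))
  out <- center_subject(es)
  expect_equal(out[[1]]$values, rep(0, 120))

  set.seed(3)
  shape <- rnorm(120, 0, 5)
  a <- center_subject(list(make_epoch(60 + shape),
                           make_epoch(60 - shape)))
  b <- center_subject(list(make_epoch(90 + shape),
                           make_epoch(90 - shape)))
  expect_equal(a[[1]]$values, b[[1]]$values, tolerance = 1e-12)

  pooled <- unlist(lapply(a, `[[`, "values"))
  expect_equal(median(pooled), 0)

  expect_error(center_subject(list(cardiosleep:::ihr_epoch())),
               class = "empty_recording_error")
})

test_that("every valid epoch from the full pipeline has 120 finite samples", {
  p <- simulate_patient("pp", fast_sim_config(), seed = 21)
  out <- preprocess_ecg(p$recording$ecg$x, p$recording$ecg$rate)
  expect_length(out$valid, 120)
  expect_true(all(is.finite(out$values[out$valid, ])))
  expect_true(all(is.na(out$values[!out$valid, ])))
})

test_that("the pipeline is deterministic and artifacts only remove epochs", {
  cfg <- fast_sim_config()
  p <- simulate_patient("pd", cfg, seed = 22)
  x <- p$recording$ecg$x
  rate <- p$recording$ecg$rate
  a <- preprocess_ecg(x, rate)
  b <- preprocess_ecg(x, rate)
  expect_identical(a, b)

  # corrupt two whole epochs: those become invalid, the rest are untouched
  x2 <- x
  x2[(5 * 30 * rate + 1):(6 * 30 * rate)] <- 0
  set.seed(1)
  x2[(8 * 30 * rate + 1):(9 * 30 * rate)] <- rnorm(30 * rate, 0, 2)
  c_ <- preprocess_ecg(x2, rate)
  expect_false(c_$valid[6])
  expect_true(all(which(c_$valid) %in% which(a$valid)))
})
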