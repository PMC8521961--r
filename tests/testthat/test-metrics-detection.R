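# independent brute-force kappa oracle: explicit agreement bookkeeping
kappa_oracle <- function(pred, truth) {
  lev <- sort(unique(c(pred, truth)))
  n <- length(pred)
  po <- sum(pred == truth) / n
  pe <- 0
  for (l in lev) pe <- pe + (sum(pred == l) / n) * (sum(truth == l) / n)
  (po - pe) / (1 - pe)
}

test_that("the 0.5 posterior threshold assigns the boundary to Wake", {
  expect_identical(classify_epochs(c(0.5, 0.49, 0, 1)), c(1L, 0L, 0L, 1L))
  ps <- structure(data.frame(patient_id = "a", epoch = 0:2,
                             valid = c(TRUE, FALSE, TRUE),
                             p_wake = c(0.6, NA, 0.2)),
                  class = c("posterior_series", "data.frame"))
  expect_identical(classify_epochs(ps), c(1L, NA_integer_, 0L))
})

test_that("confidence thresholds are median minus SD of the predicted pool", {
  a <- 0.06 * sqrt(3 / 2)
  p_sleep <- c(0.87 - a, 0.87, 0.87 + a)     # median 0.87, SD 0.06
  p_wake <- c(0.69 - a, 0.69, 0.69 + a)      # median 0.69, SD 0.06
  pool <- c(1 - p_sleep, p_wake)
  thr <- fit_confidence_thresholds(pool)
  expect_equal(thr$t_s, 0.81, tolerance = 1e-9)
  expect_equal(thr$t_w, 0.63, tolerance = 1e-9)

  # all identical posteriors: SD 0, threshold equals the common value
  thr0 <- fit_confidence_thresholds(c(0.2, 0.2, 0.9, 0.9))
  expect_equal(thr0$t_s, 0.8)
  expect_equal(thr0$t_w, 0.9)
  expect_error(fit_confidence_thresholds(c(0.9, 0.8)),
               class = "threshold_error")
})

test_that("uncertainty percentages follow the hand-enumerated example", {
  thr <- list(t_s = 0.81, t_w = 0.63)
  un <- uncertainty_metrics(c(0.10, 0.45, 0.55, 0.90), thr)
  expect_equal(un$pct_use, 25)
  expect_equal(un$pct_uwe, 25)

  expect_equal(uncertainty_metrics(rep(0.01, 10), thr)$pct_use, 0)
  eps <- 1e-6
  un2 <- uncertainty_metrics(c(0.5 + eps, 0.5 - eps),
                             list(t_s = 0.5 + eps / 2,
                                  t_w = 0.5 + eps / 2))
  expect_equal(un2$pct_use, 0)
  expect_equal(un2$pct_uwe, 0)
})

test_that("transition percentage counts label changes over valid epochs", {
  expect_equal(transition_metric(c(0L, 0L, 1L, 1L, 0L)), 40)
  expect_equal(transition_metric(rep(1L, 9)), 0)
  n <- 11
  expect_equal(transition_metric(rep(c(0L, 1L), length.out = n)),
               100 * (n - 1) / n)
  # invalid epochs are removed before counting adjacency
  expect_equal(transition_metric(c(0L, NA, 1L, 1L)), 100 * 1 / 3)
  # invariant to relabeling 0 <-> 1
  set.seed(8)
  lab <- rbinom(60, 1, 0.4)
  expect_equal(transition_metric(lab), transition_metric(1L - lab))
  expect_error(transition_metric(c(1L)), class = "empty_recording_error")
})

test_that("TST counts half a minute per valid sleep epoch", {
  expect_equal(estimate_tst(rep(0L, 960))$tst_min, 480)
  lab <- rep(c(0L, 1L), c(400L, 300L))
  expect_equal(estimate_tst(lab)$tst_min, 200)
  # perfect predictor reproduces the reference TST exactly
  truth <- rbinom(200, 1, 0.3)
  expect_equal(estimate_tst(truth)$tst_min, 0.5 * sum(truth == 0L))
  # extrapolation rescales by the discarded fraction
  lab2 <- c(rep(0L, 50), rep(NA_integer_, 50))
  expect_equal(estimate_tst(lab2)$tst_min, 25)
  expect_equal(estimate_tst(lab2)$tst_extrapolated_min, 50)
})

test_that("the screening rule is a strict-threshold OR and monotone", {
  s <- function(use, swt) list(pct_use = use, pct_swt = swt)
  expect_true(detect_osa(s(65, 10)))
  expect_false(detect_osa(s(64, 24)))        # boundary equality: negative
  expect_true(detect_osa(s(10, 30)))
  expect_false(detect_osa(s(0, 0)))

  set.seed(14)
  for (i in 1:50) {
    use <- runif(1, 0, 100); swt <- runif(1, 0, 100)
    base <- detect_osa(s(use, swt))
    more <- detect_osa(s(use + runif(1, 0, 30), swt + runif(1, 0, 30)))
    expect_false(base && !more)              # never flips positive->negative
  }
})

test_that("ROC threshold selection honors the specificity floor", {
  sel <- select_threshold_roc(c(10, 20, 70, 80), c(0, 0, 1, 1))
  expect_equal(sel$auroc, 1)
  expect_equal(sel$sensitivity, 1)
  expect_equal(sel$specificity, 1)
  expect_gt(sel$threshold, 20)
  expect_lt(sel$threshold, 70)
  expect_true(sel$floor_attained)

  # indistinguishable groups: AUROC near one half
  set.seed(6)
  v <- rnorm(200)
  lab <- rep(0:1, 100)
  sel2 <- select_threshold_roc(v, lab)
  expect_gt(sel2$auroc, 0.4)
  expect_lt(sel2$auroc, 0.6)

  expect_warning(
    sel3 <- select_threshold_roc(c(1, 2, 1.5, 2.5), c(0, 1, 1, 0),
                                 min_specificity = 1.01),
    "specificity floor")
  expect_false(sel3$floor_attained)
  expect_error(select_threshold_roc(1:4, c(1, 1, 1, 1)),
               class = "cohort_error")
})

test_that("AUROC matches an independent implementation on random instances", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:5) {
    v <- c(rnorm(30), rnorm(30, mean = runif(1, 0, 2)))
    lab <- rep(0:1, each = 30)
    mine <- select_threshold_roc(v, lab)$auroc
    ref <- as.numeric(pROC::auc(pROC::roc(lab, v, quiet = TRUE,
                                          direction = "<")))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("kappa agrees with a brute-force oracle on random instances", {
  set.seed(20)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(pred == truth) == n) next        # po = pe = 1 handled below
    expect_equal(cohen_kappa(pred, truth), kappa_oracle(pred, truth),
                 tolerance = 1e-12)
  }
  # the canonical worked confusion matrix [[40,10],[10,40]] -> 0.6
  pred <- rep(c(0L, 0L, 1L, 1L), c(40L, 10L, 10L, 40L))
  truth <- rep(c(0L, 1L, 0L, 1L), c(40L, 10L, 10L, 40L))
  expect_equal(cohen_kappa(pred, truth), 0.6, tolerance = 1e-12)
  expect_equal(cohen_kappa(rep(1L, 5), rep(1L, 5)), 1)
})

test_that("kappa is near zero for independent labels at matched marginals", {
  set.seed(21)
  n <- 10000
  expect_lt(abs(cohen_kappa(rbinom(n, 1, 0.3), rbinom(n, 1, 0.3))), 0.05)
})

test_that("evaluate reports agreement, TST bias and detection operating point", {
  pred <- c(0L, 1L, 0L, 1L, 0L)
  rep_ <- evaluate(pred, pred)
  expect_equal(rep_$kappa, 1)
  expect_error(evaluate(pred, pred, tst_est = rep(400, 4),
                        tst_ref = c(380, 400, 420, 400)),
               class = "parameter_error")
  r2 <- evaluate(pred, pred, tst_est = c(400, 380, 430, 300),
                 tst_ref = c(380, 400, 420, 310),
                 detect_pred = c(TRUE, FALSE, TRUE, FALSE),
                 detect_truth = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(r2$tst_bias_mean, mean(c(20, -20, 10, -10)))
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 2 / 3)
  expect_output(print(r2), "kappa")
})

test_that("patient summaries respect their invariants", {
  set.seed(30)
  ps <- structure(data.frame(patient_id = "x", epoch = 0:199,
                             valid = rep(c(TRUE, FALSE), c(180, 20)),
                             p_wake = c(runif(180), rep(NA, 20))),
                  class = c("posterior_series", "data.frame"))
  s <- patient_summary(ps, list(t_s = 0.81, t_w = 0.63))
  expect_lte(s$tst_min, 0.5 * s$n_valid_epochs)
  expect_true(s$pct_use >= 0 && s$pct_use <= 100)
  expect_true(s$pct_uwe >= 0 && s$pct_uwe <= 100)
  expect_lte(s$pct_use + s$pct_uwe, 100)
  expect_identical(s$n_valid_epochs, 180L)
  expect_output(print(s), "TST")
})
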