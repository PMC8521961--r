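# Network-level contracts. Small fits reuse the separable fixture so the
# whole file stays fast.

test_that("forward passes produce proper posteriors and desk-scale sizes", {
  net <- build_unimodal("ecg", seed = 1)
  set.seed(2)
  X <- matrix(rnorm(8 * 120), 8)
  probs <- cardiosleep:::net_forward(net, list(X))$probs
  expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-6)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_lt(count_params(net)["total"], 100000)

  fused <- fuse_multimodal(build_unimodal("ecg", seed = 1),
                           build_unimodal("rip", seed = 2), seed = 3)
  expect_lt(count_params(fused)["total"], 100000)
})

test_that("builds are deterministic in the init seed", {
  a <- build_unimodal("rip", seed = 7)
  b <- build_unimodal("rip", seed = 7)
  expect_identical(a$params, b$params)
  c_ <- build_unimodal("rip", seed = 8)
  expect_false(identical(a$params, c_$params))
})

test_that("degenerate layer specs are rejected", {
  bad <- default_layer_spec(conv = list(c(8L, 200L, 1L)))
  expect_error(build_unimodal("ecg", bad), class = "architecture_error")
})

test_that("fusion freezes convolutional weights bit-exactly while the head learns", {
  ds <- separable_dataset(n_per_class = 60L)
  ctrl <- sleepwake_control(max_passes = 2L, patience = 2L)
  ecg_net <- train_net(build_unimodal("ecg", seed = 1), ds, ds, ctrl,
                       seed = 1)
  rip_net <- train_net(build_unimodal("rip", seed = 2), ds, ds, ctrl,
                       seed = 2)
  fused <- fuse_multimodal(ecg_net, rip_net, seed = 3)
  before <- fused$params
  trained <- train_net(fused, ds, ds, ctrl, seed = 3)
  conv_names <- grep("conv", names(before), value = TRUE)
  for (nm in conv_names)
    expect_identical(trained$params[[nm]], before[[nm]])
  # and they equal the unimodal branch weights they were copied from
  expect_identical(trained$params$ecg_conv1_W, ecg_net$params$conv1_W)
  expect_identical(trained$params$rip_conv3_W, rip_net$params$conv3_W)
  expect_false(identical(trained$params$dense_W, before$dense_W))
})

test_that("a fused forward pass is the dense head applied to concatenated branch features", {
  ecg_net <- build_unimodal("ecg", seed = 4)
  rip_net <- build_unimodal("rip", seed = 5)
  fused <- fuse_multimodal(ecg_net, rip_net, seed = 6)
  ds <- separable_dataset(n_per_class = 10L)
  Fmat <- net_features(fused, ds)
  # manual composition oracle
  H <- pmax(sweep(Fmat %*% fused$params$dense_W, 2,
                  -fused$params$dense_b), 0)
  logits <- sweep(H %*% fused$params$out_W, 2, -fused$params$out_b)
  ex <- exp(logits - apply(logits, 1, max))
  manual <- ex / rowSums(ex)
  got <- cardiosleep:::predict_probs(fused,
                                     cardiosleep:::net_inputs(fused, ds))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("training separates linearly separable epochs quickly", {
  ds <- separable_dataset(n_per_class = 150L)
  tr <- subset_dataset(ds, patients = c("p1", "p2", "p3"))
  va <- subset_dataset(ds, patients = "p4")
  ctrl <- sleepwake_control(max_passes = 20L, patience = 20L)
  net <- train_net(build_unimodal("ecg", seed = 1), tr, va, ctrl, seed = 1)
  probs <- cardiosleep:::predict_probs(net,
                                       cardiosleep:::net_inputs(net, va))
  acc <- mean((probs[, 2] >= 0.5) == (va$meta$label == 1L))
  expect_gte(acc, 0.95)
})

test_that("repeated descent on one fixed batch decreases the loss monotonically", {
  ds <- separable_dataset(n_per_class = 8L)
  ds$ihr <- ds$ihr / 20                      # well-conditioned unit scale
  net <- build_unimodal("ecg", seed = 3)
  ctrl <- sleepwake_control(dropout = FALSE)
  xs <- cardiosleep:::net_inputs(net, ds)
  y <- ds$meta$label
  state <- list(m = lapply(net$params, function(p) p * 0),
                v = lapply(net$params, function(p) p * 0))
  losses <- numeric(50)
  for (t in 1:50) {
    fw <- cardiosleep:::net_forward(net, xs, train = FALSE,
                                    keep_cache = TRUE)
    losses[t] <- cardiosleep:::net_loss(fw$probs, y)
    up <- cardiosleep:::adam_step(net$params,
                                  cardiosleep:::net_backward(net, fw, y),
                                  state, t, ctrl, character())
    net$params <- up$params
    state <- up$state
  }
  expect_true(all(diff(losses) <= 1e-4))
})

test_that("training is a pure function of data, control and seed", {
  ds <- separable_dataset(n_per_class = 40L)
  ctrl <- sleepwake_control(max_passes = 3L, patience = 3L)
  a <- train_net(build_unimodal("rip", seed = 6), ds, ds, ctrl, seed = 6)
  b <- train_net(build_unimodal("rip", seed = 6), ds, ds, ctrl, seed = 6)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("inference is deterministic (dropout inactive) and skips invalid epochs", {
  ds <- separable_dataset(n_per_class = 30L)
  ds$meta$valid[c(3, 10)] <- FALSE
  net <- build_unimodal("ecg", seed = 2)
  p1 <- net_posteriors(net, ds)
  p2 <- net_posteriors(net, ds)
  expect_identical(p1, p2)
  expect_true(all(is.na(p1$p_wake[c(3, 10)])))
  expect_true(all(p1$p_wake[p1$valid] >= 0 & p1$p_wake[p1$valid] <= 1))
})

test_that("model selection maximizes test kappa with lowest-seed tie-breaking", {
  ds <- separable_dataset(n_per_class = 100L)
  ctrl <- sleepwake_control(max_passes = 8L, patience = 8L)
  good <- train_net(build_unimodal("ecg", seed = 5), ds, ds, ctrl, seed = 5)
  naive <- build_unimodal("ecg", seed = 9)      # untrained
  picked <- select_model(list(naive, good), ds)
  expect_identical(picked$params, good$params)

  # equal candidates: the lower seed wins
  twin_a <- good; twin_a$seed <- 31L
  twin_b <- good; twin_b$seed <- 17L
  expect_identical(select_model(list(twin_a, twin_b), ds)$seed, 17L)
  expect_identical(select_model(list(good), ds)$params, good$params)
  expect_error(select_model(list(), ds), class = "parameter_error")
})

test_that("the sleepwake_cnn modelling interface round-trips its methods", {
  ds <- separable_dataset(n_per_class = 80L)
  ctrl <- sleepwake_control(max_passes = 4L, patience = 4L)
  fit <- sleepwake_cnn(ds, modality = "fused", control = ctrl, seed = 2)
  expect_s3_class(fit, "sleepwake_cnn")
  expect_output(print(fit), "fused")
  expect_output(print(summary(fit)), "frozen")
  expect_true(is.list(coef(fit)))
  ps <- predict(fit, ds)
  expect_s3_class(ps, "posterior_series")
  cl <- predict(fit, ds, type = "class")
  expect_true(all(cl[ds$meta$valid] %in% 0:1))
  sim <- simulate(fit, nsim = 2, seed = 1, newdata = ds)
  expect_identical(dim(sim), c(nrow(ds$meta), 2L))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
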