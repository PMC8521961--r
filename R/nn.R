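# 1D convolutional network for single-epoch sleep-wake classification.
# Implemented directly in base R matrix algebra: convolutions are lowered
# to patch-matrix (im2col) products, so a forward/backward pass over a
# batch is a handful of BLAS calls. This keeps the frozen-branch fusion
# contract inspectable: freezing a branch is literally skipping its
# parameter updates.

#' Default layer specification
#'
#' Per unimodal branch: three strided valid convolutions
#' (8,7,2) -> (16,5,2) -> (32,3,2) with ReLU, flatten, a 64-neuron dense
#' layer, 50% dropout and a 2-class softmax. The fused head uses the same
#' dense/dropout/softmax stack on the concatenated branch features.
#'
#' @param conv List of `c(f, k, s)` triplets (filters, kernel, stride).
#' @param dense Dense layer width.
#' @param dropout Dropout rate applied after the dense layer in training.
#' @param classes Number of output classes (2: sleep, wake).
#' @return A `layer_spec` list.
#' @export
default_layer_spec <- function(conv = list(c(8L, 7L, 2L), c(16L, 5L, 2L),
                                           c(32L, 3L, 2L)),
                               dense = 64L, dropout = 0.5, classes = 2L) {
  structure(list(conv = conv, dense = dense, dropout = dropout,
                 classes = classes), class = "layer_spec")
}

# precompute per-layer geometry and im2col index maps for one branch
compile_branch <- function(spec, input_len = 120L) {
  L <- input_len; C <- 1L
  layers <- vector("list", length(spec$conv))
  for (l in seq_along(spec$conv)) {
    p <- spec$conv[[l]]
    f <- p[1]; k <- p[2]; s <- p[3]
    Lout <- floor((L - k) / s) + 1L
    if (Lout < 1L)
      cs_error("layer spec produces non-positive feature length",
               "architecture_error")
    idx <- matrix(0L, Lout, k * C)
    for (c in seq_len(C)) for (j in seq_len(k)) {
      m <- (c - 1L) * k + j
      idx[, m] <- (c - 1L) * L + (seq_len(Lout) - 1L) * s + j
    }
    layers[[l]] <- list(f = f, k = k, s = s, Lin = L, Cin = C,
                        Lout = Lout, idx = idx)
    L <- Lout; C <- f
  }
  list(layers = layers, flat = L * C)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_branch_params <- function(branch, prefix) {
  p <- list()
  for (l in seq_along(branch$layers)) {
    ly <- branch$layers[[l]]
    p[[paste0(prefix, "conv", l, "_W")]] <- glorot(ly$k * ly$Cin, ly$f)
    p[[paste0(prefix, "conv", l, "_b")]] <- numeric(ly$f)
  }
  p
}

init_head_params <- function(nfeat, spec) {
  list(dense_W = glorot(nfeat, spec$dense),
       dense_b = numeric(spec$dense),
       out_W = glorot(spec$dense, spec$classes),
       out_b = numeric(spec$classes))
}

#' Build an untrained unimodal network
#'
#' @param modality `"ecg"` or `"rip"`.
#' @param spec A [default_layer_spec()].
#' @param seed Integer seed controlling weight initialization.
#' @param input_len Epoch length in samples (120).
#' @return A `sleepwake_net` object.
#' @export
build_unimodal <- function(modality = c("ecg", "rip"),
                           spec = default_layer_spec(), seed = 1L,
                           input_len = 120L) {
  modality <- match.arg(modality)
  branch <- compile_branch(spec, input_len)
  params <- with_seed(seed, c(init_branch_params(branch, ""),
                              init_head_params(branch$flat, spec)))
  structure(list(modality = modality, spec = spec,
                 branches = list(branch), prefixes = "",
                 params = params, frozen = character(),
                 input_len = input_len, trained = FALSE,
                 history = NULL, seed = seed),
            class = "sleepwake_net")
}

#' Fuse two trained unimodal networks into a multimodal network
#'
#' The convolutional weights of both branches are copied and frozen
#' (marked non-trainable); only the fresh dense head over the concatenated
#' convolutional feature maps is optimized during subsequent training.
#'
#' @param ecg_model,rip_model Trained unimodal `sleepwake_net` objects.
#' @param seed Seed for the fresh dense-head initialization.
#' @return A fused `sleepwake_net`.
#' @export
fuse_multimodal <- function(ecg_model, rip_model, seed = 1L) {
  cs_assert(inherits(ecg_model, "sleepwake_net") &&
              inherits(rip_model, "sleepwake_net"),
            "both arguments must be sleepwake_net models", "parameter_error")
  cs_assert(ecg_model$input_len == rip_model$input_len,
            "incompatible branch input lengths", "architecture_error")
  be <- ecg_model$branches[[1]]; br <- rip_model$branches[[1]]
  params <- c(prefix_params(ecg_model$params, be, "ecg_"),
              prefix_params(rip_model$params, br, "rip_"),
              with_seed(seed, init_head_params(be$flat + br$flat,
                                               ecg_model$spec)))
  frozen <- grep("conv", names(params), value = TRUE)
  structure(list(modality = "fused", spec = ecg_model$spec,
                 branches = list(be, br), prefixes = c("ecg_", "rip_"),
                 params = params, frozen = frozen,
                 input_len = ecg_model$input_len, trained = FALSE,
                 history = NULL, seed = seed),
            class = "sleepwake_net")
}

prefix_params <- function(params, branch, prefix) {
  nm <- unlist(lapply(seq_along(branch$layers), function(l)
    paste0("conv", l, c("_W", "_b"))))
  out <- params[nm]
  names(out) <- paste0(prefix, nm)
  out
}

# forward through one convolutional branch; X is B x input_len
branch_forward <- function(X, branch, params, prefix, keep_cache = FALSE) {
  B <- nrow(X)
  A <- X                                   # B x (L*C), starts with C = 1
  cache <- if (keep_cache) vector("list", length(branch$layers)) else NULL
  for (l in seq_along(branch$layers)) {
    ly <- branch$layers[[l]]
    P <- A[, as.vector(ly$idx), drop = FALSE]
    dim(P) <- c(B * ly$Lout, ly$k * ly$Cin)
    W <- params[[paste0(prefix, "conv", l, "_W")]]
    b <- params[[paste0(prefix, "conv", l, "_b")]]
    Y <- P %*% W
    Y <- Y + rep(b, each = nrow(Y))
    if (keep_cache) cache[[l]] <- list(P = P, Y = Y)
    A <- pmax(Y, 0)
    dim(A) <- c(B, ly$Lout * ly$f)
  }
  list(feat = A, cache = cache)
}

branch_backward <- function(dF, branch, params, prefix, cache, B) {
  grads <- list()
  dA <- dF                                  # B x (Lout*f) of last layer
  for (l in rev(seq_along(branch$layers))) {
    ly <- branch$layers[[l]]
    dY <- dA
    dim(dY) <- c(B * ly$Lout, ly$f)
    dY <- dY * (cache[[l]]$Y > 0)
    grads[[paste0(prefix, "conv", l, "_W")]] <- crossprod(cache[[l]]$P, dY)
    grads[[paste0(prefix, "conv", l, "_b")]] <- colSums(dY)
    if (l > 1L) {
      W <- params[[paste0(prefix, "conv", l, "_W")]]
      dP <- dY %*% t(W)                     # (B*Lout) x (k*Cin)
      dA <- matrix(0, B, ly$Lin * ly$Cin)
      for (m in seq_len(ncol(dP))) {
        cols <- ly$idx[, m]
        dA[, cols] <- dA[, cols] + matrix(dP[, m], B, ly$Lout)
      }
    }
  }
  grads
}

# full forward pass; xs is a list of branch input matrices (1 or 2)
net_forward <- function(net, xs, train = FALSE, keep_cache = FALSE) {
  B <- nrow(xs[[1]])
  bf <- lapply(seq_along(net$branches), function(i)
    branch_forward(xs[[i]], net$branches[[i]], net$params,
                   net$prefixes[i], keep_cache))
  F <- if (length(bf) == 1L) bf[[1]]$feat else
    cbind(bf[[1]]$feat, bf[[2]]$feat)
  Hpre <- F %*% net$params$dense_W
  Hpre <- Hpre + rep(net$params$dense_b, each = B)
  H <- pmax(Hpre, 0)
  mask <- NULL
  if (train && net$spec$dropout > 0) {
    keep <- 1 - net$spec$dropout
    mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                   nrow(H), ncol(H))
    H <- H * mask
  }
  logits <- H %*% net$params$out_W
  logits <- logits + rep(net$params$out_b, each = B)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs,
       cache = if (keep_cache) list(bf = bf, F = F, Hpre = Hpre, H = H,
                                    mask = mask) else NULL)
}

# mean cross-entropy and gradients for a labelled batch
net_backward <- function(net, fw, y) {
  B <- length(y)
  onehot <- matrix(0, B, net$spec$classes)
  onehot[cbind(seq_len(B), y + 1L)] <- 1
  dlogits <- (fw$probs - onehot) / B
  cc <- fw$cache
  grads <- list(out_W = crossprod(cc$H, dlogits),
                out_b = colSums(dlogits))
  dH <- dlogits %*% t(net$params$out_W)
  if (!is.null(cc$mask)) dH <- dH * cc$mask
  dH <- dH * (cc$Hpre > 0)
  grads$dense_W <- crossprod(cc$F, dH)
  grads$dense_b <- colSums(dH)
  dF <- dH %*% t(net$params$dense_W)
  at <- 0L
  for (i in seq_along(net$branches)) {
    nf <- net$branches[[i]]$flat
    gb <- branch_backward(dF[, at + seq_len(nf), drop = FALSE],
                          net$branches[[i]], net$params, net$prefixes[i],
                          cc$bf[[i]]$cache, B)
    grads <- c(grads, gb)
    at <- at + nf
  }
  grads
}

net_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Training control parameters
#'
#' @param batch_size Balanced batch size (16).
#' @param max_passes Maximum training passes over the (balanced) data.
#' @param patience Early-stopping patience, in passes without validation
#'   loss improvement.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param dropout Logical; disable to make single-batch training exactly
#'   deterministic layer-wise (used in diagnostics).
#' @return A list of control parameters.
#' @export
sleepwake_control <- function(batch_size = 16L, max_passes = 100L,
                              patience = 10L, lr = 1e-3, beta1 = 0.9,
                              beta2 = 0.999, eps = 1e-8, dropout = TRUE) {
  list(batch_size = batch_size, max_passes = max_passes,
       patience = patience, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, dropout = dropout)
}

adam_step <- function(params, grads, state, t, ctrl, frozen) {
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    state$m[[nm]] <- ctrl$beta1 * state$m[[nm]] + (1 - ctrl$beta1) * g
    state$v[[nm]] <- ctrl$beta2 * state$v[[nm]] + (1 - ctrl$beta2) * g^2
    mhat <- state$m[[nm]] / (1 - ctrl$beta1^t)
    vhat <- state$v[[nm]] / (1 - ctrl$beta2^t)
    params[[nm]] <- params[[nm]] - ctrl$lr * mhat / (sqrt(vhat) + ctrl$eps)
  }
  list(params = params, state = state)
}

net_inputs <- function(net, ds, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(ds$meta))
  switch(net$modality,
         ecg = list(ds$ihr[rows, , drop = FALSE]),
         rip = list(ds$rip[rows, , drop = FALSE]),
         fused = list(ds$ihr[rows, , drop = FALSE],
                      ds$rip[rows, , drop = FALSE]))
}

#' Train a network on balanced batches with early stopping
#'
#' Trains with Adam on class-balanced, shuffled batches of valid epochs,
#' evaluates the validation loss after every pass and retains the weights
#' with the best validation loss. Entirely deterministic given
#' `(data, control, seed)`.
#'
#' @param net A `sleepwake_net` (frozen parameters are not updated).
#' @param train,val [epoch_dataset] objects; patient-disjoint.
#' @param control A [sleepwake_control()] list.
#' @param seed Integer seed driving batch sampling and dropout.
#' @return The trained network with a `history` data frame.
#' @export
train_net <- function(net, train, val, control = sleepwake_control(),
                      seed = 1L) {
  train <- subset_dataset(train, valid_only = TRUE)
  val <- subset_dataset(val, valid_only = TRUE)
  cs_assert(nrow(train$meta) > 0L && nrow(val$meta) > 0L,
            "empty training or validation set", "cohort_error")
  ytr <- train$meta$label
  idx0 <- which(ytr == 0L); idx1 <- which(ytr == 1L)
  cs_assert(length(idx0) > 0L && length(idx1) > 0L,
            "training set must contain both classes", "balance_error")
  xval <- net_inputs(net, val)
  yval <- val$meta$label
  steps_per_pass <- max(1L, floor(nrow(train$meta) / control$batch_size))
  state <- list(m = lapply(net$params, function(p) p * 0),
                v = lapply(net$params, function(p) p * 0))
  best <- list(loss = Inf, params = net$params)
  hist <- NULL
  with_seed(seed, {
    t <- 0L
    stall <- 0L
    for (pass in seq_len(control$max_passes)) {
      tr_loss <- 0
      for (step in seq_len(steps_per_pass)) {
        cls <- stats::rbinom(control$batch_size, 1L, 0.5)
        rows <- c(sample(idx0, sum(cls == 0L), replace = TRUE),
                  sample(idx1, sum(cls == 1L), replace = TRUE))
        rows <- sample(rows)
        fw <- net_forward(net, net_inputs(net, train, rows),
                          train = control$dropout, keep_cache = TRUE)
        y <- ytr[rows]
        grads <- net_backward(net, fw, y)
        t <- t + 1L
        up <- adam_step(net$params, grads, state, t, control, net$frozen)
        net$params <- up$params
        state <- up$state
        tr_loss <- tr_loss + net_loss(fw$probs, y)
      }
      vl <- net_loss(predict_probs(net, xval), yval)
      hist <- rbind(hist, data.frame(pass = pass,
                                     train_loss = tr_loss / steps_per_pass,
                                     val_loss = vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = net$params)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= control$patience) break
      }
    }
  })
  net$params <- best$params
  net$trained <- TRUE
  net$history <- hist
  net
}

# chunked inference; xs is a list of branch input matrices
predict_probs <- function(net, xs, chunk = 512L) {
  n <- nrow(xs[[1]])
  out <- matrix(NA_real_, n, net$spec$classes)
  at <- 1L
  while (at <= n) {
    rows <- at:min(n, at + chunk - 1L)
    out[rows, ] <- net_forward(net, lapply(xs, function(x)
      x[rows, , drop = FALSE]), train = FALSE)$probs
    at <- at + chunk
  }
  out
}

#' Convolutional branch features for a dataset
#'
#' Returns the flattened (concatenated, for fused models) convolutional
#' feature maps the dense head consumes; exposed so the fused network can
#' be verified as dense-head-on-frozen-features.
#'
#' @param net A `sleepwake_net`.
#' @param ds An [epoch_dataset] (valid epochs are used as given).
#' @return Numeric matrix, one row per epoch.
#' @export
net_features <- function(net, ds) {
  xs <- net_inputs(net, ds)
  bf <- lapply(seq_along(net$branches), function(i)
    branch_forward(xs[[i]], net$branches[[i]], net$params,
                   net$prefixes[i]))
  if (length(bf) == 1L) bf[[1]]$feat else cbind(bf[[1]]$feat, bf[[2]]$feat)
}

#' Number of trainable and frozen parameters
#' @param net A `sleepwake_net`.
#' @return Named numeric vector with `total`, `trainable`, `frozen` counts.
#' @export
count_params <- function(net) {
  sizes <- vapply(net$params, length, 0L)
  fr <- sum(sizes[names(sizes) %in% net$frozen])
  c(total = sum(sizes), trainable = sum(sizes) - fr, frozen = fr)
}

#' Per-epoch wake posteriors for a dataset
#'
#' Invalid epochs carry no posterior (`NA`); dropout is inactive, so
#' repeated calls are identical.
#'
#' @param net A trained `sleepwake_net`.
#' @param ds An [epoch_dataset].
#' @return A `posterior_series` data frame with columns `patient_id`,
#'   `epoch`, `valid`, `p_wake`.
#' @export
net_posteriors <- function(net, ds) {
  p <- rep(NA_real_, nrow(ds$meta))
  rows <- which(ds$meta$valid)
  if (length(rows))
    p[rows] <- predict_probs(net, net_inputs(net, ds, rows))[, 2L]
  structure(data.frame(patient_id = ds$meta$patient_id,
                       epoch = ds$meta$epoch,
                       valid = ds$meta$valid, p_wake = p,
                       stringsAsFactors = FALSE),
            class = c("posterior_series", "data.frame"))
}

#' Select the best of several trained models by test-set agreement
#'
#' Returns the candidate with the highest Cohen's kappa against the
#' reference labels of a fixed test set; ties are broken by the lowest
#' training seed.
#'
#' @param candidates List of trained `sleepwake_net` models.
#' @param test An [epoch_dataset] with reference labels.
#' @param threshold Posterior decision threshold (wake iff
#'   `p_wake >= threshold`).
#' @return The selected model, with its test kappa in `$selection_kappa`.
#' @export
select_model <- function(candidates, test, threshold = 0.5) {
  cs_assert(length(candidates) >= 1L, "no candidate models",
            "parameter_error")
  stats <- vapply(candidates, function(m) {
    ps <- net_posteriors(m, test)
    ok <- ps$valid
    cohen_kappa(as.integer(ps$p_wake[ok] >= threshold),
                test$meta$label[ok])
  }, 0)
  seeds <- vapply(candidates, function(m) as.numeric(m$seed), 0)
  best <- order(-stats, seeds)[1L]
  m <- candidates[[best]]
  m$selection_kappa <- stats[best]
  m
}
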