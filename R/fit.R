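#' Fit a single-epoch sleep-wake classifier
#'
#' The main modelling entry point. For the multimodal (default) fit, the
#' ECG and RIP branches are first trained as unimodal networks, then their
#' convolutional layers are fused with frozen weights and only the dense
#' head of the multimodal network is optimized. Training uses
#' class-balanced, shuffled batches of 16 valid epochs, Adam, dropout, and
#' early stopping on validation loss.
#'
#' @param train Training [epoch_dataset] (valid epochs of the weight
#'   -training patients).
#' @param val Validation [epoch_dataset]; if `NULL`, patients in `train`
#'   are split 70/30 with `seed`.
#' @param modality `"fused"` (ECG + RIP), `"ecg"` or `"rip"`.
#' @param spec Layer specification, see [default_layer_spec()].
#' @param control Optimizer settings, see [sleepwake_control()].
#' @param seed Integer seed; initialization, batch sampling and dropout
#'   all derive from it, so the fit is a pure function of
#'   `(data, spec, control, seed)`.
#' @return An object of class `sleepwake_cnn` with components `net` (the
#'   final network), `branch_nets` (trained unimodal models, fused fit
#'   only), `history`, `seed` and `call`.
#' @seealso [predict.sleepwake_cnn()], [patient_summary()], [detect_osa()]
#' @export
sleepwake_cnn <- function(train, val = NULL,
                          modality = c("fused", "ecg", "rip"),
                          spec = default_layer_spec(),
                          control = sleepwake_control(), seed = 1L) {
  modality <- match.arg(modality)
  cl <- match.call()
  if (is.null(val)) {
    ids <- unique(train$meta$patient_id)
    cs_assert(length(ids) >= 2L,
              "need at least two patients to auto-split train/val",
              "cohort_error")
    ids <- with_seed(seed, sample(ids))
    n_tr <- max(1L, round(0.7 * length(ids)))
    val <- subset_dataset(train, patients = ids[-seq_len(n_tr)])
    train <- subset_dataset(train, patients = ids[seq_len(n_tr)])
  }
  branch_nets <- NULL
  if (modality == "fused") {
    ecg_net <- train_net(build_unimodal("ecg", spec, seed = seed),
                         train, val, control, seed = seed)
    rip_net <- train_net(build_unimodal("rip", spec, seed = seed + 1L),
                         train, val, control, seed = seed + 1L)
    net <- train_net(fuse_multimodal(ecg_net, rip_net, seed = seed + 2L),
                     train, val, control, seed = seed + 2L)
    net$seed <- seed
    branch_nets <- list(ecg = ecg_net, rip = rip_net)
  } else {
    net <- train_net(build_unimodal(modality, spec, seed = seed),
                     train, val, control, seed = seed)
  }
  structure(list(net = net, branch_nets = branch_nets,
                 modality = modality, spec = spec, control = control,
                 history = net$history, seed = seed, call = cl),
            class = "sleepwake_cnn")
}

#' @export
print.sleepwake_cnn <- function(x, ...) {
  np <- count_params(x$net)
  cat(sprintf("Sleep-wake CNN (%s), %d parameters (%d frozen)\n",
              x$modality, np["total"], np["frozen"]))
  if (!is.null(x$history))
    cat(sprintf("  trained %d passes; best validation loss %.4f\n",
                max(x$history$pass), min(x$history$val_loss)))
  invisible(x)
}

#' @export
summary.sleepwake_cnn <- function(object, ...) {
  np <- count_params(object$net)
  out <- list(modality = object$modality, parameters = np,
              passes = if (is.null(object$history)) 0L else
                max(object$history$pass),
              best_val_loss = if (is.null(object$history)) NA_real_ else
                min(object$history$val_loss),
              seed = object$seed)
  class(out) <- "summary.sleepwake_cnn"
  out
}

#' @export
print.summary.sleepwake_cnn <- function(x, ...) {
  cat(sprintf("Sleep-wake CNN (%s)\n", x$modality))
  cat(sprintf("  parameters: %d total, %d trainable, %d frozen\n",
              x$parameters["total"], x$parameters["trainable"],
              x$parameters["frozen"]))
  cat(sprintf("  training passes: %d, best validation loss: %.4f, seed: %d\n",
              x$passes, x$best_val_loss, x$seed))
  invisible(x)
}

#' Network weights of a fitted sleep-wake CNN
#' @param object A `sleepwake_cnn`.
#' @param ... Unused.
#' @return Named list of weight matrices and bias vectors.
#' @export
coef.sleepwake_cnn <- function(object, ...) object$net$params

#' Per-epoch wake posteriors for new data
#'
#' @param object A fitted `sleepwake_cnn`.
#' @param newdata An [epoch_dataset].
#' @param type `"posterior"` for the `posterior_series` (default) or
#'   `"class"` for hard 0/1 labels at the 0.5 threshold.
#' @param ... Unused.
#' @return A `posterior_series` data frame or an integer label vector
#'   (`NA` for invalid epochs).
#' @export
predict.sleepwake_cnn <- function(object, newdata,
                                  type = c("posterior", "class"), ...) {
  type <- match.arg(type)
  ps <- net_posteriors(object$net, newdata)
  if (type == "posterior") return(ps)
  ifelse(ps$valid, as.integer(ps$p_wake >= 0.5), NA_integer_)
}

#' Plot training history of a fitted sleep-wake CNN
#' @param x A `sleepwake_cnn`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sleepwake_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$pass, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "training pass", ylab = "cross-entropy loss",
                    ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Simulate sleep-wake label sequences from the fitted posterior
#'
#' Draws per-epoch labels as independent Bernoulli variables with the
#' model's wake posterior; useful for posterior-predictive checks of
#' architecture metrics such as the transition percentage.
#'
#' @param object A fitted `sleepwake_cnn`.
#' @param nsim Number of simulated label sequences.
#' @param seed Integer seed.
#' @param newdata An [epoch_dataset].
#' @param ... Unused.
#' @return Matrix of `nsim` columns of 0/1 labels (`NA` on invalid
#'   epochs).
#' @export
simulate.sleepwake_cnn <- function(object, nsim = 1L, seed = 1L,
                                   newdata, ...) {
  ps <- net_posteriors(object$net, newdata)
  with_seed(seed, {
    sapply(seq_len(nsim), function(i)
      ifelse(ps$valid, stats::rbinom(length(ps$p_wake), 1L,
                                     ifelse(is.na(ps$p_wake), 0,
                                            ps$p_wake)), NA_integer_))
  })
}
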