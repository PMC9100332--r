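# Optimization: Adam with an epoch-indexed exponentially decaying learning
# rate, smoothed targets for both heads, per-epoch validation and patience-3
# early stopping on the validation loss.

#' Epoch-indexed learning rate schedule
#'
#' `lr(epoch) = 0.000012 * exp(2 - 0.03 * epoch) + 0.00008`: strictly
#' decreasing with limit 8e-5.
#'
#' @param epoch epoch number(s), 0-based, >= 0.
#' @return learning rate(s).
#' @export
lr_schedule <- function(epoch) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  0.000012 * exp(2 - 0.03 * epoch) + 0.00008
}

#' Label smoothing
#'
#' Binary targets become `1 - eps/2` / `eps/2`; K-class one-hot targets become
#' `1 - eps + eps/K` / `eps/K`. With eps = 0.1 this gives 0.95/0.05 for
#' verification and 0.903125/0.003125 for 32-class identification.
#'
#' @param target for `type = "binary"`, a 0/1 vector; for `"multiclass"`, either
#'   a one-hot matrix or an integer vector of class indices (with `K` classes).
#' @param eps smoothing amount in `[0, 1)`.
#' @param type target type.
#' @param K number of classes (needed when `target` is an index vector).
#' @return smoothed targets, same shape as the one-hot input.
#' @export
smooth_labels <- function(target, eps = 0.1, type = c("binary", "multiclass"),
                          K = NULL) {
  type <- match.arg(type)
  if (eps < 0 || eps >= 1) stop("eps must be in [0, 1)")
  if (type == "binary") {
    # algebraically target*(1-eps) + eps/2, arranged to round cleanly
    return(target + eps * (0.5 - target))
  }
  if (is.vector(target) && !is.matrix(target)) {
    if (is.null(K)) stop("K required for class-index targets")
    onehot <- matrix(0, length(target), K)
    onehot[cbind(seq_along(target), target)] <- 1
    target <- onehot
  }
  K <- ncol(target)
  target + eps * (1 / K - target)
}

#' Joint verification + identification loss
#'
#' Mean binary cross-entropy of the h verification probabilities against
#' smoothed binary targets, plus cross-entropy of the identification
#' distribution against the smoothed one-hot target, combined with unit
#' weights by default.
#'
#' @param outputs list with `verification` (h probabilities) and
#'   `identification` (h probabilities summing to 1), as returned by
#'   [model_classify()].
#' @param q true scope position (1..h).
#' @param eps label smoothing amount.
#' @param weights length-2 weights for (verification, identification) terms.
#' @return scalar loss.
#' @export
joint_loss <- function(outputs, q, eps = 0.1, weights = c(1, 1)) {
  pv <- as.numeric(outputs$verification)
  pid <- as.numeric(outputs$identification)
  h <- length(pv)
  tv <- smooth_labels(as.numeric(seq_len(h) == q), eps)
  tid <- smooth_labels(q, eps, "multiclass", K = h)
  e <- 1e-12
  bce <- -mean(tv * log(pv + e) + (1 - tv) * log(1 - pv + e))
  ce <- -sum(tid * log(pid + e))
  weights[1] * bce + weights[2] * ce
}

#' Combined accuracy monitor
#'
#' The arithmetic mean of verification TPR, verification FPR and identification
#' accuracy, exactly as defined for training monitoring. Including the raw FPR
#' (rather than 1 - FPR) in a mean of accuracies is unusual but intentional
#' here; `corrected = TRUE` gives `mean(TPR, 1 - FPR, accuracy)` for sanity
#' monitoring.
#'
#' @param ver_tpr,ver_fpr,id_acc rates in `[0, 1]`.
#' @param corrected use `1 - FPR` instead of `FPR`.
#' @return scalar.
#' @export
combined_accuracy <- function(ver_tpr, ver_fpr, id_acc, corrected = FALSE) {
  stopifnot(all(c(ver_tpr, ver_fpr, id_acc) >= 0),
            all(c(ver_tpr, ver_fpr, id_acc) <= 1))
  mean(c(ver_tpr, if (corrected) 1 - ver_fpr else ver_fpr, id_acc))
}

#' Training configuration
#'
#' Full-scale defaults: batch 512, 256 steps per epoch, Adam with beta1 = 0.9,
#' beta2 = 0.98, eps = 1e-9, label smoothing 0.1, patience 3. `lr_multiplier`
#' scales the whole [lr_schedule()]; desk-scale models train with a larger
#' multiplier because the schedule's absolute level is tuned to the full-width
#' network.
#'
#' @param batch_size examples per step.
#' @param steps_per_epoch training steps per epoch.
#' @param adam_beta1,adam_beta2,adam_eps Adam moments/epsilon.
#' @param label_smoothing smoothing eps for both heads.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs hard cap on epochs.
#' @param lr_multiplier multiplies [lr_schedule()].
#' @param warmup_steps linear learning-rate warmup over this many initial steps
#'   (0 disables; the epoch-level schedule is unchanged).
#' @param clip_grad global-norm gradient clipping threshold (`NULL` = off).
#' @param bn_recalibrate re-estimate batch-norm population statistics from a
#'   few training batches before each validation pass, so evaluation-mode
#'   normalization tracks the current parameters.
#' @param loss_weights weights of (verification, identification) loss terms.
#' @param seed seed for shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 512L, steps_per_epoch = 256L,
                         adam_beta1 = 0.9, adam_beta2 = 0.98, adam_eps = 1e-9,
                         label_smoothing = 0.1, patience = 3L, max_epochs = 1000L,
                         lr_multiplier = 1, warmup_steps = 0L, clip_grad = NULL,
                         bn_recalibrate = TRUE, loss_weights = c(1, 1), seed = 1L) {
  stopifnot(batch_size >= 1, steps_per_epoch >= 1, patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, label_smoothing = label_smoothing,
                 patience = as.integer(patience), max_epochs = as.integer(max_epochs),
                 lr_multiplier = lr_multiplier, warmup_steps = as.integer(warmup_steps),
                 clip_grad = clip_grad, bn_recalibrate = bn_recalibrate,
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "train_config")
}

# Re-estimate batch-norm population statistics as the plain average of batch
# statistics over a few training batches (momentum 1/j gives an incremental
# mean), leaving parameters untouched.
.bn_recalibrate <- function(model, dataset, n_batches = 4L, batch_size = 32L) {
  model$bn <- .bn_reset(model$bn)
  model$config$dropout <- 0   # statistics without dropout noise
  n <- dataset$count
  for (j in seq_len(n_batches)) {
    idx <- (((j - 1L) * batch_size):(j * batch_size - 1L)) %% n + 1L
    segs <- .batch_segs(dataset, idx)
    fw <- .network_fwd(model, segs, B = length(idx), h = dataset$scope_size,
                       train = TRUE, bn_momentum = 1 / j)
    model$bn <- fw$bn
  }
  model$bn
}

# assemble the (B*(h+1)) x 384 segment matrix for a set of example indices
.batch_segs <- function(dataset, idx) {
  B <- length(idx); h <- dataset$scope_size
  segs <- matrix(0, B * (h + 1L), dim(dataset$J)[3])
  for (j in seq_len(B)) {
    r0 <- (j - 1L) * (h + 1L)
    segs[(r0 + 1L):(r0 + h), ] <- dataset$J[idx[j], , ]
    segs[r0 + h + 1L, ] <- dataset$query[idx[j], ]
  }
  segs
}

# eval-mode pass over a dataset: joint loss + monitoring metrics
.evaluate_dataset <- function(model, dataset, eps_ls, weights, chunk = 64L) {
  n <- dataset$count
  h <- dataset$scope_size
  tot_bce <- 0; tot_ce <- 0
  pred <- integer(n)
  tp <- 0; fn <- 0; fp <- 0; tn <- 0
  e <- 1e-12
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    segs <- .batch_segs(dataset, idx)
    fw <- .network_fwd(model, segs, B = length(idx), h = h, train = FALSE)
    q <- dataset$label[idx]
    tver <- matrix(eps_ls / 2, length(idx), h)
    tver[cbind(seq_along(idx), q)] <- 1 - eps_ls / 2
    tid <- matrix(eps_ls / h, length(idx), h)
    tid[cbind(seq_along(idx), q)] <- 1 - eps_ls + eps_ls / h
    tot_bce <- tot_bce - sum(tver * log(fw$verification + e) +
                               (1 - tver) * log(1 - fw$verification + e)) / h
    tot_ce <- tot_ce - sum(tid * log(fw$identification + e))
    pred[idx] <- max.col(fw$identification, ties.method = "first")
    pos <- cbind(seq_along(idx), q)
    dec <- fw$verification >= 0.5
    tp <- tp + sum(dec[pos]); fn <- fn + sum(!dec[pos])
    dec[pos] <- NA
    fp <- fp + sum(dec, na.rm = TRUE); tn <- tn + sum(!dec, na.rm = TRUE)
  }
  list(loss = weights[1] * tot_bce / n + weights[2] * tot_ce / n,
       id_acc = mean(pred == dataset$label),
       ver_tpr = tp / max(1, tp + fn), ver_fpr = fp / max(1, fp + tn))
}

#' Train a model
#'
#' Adam updates with [lr_schedule()] (times `lr_multiplier`), dropout active,
#' smoothed targets on both heads. The dataset is shuffled and cycled; after
#' every epoch the joint loss and accuracy metrics are computed on the
#' validation set in evaluation mode, and training stops when the validation
#' loss has not improved for `patience` consecutive epochs (or at
#' `max_epochs`). The returned model carries the parameters of the
#' best-validation-loss epoch.
#'
#' @param model a `scope_model` from [model_init()].
#' @param train_ds,val_ds `ecg_dataset`s with segment arrays; their scope sizes
#'   must match.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (best parameters), `history` (per-epoch
#'   data.frame: losses, validation metrics, learning rate), `epochs_run` and
#'   `best_epoch`.
#' @export
train_model <- function(model, train_ds, val_ds, config = train_config(),
                        verbose = FALSE) {
  if (is.null(train_ds$J) || train_ds$count < 1) stop("empty training dataset")
  if (is.null(val_ds$J) || val_ds$count < 1) stop("empty validation dataset")
  h <- train_ds$scope_size
  opt <- .adam_init(model$params)
  best <- list(loss = Inf, params = model$params, bn = model$bn, epoch = NA_integer_)
  hist <- list()
  .with_seed(config$seed, {
    order_ <- sample.int(train_ds$count)
    cursor <- 1L
    next_batch <- function() {
      idx <- integer(0)
      while (length(idx) < config$batch_size) {
        take <- min(config$batch_size - length(idx), train_ds$count - cursor + 1L)
        idx <- c(idx, order_[cursor:(cursor + take - 1L)])
        cursor <<- cursor + take
        if (cursor > train_ds$count) { order_ <<- sample.int(train_ds$count); cursor <<- 1L }
      }
      idx
    }
    bad_epochs <- 0L
    gstep <- 0L
    for (epoch in seq_len(config$max_epochs) - 1L) {
      lr_epoch <- config$lr_multiplier * lr_schedule(epoch)
      ep_loss <- 0
      for (step in seq_len(config$steps_per_epoch)) {
        gstep <- gstep + 1L
        lr <- lr_epoch * if (config$warmup_steps > 0L)
          min(1, gstep / config$warmup_steps) else 1
        idx <- next_batch()
        segs <- .batch_segs(train_ds, idx)
        res <- .network_grad(model, segs, B = length(idx), h = h,
                             q = train_ds$label[idx],
                             eps_ls = config$label_smoothing,
                             loss_weights = config$loss_weights)
        if (!is.finite(res$loss))
          stop("non-finite training loss at epoch ", epoch, " step ", step,
               " (ver=", res$loss_ver, ", id=", res$loss_id, ")")
        model$bn <- res$bn
        grads <- if (!is.null(config$clip_grad))
          .clip_grads(res$grads, config$clip_grad) else res$grads
        upd <- .adam_step(model$params, grads, opt, lr,
                          config$adam_beta1, config$adam_beta2, config$adam_eps)
        model$params <- upd$params
        opt <- upd$opt
        ep_loss <- ep_loss + res$loss
      }
      if (config$bn_recalibrate)
        model$bn <- .bn_recalibrate(model, train_ds,
                                    batch_size = min(config$batch_size, 32L))
      val <- .evaluate_dataset(model, val_ds, config$label_smoothing,
                               config$loss_weights)
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / config$steps_per_epoch,
        val_loss = val$loss, val_id_acc = val$id_acc,
        val_ver_tpr = val$ver_tpr, val_ver_fpr = val$ver_fpr,
        val_combined = combined_accuracy(val$ver_tpr, val$ver_fpr, val$id_acc),
        lr = lr_epoch)
      if (verbose)
        message(sprintf("epoch %d: train %.4f | val %.4f | id acc %.3f | lr %.2e",
                        epoch, ep_loss / config$steps_per_epoch, val$loss,
                        val$id_acc, lr))
      if (val$loss < best$loss) {
        best <- list(loss = val$loss, params = model$params, bn = model$bn,
                     epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$bn <- best$bn
  list(model = model, history = do.call(rbind, hist),
       epochs_run = length(hist), best_epoch = best$epoch)
}
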