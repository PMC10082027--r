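#' Numerically stable softmax
#'
#' @param logits finite numeric vector.
#' @return probability vector summing to 1; invariant to adding a
#'   constant to all logits (the maximum is subtracted before
#'   exponentiation).
#' @export
softmax <- function(logits) {
  if (!all(is.finite(logits))) stop("softmax: logits must be finite")
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Cross-entropy loss
#'
#' `-log` of the probability assigned to the true class, with the
#' probability clipped below at `1e-12`.
#'
#' @param probabilities probability vector (or `N x K` matrix of rows).
#' @param target one-hot vector (or matrix), or an integer 0-based label
#'   (or vector of labels).
#' @return mean loss over the batch (scalar).
#' @export
cross_entropy_loss <- function(probabilities, target) {
  p <- rbind(probabilities)
  if (is.matrix(target)) {
    idx <- max.col(rbind(target))
  } else if (length(target) == ncol(p) && nrow(p) == 1L &&
             sum(target) == 1 && all(target %in% c(0, 1))) {
    idx <- which(target == 1)
  } else {
    idx <- as.integer(target) + 1L
  }
  ptrue <- pmax(p[cbind(seq_len(nrow(p)), idx)], 1e-12)
  mean(-log(ptrue))
}

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with initial learning rate
#' 0.001 and batch size 4, at most 65 epochs, learning rate halved after 5
#' epochs without a validation-accuracy improvement of at least 1e-4, and
#' early stopping with patience 30 restoring the best weights.
#'
#' @param initial_lr initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs maximum number of epochs.
#' @param plateau_factor multiplicative learning-rate decay factor.
#' @param plateau_patience epochs without improvement before decay.
#' @param min_delta minimum increase in validation accuracy that counts
#'   as an improvement.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param seed RNG seed covering data order and all training randomness.
#' @param checkpoint_path optional file; the best weights seen so far are
#'   saved there whenever validation accuracy improves.
#' @param shuffle shuffle the training order each epoch.
#' @param stop_at_monitor optional level of the monitored (validation)
#'   accuracy at which the loop ends early — used by overfit sanity
#'   checks, where the monitored set is the training subset itself;
#'   `NULL` disables.
#' @return an object of class `rccg_train_config`.
#' @export
train_config <- function(initial_lr = 0.001, batch_size = 4L,
                         max_epochs = 65L, plateau_factor = 0.5,
                         plateau_patience = 5L, min_delta = 1e-4,
                         early_stop_patience = 30L, seed = 1L,
                         checkpoint_path = NULL, shuffle = TRUE,
                         stop_at_monitor = NULL) {
  stopifnot(plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1, early_stop_patience >= 1)
  structure(list(initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_delta = min_delta,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 checkpoint_path = checkpoint_path,
                 shuffle = isTRUE(shuffle),
                 stop_at_monitor = stop_at_monitor),
            class = "rccg_train_config")
}

#' Fresh training state
#'
#' @param cfg a [train_config()].
#' @return a `rccg_train_state` list tracking the learning rate, the best
#'   monitored value, independent plateau and early-stop counters, the
#'   best-weight snapshot, and the per-epoch history.
#' @export
train_state <- function(cfg = train_config()) {
  structure(list(epoch = 0L, lr = cfg$initial_lr,
                 plateau_best = -Inf, plateau_wait = 0L,
                 best_value = -Inf, es_wait = 0L,
                 best_weights = NULL, stopped = FALSE,
                 history = NULL),
            class = "rccg_train_state")
}

#' Reduce the learning rate on a validation plateau
#'
#' An improvement is `val_acc > best + min_delta`.  After
#' `plateau_patience` consecutive epochs without improvement the learning
#' rate is multiplied by `plateau_factor` (0.5: each change is exactly a
#' halving) and the counter resets; there is no lower floor.
#'
#' @param state a `rccg_train_state`.
#' @param val_acc validation accuracy of the finished epoch.
#' @param cfg a [train_config()].
#' @return the updated state.
#' @export
reduce_lr_on_plateau <- function(state, val_acc, cfg) {
  if (val_acc > state$plateau_best + cfg$min_delta) {
    state$plateau_best <- val_acc
    state$plateau_wait <- 0L
  } else {
    state$plateau_wait <- state$plateau_wait + 1L
    if (state$plateau_wait >= cfg$plateau_patience) {
      state$lr <- state$lr * cfg$plateau_factor
      state$plateau_wait <- 0L
    }
  }
  state
}

#' Early stopping and best-weight checkpointing
#'
#' On improvement (same `min_delta` rule as the plateau callback) the
#' current weights are snapshotted and, if a checkpoint path is
#' configured, persisted.  After `early_stop_patience` epochs without
#' improvement the stop flag is set; [train_model()] then restores the
#' snapshot.
#'
#' @param state a `rccg_train_state`.
#' @param val_acc validation accuracy of the finished epoch.
#' @param weights the model snapshot to checkpoint: the trainable
#'   parameters together with the batch-norm running statistics
#'   (restoring one without the other would mismatch normalization).
#' @param cfg a [train_config()].
#' @return the updated state.
#' @export
early_stop_and_checkpoint <- function(state, val_acc, weights, cfg) {
  if (val_acc > state$best_value + cfg$min_delta) {
    state$best_value <- val_acc
    state$es_wait <- 0L
    state$best_weights <- weights
    if (!is.null(cfg$checkpoint_path)) {
      ok <- tryCatch({
        saveRDS(weights, cfg$checkpoint_path)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) stop("could not write checkpoint to ", cfg$checkpoint_path)
    }
  } else {
    state$es_wait <- state$es_wait + 1L
    if (state$es_wait >= cfg$early_stop_patience) state$stopped <- TRUE
  }
  state
}

# ---- Adam ------------------------------------------------------------------

.adam_new <- function(flat) {
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-7)
}

.adam_step <- function(opt, flat, grads, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(opt = opt, flat = flat)
}

# ---- training loop ---------------------------------------------------------

#' Bundle patches into a patch set
#'
#' @param x `H x W x 3 x N` array of normalized patches.
#' @param y integer vector of 0-based grade labels.
#' @param source_id optional character vector of originating image ids.
#' @return a `rccg_patch_set`.
#' @export
patch_set <- function(x, y, source_id = NULL) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[4L] != length(y)) stop("x and y disagree on the sample count")
  structure(list(x = x, y = as.integer(y),
                 source_id = source_id %||% as.character(seq_along(y))),
            class = "rccg_patch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Loss and accuracy of a model on a patch set
#'
#' @param model an `rccg_model`.
#' @param set a [patch_set()].
#' @param batch_size forward-pass micro-batch size.
#' @return list with `loss`, `accuracy`, `proba` and `predicted`.
#' @export
evaluate_patch_set <- function(model, set, batch_size = 16L) {
  proba <- predict_proba(model, set$x, batch_size)
  pred <- max.col(proba) - 1L
  list(loss = cross_entropy_loss(proba, set$y),
       accuracy = mean(pred == set$y),
       proba = proba, predicted = pred)
}

#' Train a model
#'
#' Minibatch training with Adam and softmax cross-entropy, monitoring
#' validation accuracy with the two callbacks
#' ([reduce_lr_on_plateau()] and [early_stop_and_checkpoint()]).  After
#' the final epoch the best weights seen on validation are restored.  All
#' randomness (data order) is derived from `cfg$seed`, so two runs from
#' the same initial model and configuration are identical.
#'
#' @param model an `rccg_model`.
#' @param train a [patch_set()] used for gradient updates.
#' @param validation a [patch_set()] monitored by the callbacks.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and the final `state` (whose
#'   `history` data frame has columns epoch, loss, accuracy, val_loss,
#'   val_accuracy, lr).
#' @export
train_model <- function(model, train, validation, cfg = train_config(),
                        verbose = FALSE) {
  if (length(train$y) == 0L || length(validation$y) == 0L)
    stop("train and validation sets must be non-empty")
  set.seed(cfg$seed)
  state <- train_state(cfg)
  flat <- flatten_params(model)
  opt <- .adam_new(flat)
  n <- length(train$y)
  K <- model$config$num_classes
  hist_rows <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    tot_loss <- 0
    tot_correct <- 0L
    for (s in seq(1L, n, by = cfg$batch_size)) {
      take <- idx[s:min(s + cfg$batch_size - 1L, n)]
      xb <- train$x[, , , take, drop = FALSE]
      yb <- train$y[take]
      fw <- net_forward(model, xb, training = TRUE)
      model <- fw$model
      logits <- fw$logits  # K x nb
      nb <- length(take)
      p <- apply(logits, 2L, softmax)
      onehot <- matrix(0, K, nb)
      onehot[cbind(yb + 1L, seq_len(nb))] <- 1
      tot_loss <- tot_loss + sum(-log(pmax(p[onehot == 1], 1e-12)))
      tot_correct <- tot_correct + sum(max.col(t(p)) - 1L == yb)
      dlogits <- (p - onehot) / nb
      bw <- net_backward(model, fw$caches, dlogits)
      gflat <- flatten_grads(model, bw$grads)
      stepped <- .adam_step(opt, flat, gflat, state$lr)
      opt <- stepped$opt
      flat <- stepped$flat
      model <- set_flat_params(model, flat)
    }
    val <- evaluate_patch_set(model, validation,
                              batch_size = max(cfg$batch_size, 16L))
    state$epoch <- epoch
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = tot_loss / n, accuracy = tot_correct / n,
      val_loss = val$loss, val_accuracy = val$accuracy, lr = state$lr)
    if (verbose)
      message(sprintf(
        "epoch %3d  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f  lr %g",
        epoch, tot_loss / n, tot_correct / n, val$loss, val$accuracy,
        state$lr))
    state <- reduce_lr_on_plateau(state, val$accuracy, cfg)
    state <- early_stop_and_checkpoint(state, val$accuracy,
                                       model_snapshot(model), cfg)
    if (state$stopped) break
    if (!is.null(cfg$stop_at_monitor) &&
        val$accuracy >= cfg$stop_at_monitor) break
  }
  state$history <- do.call(rbind, hist_rows)
  if (!is.null(state$best_weights))
    model <- restore_snapshot(model, state$best_weights)
  list(model = model, state = state)
}
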