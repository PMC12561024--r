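# Optimisation loop, LR scheduling, checkpoint selection, k-fold
# cross-validation and the probability-averaged fold ensemble.

#' Training configuration
#'
#' @param total_epochs epochs per fold.
#' @param batch_size minibatch size.
#' @param lr initial learning rate (AdamW).
#' @param weight_decay decoupled weight decay (AdamW).
#' @param scheduler_factor multiplicative LR reduction on plateau.
#' @param scheduler_patience consecutive non-improving validation-loss
#'   epochs before the LR is reduced.
#' @param n_folds number of cross-validation folds.
#' @param seed global seed controlling fold assignment, shuffling,
#'   augmentation and weight initialisation.
#' @param schedule a [loss_schedule()]; default warm-up 10 epochs, 50:50 at
#'   the last epoch.
#' @param skel_params [soft_skeleton_params()] for the soft clDice loss.
#' @param augment an [augment_config()], or `NULL` to disable augmentation.
#' @param model_cfg a [unext_config()].
#' @param combine fold-combination rule of the resulting ensemble.
#' @export
train_config <- function(total_epochs = 60L, batch_size = 8L, lr = 1e-3,
                         weight_decay = 5e-4, scheduler_factor = 0.5,
                         scheduler_patience = 3L, n_folds = 5L, seed = 1L,
                         schedule = loss_schedule(total_epochs),
                         skel_params = soft_skeleton_params(),
                         augment = augment_config(),
                         model_cfg = unext_config(),
                         combine = c("uniform", "val_cldice")) {
  stopifnot(lr > 0, weight_decay >= 0, scheduler_patience >= 1, n_folds >= 2,
            total_epochs >= 1, batch_size >= 1,
            schedule$total_epochs == total_epochs)
  combine <- match.arg(combine)
  structure(list(total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 schedule = schedule, skel_params = skel_params,
                 augment = augment, model_cfg = model_cfg,
                 combine = combine),
            class = "train_config")
}

# ------------------------------------------------------------------ AdamW ---

adamw_new <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p$v * 0)
  st$v <- lapply(params, function(p) p$v * 0)
  st
}

adamw_step <- function(params, st, lr, wd, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * p$g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * p$g * p$g
    p$v <- p$v - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps) -
      lr * wd * p$v
    p$g <- NULL
  }
  invisible(NULL)
}

# --------------------------------------------------------------- training ---

# pairs: list of list(frame=<matrix|bmode_frame>, label=<0/1 matrix>, ...)
pair_pixels <- function(p) {
  if (inherits(p$frame, "bmode_frame")) p$frame$pixels else p$frame
}

pairs_to_batch <- function(pairs, idx) {
  d <- dim(pair_pixels(pairs[[idx[1]]]))
  x <- array(0, dim = c(d[1], d[2], 1, length(idx)))
  y <- array(0, dim = c(d[1], d[2], 1, length(idx)))
  for (k in seq_along(idx)) {
    x[, , 1, k] <- pair_pixels(pairs[[idx[k]]])
    y[, , 1, k] <- pairs[[idx[k]]]$label
  }
  list(x = x, y = y)
}

# evaluation-mode forward over a pair list; returns list of prob matrices
predict_probs <- function(model, pairs, batch_size = 16L) {
  out <- vector("list", length(pairs))
  idx0 <- seq_along(pairs)
  for (bs in split(idx0, ceiling(idx0 / batch_size))) {
    b <- pairs_to_batch(pairs, bs)
    z <- unext_forward(model, b$x, training = FALSE)$v
    for (k in seq_along(bs)) out[[bs[k]]] <- cpp_sigmoid(z[, , 1, k])
  }
  out
}

validate_model <- function(model, val_pairs, w, cfg, threshold = 0.5) {
  probs <- predict_probs(model, val_pairs)
  # blended loss on validation (evaluation mode, no tape)
  vloss <- 0
  idx0 <- seq_along(val_pairs)
  for (bs in split(idx0, ceiling(idx0 / 16L))) {
    b <- pairs_to_batch(val_pairs, bs)
    z <- unext_forward(model, b$x, training = FALSE)$v
    l <- w[["wbce"]] * cpp_wbce(z, b$y, cfg$schedule$pos_weight)$loss
    if (w[["cldice"]] > 0)
      l <- l + w[["cldice"]] *
        soft_cldice_loss(cpp_sigmoid(z), b$y, cfg$skel_params)
    vloss <- vloss + l * length(bs)
  }
  vloss <- vloss / length(val_pairs)
  cd <- vapply(seq_along(val_pairs), function(i) {
    cl_dice((probs[[i]] >= threshold) * 1, val_pairs[[i]]$label)$cl_dice
  }, 0)
  list(loss = vloss, cl_dice = mean(cd))
}

#' Train the network on one fold
#'
#' Runs `total_epochs` of AdamW on the blended WBCE / soft-clDice loss.
#' The learning rate is halved whenever the validation loss has not improved
#' for `scheduler_patience` consecutive epochs; the returned checkpoint is
#' the epoch with the highest validation (hard) centerline Dice -- the
#' scheduler and the checkpoint deliberately track different quantities.
#' Validation metrics are computed on un-augmented images.
#'
#' @param train_pairs,val_pairs disjoint lists of `list(frame, label)`.
#' @param cfg a [train_config()].
#' @param model optionally a pre-built [unext()] model (else one is
#'   initialised from `cfg$model_cfg`).
#' @param verbose print one line per epoch.
#' @return list with `state` (best checkpoint, a [unext_state()]),
#'   `history` (one row per epoch), `best_epoch`, `best_val_cldice`.
#' @export
train_fold <- function(train_pairs, val_pairs, cfg, model = NULL,
                       verbose = FALSE) {
  stopifnot(length(train_pairs) > 0, length(val_pairs) > 0)
  if (is.null(model)) model <- unext(cfg$model_cfg)
  params <- unext_params(model)
  opt <- adamw_new(params)
  lr <- cfg$lr
  best_cd <- -Inf; best_state <- NULL; best_epoch <- 0L
  best_vloss <- Inf; bad <- 0L
  hist <- vector("list", cfg$total_epochs)
  for (epoch in seq_len(cfg$total_epochs)) {
    w <- blend_weights(epoch, cfg$schedule)
    ep_pairs <- train_pairs
    if (!is.null(cfg$augment) && cfg$augment$augment_fraction > 0) {
      ep_pairs <- lapply(train_pairs, function(p) {
        a <- augment_pair(pair_pixels(p), p$label, cfg$augment)
        list(frame = a$frame, label = a$mask)
      })
    }
    ord <- sample(length(ep_pairs))
    tloss <- 0; nb <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      b <- pairs_to_batch(ep_pairs, bs)
      ag_tape_start()
      z <- unext_forward(model, b$x, training = TRUE)
      loss <- compound_loss_node(z, b$y, w, cfg$schedule, cfg$skel_params)
      lv <- loss$v
      if (!is.finite(lv)) {
        ag_tape_stop()
        stop(sprintf("non-finite training loss at epoch %d (loss=%g)",
                     epoch, lv))
      }
      ag_backward(loss)
      adamw_step(params, opt, lr, cfg$weight_decay)
      tloss <- tloss + lv; nb <- nb + 1
    }
    val <- validate_model(model, val_pairs, w, cfg)
    if (val$loss < best_vloss - 1e-10) {
      best_vloss <- val$loss; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$scheduler_patience) {
        lr <- lr * cfg$scheduler_factor
        bad <- 0L
      }
    }
    if (val$cl_dice > best_cd) {
      best_cd <- val$cl_dice
      best_state <- unext_state(model)
      best_epoch <- epoch
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tloss / nb,
                                val_loss = val$loss,
                                val_cl_dice = val$cl_dice, lr = lr,
                                w_wbce = w[["wbce"]], w_cldice = w[["cldice"]])
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val clDice %.3f  lr %.2e",
                      epoch, tloss / nb, val$loss, val$cl_dice, lr))
  }
  list(state = best_state, history = do.call(rbind, hist),
       best_epoch = best_epoch, best_val_cldice = best_cd)
}

#' Cross-validated training of a fold ensemble
#'
#' Assigns groups (patients) to `n_folds` folds, trains one model per fold
#' (validating on the held-in fold's groups) and returns the ensemble whose
#' prediction is the (optionally validation-clDice-weighted) mean of the
#' per-fold sigmoid probabilities -- the "weighted model".
#'
#' @param pairs list of `list(frame, label, meta)` where `meta$group_id`
#'   identifies the group (as produced by [load_manifest_pairs()]); a plain
#'   `group` element is also honoured.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `fold_ensemble`.
#' @export
crossval_unext <- function(pairs, cfg, verbose = FALSE) {
  gids <- vapply(pairs, function(p) {
    if (!is.null(p$meta$group_id)) as.character(p$meta$group_id)
    else if (!is.null(p$group)) as.character(p$group)
    else stop("pairs must carry a group id")
  }, "")
  set.seed(cfg$seed)
  gu <- sample(unique(gids))
  if (length(gu) < cfg$n_folds) stop("fewer groups than folds")
  fold_of <- stats::setNames(rep(seq_len(cfg$n_folds), length.out = length(gu)), gu)
  models <- vector("list", cfg$n_folds)
  hists <- vector("list", cfg$n_folds)
  scores <- numeric(cfg$n_folds)
  for (k in seq_len(cfg$n_folds)) {
    val_idx <- which(fold_of[gids] == k)
    tr_idx <- setdiff(seq_along(pairs), val_idx)
    set.seed(cfg$seed * 1000L + k)
    fit <- train_fold(pairs[tr_idx], pairs[val_idx], cfg, verbose = verbose)
    models[[k]] <- fit$state
    hists[[k]] <- fit$history
    scores[k] <- fit$best_val_cldice
    if (verbose)
      message(sprintf("fold %d/%d: best val clDice %.3f (epoch %d)",
                      k, cfg$n_folds, scores[k], fit$best_epoch))
  }
  structure(list(fold_states = models, fold_scores = scores,
                 histories = hists, model_cfg = cfg$model_cfg,
                 combine = cfg$combine, threshold = 0.5,
                 fold_of = fold_of, train_cfg = cfg),
            class = "fold_ensemble")
}

ensemble_models <- function(ensemble) {
  lapply(ensemble$fold_states, function(st) {
    m <- unext(st$cfg)
    unext_load_state(m, st)
  })
}

#' Ensemble prediction by probability averaging
#'
#' @param ensemble a `fold_ensemble` from [crossval_unext()].
#' @param frames matrix, list of matrices/`bmode_frame`s, or 4-d batch.
#' @param threshold binarisation threshold on the averaged probability.
#' @return list with `prob` (list of probability matrices) and `mask`
#'   (list of binary masks).
#' @export
ensemble_predict <- function(ensemble, frames, threshold = NULL) {
  stopifnot(inherits(ensemble, "fold_ensemble"),
            length(ensemble$fold_states) > 0)
  if (is.null(threshold)) threshold <- ensemble$threshold
  x <- frames_to_batch(frames)
  wts <- if (identical(ensemble$combine, "val_cldice")) {
    s <- pmax(ensemble$fold_scores, 1e-8); s / sum(s)
  } else rep(1 / length(ensemble$fold_states), length(ensemble$fold_states))
  acc <- NULL
  for (k in seq_along(ensemble$fold_states)) {
    m <- unext(ensemble$fold_states[[k]]$cfg)
    unext_load_state(m, ensemble$fold_states[[k]])
    p <- cpp_sigmoid(unext_forward(m, x, training = FALSE)$v)
    acc <- if (is.null(acc)) wts[k] * p else acc + wts[k] * p
  }
  probs <- lapply(seq_len(dim(acc)[4]), function(n) acc[, , 1, n])
  list(prob = probs, mask = lapply(probs, function(p) (p >= threshold) * 1L))
}

#' @export
predict.fold_ensemble <- function(object, frames,
                                  type = c("prob", "mask"),
                                  threshold = NULL, ...) {
  type <- match.arg(type)
  r <- ensemble_predict(object, frames, threshold)
  if (type == "prob") r$prob else r$mask
}

#' @export
print.fold_ensemble <- function(x, ...) {
  cat(sprintf("Fold ensemble: %d models (%s combination, threshold %.2f)\n",
              length(x$fold_states), x$combine, x$threshold))
  cat(sprintf("  per-fold best validation clDice: %s\n",
              paste(sprintf("%.3f", x$fold_scores), collapse = ", ")))
  invisible(x)
}

#' @export
summary.fold_ensemble <- function(object, ...) {
  data.frame(fold = seq_along(object$fold_scores),
             best_val_cl_dice = object$fold_scores,
             best_epoch = vapply(object$histories, function(h)
               h$epoch[which.max(h$val_cl_dice)], 0))
}
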