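#' Training configuration
#'
#' Defaults follow the study protocol: Adam with L2 weight decay
#' `1e-4`, initial learning rate `0.001` decaying by a factor `0.95` every
#' `500` optimizer steps (continuous exponent), batch size `6`, at most
#' `100` epochs with early stopping after `5` epochs without validation
#' improvement, and batch-normalization epsilon `0.001` / momentum `0.99`.
#'
#' @param lr_initial,decay_rate,decay_step Learning-rate schedule.
#' @param weight_decay L2 penalty coefficient added to weight gradients.
#' @param batch_size,max_epochs,patience Loop control.
#' @param norm_epsilon,norm_momentum Batch-normalization constants.
#' @param eps_clip Probability clamp for the cross-entropy logs.
#' @param dice_smooth Smoothing constant of the soft Dice loss.
#' @param seed RNG seed for shuffling and initialization.
#' @return A `train_config`.
#' @export
train_config <- function(lr_initial = 0.001, decay_rate = 0.95,
                         decay_step = 500, weight_decay = 1e-4,
                         batch_size = 6L, max_epochs = 100L, patience = 5L,
                         norm_epsilon = 0.001, norm_momentum = 0.99,
                         eps_clip = 1e-7, dice_smooth = 1, seed = 1L) {
  stopifnot(lr_initial > 0, decay_rate > 0, decay_step > 0, weight_decay >= 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1,
            patience <= max_epochs, norm_epsilon > 0, norm_momentum > 0)
  structure(list(lr_initial = lr_initial, decay_rate = decay_rate,
                 decay_step = decay_step, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 norm_epsilon = norm_epsilon, norm_momentum = norm_momentum,
                 eps_clip = eps_clip, dice_smooth = dice_smooth,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Pixelwise binary cross-entropy loss
#'
#' Mean over pixels of `-[y log p + (1 - y) log(1 - p)]`, with predictions
#' clamped to `[eps_clip, 1 - eps_clip]` before taking logs.
#'
#' @param y Binary label array.
#' @param p Probability array of the same shape.
#' @param eps_clip Clamp for the log arguments.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(y, p, eps_clip = 1e-7) {
  if (!identical(dim(y) %||% length(y), dim(p) %||% length(p)))
    stop("shape mismatch between labels and predictions")
  pc <- pmin(pmax(p, eps_clip), 1 - eps_clip)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(x * y) + s) / (sum(x) + sum(y) + s)` with smoothing
#' constant `s`; lies in `[0, 1]` and vanishes for identical masks.
#'
#' @param x Binary label array.
#' @param y Prediction array in `[0, 1]`.
#' @param smooth Smoothing constant `s`.
#' @return Scalar in `[0, 1]`.
#' @export
dice_loss <- function(x, y, smooth = 1) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("shape mismatch between labels and predictions")
  1 - (2 * sum(x * y) + smooth) / (sum(x) + sum(y) + smooth)
}

#' Combined segmentation loss
#'
#' The training loss `L = L_ce + L_Dice`, the plain sum of
#' [cross_entropy_loss()] and [dice_loss()].
#'
#' @inheritParams cross_entropy_loss
#' @param smooth Dice smoothing constant.
#' @return Scalar loss.
#' @export
total_loss <- function(y, p, eps_clip = 1e-7, smooth = 1) {
  cross_entropy_loss(y, p, eps_clip) + dice_loss(y, p, smooth)
}

# Loss components and gradient w.r.t. the probability map.
.loss_and_grad <- function(y, p, eps_clip, smooth) {
  n <- length(p)
  pc <- pmin(pmax(p, eps_clip), 1 - eps_clip)
  ce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  d_ce <- (pc - y) / (pc * (1 - pc)) / n
  num <- 2 * sum(y * p) + smooth
  den <- sum(y) + sum(p) + smooth
  dice <- 1 - num / den
  d_dice <- -(2 * y * den - num) / den^2
  list(loss = ce + dice, ce = ce, dice = dice, dp = d_ce + d_dice)
}

#' Learning rate at a global step
#'
#' `lr_initial * decay_rate^(step / decay_step)` with a continuous
#' exponent: 0.001 at step 0, 0.00095 at step 500, 0.0009025 at step 1000
#' under the defaults.
#'
#' @param step_global Non-negative optimizer step count.
#' @param config A [train_config()].
#' @return Learning rate; monotone non-increasing in `step_global`.
#' @export
lr_at_step <- function(step_global, config = train_config()) {
  if (any(step_global < 0)) stop("step_global must be >= 0")
  config$lr_initial * config$decay_rate^(step_global / config$decay_step)
}

# Stack a list of slice samples into batch arrays for the markers routed
# from their (common) sequence.
.stack_batch <- function(chunk, markers) {
  h <- nrow(chunk[[1]]$image)
  wd <- ncol(chunk[[1]]$image)
  n <- length(chunk)
  x <- array(0, c(h, wd, 1L, n))
  ys <- stats::setNames(lapply(markers, function(m) array(0, c(h, wd, 1L, n))),
                        markers)
  for (i in seq_len(n)) {
    x[, , 1L, i] <- chunk[[i]]$image
    for (m in markers) {
      lab <- chunk[[i]]$labels[[m]]
      if (!is.null(lab)) ys[[m]][, , 1L, i] <- lab
    }
  }
  list(x = x, y = ys, sequence = chunk[[1]]$sequence_tag)
}

.make_batches <- function(samples, batch_size, shuffle = TRUE) {
  seqs <- vapply(samples, function(s) s$sequence_tag, character(1))
  batches <- list()
  for (sq in unique(seqs)) {
    ss <- samples[seqs == sq]
    if (shuffle) ss <- ss[sample.int(length(ss))]
    for (start in seq(1L, length(ss), by = batch_size)) {
      batches[[length(batches) + 1L]] <-
        ss[start:min(start + batch_size - 1L, length(ss))]
    }
  }
  if (shuffle && length(batches) > 1L) batches <- batches[sample.int(length(batches))]
  batches
}

# Pooled validation metrics in evaluation mode: per-marker Dice (pooled
# voxel counts over the whole set) and mean combined loss.
.validate <- function(model, samples, config, threshold = 0.5) {
  if (!length(samples)) return(list(dice = numeric(), loss = NA_real_))
  counts <- list()
  loss_sum <- 0
  nb <- 0L
  for (chunk in .make_batches(samples, config$batch_size, shuffle = FALSE)) {
    sq <- chunk[[1]]$sequence_tag
    markers <- intersect(model$config$routing[[sq]], names(chunk[[1]]$labels))
    b <- .stack_batch(chunk, markers)
    probs <- forward_route(model, b$x, sq, train = FALSE)
    for (m in markers) {
      lg <- .loss_and_grad(b$y[[m]], probs[[m]], config$eps_clip, config$dice_smooth)
      loss_sum <- loss_sum + lg$loss
      nb <- nb + 1L
      pb <- probs[[m]] >= threshold
      yb <- b$y[[m]] > 0
      cc <- counts[[m]] %||% c(tp = 0, fp = 0, fn = 0)
      cc <- cc + c(tp = sum(pb & yb), fp = sum(pb & !yb), fn = sum(!pb & yb))
      counts[[m]] <- cc
    }
  }
  dice <- vapply(counts, function(cc) {
    den <- 2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]]
    if (den == 0) 1 else 2 * cc[["tp"]] / den
  }, numeric(1))
  list(dice = dice, loss = if (nb > 0) loss_sum / nb else NA_real_)
}

#' Train the model on one train/validation split
#'
#' Adam with L2 weight decay and the exponential learning-rate schedule;
#' the per-marker combined loss (cross-entropy + Dice) is summed over the
#' markers routed from each batch's sequence. Training stops after
#' `max_epochs` or when the mean validation Dice fails to improve for
#' `patience` consecutive epochs; the best-validation parameters are
#' restored before returning. A non-finite training loss aborts with the
#' last good checkpoint and a warning.
#'
#' @param model A `mo_unet` from [build_mo_unet()].
#' @param data List with `train` and `val` lists of [slice_sample()]s
#'   (disjoint patients).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model`, `history` (per-epoch data frame: train loss,
#'   validation loss, validation Dice per marker, learning rate),
#'   `best_epoch` and `stopped_epoch`.
#' @export
train_one_iteration <- function(model, data, config = train_config(),
                                verbose = FALSE) {
  tr_pat <- unique(vapply(data$train, function(s) s$patient_id, character(1)))
  va_pat <- unique(vapply(data$val, function(s) s$patient_id, character(1)))
  if (length(intersect(tr_pat, va_pat)))
    stop("train and validation patients must be disjoint")
  layers <- collect_layers(model)
  opt <- adam_init(layers, weight_decay = config$weight_decay)
  best <- -Inf
  best_state <- collect_state(layers)
  best_epoch <- 0L
  wait <- 0L
  step <- 0L
  hist <- list()
  set.seed(config$seed)
  for (ep in seq_len(config$max_epochs)) {
    loss_sum <- 0
    nb <- 0L
    aborted <- FALSE
    for (chunk in .make_batches(data$train, config$batch_size)) {
      sq <- chunk[[1]]$sequence_tag
      markers <- intersect(model$config$routing[[sq]], names(chunk[[1]]$labels))
      if (!length(markers)) next
      b <- .stack_batch(chunk, markers)
      probs <- forward_route(model, b$x, sq, train = TRUE)
      dps <- list()
      bl <- 0
      for (m in markers) {
        lg <- .loss_and_grad(b$y[[m]], probs[[m]], config$eps_clip,
                             config$dice_smooth)
        bl <- bl + lg$loss
        dps[[m]] <- lg$dp
      }
      if (!is.finite(bl)) {
        warning("non-finite loss at epoch ", ep, "; restoring last checkpoint")
        aborted <- TRUE
        break
      }
      model_backward(model, dps)
      lr <- lr_at_step(step, config)
      opt <- adam_step(opt, layers, lr)
      step <- step + 1L
      loss_sum <- loss_sum + bl
      nb <- nb + 1L
    }
    if (aborted) break
    val <- .validate(model, data$val, config)
    metric <- if (length(val$dice)) mean(val$dice) else NA_real_
    dice_cols <- if (length(val$dice))
      as.data.frame(as.list(stats::setNames(val$dice,
                                            paste0("val_dice_", names(val$dice)))))
    else NULL
    row <- data.frame(epoch = ep, train_loss = loss_sum / max(nb, 1L),
                      val_loss = val$loss, val_dice_mean = metric,
                      lr = lr_at_step(step, config))
    hist[[ep]] <- if (is.null(dice_cols)) row else cbind(row, dice_cols)
    if (verbose)
      message(sprintf("epoch %d train %.4f val dice %.4f", ep,
                      loss_sum / max(nb, 1L), metric))
    if (!is.na(metric) && metric > best + 1e-8) {
      best <- metric
      best_state <- collect_state(layers)
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  restore_state(layers, best_state)
  history <- do.call(rbind, lapply(hist, function(h) {
    h[setdiff(unlist(lapply(hist, names)), names(h))] <- NA
    h
  }))
  rownames(history) <- NULL
  list(model = model, history = history, best_epoch = best_epoch,
       stopped_epoch = length(hist))
}

#' Segment one patient volume
#'
#' Slices each available sequence, per-slice min-max normalizes, runs the
#' routed decoders in evaluation mode and reassembles 3D probability and
#' binary mask volumes per marker. When several sequences route the same
#' marker the probability maps are averaged.
#'
#' @param model A trained `mo_unet`.
#' @param msv A `multiseq_volume`.
#' @param threshold Binarization threshold.
#' @param chunk_size Slices per forward batch.
#' @return List with `prob` and `masks`, named by marker.
#' @export
segment_patient <- function(model, msv, threshold = 0.5, chunk_size = 8L) {
  routing <- model$config$routing
  prob_sum <- list()
  prob_n <- list()
  for (sq in intersect(names(routing), names(msv$volumes))) {
    vol <- msv$volumes[[sq]]
    nz <- dim(vol)[3]
    markers <- routing[[sq]]
    acc <- stats::setNames(lapply(markers, function(m) array(0, dim(vol))), markers)
    for (start in seq(1L, nz, by = chunk_size)) {
      zs <- start:min(start + chunk_size - 1L, nz)
      x <- array(0, c(dim(vol)[1], dim(vol)[2], 1L, length(zs)))
      for (i in seq_along(zs)) x[, , 1L, i] <- minmax_normalize(vol[, , zs[i]])
      probs <- forward_route(model, x, sq, train = FALSE)
      for (m in markers) acc[[m]][, , zs] <- probs[[m]][, , 1L, ]
    }
    for (m in markers) {
      prob_sum[[m]] <- if (is.null(prob_sum[[m]])) acc[[m]] else prob_sum[[m]] + acc[[m]]
      prob_n[[m]] <- (prob_n[[m]] %||% 0L) + 1L
    }
  }
  prob <- lapply(stats::setNames(names(prob_sum), names(prob_sum)),
                 function(m) prob_sum[[m]] / prob_n[[m]])
  masks <- lapply(prob, function(p) p >= threshold)
  list(prob = prob, masks = masks)
}

#' Nested cross-validation over a hyperparameter grid
#'
#' For each fold of the plan, every grid point is trained on the inner
#' 80:20 train/validation split; the point with the highest mean validation
#' Dice is selected and its model evaluated once on the held-out fold, so
#' each patient is tested exactly once.
#'
#' @param patients Phantom patients (list with `volume`, `truth`).
#' @param fold_plan A [make_fold_plan()] over these patients' ids.
#' @param grid Non-empty list of named lists; entries override
#'   [network_config()] and/or [train_config()] fields.
#' @param base_net A [network_config()].
#' @param base_train A [train_config()].
#' @param routing Routing used to build the slice datasets.
#' @return List with one element per fold: chosen grid point, per-point
#'   validation scores and held-out per-marker Dice.
#' @export
run_nested_cv <- function(patients, fold_plan, grid, base_net = network_config(),
                          base_train = train_config(),
                          routing = base_net$routing) {
  if (!length(grid)) stop("hyperparameter grid must be non-empty")
  ids <- vapply(patients, function(p) p$volume$patient_id, character(1))
  out <- vector("list", fold_plan$k)
  for (f in seq_len(fold_plan$k)) {
    it <- fold_plan$iterations[[f]]
    d_train <- slice_dataset(patients[ids %in% it$train], routing)
    d_val <- slice_dataset(patients[ids %in% it$validation], routing)
    d_test <- slice_dataset(patients[ids %in% it$test], routing)
    scores <- numeric(length(grid))
    fits <- vector("list", length(grid))
    for (g in seq_along(grid)) {
      nc <- base_net
      tc <- base_train
      for (nm in names(grid[[g]])) {
        if (nm %in% names(nc)) nc[[nm]] <- grid[[g]][[nm]]
        if (nm %in% names(tc)) tc[[nm]] <- grid[[g]][[nm]]
      }
      nc$n_stages <- length(nc$encoder_stage_widths)
      set.seed(tc$seed)
      model <- build_mo_unet(nc)
      fit <- train_one_iteration(model, list(train = d_train, val = d_val), tc)
      v <- .validate(fit$model, d_val, tc)
      scores[g] <- if (length(v$dice)) mean(v$dice) else -Inf
      fits[[g]] <- fit
    }
    pick <- which.max(scores)
    test <- .validate(fits[[pick]]$model, d_test, base_train)
    out[[f]] <- list(fold = f, chosen = grid[[pick]], val_scores = scores,
                     test_dice = test$dice, test_patients = it$test)
  }
  out
}
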