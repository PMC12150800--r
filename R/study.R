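#' Desk-scale end-to-end study on phantom data
#'
#' The miniature analogue of the full pipeline: generates a phantom cohort,
#' pretrains the encoder as an autoencoder, trains a miniature MO-UNet on
#' the FLAIR-routed decoders (WMH + lacune), segments the cohort and
#' quantifies agreement and burden. Patients are split by burden-stratified
#' sampling into train/validation/test at patient level.
#'
#' The default problem size (30 patients of 64 x 64 x 24 voxels, stage
#' widths 8-16-32, 10 autoencoder epochs, at most 30 training epochs with
#' early stopping) is chosen so the whole study runs on one CPU core in
#' minutes while leaving the trained model clearly better than chance.
#'
#' @param seed Master seed for phantom generation, splits, initialization
#'   and training order.
#' @param n_patients Cohort size.
#' @param image_shape Phantom grid.
#' @param widths Encoder stage widths.
#' @param ae_epochs Autoencoder pretraining epochs.
#' @param max_epochs Segmentation training epoch cap.
#' @param max_train_slices Cap on training slices (subsampled reproducibly
#'   when exceeded) to keep the desk run bounded.
#' @param verbose Print training progress.
#' @return List with the cohort manifest, data splits, training history,
#'   held-out per-marker Dice, per-patient volume agreement (Pearson,
#'   Bland-Altman), burden records and Z-score summaries.
#' @export
run_desk_study <- function(seed = 1L, n_patients = 30L,
                           image_shape = c(64L, 64L, 24L),
                           widths = c(8L, 16L, 32L),
                           ae_epochs = 10L, max_epochs = 30L,
                           max_train_slices = 240L, verbose = FALSE) {
  spec <- phantom_spec(image_shape = image_shape, seed = seed)
  cohort <- generate_cohort(spec, n_patients)
  ids <- cohort$manifest$patient_id
  burden <- cohort$manifest$burden_level

  split <- with_seed(seed + 1L, {
    test <- character()
    val <- character()
    for (b in unique(burden)) {
      pool <- sample(ids[burden == b])
      test <- c(test, pool[1])
      if (length(pool) > 1) val <- c(val, pool[2])
    }
    list(test = test, val = val, train = setdiff(ids, c(test, val)))
  })

  routing <- list(FLAIR = c("WMH", "lacune"))
  nc <- network_config(input_size = image_shape[1],
                       encoder_stage_widths = widths,
                       markers = c("WMH", "lacune"), routing = routing)
  tc <- train_config(max_epochs = max_epochs, seed = seed)

  # train on positive slices plus an equal share of lesion-free slices:
  # the network must also learn to reject noise-only slices, whose per-slice
  # min-max normalization stretches background texture to the full range
  d_all <- slice_dataset(cohort$patients[ids %in% split$train], routing,
                         positive_only = FALSE)
  pos <- Filter(function(s) s$is_positive, d_all)
  neg <- Filter(function(s) !s$is_positive, d_all)
  neg <- with_seed(seed + 2L, sample(neg, min(length(neg), length(pos))))
  d_train <- c(pos, neg)
  if (length(d_train) > max_train_slices) {
    keep <- with_seed(seed + 2L, sample.int(length(d_train), max_train_slices))
    d_train <- d_train[keep]
  }
  d_val <- slice_dataset(cohort$patients[ids %in% split$val], routing,
                         positive_only = FALSE)

  set.seed(seed + 3L)
  ae <- pretrain_autoencoder(lapply(d_train, function(s) s$image), nc,
                             epochs = ae_epochs, batch_size = tc$batch_size)
  set.seed(seed + 4L)
  model <- build_mo_unet(nc, pretrained_encoder = ae$encoder)
  fit <- train_one_iteration(model, list(train = d_train, val = d_val), tc,
                             verbose = verbose)

  # held-out evaluation: pooled voxel counts over the test patients
  test_patients <- cohort$patients[ids %in% split$test]
  counts <- list()
  seg_all <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    p <- cohort$patients[[i]]
    seg <- segment_patient(fit$model, p$volume)
    seg_all[[i]] <- seg
    if (p$volume$patient_id %in% split$test) {
      for (m in names(seg$masks)) {
        pb <- seg$masks[[m]]
        yb <- p$truth$masks[[m]]
        cc <- counts[[m]] %||% c(tp = 0, fp = 0, fn = 0)
        counts[[m]] <- cc + c(tp = sum(pb & yb), fp = sum(pb & !yb),
                              fn = sum(!pb & yb))
      }
    }
  }
  test_dice <- vapply(counts, function(cc)
    2 * cc[["tp"]] / max(2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]], 1),
    numeric(1))

  src <- csvd_marker_source()
  trained <- names(seg_all[[1]]$masks)
  vol_pred <- sapply(trained, function(m)
    vapply(seg_all, function(s)
      marker_volume(s$masks[[m]] + 0L, spec$spacing[[src[[m]]]]), numeric(1)))
  vol_true <- sapply(trained, function(m)
    vapply(cohort$patients, function(p)
      marker_volume(p$truth$masks[[m]] + 0L, spec$spacing[[src[[m]]]]),
      numeric(1)))
  agreement <- lapply(stats::setNames(trained, trained), function(m) {
    list(pearson = pearson_r(vol_pred[, m], vol_true[, m]),
         bland_altman = bland_altman(vol_pred[, m], vol_true[, m]))
  })

  records <- burden_records(lapply(cohort$patients, function(p) p$truth),
                            spec$spacing, patient_ids = ids)
  z_by_level <- tapply(records$z_sum, burden, mean)

  list(spec = spec, manifest = cohort$manifest, split = split,
       history = fit$history, best_epoch = fit$best_epoch,
       ae_history = ae$history, model = fit$model,
       test_dice = test_dice, vol_pred = vol_pred, vol_true = vol_true,
       agreement = agreement, records = records,
       z_sum_by_level = z_by_level)
}
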