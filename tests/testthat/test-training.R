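test_that("cross-entropy loss matches its closed form", {
  expect_equal(cross_entropy_loss(1, 0.5), log(2))
  expect_equal(cross_entropy_loss(c(1, 0), c(0.9, 0.2)),
               -(log(0.9) + log(0.8)) / 2)
  expect_lt(cross_entropy_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  expect_error(cross_entropy_loss(matrix(1, 2, 2), matrix(0.5, 3, 3)), "shape")
})

test_that("Dice loss matches its closed form at the stated corner cases", {
  x <- c(1, 1, 1, 1, 0, 0)
  expect_equal(dice_loss(x, x, smooth = 0), 0)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 0, 1, 1), smooth = 0), 1)
  # four labelled voxels predicted at 0.5: 1 - 4/(4 + 2) = 1/3
  expect_equal(dice_loss(c(1, 1, 1, 1), rep(0.5, 4), smooth = 0), 1 / 3)
  y <- runif(32)
  xb <- rbinom(32, 1, 0.4)
  expect_gte(dice_loss(xb, y), 0)
  expect_lte(dice_loss(xb, y), 1)
})

test_that("total loss is exactly the sum of its two components", {
  set.seed(6)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.3)
    p <- runif(50, 0.01, 0.99)
    expect_equal(total_loss(y, p),
                 cross_entropy_loss(y, p) + dice_loss(y, p),
                 tolerance = 1e-9)
    expect_gte(total_loss(y, p), max(cross_entropy_loss(y, p), dice_loss(y, p)))
  }
})

test_that("Dice from confusion counts complements the Dice loss on binary pairs", {
  set.seed(8)
  for (i in 1:10) {
    a <- rbinom(100, 1, 0.3)
    b <- rbinom(100, 1, 0.3)
    cc <- confusion_counts(a, b)
    expect_equal(dice_from_counts(cc), 1 - dice_loss(b, a, smooth = 0),
                 tolerance = 1e-9)
  }
})

test_that("learning-rate schedule follows the continuous exponential decay", {
  tc <- train_config()
  expect_equal(lr_at_step(0, tc), 0.001, tolerance = 1e-12)
  expect_equal(lr_at_step(500, tc), 0.00095, tolerance = 1e-12)
  expect_equal(lr_at_step(1000, tc), 0.0009025, tolerance = 1e-12)
  steps <- seq(0, 5000, by = 37)
  expect_true(all(diff(lr_at_step(steps, tc)) <= 0))
  expect_error(lr_at_step(-1, tc), ">= 0")
})

tiny_fit <- function(lr_initial = 1e-12, max_epochs = 10L, patience = 5L,
                     n_patients = 2L) {
  sp <- phantom_spec(image_shape = c(16, 16, 6), seed = 17L)
  co <- generate_cohort(sp, n_patients + 1L)
  routing <- list(FLAIR = "WMH")
  nc <- network_config(input_size = 16L, encoder_stage_widths = c(4L, 6L),
                       markers = "WMH", routing = routing)
  tc <- train_config(lr_initial = lr_initial, max_epochs = max_epochs,
                     patience = patience, seed = 1L)
  ds_tr <- slice_dataset(co$patients[seq_len(n_patients)], routing)
  ds_va <- slice_dataset(co$patients[n_patients + 1L], routing)
  set.seed(2)
  model <- build_mo_unet(nc)
  list(fit = train_one_iteration(model, list(train = ds_tr, val = ds_va), tc),
       model = model, data = list(train = ds_tr, val = ds_va), tc = tc)
}

test_that("early stopping waits exactly `patience` flat epochs", {
  # with a vanishing learning rate the validation metric never improves
  # after the first epoch, so training stops at epoch 1 + patience
  out <- tiny_fit(lr_initial = 1e-12, max_epochs = 10L, patience = 5L)
  expect_identical(out$fit$stopped_epoch, 6L)
  expect_identical(out$fit$best_epoch, 1L)
  expect_lte(nrow(out$fit$history), 10L)
})

test_that("one optimization step changes the shared encoder parameters", {
  sp <- phantom_spec(image_shape = c(16, 16, 6), seed = 19L)
  co <- generate_cohort(sp, 1L)
  routing <- list(FLAIR = "WMH")
  nc <- network_config(input_size = 16L, encoder_stage_widths = c(4L, 6L),
                       markers = "WMH", routing = routing)
  ds <- slice_dataset(co$patients, routing)
  set.seed(3)
  model <- build_mo_unet(nc)
  w0 <- model$encoder$stem$w
  b <- csvdseg:::.stack_batch(ds[seq_len(min(4, length(ds)))], "WMH")
  pr <- forward_route(model, b$x, "FLAIR", train = TRUE)
  lg <- csvdseg:::.loss_and_grad(b$y$WMH, pr$WMH, 1e-7, 1)
  csvdseg:::model_backward(model, list(WMH = lg$dp))
  layers <- csvdseg:::collect_layers(model)
  opt <- csvdseg:::adam_init(layers, weight_decay = 1e-4)
  invisible(csvdseg:::adam_step(opt, layers, 1e-3))
  expect_false(identical(w0, model$encoder$stem$w))
})

test_that("training on phantoms reduces the loss over epochs", {
  sp <- phantom_spec(image_shape = c(32, 32, 8), seed = 23L)
  co <- generate_cohort(sp, 4L)
  routing <- list(FLAIR = "WMH")
  nc <- network_config(input_size = 32L, encoder_stage_widths = c(4L, 8L),
                       markers = "WMH", routing = routing)
  tc <- train_config(max_epochs = 8L, patience = 8L, seed = 1L)
  set.seed(5)
  model <- build_mo_unet(nc)
  fit <- train_one_iteration(
    model, list(train = slice_dataset(co$patients[1:3], routing),
                val = slice_dataset(co$patients[4], routing)), tc)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # the recorded learning rate follows the decaying schedule
  expect_true(all(diff(h$lr) <= 0))
  expect_true(all(h$lr <= lr_at_step(0, tc)))
})

test_that("nested cross-validation tests every patient exactly once", {
  sp <- phantom_spec(image_shape = c(16, 16, 6), seed = 29L)
  co <- generate_cohort(sp, 6L)
  ids <- co$manifest$patient_id
  plan <- make_fold_plan(ids, k = 3L, seed = 1L)
  nc <- network_config(input_size = 16L, encoder_stage_widths = c(4L, 6L),
                       markers = "WMH", routing = list(FLAIR = "WMH"))
  tc <- train_config(max_epochs = 1L, patience = 1L, seed = 1L)
  res <- run_nested_cv(co$patients, plan, grid = list(list(lr_initial = 0.001)),
                       base_net = nc, base_train = tc)
  expect_length(res, 3L)
  tested <- unlist(lapply(res, `[[`, "test_patients"))
  expect_setequal(tested, ids)
  expect_identical(anyDuplicated(tested), 0L)
  # a one-point grid is always the chosen point
  for (r in res) expect_identical(r$chosen, list(lr_initial = 0.001))
  expect_error(run_nested_cv(co$patients, plan, grid = list(),
                             base_net = nc, base_train = tc), "non-empty")
})
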