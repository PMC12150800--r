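test_that("confusion counts match the per-voxel oracle", {
  set.seed(14)
  for (i in 1:5) {
    a <- random_mask(c(8, 8, 4))
    b <- random_mask(c(8, 8, 4))
    cc <- confusion_counts(a, b)
    oc <- oracle_confusion(a, b)
    expect_identical(cc$TP, oc$TP)
    expect_identical(cc$TN, oc$TN)
    expect_identical(cc$FP, oc$FP)
    expect_identical(cc$FN, oc$FN)
    expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, length(a))
  }
  same <- random_mask(c(6, 6, 3))
  cc <- confusion_counts(same, same)
  expect_identical(cc$FP, 0L)
  expect_identical(cc$FN, 0L)
  all1 <- array(1L, c(5, 5, 4))
  cc <- confusion_counts(all1, array(0L, c(5, 5, 4)))
  expect_identical(cc$FP, 100L)
  expect_error(confusion_counts(array(2, c(2, 2, 2)), array(0, c(2, 2, 2))),
               "binary")
})

test_that("precision, specificity and Dice follow the printed formulas", {
  cc <- structure(list(TP = 3L, TN = 0L, FP = 1L, FN = 0L),
                  class = "confusion_counts")
  expect_equal(precision_from_counts(cc), 0.75)
  cc <- structure(list(TP = 4L, TN = 0L, FP = 1L, FN = 1L),
                  class = "confusion_counts")
  expect_equal(dice_from_counts(cc), 0.8)
  cc <- structure(list(TP = 0L, TN = 90L, FP = 10L, FN = 0L),
                  class = "confusion_counts")
  expect_equal(specificity_from_counts(cc), 0.9)
  # empty-mask conventions
  empty <- structure(list(TP = 0L, TN = 10L, FP = 0L, FN = 0L),
                     class = "confusion_counts")
  expect_equal(dice_from_counts(empty), 1)
  expect_equal(precision_from_counts(empty), 1)
})

test_that("HD95 matches simple geometry and basic identities", {
  a <- array(0L, c(10, 10, 5)); a[2, 2, 2] <- 1L
  b <- array(0L, c(10, 10, 5)); b[5, 2, 2] <- 1L
  expect_equal(hd95(a, b, c(1, 1, 1)), 3.0)
  expect_equal(hd95(a, a, c(1, 1, 1)), 0)
  # physical spacing scales the answer
  expect_equal(hd95(a, b, c(2, 1, 1)), 6.0)
  # symmetry and non-negativity
  set.seed(15)
  x <- random_mask(c(8, 8, 4)); y <- random_mask(c(8, 8, 4))
  expect_equal(hd95(x, y), hd95(y, x))
  expect_gte(hd95(x, y), 0)
  # empty masks are reported missing, never zero
  expect_true(is.na(hd95(array(0L, c(4, 4, 2)), b[1:4, 1:4, 1:2])))
})

test_that("HD95 agrees with the all-pairs oracle and is below exact Hausdorff", {
  set.seed(16)
  for (i in 1:10) {
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2), runif(1, 0.5, 3))
    a <- random_mask(c(10, 10, 10), n_blobs = sample(1:3, 1))
    b <- random_mask(c(10, 10, 10), n_blobs = sample(1:3, 1))
    expect_equal(hd95(a, b, sp), oracle_hd95(a, b, sp), tolerance = 1e-6)
    expect_lte(hd95(a, b, sp), oracle_hausdorff(a, b, sp) + 1e-9)
  }
  # the printed scaled-max variant is 95% of the exact Hausdorff distance
  a <- random_mask(c(8, 8, 8)); b <- random_mask(c(8, 8, 8))
  expect_equal(hd95(a, b, method = "scaled_max"),
               0.95 * oracle_hausdorff(a, b), tolerance = 1e-9)
})

test_that("lesion extraction uses 26-connectivity components", {
  m <- array(0L, c(12, 12, 6))
  m[2:4, 2:4, 2:3] <- 1L
  m[8:10, 8:10, 4:5] <- 1L
  les <- extract_lesions(m, c(1, 1, 2))
  expect_length(les, 2L)
  expect_equal(sum(vapply(les, `[[`, numeric(1), "volume")), sum(m) * 2)
  expect_length(extract_lesions(array(0L, c(4, 4, 2))), 0L)
  # diagonal touch merges under 26-connectivity
  dg <- array(0L, c(4, 4, 4)); dg[1, 1, 1] <- 1L; dg[2, 2, 2] <- 1L
  expect_length(extract_lesions(dg), 1L)
  expect_length(extract_lesions(dg, connectivity = 6L), 2L)
})

test_that("the 50% coverage rule is boundary-inclusive", {
  truth <- array(0L, c(10, 10, 2))
  truth[1:10, 1, 1] <- 1L                 # one 10-voxel lesion
  inst <- extract_lesions(truth)
  pred5 <- array(0L, c(10, 10, 2)); pred5[1:5, 1, 1] <- 1L
  pred4 <- array(0L, c(10, 10, 2)); pred4[1:4, 1, 1] <- 1L
  expect_equal(per_lesion_sensitivity(pred5, inst)$sensitivity, 1)   # 0.50 -> TP
  expect_equal(per_lesion_sensitivity(pred4, inst)$sensitivity, 0)   # 0.40 -> FN
  expect_true(is.na(per_lesion_sensitivity(pred5, list())$sensitivity))
})

test_that("lesion sensitivity averages the per-lesion rule and ignores order", {
  truth <- array(0L, c(20, 10, 2))
  truth[1:10, 1, 1] <- 1L
  truth[1:10, 5, 1] <- 1L
  truth[1:10, 9, 1] <- 1L
  pred <- array(0L, c(20, 10, 2))
  pred[1:10, 1, 1] <- 1L                   # coverage 1.0
  pred[1:6, 5, 1] <- 1L                    # coverage 0.6
  pred[1, 9, 1] <- 1L                      # coverage 0.1
  inst <- extract_lesions(truth)
  res <- per_lesion_sensitivity(pred, inst)
  expect_equal(res$sensitivity, 2 / 3)
  res_rev <- per_lesion_sensitivity(pred, rev(inst))
  expect_equal(res_rev$sensitivity, res$sensitivity)
})

test_that("bootstrap intervals behave like percentile bootstraps", {
  expect_equal(bootstrap_ci(rep(0.8, 10), n_boot = 500), c(0.8, 0.8))
  set.seed(18)
  v <- rnorm(60, mean = 2)
  ci <- bootstrap_ci(v, n_boot = 2000, seed = 4)
  expect_true(ci[1] <= mean(v) && mean(v) <= ci[2])
  big <- rnorm(500, 1)
  small <- big[1:5]
  w_small <- diff(bootstrap_ci(small, n_boot = 1000, seed = 5))
  w_big <- diff(bootstrap_ci(big, n_boot = 1000, seed = 5))
  expect_gt(w_small, w_big)
  expect_warning(bootstrap_ci(v, n_boot = 50), "unstable")
})

test_that("a perfect segmentation scores perfectly on a phantom patient", {
  sp <- phantom_spec(seed = 33L)
  p <- generate_patient(sp, 3)
  preds <- list(lapply(p$truth$masks, function(m) m + 0L))
  df <- evaluate_segmentation(preds, list(p$truth), sp$spacing)
  expect_true(all(df$precision == 1))
  expect_true(all(df$specificity == 1))
  expect_true(all(df$dice == 1))
  nonempty <- df$marker[vapply(p$truth$masks[df$marker], sum, numeric(1)) > 0]
  expect_true(all(df$hd95[df$marker %in% nonempty] == 0))
  expect_true(all(df$lesion_sensitivity[df$marker != "WMH" &
                                          df$marker %in% nonempty] == 1))
  expect_true(all(is.na(df$lesion_sensitivity[df$marker == "WMH"])))
})
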