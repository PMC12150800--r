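test_that("marker volume is voxel count times voxel volume", {
  m <- array(0L, c(10, 10, 4))
  m[1:10, 1:10, 1] <- 1L
  expect_equal(marker_volume(m, c(1, 1, 2)), 200)
  expect_equal(marker_volume(array(0L, c(4, 4, 2)), c(1, 1, 1)), 0)
  expect_error(marker_volume(array(2, c(2, 2, 2)), c(1, 1, 1)), "binary")
  expect_error(marker_volume(m, c(1, 0, 1)), "positive")
})

test_that("visual-score bins follow the rating-scale categories", {
  b <- bin_visual_scores(10, 5, 15, fazekas_sum = 4)
  expect_identical(as.character(b$cmb_bin), "1-10")
  expect_identical(as.character(b$lacune_bin), ">4")
  expect_identical(b$epvs_bin, 2L)
  expect_identical(b$wmh_grade, 1L)
  expect_identical(bin_visual_scores(11, 0, 0)$cmb_bin, factor(">10", levels = c("0", "1-10", ">10")))
  expect_identical(bin_visual_scores(0, 4, 0)$lacune_bin,
                   factor("1-4", levels = c("0", "1-4", ">4")))
  expect_identical(bin_visual_scores(0, 0, 41)$epvs_bin, 4L)
  expect_identical(bin_visual_scores(0, 0, 40)$epvs_bin, 3L)
  expect_identical(bin_visual_scores(0, 0, 0, fazekas_sum = 6)$wmh_grade, 2L)
  expect_identical(bin_visual_scores(0, 0, 0, fazekas_sum = 2)$wmh_grade, 0L)
  expect_error(bin_visual_scores(0, 0, 0, fazekas_sum = 7), "0..6")
})

test_that("total burden scores the four-point presence rule", {
  expect_identical(total_burden_score(0, 0, 0), 0L)
  expect_identical(total_burden_score(20, 5, 30, fazekas_deep = 3,
                                      fazekas_pv = 3), 4L)
  # 1 lacune, no CMBs, mild perivascular spaces, WMH rule unmet -> 1
  expect_identical(total_burden_score(0, 1, 5, fazekas_deep = 1,
                                      fazekas_pv = 1), 1L)
  # adding lesions never decreases the score
  set.seed(20)
  for (i in 1:25) {
    cm <- rpois(1, 3); la <- rpois(1, 2); ep <- rpois(1, 10)
    s0 <- total_burden_score(cm, la, ep, fazekas_sum = 3)
    s1 <- total_burden_score(cm + 1, la, ep + 8, fazekas_sum = 3)
    expect_gte(s1, s0)
  }
})

test_that("Z-score burden standardizes each marker against the cohort", {
  vols <- data.frame(WMH = c(0, 2000), CMB = c(0, 40), lacune = c(0, 100),
                     EPVS = c(0, 60))
  zb <- zscore_burden(vols)
  # two-point standardization: symmetric z of +/- 1/sqrt(2) under sample SD
  expect_equal(unname(unlist(zb$z[1, ])), rep(-1 / sqrt(2), 4))
  expect_equal(unname(unlist(zb$z[2, ])), rep(1 / sqrt(2), 4))
  expect_equal(zb$z_sum, c(-4, 4) / sqrt(2))
  set.seed(22)
  v <- as.data.frame(matrix(rlnorm(200), 50, 4,
                            dimnames = list(NULL, csvd_markers())))
  zb <- zscore_burden(v)
  expect_equal(unname(colMeans(zb$z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(zb$z, 2, sd)), rep(1, 4), tolerance = 1e-9)
  expect_equal(zb$z_sum, rowSums(zb$z))
  expect_warning(zscore_burden(data.frame(WMH = c(1, 1), CMB = c(0, 1))),
                 "zero cohort SD")
})

test_that("Pearson correlation matches the printed formula", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 7)), 5 / sqrt(2 * 114 / 9),
               tolerance = 1e-9)
  expect_equal(round(pearson_r(c(1, 2, 3), c(2, 4, 7)), 4), 0.9934)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("Bland-Altman limits are symmetric and cover ~95% of differences", {
  x <- c(1, 2, 3, 4)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$lower, 0)
  expect_equal(ba$upper, 0)
  ba <- bland_altman(x + 2.5, x)
  expect_equal(ba$mean_diff, 2.5)
  expect_equal(ba$sd_diff, 0)
  set.seed(24)
  x <- rnorm(1e4); y <- x + rnorm(1e4, 0, 0.5)
  ba <- bland_altman(x, y)
  cover <- mean(ba$diffs >= ba$lower & ba$diffs <= ba$upper)
  expect_equal(cover, 0.95, tolerance = 0.01)
  expect_equal(ba$upper - ba$mean_diff, ba$mean_diff - ba$lower)
})

test_that("ANOVA with LSD post-hoc behaves like the textbook procedure", {
  g <- rep(c("a", "b", "c"), each = 3)
  v <- rep(c(1, 2, 3), times = 3)
  res <- anova_lsd(v, g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # two groups: F equals the square of the pooled t statistic
  set.seed(26)
  x1 <- rnorm(8); x2 <- rnorm(8, 1)
  res2 <- anova_lsd(c(x1, x2), rep(c("a", "b"), each = 8))
  tt <- t.test(x1, x2, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-9)
  # well-separated groups are detected
  set.seed(27)
  vals <- c(rnorm(10), rnorm(10), rnorm(10, 5))
  res3 <- anova_lsd(vals, rep(1:3, each = 10))
  expect_lt(res3$p, 0.001)
  expect_lt(res3$lsd["3", "1"], 0.001)
  expect_error(anova_lsd(1:3, c("a", "a", "b")), "at least 2 values")
})

test_that("burden records agree with the phantom manifest", {
  sp <- phantom_spec(seed = 37L)
  co <- generate_cohort(sp, 6L)
  rec <- burden_records(lapply(co$patients, function(p) p$truth), sp$spacing,
                        patient_ids = co$manifest$patient_id)
  for (m in csvd_markers()) {
    expect_equal(rec[[paste0("volume_", m)]], co$manifest[[paste0("volume_", m)]])
    expect_equal(rec[[paste0("count_", m)]], co$manifest[[paste0("count_", m)]])
  }
  expect_true(all(rec$total_burden >= 0 & rec$total_burden <= 4))
  expect_equal(mean(rec$z_sum), 0, tolerance = 1e-9)
})
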