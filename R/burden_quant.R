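#' Lesion volume from a mask
#'
#' Foreground voxel count times the voxel volume (product of the mm voxel
#' spacing components).
#'
#' @param mask Binary array.
#' @param spacing mm voxel size triplet.
#' @return Volume in mm^3.
#' @export
marker_volume <- function(mask, spacing) {
  if (!all(mask %in% c(0, 1)) && !is.logical(mask)) stop("mask must be binary")
  if (any(spacing <= 0)) stop("spacing must be positive")
  sum(mask > 0) * prod(spacing)
}

#' Bin counts into the visual-score categories
#'
#' Categorical bins of the rating scales: microbleed count 0 / 1-10 / >10;
#' lacune count 0 / 1-4 / >4; basal-ganglia perivascular-space score
#' 0 = none, 1 = 1-10, 2 = 11-20, 3 = 21-40, 4 = >40; WMH grade from the
#' summed periventricular + deep Fazekas scales, 0 for sums 0-2, 1 for
#' 3-4, 2 for 5-6.
#'
#' @param cmb_count,lacune_count,epvs_bg_count Non-negative counts.
#' @param fazekas_sum Optional summed Fazekas grade (0-6).
#' @return List with `cmb_bin`, `lacune_bin` (factors), `epvs_bin` (0-4)
#'   and `wmh_grade` (0-2 or NA when no Fazekas sum is given).
#' @export
bin_visual_scores <- function(cmb_count, lacune_count, epvs_bg_count,
                              fazekas_sum = NULL) {
  stopifnot(cmb_count >= 0, lacune_count >= 0, epvs_bg_count >= 0)
  cmb_bin <- cut(cmb_count, c(-Inf, 0, 10, Inf), labels = c("0", "1-10", ">10"))
  lacune_bin <- cut(lacune_count, c(-Inf, 0, 4, Inf), labels = c("0", "1-4", ">4"))
  epvs_bin <- as.integer(cut(epvs_bg_count, c(-Inf, 0, 10, 20, 40, Inf),
                             labels = FALSE)) - 1L
  wmh_grade <- if (is.null(fazekas_sum)) NA_integer_ else {
    if (fazekas_sum < 0 || fazekas_sum > 6) stop("fazekas_sum must be in 0..6")
    if (fazekas_sum <= 2) 0L else if (fazekas_sum <= 4) 1L else 2L
  }
  list(cmb_bin = cmb_bin, lacune_bin = lacune_bin, epvs_bin = epvs_bin,
       wmh_grade = wmh_grade)
}

#' Total small-vessel-disease burden score (0-4)
#'
#' One point for each of: at least one lacune; at least one microbleed;
#' moderate-to-severe basal-ganglia perivascular spaces (bin >= 2, i.e.
#' more than 10); and white-matter-hyperintensity severity. The WMH point
#' uses the Fazekas rule (deep grade >= 2 or periventricular grade 3) when
#' the separate grades are given, otherwise the summed-grade surrogate
#' (grade 2, sums 5-6). Adding a lesion never decreases the score.
#'
#' @param cmb_count,lacune_count,epvs_bg_count Counts.
#' @param fazekas_deep,fazekas_pv Optional separate Fazekas grades (0-3).
#' @param fazekas_sum Optional summed grade, used when the separate grades
#'   are absent.
#' @return Integer 0-4.
#' @export
total_burden_score <- function(cmb_count, lacune_count, epvs_bg_count,
                               fazekas_deep = NULL, fazekas_pv = NULL,
                               fazekas_sum = NULL) {
  bins <- bin_visual_scores(cmb_count, lacune_count, epvs_bg_count, fazekas_sum)
  wmh_point <- if (!is.null(fazekas_deep) && !is.null(fazekas_pv)) {
    fazekas_deep >= 2 || fazekas_pv == 3
  } else if (!is.null(fazekas_sum)) {
    bins$wmh_grade == 2L
  } else FALSE
  as.integer((lacune_count >= 1) + (cmb_count >= 1) +
               (bins$epvs_bin >= 2L) + wmh_point)
}

#' Cohort Z-score burden
#'
#' Standardizes each marker's volume against the cohort (`z = (v - mean) /
#' sd`) and sums the four marker Z scores into a quantitative global burden
#' `z_sum`. Each marker's Z scores have cohort mean 0 and SD 1; a marker
#' with zero cohort SD gets z = 0 with a warning.
#'
#' @param volumes Data frame or matrix of per-patient marker volumes
#'   (columns = markers).
#' @return List with `z` (same shape) and `z_sum` (per patient).
#' @export
zscore_burden <- function(volumes) {
  volumes <- as.data.frame(volumes)
  if (nrow(volumes) < 2L) stop("need a cohort of at least 2 patients")
  z <- volumes
  for (m in names(volumes)) {
    s <- stats::sd(volumes[[m]])
    if (!is.finite(s) || s == 0) {
      warning("zero cohort SD for ", m, "; z fixed at 0")
      z[[m]] <- 0
    } else {
      z[[m]] <- (volumes[[m]] - mean(volumes[[m]])) / s
    }
  }
  list(z = z, z_sum = rowSums(z))
}

#' Pearson correlation coefficient
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant series")
  stats::cor(x, y)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference and limits of agreement `mean(d) +/- 1.96 sd(d)` for
#' paired measurements; the limits are symmetric about the mean difference.
#'
#' @param x,y Paired numeric vectors (length >= 2).
#' @return List with `mean_diff`, `sd_diff`, `lower`, `upper` and the
#'   per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_diff = md, sd_diff = sdd,
       lower = md - 1.96 * sdd, upper = md + 1.96 * sdd,
       means = (x + y) / 2, diffs = d)
}

#' One-way ANOVA with LSD post-hoc comparisons
#'
#' Fits a one-way ANOVA of values on group and performs Fisher's least
#' significant difference test for all pairwise comparisons: t tests using
#' the pooled within-group variance, deliberately without multiplicity
#' correction (the LSD procedure assumes equal variances).
#'
#' @param values Numeric response.
#' @param groups Grouping vector (>= 2 groups with >= 2 values each).
#' @return List with `F`, `p` and the `lsd` pairwise p-value matrix.
#' @export
anova_lsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  lsd <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                pool.sd = TRUE)
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], lsd = lsd$p.value)
}

#' Per-patient burden records for a cohort
#'
#' Combines marker volumes (from masks), instance counts, visual-score
#' bins, the 0-4 total burden score and the cohort Z-score burden.
#'
#' @param truths List of `lesion_ground_truth` objects (or compatible
#'   lists with `masks`, `counts`, `epvs_bg_count`).
#' @param spacing Named list of mm triplets per sequence.
#' @param patient_ids Optional ids.
#' @return Data frame, one row per patient, with volume, count, bin, total
#'   burden and Z-score columns.
#' @export
burden_records <- function(truths, spacing, patient_ids = NULL) {
  src <- csvd_marker_source()
  rows <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    vols <- vapply(csvd_markers(), function(m)
      marker_volume(tr$masks[[m]] + 0L, spacing[[src[[m]]]]), numeric(1))
    cts <- tr$counts
    score <- total_burden_score(cts[["CMB"]], cts[["lacune"]], tr$epvs_bg_count)
    data.frame(patient_id = patient_ids[i] %||% sprintf("P%03d", i),
               t(stats::setNames(vols, paste0("volume_", csvd_markers()))),
               t(stats::setNames(as.numeric(cts), paste0("count_", csvd_markers()))),
               epvs_bg_count = tr$epvs_bg_count,
               total_burden = score)
  })
  df <- do.call(rbind, rows)
  zb <- zscore_burden(df[paste0("volume_", csvd_markers())])
  names(zb$z) <- paste0("z_", csvd_markers())
  cbind(df, zb$z, z_sum = zb$z_sum)
}
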