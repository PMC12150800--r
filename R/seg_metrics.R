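#' Voxelwise confusion counts
#'
#' Compares two binary grids of equal shape and returns the true/false
#' positive/negative voxel counts (probabilities must be thresholded
#' upstream, conventionally at 0.5).
#'
#' @param pred,truth Binary arrays of equal shape (logical or 0/1).
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  if (!identical(dim(pred) %||% length(pred), dim(truth) %||% length(truth)))
    stop("pred and truth must share shape")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("inputs must be binary")
  p <- pred > 0
  t <- truth > 0
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' Confusion-derived segmentation metrics
#'
#' Precision `TP / (TP + FP)`, specificity `TN / (FP + TN)` and Dice
#' `2TP / (FP + 2TP + FN)`. Zero-denominator conventions: when both masks
#' are empty all three are 1 (perfect agreement on absence); precision with
#' no predicted positives and a nonempty truth is 0.
#'
#' @param c A [confusion_counts()].
#' @return Scalar in `[0, 1]`.
#' @export
precision_from_counts <- function(c) {
  if (c$TP + c$FP == 0) return(if (c$FN == 0) 1 else 0)
  c$TP / (c$TP + c$FP)
}

#' @rdname precision_from_counts
#' @export
specificity_from_counts <- function(c) {
  if (c$FP + c$TN == 0) return(1)
  c$TN / (c$FP + c$TN)
}

#' @rdname precision_from_counts
#' @export
dice_from_counts <- function(c) {
  den <- c$FP + 2 * c$TP + c$FN
  if (den == 0) return(1)
  2 * c$TP / den
}

# Surface point coordinates (mm) of a binary mask; falls back to all
# foreground voxels when the mask has no in-bounds background neighbour.
.surface_points <- function(mask, spacing) {
  mk <- mask > 0
  dim(mk) <- dim(mask)
  surf <- surface_voxels(mk)
  if (!any(surf)) surf <- mk
  sub <- arrayInd(which(surf), dim(mask))
  cbind(sub[, 1] * spacing[1], sub[, 2] * spacing[2], sub[, 3] * spacing[3])
}

#' 95th-percentile Hausdorff distance
#'
#' The default method pools the directed surface distances `d(X -> Y)` and
#' `d(Y -> X)` (minimum Euclidean distance from each surface voxel of one
#' mask to the surface of the other, in physical mm) and returns their 95th
#' percentile; it is symmetric in its arguments, zero for identical masks
#' and bounded above by the exact Hausdorff distance.
#' `method = "scaled_max"` instead returns 0.95 times the larger of the two
#' directed Hausdorff distances, provided for comparability with reports
#' that scale the maximum rather than take a percentile.
#'
#' @param pred,truth Binary 3D arrays (2D inputs are treated as one-slice
#'   volumes).
#' @param spacing mm voxel size triplet.
#' @param method `"percentile"` (default) or `"scaled_max"`.
#' @return Distance in mm, or `NA` when either mask is empty (an empty mask
#'   has no surface; the value is reported as missing, never 0).
#' @export
hd95 <- function(pred, truth, spacing = c(1, 1, 1),
                 method = c("percentile", "scaled_max")) {
  method <- match.arg(method)
  if (is.matrix(pred)) dim(pred) <- c(dim(pred), 1L)
  if (is.matrix(truth)) dim(truth) <- c(dim(truth), 1L)
  if (!identical(dim(pred), dim(truth))) stop("masks must share shape")
  if (!any(pred > 0) || !any(truth > 0)) return(NA_real_)
  a <- .surface_points(pred, spacing)
  b <- .surface_points(truth, spacing)
  dab <- min_point_dists(a, b)
  dba <- min_point_dists(b, a)
  if (method == "percentile") {
    unname(stats::quantile(c(dab, dba), 0.95))
  } else {
    0.95 * max(max(dab), max(dba))
  }
}

#' Decompose a mask into lesion instances
#'
#' Connected components under 26-connectivity in 3D (8-connectivity for a
#' single slice); each instance records its voxel indices, voxel count and
#' physical volume.
#'
#' @param mask Binary 3D (or 2D) array.
#' @param spacing mm voxel size triplet (or pair for 2D).
#' @param connectivity 26 (default) or 6.
#' @return List of `lesion_instance` lists, empty for an empty mask.
#' @export
extract_lesions <- function(mask, spacing = c(1, 1, 1), connectivity = 26L) {
  if (is.matrix(mask)) {
    dim(mask) <- c(dim(mask), 1L)
    spacing <- c(spacing[1:2], 1)
  }
  mk <- mask > 0
  dim(mk) <- dim(mask)
  lab <- label_components(mk, connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  voxvol <- prod(spacing)
  idx_by <- split(which(lab > 0), lab[lab > 0])
  lapply(seq_len(k), function(i) {
    vx <- idx_by[[as.character(i)]]
    list(id = i, voxels = vx, size = length(vx), volume = length(vx) * voxvol)
  })
}

#' Lesion-wise sensitivity
#'
#' A ground-truth lesion counts as detected (lesion-level TP) when the
#' prediction covers at least 50% of its voxels (boundary inclusive);
#' sensitivity is `TP / (TP + FN)` over lesions. Invariant to the order of
#' the instances. White matter hyperintensities are conventionally excluded
#' from this statistic (confluent lesions are not countable objects).
#'
#' @param pred Binary mask.
#' @param truth_instances Instances from [extract_lesions()] on the truth
#'   mask.
#' @param coverage Minimum covered fraction (default 0.5).
#' @return List with `sensitivity` (NA when there are no truth lesions),
#'   `tp_lesions`, `fn_lesions` and the per-lesion covered fractions.
#' @export
per_lesion_sensitivity <- function(pred, truth_instances, coverage = 0.5) {
  if (!length(truth_instances))
    return(list(sensitivity = NA_real_, tp_lesions = 0L, fn_lesions = 0L,
                coverages = numeric()))
  pv <- which(pred > 0)
  covs <- vapply(truth_instances, function(ins)
    sum(ins$voxels %in% pv) / ins$size, numeric(1))
  tp <- sum(covs >= coverage)
  list(sensitivity = tp / length(covs), tp_lesions = as.integer(tp),
       fn_lesions = as.integer(length(covs) - tp), coverages = covs)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples patients with replacement and returns the percentile interval
#' of the mean of a per-patient metric.
#'
#' @param values Per-patient metric values (length >= 2; NAs dropped).
#' @param n_boot Bootstrap replicates (warns below 100).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, n_boot = 2000L, level = 0.95, seed = 1L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  if (n_boot < 100L) warning("n_boot < 100 gives unstable intervals")
  means <- with_seed(seed, vapply(seq_len(n_boot), function(i)
    mean(values[sample.int(length(values), replace = TRUE)]), numeric(1)))
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha)))
}

#' Evaluate predicted against true masks for a cohort
#'
#' Per patient and marker: precision, specificity, Dice (voxelwise, on the
#' full 3D volume), HD95 and lesion-wise sensitivity (skipped for WMH).
#'
#' @param predictions List (per patient) of named binary mask lists.
#' @param truths List (per patient) of `lesion_ground_truth` objects.
#' @param spacing Named list of mm triplets per sequence (the marker's
#'   source-sequence spacing is used).
#' @param patient_ids Optional ids.
#' @return Data frame with one row per patient x marker.
#' @export
evaluate_segmentation <- function(predictions, truths, spacing,
                                  patient_ids = NULL) {
  src <- csvd_marker_source()
  rows <- list()
  for (i in seq_along(predictions)) {
    pid <- patient_ids[i] %||% sprintf("P%03d", i)
    for (m in names(predictions[[i]])) {
      pr <- predictions[[i]][[m]] + 0L
      tr <- truths[[i]]$masks[[m]] + 0L
      sp <- spacing[[src[[m]]]]
      cc <- confusion_counts(pr, tr)
      sen <- if (m == "WMH") NA_real_ else
        per_lesion_sensitivity(pr, extract_lesions(tr, sp))$sensitivity
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, marker = m,
        precision = precision_from_counts(cc),
        specificity = specificity_from_counts(cc),
        dice = dice_from_counts(cc),
        hd95 = hd95(pr, tr, sp),
        lesion_sensitivity = sen)
    }
  }
  do.call(rbind, rows)
}
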