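#' Read one sequence volume from disk
#'
#' Reads a NIfTI file and returns the intensity grid together with the voxel
#' spacing from the header. Fails loudly when the header carries no usable
#' spacing. DICOM series directories are not supported in this build (no
#' DICOM reader is available to R); convert series to NIfTI first.
#'
#' @param path Path to a NIfTI file (`.nii` / `.nii.gz`).
#' @param sequence_tag One of `"T1"`, `"FLAIR"`, `"SWI"`.
#' @return A `multiseq_volume` fragment holding this one sequence.
#' @export
read_volume <- function(path, sequence_tag) {
  sequence_tag <- match.arg(sequence_tag, csvd_sequences())
  if (dir.exists(path))
    stop("DICOM series directories are not supported; convert to NIfTI")
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("NIfTI header carries no usable voxel spacing: ", path)
  grid <- array(as.numeric(img), dim(img))
  vols <- stats::setNames(list(grid), sequence_tag)
  spn <- stats::setNames(list(as.numeric(sp)), sequence_tag)
  new_multiseq_volume(patient_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
                      volumes = vols, spacing = spn)
}

#' Min-max normalization to [0, 1]
#'
#' Maps `x` pointwise to `(x - min) / (max - min)`. A constant image maps to
#' all zeros. Idempotent: normalizing a normalized image changes nothing.
#'
#' @param x Numeric array.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) return(array(0, dim(x) %||% length(x)))
  (x - lo) / (hi - lo)
}

#' Resize a slice and normalize it
#'
#' Resizes a 2D slice to `target_size` x `target_size` (bilinear for images,
#' nearest-neighbour for masks so they stay binary), then min-max normalizes
#' the image. Masks are re-binarized, never normalized.
#'
#' @param image 2D numeric matrix.
#' @param target_size Edge length of the square output (e.g. 320).
#' @param masks Optional named list of binary matrices resized alongside.
#' @return List with `image` (in `[0, 1]`) and `masks`.
#' @export
normalize_resize <- function(image, target_size, masks = NULL) {
  if (!all(dim(image) == target_size)) {
    image <- EBImage::resize(EBImage::Image(image), w = target_size,
                             h = target_size)
    image <- matrix(EBImage::imageData(image), target_size, target_size)
  }
  image <- minmax_normalize(image)
  if (!is.null(masks)) {
    masks <- lapply(masks, function(mk) {
      if (!all(dim(mk) == target_size)) {
        mk <- EBImage::resize(EBImage::Image(mk + 0), w = target_size,
                              h = target_size, filter = "none")
        mk <- matrix(EBImage::imageData(mk), target_size, target_size)
      }
      (mk > 0.5) + 0L
    })
  }
  list(image = image, masks = masks)
}

#' One normalized training slice
#'
#' @param patient_id,sequence_tag,slice_index Identification.
#' @param image 2D matrix in `[0, 1]`.
#' @param labels Named list of binary matrices, one per marker.
#' @return A `slice_sample`; `is_positive` flags any labelled voxel.
#' @export
slice_sample <- function(patient_id, sequence_tag, slice_index, image, labels) {
  if (min(image) < 0 || max(image) > 1) stop("image values must lie in [0, 1]")
  for (l in labels) {
    if (!all(dim(l) == dim(image))) stop("image and labels must share shape")
    if (!all(l %in% c(0, 1))) stop("labels must be binary")
  }
  structure(list(patient_id = patient_id, sequence_tag = sequence_tag,
                 slice_index = slice_index, image = image, labels = labels,
                 is_positive = any(vapply(labels, function(l) any(l > 0),
                                          logical(1)))),
            class = "slice_sample")
}

#' Positive-sample augmentation policy
#'
#' The expansion realizes the stated factor of 11 exactly: the original
#' slice plus vertical flip, horizontal flip, rotations of +30 and -30
#' degrees, displacements of +/-20% along each in-plane axis, and scalings
#' by 0.8 and 1.2. Images are interpolated bilinearly, masks with nearest
#' neighbour, and all transforms pad with zeros.
#'
#' @param rotation_degrees Magnitude of the two rotations.
#' @param max_displacement_fraction Displacement as a fraction of the edge.
#' @param scale_range Low/high scale factors.
#' @return An `augmentation_policy` with `expansion_factor` 11.
#' @export
augmentation_policy <- function(rotation_degrees = 30,
                                max_displacement_fraction = 0.2,
                                scale_range = c(0.8, 1.2)) {
  structure(list(flips = c("vertical", "horizontal"),
                 rotation_degrees = rotation_degrees,
                 max_displacement_fraction = max_displacement_fraction,
                 scale_range = scale_range,
                 expansion_factor = 11L),
            class = "augmentation_policy")
}

# Backward-mapping affine transform of a slice about its centre:
# rotation (degrees), translation (pixels), isotropic scale. Zero padding;
# bilinear for images, nearest for masks.
affine_slice <- function(x, angle = 0, dx = 0, dy = 0, scale = 1,
                         interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(x); w <- ncol(x)
  cx <- (h + 1) / 2; cy <- (w + 1) / 2
  th <- angle * pi / 180
  gi <- matrix(seq_len(h) - cx, h, w)
  gj <- matrix(rep(seq_len(w) - cy, each = h), h, w)
  # inverse map: undo translation, rotation, scale
  ui <- gi - dx
  uj <- gj - dy
  si <- (cos(th) * ui + sin(th) * uj) / scale + cx
  sj <- (-sin(th) * ui + cos(th) * uj) / scale + cy
  out <- matrix(0, h, w)
  if (interp == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= h & rj >= 1 & rj <= w
    out[ok] <- x[cbind(ri[ok], rj[ok])]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    for (di in 0:1) {
      for (dj in 0:1) {
        ii <- i0 + di; jj <- j0 + dj
        ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
        wgt <- (if (di == 1) fi else 1 - fi) * (if (dj == 1) fj else 1 - fj)
        idx <- which(ok)
        out[idx] <- out[idx] + wgt[idx] * x[cbind(ii[idx], jj[idx])]
      }
    }
  }
  out
}

# Apply one named transform to image + masks jointly.
.apply_transform <- function(image, labels, tf) {
  tr_img <- switch(tf$kind,
    identity = image,
    vflip = image[rev(seq_len(nrow(image))), , drop = FALSE],
    hflip = image[, rev(seq_len(ncol(image))), drop = FALSE],
    affine = affine_slice(image, tf$angle, tf$dx, tf$dy, tf$scale, "bilinear"))
  tr_lab <- lapply(labels, function(l) {
    out <- switch(tf$kind,
      identity = l,
      vflip = l[rev(seq_len(nrow(l))), , drop = FALSE],
      hflip = l[, rev(seq_len(ncol(l))), drop = FALSE],
      affine = affine_slice(l, tf$angle, tf$dx, tf$dy, tf$scale, "nearest"))
    (out > 0.5) + 0L
  })
  list(image = pmin(pmax(tr_img, 0), 1), labels = tr_lab)
}

#' Augment one positive slice
#'
#' Expands a lesion-positive slice into exactly
#' `policy$expansion_factor` (11) samples; the identical transform is
#' applied to the image and every label mask, and masks are re-binarized
#' after interpolation. Negative slices are refused: augmentation is
#' positive-only to counter class imbalance.
#'
#' @param sample A positive [slice_sample()].
#' @param policy An [augmentation_policy()].
#' @return List of 11 `slice_sample` objects (original first).
#' @export
augment_positives <- function(sample, policy = augmentation_policy()) {
  stopifnot(inherits(sample, "slice_sample"))
  if (!sample$is_positive)
    stop("augmentation is positive-only; refusing a negative sample")
  h <- nrow(sample$image)
  dpix <- policy$max_displacement_fraction * h
  tfs <- list(
    list(kind = "identity"),
    list(kind = "vflip"),
    list(kind = "hflip"),
    list(kind = "affine", angle = policy$rotation_degrees, dx = 0, dy = 0, scale = 1),
    list(kind = "affine", angle = -policy$rotation_degrees, dx = 0, dy = 0, scale = 1),
    list(kind = "affine", angle = 0, dx = dpix, dy = 0, scale = 1),
    list(kind = "affine", angle = 0, dx = -dpix, dy = 0, scale = 1),
    list(kind = "affine", angle = 0, dx = 0, dy = dpix, scale = 1),
    list(kind = "affine", angle = 0, dx = 0, dy = -dpix, scale = 1),
    list(kind = "affine", angle = 0, dx = 0, dy = 0, scale = policy$scale_range[1]),
    list(kind = "affine", angle = 0, dx = 0, dy = 0, scale = policy$scale_range[2]))
  lapply(tfs, function(tf) {
    tr <- .apply_transform(sample$image, sample$labels, tf)
    slice_sample(sample$patient_id, sample$sequence_tag, sample$slice_index,
                 tr$image, tr$labels)
  })
}

#' Patient-level nested cross-validation plan
#'
#' Partitions patients into `k` folds as equal as possible (optionally
#' stratified on a key such as the burden level); for each held-out fold the
#' remaining patients are split 80:20 into train and validation at patient
#' level, with validation size `round(0.2 * n_remaining)`.
#'
#' @param patient_ids Character vector of ids.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the shuffles.
#' @param strata Optional vector (same length) used for stratified folding.
#' @return A `fold_plan` with `folds` and per-iteration train/validation ids.
#' @export
make_fold_plan <- function(patient_ids, k = 5L, seed = 1L, strata = NULL) {
  n <- length(patient_ids)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k patients")
  if (anyDuplicated(patient_ids)) stop("patient_ids must be unique")
  folds <- with_seed(seed, {
    fold_of <- integer(n)
    if (is.null(strata)) strata <- rep(1L, n)
    for (g in unique(strata)) {
      idx <- which(strata == g)
      idx <- idx[sample.int(length(idx))]
      # deal round-robin starting at a fold offset balancing overall sizes
      start <- (sum(fold_of > 0L)) %% k
      fold_of[idx] <- ((seq_along(idx) - 1L + start) %% k) + 1L
    }
    lapply(seq_len(k), function(f) patient_ids[fold_of == f])
  })
  iterations <- lapply(seq_len(k), function(f) {
    rest <- unlist(folds[-f], use.names = FALSE)
    n_val <- round(0.2 * length(rest))
    val <- with_seed(seed + f, sample(rest, n_val))
    list(test = folds[[f]], validation = val, train = setdiff(rest, val))
  })
  structure(list(k = k, folds = folds, iterations = iterations, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> k =", x$k, "| fold sizes:",
      paste(lengths(x$folds), collapse = ", "), "\n")
  invisible(x)
}

#' Build a slice dataset from phantom patients
#'
#' Extracts axial slices from each patient's sequences, per-slice min-max
#' normalizes them and attaches the label masks of the markers routed from
#' that sequence. Optionally keeps only lesion-positive slices (the training
#' regime) and applies the 11-fold positive augmentation.
#'
#' @param patients List of patients from [generate_cohort()].
#' @param routing Sequence-to-marker routing (default [default_routing()]).
#' @param sequences Which sequences to slice (default all in routing).
#' @param positive_only Keep only slices with at least one labelled voxel.
#' @param augment Apply [augment_positives()] to every positive slice.
#' @return List of [slice_sample()] objects.
#' @export
slice_dataset <- function(patients, routing = default_routing(),
                          sequences = names(routing), positive_only = TRUE,
                          augment = FALSE) {
  out <- list()
  for (p in patients) {
    for (sq in sequences) {
      markers <- routing[[sq]]
      vol <- p$volume$volumes[[sq]]
      if (is.null(vol)) next
      nz <- dim(vol)[3]
      for (z in seq_len(nz)) {
        labels <- lapply(markers, function(m) p$truth$masks[[m]][, , z] + 0L)
        names(labels) <- markers
        pos <- any(vapply(labels, function(l) any(l > 0), logical(1)))
        if (positive_only && !pos) next
        s <- slice_sample(p$volume$patient_id, sq, z,
                          minmax_normalize(vol[, , z]), labels)
        if (augment && pos) out <- c(out, augment_positives(s))
        else out <- c(out, list(s))
      }
    }
  }
  out
}
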