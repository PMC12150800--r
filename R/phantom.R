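#' Specification of a multisequence brain-MRI phantom
#'
#' Describes the geometry, lesion load and noise of the synthetic phantoms
#' that stand in for patient data. Phantoms are co-registered T1 / FLAIR /
#' SWI grids of a common shape containing an ellipsoidal "brain", a central
#' ellipsoidal ventricle surrogate (CSF signal) and an interior
#' "basal-ganglia" box used to count perivascular spaces.
#'
#' Lesion counts per marker are drawn as Poisson(rate * (1 + burden_level)),
#' stated explicitly so the generator has a testable null distribution.
#' Lesion geometry: WMH are anisotropic blobs 5-30 mm placed in a
#' periventricular shell; microbleeds spheres 2-10 mm; lacunes spheres
#' 3-15 mm carrying a one-voxel bright rim on FLAIR; perivascular spaces
#' thin cylinders (diameter 1-3 mm, length 3-20 mm), half of them directed
#' at the basal-ganglia box. Intensities are piecewise-constant tissue
#' classes plus i.i.d. Gaussian noise; there is no bias field, scanner or
#' registration simulation.
#'
#' @param image_shape Integer triplet, voxels per axis. Default desk scale
#'   64 x 64 x 24; larger grids (e.g. 320 x 320) are supported.
#' @param spacing Named list of mm voxel-size triplets for `T1`, `FLAIR`,
#'   `SWI`, or a single triplet used for all three. Default 3 x 3 x 5 mm,
#'   giving a roughly brain-sized field of view at desk scale.
#' @param lesion_rates Named non-negative expected counts per marker at
#'   burden level 0.
#' @param lesion_size_ranges Named list of mm diameter ranges per marker.
#' @param epvs_length_range mm length range of perivascular-space cylinders.
#' @param noise_sigma Gaussian noise standard deviation as a fraction of the
#'   intensity dynamic range.
#' @param seed Integer seed; identical spec + seed gives identical phantoms.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(image_shape = c(64L, 64L, 24L),
                         spacing = c(3, 3, 5),
                         lesion_rates = c(WMH = 2, CMB = 3, lacune = 2, EPVS = 6),
                         lesion_size_ranges = list(WMH = c(5, 30), CMB = c(2, 10),
                                                   lacune = c(3, 15), EPVS = c(1, 3)),
                         epvs_length_range = c(3, 20),
                         noise_sigma = 0.05,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 3L || any(image_shape <= 0L))
    stop("image_shape must be three positive integers")
  if (!is.list(spacing)) spacing <- list(T1 = spacing, FLAIR = spacing, SWI = spacing)
  if (!all(csvd_sequences() %in% names(spacing)))
    stop("spacing must cover T1, FLAIR and SWI")
  if (any(unlist(spacing) <= 0)) stop("all spacings must be > 0")
  mk <- csvd_markers()
  if (!all(mk %in% names(lesion_rates))) stop("lesion_rates must name all four markers")
  if (any(lesion_rates < 0)) stop("lesion_rates must be >= 0")
  for (m in mk) {
    r <- lesion_size_ranges[[m]]
    if (length(r) != 2L || r[1] > r[2] || r[1] <= 0)
      stop("lesion_size_ranges must be ordered positive low <= high")
  }
  if (epvs_length_range[1] > epvs_length_range[2]) stop("epvs_length_range out of order")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(image_shape = image_shape,
                 spacing = lapply(spacing[csvd_sequences()], as.numeric),
                 lesion_rates = lesion_rates[mk],
                 lesion_size_ranges = lesion_size_ranges[mk],
                 epvs_length_range = as.numeric(epvs_length_range),
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$image_shape, collapse = " x "),
      " voxels, seed ", x$seed, "\n", sep = "")
  cat("  rates:", paste(names(x$lesion_rates), x$lesion_rates,
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Reference tissue intensities (arbitrary units on a 0-100 scale).
.tissue <- list(
  T1    = c(background = 0, brain = 70, csf = 25),
  FLAIR = c(background = 0, brain = 65, csf = 12),
  SWI   = c(background = 0, brain = 60, csf = 45))
.lesion_intensity <- list(
  WMH = list(FLAIR = 95),
  CMB = list(SWI = 10),
  lacune = list(T1 = 25, FLAIR = 12),  # rim on FLAIR handled separately
  EPVS = list(T1 = 25))
.rim_intensity <- 92

# Phantom geometry in reference (T1) mm coordinates.
phantom_geometry <- function(spec) {
  shp <- spec$image_shape
  sp <- spec$spacing$T1
  cx <- (seq_len(shp[1]) - 0.5) * sp[1]
  cy <- (seq_len(shp[2]) - 0.5) * sp[2]
  cz <- (seq_len(shp[3]) - 0.5) * sp[3]
  ext <- shp * sp
  ctr <- ext / 2
  X <- array(cx, shp)
  Y <- array(rep(cy, each = shp[1]), shp)
  Z <- array(rep(cz, each = shp[1] * shp[2]), shp)
  brain_q <- ((X - ctr[1]) / (0.45 * ext[1]))^2 +
    ((Y - ctr[2]) / (0.45 * ext[2]))^2 +
    ((Z - ctr[3]) / (0.42 * ext[3]))^2
  vent_q <- ((X - ctr[1]) / (0.08 * ext[1]))^2 +
    ((Y - ctr[2]) / (0.12 * ext[2]))^2 +
    ((Z - ctr[3]) / (0.25 * ext[3]))^2
  bg_half <- 0.15 * ext
  bg_box <- abs(X - ctr[1]) <= bg_half[1] &
    abs(Y - ctr[2]) <= bg_half[2] &
    abs(Z - ctr[3]) <= bg_half[3]
  list(X = X, Y = Y, Z = Z, cx = cx, cy = cy, cz = cz, ext = ext, ctr = ctr,
       brain = brain_q <= 1, vent = vent_q <= 1, brain_q = brain_q,
       vent_q = vent_q, bg_box = bg_box, bg_half = bg_half)
}

# Voxelize one lesion inside a bounding box; returns linear indices or NULL.
# `kind` is "blob" (anisotropic ellipsoid), "sphere" or "cylinder".
.voxelize_lesion <- function(geo, shp, center, kind, diameter, length_mm = NULL,
                             axis_jitter = NULL, direction = NULL) {
  reach <- if (kind == "cylinder") length_mm / 2 + diameter else diameter
  ix <- which(abs(geo$cx - center[1]) <= reach)
  iy <- which(abs(geo$cy - center[2]) <= reach)
  iz <- which(abs(geo$cz - center[3]) <= reach)
  if (!length(ix) || !length(iy) || !length(iz)) return(NULL)
  px <- array(geo$cx[ix] - center[1], c(length(ix), length(iy), length(iz)))
  py <- array(rep(geo$cy[iy] - center[2], each = length(ix)), dim(px))
  pz <- array(rep(geo$cz[iz] - center[3], each = length(ix) * length(iy)), dim(px))
  if (kind == "cylinder") {
    u <- direction / sqrt(sum(direction^2))
    t <- px * u[1] + py * u[2] + pz * u[3]
    rad2 <- (px - t * u[1])^2 + (py - t * u[2])^2 + (pz - t * u[3])^2
    inside <- abs(t) <= length_mm / 2 & rad2 <= (diameter / 2)^2
  } else {
    r <- rep(diameter / 2, 3)
    if (!is.null(axis_jitter)) r <- r * axis_jitter
    inside <- (px / r[1])^2 + (py / r[2])^2 + (pz / r[3])^2 <= 1
  }
  # guarantee at least the voxel nearest the centre, so every drawn lesion
  # is realised even when thinner than a voxel
  if (!any(inside)) {
    nearest <- which.min(px^2 + py^2 + pz^2)
    inside[nearest] <- TRUE
  }
  grid <- as.matrix(expand.grid(ix = ix, iy = iy, iz = iz))
  list(idx = grid[as.vector(inside), 1L] +
         (grid[as.vector(inside), 2L] - 1L) * shp[1] +
         (grid[as.vector(inside), 3L] - 1L) * shp[1] * shp[2],
       sub = inside, ix = ix, iy = iy, iz = iz)
}

# Linear indices of the one-voxel 26- (or 6-) neighbourhood expansion of a
# lesion's sub-box mask, clipped to the grid.
.expand_idx <- function(les, shp, connectivity) {
  d <- dim(les$sub)
  sub <- les$sub
  dim(sub) <- c(d, 1L)[seq_len(max(3L, length(d)))]
  if (length(dim(sub)) < 3L) dim(sub) <- c(dim(sub), 1L)
  grown <- array(FALSE, dim(sub) + 2L)
  grown[seq_len(d[1]) + 1L, seq_len(d[2]) + 1L, seq_len(d[3]) + 1L] <- sub
  gd <- dilate_mask(grown, connectivity)
  ixg <- c(les$ix[1] - 1L, les$ix, les$ix[length(les$ix)] + 1L)
  iyg <- c(les$iy[1] - 1L, les$iy, les$iy[length(les$iy)] + 1L)
  izg <- c(les$iz[1] - 1L, les$iz, les$iz[length(les$iz)] + 1L)
  keep <- which(gd & !grown)
  if (!length(keep)) return(integer())
  sub2ind <- arrayInd(keep, dim(grown))
  gx <- ixg[sub2ind[, 1]]; gy <- iyg[sub2ind[, 2]]; gz <- izg[sub2ind[, 3]]
  ok <- gx >= 1L & gx <= shp[1] & gy >= 1L & gy <= shp[2] & gz >= 1L & gz <= shp[3]
  gx[ok] + (gy[ok] - 1L) * shp[1] + (gz[ok] - 1L) * shp[1] * shp[2]
}

#' Generate one synthetic patient
#'
#' Draws lesion counts as Poisson(rate * (1 + burden_level)) per marker,
#' places non-overlapping lesions inside the phantom brain and renders the
#' three sequence grids with their marker-specific contrast: WMH hyperintense
#' on FLAIR only, microbleeds hypointense on SWI only, lacunes CSF-like on
#' T1/FLAIR with a bright FLAIR rim, perivascular spaces thin CSF-like tubes
#' on T1. Ground-truth masks cover exactly the inserted lesions; lesions of
#' all markers are kept mutually non-adjacent so connected components equal
#' inserted instances.
#'
#' @param spec A [phantom_spec()].
#' @param burden_level Ordinal 0-4 global severity; scales the Poisson rates.
#' @param patient_id Optional identifier.
#' @return List with elements `volume` (a `multiseq_volume`) and `truth`
#'   (a `lesion_ground_truth`).
#' @export
generate_patient <- function(spec, burden_level = 0L, patient_id = "P001") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(burden_level) != 1L || is.na(burden_level) ||
      burden_level < 0 || burden_level > 4)
    stop("burden_level must be a single value in 0..4")
  with_seed(spec$seed, .generate_patient_impl(spec, as.integer(burden_level), patient_id))
}

.generate_patient_impl <- function(spec, burden_level, patient_id) {
  shp <- spec$image_shape
  geo <- phantom_geometry(spec)
  nvox <- prod(shp)
  occ <- logical(nvox)              # all lesion voxels incl. lacune rims
  masks <- lapply(csvd_markers(), function(m) {
    a <- array(FALSE, shp); a
  })
  names(masks) <- csvd_markers()
  rim_idx <- integer()
  interior <- geo$brain_q <= 0.85 & !(geo$vent_q <= 1.4)
  allowed <- list(
    WMH = interior & geo$vent_q > 1.4 & geo$vent_q <= 6,
    CMB = interior,
    lacune = interior,
    EPVS = interior)
  counts_drawn <- vapply(csvd_markers(), function(m)
    stats::rpois(1L, spec$lesion_rates[[m]] * (1 + burden_level)), integer(1))

  for (m in csvd_markers()) {
    rng <- spec$lesion_size_ranges[[m]]
    n <- counts_drawn[[m]]
    if (n == 0L) next
    for (j in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(30L)) {
        pool_mask <- allowed[[m]] & !occ
        if (m == "EPVS" && j %% 2L == 1L) {
          bg_pool <- pool_mask & geo$bg_box
          if (any(bg_pool)) pool_mask <- bg_pool
        }
        pool <- which(pool_mask)
        if (!length(pool)) break
        v <- pool[sample.int(length(pool), 1L)]
        sub <- arrayInd(v, shp)
        center <- c(geo$cx[sub[1]], geo$cy[sub[2]], geo$cz[sub[3]]) +
          stats::runif(3, -0.5, 0.5) * spec$spacing$T1
        d <- stats::runif(1, rng[1], rng[2])
        les <- switch(m,
          WMH = .voxelize_lesion(geo, shp, center, "blob", d,
                                 axis_jitter = stats::runif(3, 0.7, 1.3)),
          CMB = .voxelize_lesion(geo, shp, center, "sphere", d),
          lacune = .voxelize_lesion(geo, shp, center, "sphere", d,
                                    axis_jitter = stats::runif(3, 0.8, 1.2)),
          EPVS = {
            u <- stats::rnorm(3)
            .voxelize_lesion(geo, shp, center, "cylinder", d,
                             length_mm = stats::runif(1, spec$epvs_length_range[1],
                                                      spec$epvs_length_range[2]),
                             direction = u)
          })
        if (is.null(les) || !length(les$idx)) next
        # must lie in brain parenchyma and keep one voxel clearance from
        # everything already placed (no merging of connected components)
        if (any(!(geo$brain_q[les$idx] <= 1)) || any(geo$vent_q[les$idx] <= 1)) next
        halo <- .expand_idx(les, shp, 26L)
        if (any(occ[les$idx]) || any(occ[halo])) next
        if (m == "lacune") {
          rim <- .expand_idx(les, shp, 6L)
          rim_idx <- c(rim_idx, rim)
          occ[rim] <- TRUE
        }
        masks[[m]][les$idx] <- TRUE
        occ[les$idx] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) next  # space exhausted; lesion skipped
    }
  }

  vols <- list()
  for (sq in csvd_sequences()) {
    ti <- .tissue[[sq]]
    g <- array(ti[["background"]], shp)
    g[geo$brain] <- ti[["brain"]]
    g[geo$vent] <- ti[["csf"]]
    for (m in csvd_markers()) {
      li <- .lesion_intensity[[m]][[sq]]
      if (!is.null(li)) g[masks[[m]]] <- li
    }
    if (sq == "FLAIR" && length(rim_idx)) g[rim_idx] <- .rim_intensity
    g <- g + stats::rnorm(nvox, 0, spec$noise_sigma * 100)
    vols[[sq]] <- g
  }

  truth <- new_lesion_ground_truth(masks, spec, geo)
  list(volume = new_multiseq_volume(patient_id, vols, spec$spacing),
       truth = truth, burden_level = burden_level)
}

#' Co-registered multisequence volume
#'
#' @param patient_id Identifier.
#' @param volumes Named list of 3D arrays (tags among T1/FLAIR/SWI).
#' @param spacing Named list of mm triplets per sequence.
#' @return A `multiseq_volume`.
#' @export
new_multiseq_volume <- function(patient_id, volumes, spacing) {
  if (!all(names(volumes) %in% csvd_sequences()))
    stop("sequence tags must be among T1, FLAIR, SWI")
  if (!all(vapply(volumes, function(v) all(is.finite(v)), logical(1))))
    stop("volume grids must be finite")
  structure(list(patient_id = patient_id, volumes = volumes,
                 spacing = spacing[names(volumes)]),
            class = "multiseq_volume")
}

# Build ground-truth object: per-marker instance decomposition and counts.
new_lesion_ground_truth <- function(masks, spec, geo) {
  src <- csvd_marker_source()
  instances <- list()
  counts <- integer(length(csvd_markers()))
  names(counts) <- csvd_markers()
  epvs_bg <- 0L
  for (m in csvd_markers()) {
    voxvol <- prod(spec$spacing[[src[[m]]]])
    lab <- label_components(masks[[m]], 26L)
    k <- max(lab)
    counts[[m]] <- k
    inst <- vector("list", k)
    if (k > 0) {
      idx_by <- split(which(lab > 0), lab[lab > 0])
      for (i in seq_len(k)) {
        vx <- idx_by[[as.character(i)]]
        sub <- arrayInd(vx, spec$image_shape)
        cen <- c(mean(geo$cx[sub[, 1]]), mean(geo$cy[sub[, 2]]), mean(geo$cz[sub[, 3]]))
        inst[[i]] <- list(marker = m, voxels = vx, size = length(vx),
                          volume = length(vx) * voxvol, centroid = cen)
        if (m == "EPVS" &&
            all(abs(cen - geo$ctr) <= geo$bg_half)) epvs_bg <- epvs_bg + 1L
      }
    }
    instances[[m]] <- inst
  }
  structure(list(masks = masks, instances = instances, counts = counts,
                 epvs_bg_count = epvs_bg),
            class = "lesion_ground_truth")
}

#' Generate a phantom cohort
#'
#' Patient seeds are derived deterministically from `spec$seed`; burden
#' levels cycle 0..4 across the cohort unless given. Optionally writes one
#' NIfTI file per sequence and per marker mask plus a CSV manifest
#' (patient id, burden level, true counts and volumes).
#'
#' @param spec A [phantom_spec()].
#' @param n_patients Number of patients (>= 1).
#' @param out_dir Optional output directory; refuses to overwrite an
#'   existing one unless `force = TRUE`.
#' @param burden_levels Optional integer vector recycled over patients.
#' @param keep_patients Keep generated volumes in memory (set `FALSE` when
#'   only the manifest or on-disk files are needed).
#' @param force Overwrite an existing `out_dir`.
#' @return List with `manifest` (data frame), `patients` (list or NULL) and
#'   `out_dir`.
#' @export
generate_cohort <- function(spec, n_patients, out_dir = NULL,
                            burden_levels = NULL, keep_patients = TRUE,
                            force = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && !force)
      stop("cohort directory exists; use force = TRUE to overwrite")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  if (is.null(burden_levels)) burden_levels <- rep(0:4, length.out = n_patients)
  burden_levels <- rep(burden_levels, length.out = n_patients)
  rows <- vector("list", n_patients)
  patients <- if (keep_patients) vector("list", n_patients) else NULL
  for (i in seq_len(n_patients)) {
    sd_i <- as.integer((as.double(spec$seed) + 7919 * i) %% 2147483647)
    sp_i <- spec
    sp_i$seed <- sd_i
    pid <- sprintf("P%03d", i)
    p <- generate_patient(sp_i, burden_levels[i], pid)
    src <- csvd_marker_source()
    volumes <- vapply(csvd_markers(), function(m)
      sum(p$truth$masks[[m]]) * prod(spec$spacing[[src[[m]]]]), numeric(1))
    rows[[i]] <- data.frame(patient_id = pid, burden_level = burden_levels[i],
                            seed = sd_i,
                            t(stats::setNames(as.numeric(p$truth$counts),
                                              paste0("count_", csvd_markers()))),
                            t(stats::setNames(volumes,
                                              paste0("volume_", csvd_markers()))),
                            epvs_bg_count = p$truth$epvs_bg_count)
    if (!is.null(out_dir)) write_patient_nifti(p, out_dir)
    if (keep_patients) patients[[i]] <- p
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, patients = patients, out_dir = out_dir)
}

# Write one patient's sequences and masks as NIfTI with correct pixdim.
write_patient_nifti <- function(patient, out_dir) {
  pid <- patient$volume$patient_id
  for (sq in names(patient$volume$volumes)) {
    img <- RNifti::asNifti(patient$volume$volumes[[sq]])
    RNifti::pixdim(img) <- patient$volume$spacing[[sq]]
    RNifti::writeNifti(img, file.path(out_dir, paste0(pid, "_", sq, ".nii.gz")))
  }
  src <- csvd_marker_source()
  for (m in csvd_markers()) {
    img <- RNifti::asNifti(patient$truth$masks[[m]] + 0L)
    RNifti::pixdim(img) <- patient$volume$spacing[[src[[m]]]]
    RNifti::writeNifti(img, file.path(out_dir, paste0(pid, "_mask_", m, ".nii.gz")))
  }
  invisible(NULL)
}
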