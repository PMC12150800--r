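# Independent brute-force oracles used to cross-check the metric
# implementations. These deliberately avoid the package's compiled kernels:
# everything here is plain R loops / vectorized arithmetic.

# Per-voxel confusion counts by explicit loop.
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  p <- as.logical(pred)
  t <- as.logical(truth)
  for (i in seq_along(p)) {
    if (p[i] && t[i]) tp <- tp + 1L
    else if (!p[i] && !t[i]) tn <- tn + 1L
    else if (p[i] && !t[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Surface voxels in plain R: foreground with an in-bounds background face
# neighbour; falls back to all foreground voxels when none qualifies.
oracle_surface <- function(mask) {
  d <- dim(mask)
  fg <- which(mask > 0)
  if (!length(fg)) return(integer())
  sub <- arrayInd(fg, d)
  is_surf <- logical(length(fg))
  for (k in seq_along(fg)) {
    v <- sub[k, ]
    for (ax in 1:3) {
      for (s in c(-1L, 1L)) {
        nb <- v
        nb[ax] <- nb[ax] + s
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        if (mask[nb[1], nb[2], nb[3]] == 0) {
          is_surf[k] <- TRUE
        }
      }
    }
  }
  if (!any(is_surf)) fg else fg[is_surf]
}

# All-pairs HD95 oracle: pooled directed surface distances, 95th percentile.
oracle_hd95 <- function(pred, truth, spacing = c(1, 1, 1)) {
  if (!any(pred > 0) || !any(truth > 0)) return(NA_real_)
  d <- dim(pred)
  pa <- arrayInd(oracle_surface(pred), d)
  pb <- arrayInd(oracle_surface(truth), d)
  a <- sweep(pa, 2, spacing, `*`)
  b <- sweep(pb, 2, spacing, `*`)
  dd <- sqrt(outer(a[, 1], b[, 1], `-`)^2 +
               outer(a[, 2], b[, 2], `-`)^2 +
               outer(a[, 3], b[, 3], `-`)^2)
  unname(stats::quantile(c(apply(dd, 1, min), apply(dd, 2, min)), 0.95))
}

# Exact (maximum) Hausdorff distance on the same surfaces.
oracle_hausdorff <- function(pred, truth, spacing = c(1, 1, 1)) {
  d <- dim(pred)
  pa <- arrayInd(oracle_surface(pred), d)
  pb <- arrayInd(oracle_surface(truth), d)
  a <- sweep(pa, 2, spacing, `*`)
  b <- sweep(pb, 2, spacing, `*`)
  dd <- sqrt(outer(a[, 1], b[, 1], `-`)^2 +
               outer(a[, 2], b[, 2], `-`)^2 +
               outer(a[, 3], b[, 3], `-`)^2)
  max(max(apply(dd, 1, min)), max(apply(dd, 2, min)))
}

# Random test mask: a few solid balls plus salt noise, possibly empty-free.
random_mask <- function(shape, n_blobs = 2, salt = 0.01) {
  m <- array(0L, shape)
  sub <- arrayInd(seq_len(prod(shape)), shape)
  for (b in seq_len(n_blobs)) {
    c0 <- runif(3, 1, shape)
    r <- runif(1, 1, max(2, min(shape) / 3))
    inside <- (sub[, 1] - c0[1])^2 + (sub[, 2] - c0[2])^2 +
      (sub[, 3] - c0[3])^2 <= r^2
    m[inside] <- 1L
  }
  m[runif(prod(shape)) < salt] <- 1L
  if (!any(m > 0)) m[sample(prod(shape), 1)] <- 1L
  m
}
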