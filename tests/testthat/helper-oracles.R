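# Brute-force oracles, kept deliberately naive and independent of the
# package implementations they check.

# voxel-centre coordinates of all occupied voxels (LPS mm), via explicit loop
oracle_occupied_coords <- function(mask) {
  dm <- dim(mask$voxels)
  out <- NULL
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (mask$voxels[i, j, k]) {
      out <- rbind(out, mask$origin + (c(i, j, k) - 1) * mask$spacing)
    }
  }
  out
}

oracle_centroid <- function(mask) {
  colMeans(oracle_occupied_coords(mask))
}

oracle_overlap <- function(m1, m2) {
  n1 <- 0L; n2 <- 0L; ni <- 0L; nu <- 0L
  v1 <- as.vector(m1$voxels); v2 <- as.vector(m2$voxels)
  for (q in seq_along(v1)) {
    if (v1[q]) n1 <- n1 + 1L
    if (v2[q]) n2 <- n2 + 1L
    if (v1[q] && v2[q]) ni <- ni + 1L
    if (v1[q] || v2[q]) nu <- nu + 1L
  }
  list(dice = 2 * ni / (n1 + n2), jaccard = ni / nu)
}

# boundary via explicit 6-neighbour scan
oracle_boundary_coords <- function(mask) {
  dm <- dim(mask$voxels)
  v <- mask$voxels
  out <- NULL
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    if (!v[i, j, k]) next
    nb <- c(
      if (i > 1) v[i - 1, j, k] else FALSE,
      if (i < dm[1]) v[i + 1, j, k] else FALSE,
      if (j > 1) v[i, j - 1, k] else FALSE,
      if (j < dm[2]) v[i, j + 1, k] else FALSE,
      if (k > 1) v[i, j, k - 1] else FALSE,
      if (k < dm[3]) v[i, j, k + 1] else FALSE
    )
    if (!all(nb)) out <- rbind(out, mask$origin + (c(i, j, k) - 1) * mask$spacing)
  }
  out
}

# all-pairs symmetric mean surface distance
oracle_mda <- function(m1, m2) {
  b1 <- oracle_boundary_coords(m1)
  b2 <- oracle_boundary_coords(m2)
  d12 <- apply(b1, 1, function(p)
    sqrt(min(colSums((t(b2) - p)^2))))
  d21 <- apply(b2, 1, function(p)
    sqrt(min(colSums((t(b1) - p)^2))))
  mean(c(d12, d21))
}

# per-voxel Euclidean scan for isotropic expansion
oracle_expand_iso <- function(mask, margin) {
  occ <- oracle_occupied_coords(mask)
  dm <- dim(mask$voxels)
  out <- array(FALSE, dm)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    p <- mask$origin + (c(i, j, k) - 1) * mask$spacing
    d2 <- min(colSums((t(occ) - p)^2))
    out[i, j, k] <- d2 <= margin^2 + 1e-9
  }
  out
}

# per-voxel signed-direction box scan for anisotropic expansion;
# v occupied iff some occupied u has (u - v) in [-l, r] x [-p, a] x [-s, i]
oracle_expand_aniso <- function(mask, mg) {
  occ <- oracle_occupied_coords(mask)
  dm <- dim(mask$voxels)
  out <- array(FALSE, dm)
  eps <- 1e-9
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    p <- mask$origin + (c(i, j, k) - 1) * mask$spacing
    du <- t(occ) - p
    hit <- du[1, ] >= -mg[["l"]] - eps & du[1, ] <= mg[["r"]] + eps &
           du[2, ] >= -mg[["p"]] - eps & du[2, ] <= mg[["a"]] + eps &
           du[3, ] >= -mg[["s"]] - eps & du[3, ] <= mg[["i"]] + eps
    out[i, j, k] <- any(hit)
  }
  out
}

# per-direction extreme face coordinates by explicit scan
oracle_extents <- function(mask) {
  occ <- oracle_occupied_coords(mask)
  sp <- mask$spacing
  c(r = -(min(occ[, 1]) - sp[1] / 2), l = max(occ[, 1]) + sp[1] / 2,
    a = -(min(occ[, 2]) - sp[2] / 2), p = max(occ[, 2]) + sp[2] / 2,
    s = max(occ[, 3]) + sp[3] / 2,   i = -(min(occ[, 3]) - sp[3] / 2))
}

oracle_margins <- function(itv2, itv1) {
  e1 <- oracle_extents(itv1)
  e2 <- oracle_extents(itv2)
  pmax(e1[c("r", "l", "a", "p", "s", "i")] - e2[c("r", "l", "a", "p", "s", "i")], 0)
}

# type-7 quantile from the defining formula, on sorted data
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (if (lo < length(x)) x[lo + 1] - x[lo] else 0)
}

oracle_tukey_outliers <- function(x) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  iqr <- q3 - q1
  x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr
}

# random blobby test mask: union of 1-3 random ellipsoids, guaranteed
# non-empty
random_mask <- function(dims = c(14, 12, 10), spacing = c(1, 1.5, 2),
                        origin = c(0, 0, 0), n_blobs = NULL) {
  if (is.null(n_blobs)) n_blobs <- sample(1:3, 1)
  ext <- (dims - 1) * spacing
  arr <- array(FALSE, dims)
  cx <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  for (b in seq_len(n_blobs)) {
    ctr <- origin + runif(3, 0.25, 0.75) * ext
    rad <- runif(3, 0.15, 0.4) * ext
    q <- outer(outer(((cx - ctr[1]) / rad[1])^2,
                     ((cy - ctr[2]) / rad[2])^2, `+`),
               ((cz - ctr[3]) / rad[3])^2, `+`)
    arr <- arr | (q <= 1)
  }
  if (!any(arr)) arr[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                     ceiling(dims[3] / 2)] <- TRUE
  voxel_mask(arr, spacing = spacing, origin = origin)
}

# compact phantom spec for fast scenario tests
small_phantom_spec <- function(motion_amplitude = c(0, 0, 8), ...) {
  phantom_spec(grid_dims = c(36, 36, 28), spacing = c(1, 1, 2),
               lesion_center = c(18, 18, 27), lesion_radii = c(7, 7, 7),
               motion_amplitude = motion_amplitude,
               aorta_center_xy = c(8, 8), aorta_diameter = 10, ...)
}

masks_equal <- function(a, b) {
  identical(a$voxels, b$voxels) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-6
}
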