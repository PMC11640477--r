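# Internal grid machinery shared by masks, CT volumes and metrics.
#
# Canonical patient frame: LPS (+x toward Left, +y toward Posterior,
# +z toward Superior), grid axes stored in that order.  `origin` is the
# LPS coordinate (mm) of the centre of voxel [1,1,1]; voxel centres along
# axis a are origin[a] + (i-1)*spacing[a].

.DIR_POS <- c("L", "P", "S")  # label of +axis direction, canonical order
.DIR_NEG <- c("R", "A", "I")

# axis index (1=RL, 2=AP, 3=IS) and sign (+1 = canonical positive) of a label
.axis_of_label <- function(lab) {
  i <- match(lab, .DIR_POS)
  if (!is.na(i)) return(c(axis = i, sign = 1))
  i <- match(lab, .DIR_NEG)
  if (!is.na(i)) return(c(axis = i, sign = -1))
  stop("unknown patient-direction label: '", lab, "'", call. = FALSE)
}

# Reorient an array stored with arbitrary axis-aligned patient labels into
# the canonical (+L, +P, +S) frame.  `axis_labels[g]` is the patient
# direction of increasing index along grid axis g; `origin` is the LPS
# point of the first stored voxel's centre.
canonicalize_axes <- function(voxels, spacing, origin, axis_labels) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L,
            length(origin) == 3L, length(axis_labels) == 3L)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  info <- vapply(axis_labels, .axis_of_label, numeric(2))
  pax <- info["axis", ]
  sgn <- info["sign", ]
  if (!setequal(pax, 1:3))
    stop("axis_labels must name one axis from each of R/L, A/P, S/I",
         call. = FALSE)
  dm <- dim(voxels)
  for (g in 1:3) {
    if (sgn[g] < 0) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[g]] <- dm[g]:1
      voxels <- do.call(`[`, c(list(voxels), idx, list(drop = FALSE)))
      origin[pax[g]] <- origin[pax[g]] - spacing[g] * (dm[g] - 1)
    }
  }
  perm <- order(pax)  # perm[j]: grid axis holding patient axis j
  voxels <- aperm(voxels, perm)
  list(voxels = voxels, spacing = unname(spacing[perm]),
       origin = unname(origin))
}

# Shift a logical 3D array by integer voxel offsets, filling with FALSE.
# Returns list(arr, clipped): clipped is TRUE when occupied voxels fell
# off the grid.
shift_logical <- function(arr, d) {
  dm <- dim(arr)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- max(1L, 1L - d[a]):min(dm[a], dm[a] - d[a])
    if (s[1] > s[length(s)] || min(dm[a], dm[a] - d[a]) < max(1L, 1L - d[a])) {
      return(list(arr = array(FALSE, dm), clipped = any(arr)))
    }
    src[[a]] <- s
    dst[[a]] <- s + d[a]
  }
  out <- array(FALSE, dm)
  block <- arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out[dst[[1]], dst[[2]], dst[[3]]] <- block
  list(arr = out, clipped = sum(block) < sum(arr))
}

# Face-connectivity boundary: occupied voxels with >= 1 of their 6 face
# neighbours unoccupied; faces on the grid edge count as unoccupied.
boundary_voxels <- function(arr) {
  interior <- arr
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      d <- integer(3)
      d[a] <- s
      interior <- interior & shift_logical(arr, d)$arr
    }
  }
  arr & !interior
}

# 1D squared-distance transform (lower envelope of parabolas), sample
# positions i*s.  Accepts Inf entries (no source on that line).
.dt1d <- function(f, s) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 0L
  for (q in fin) {
    xq <- q * s
    sec <- Inf
    while (k > 0L) {
      p <- v[k]
      xp <- p * s
      sec <- ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2 * (xq - xp))
      if (sec <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else sec
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    xq <- q * s
    while (z[j + 1L] < xq) j <- j + 1L
    p <- v[j]
    d[q] <- (xq - p * s)^2 + f[p]
  }
  d
}

# Exact squared Euclidean distance (mm^2) from every voxel centre to the
# nearest TRUE voxel centre, with anisotropic spacing (separable passes).
edt_squared <- function(arr, spacing) {
  dm <- dim(arr)
  f <- array(ifelse(arr, 0, Inf), dm)
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    g <- aperm(f, perm)
    m <- matrix(g, nrow = dm[a])
    for (col in seq_len(ncol(m))) {
      if (any(is.finite(m[, col]))) m[, col] <- .dt1d(m[, col], spacing[a])
    }
    g <- array(m, dim(g))
    f <- aperm(g, order(perm))
  }
  f
}

# round half away from zero, the convention used for reported mm values
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
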