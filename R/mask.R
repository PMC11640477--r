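#' Binary structure mask on a physical voxel grid
#'
#' `voxel_mask()` wraps a logical 3D array together with its physical
#' geometry (voxel spacing in mm, origin in mm, patient-axis labels) into
#' the container used by every downstream operation (ITV construction,
#' margin expansion, contour comparison).  On construction the array is
#' reoriented into a single canonical patient frame -- LPS, i.e. grid axis
#' 1 increases toward Left, axis 2 toward Posterior, axis 3 toward
#' Superior -- so that direction-dependent operations (six-direction
#' margins, superior-inferior slice location) are unambiguous.
#'
#' Voxel coordinates refer to voxel centres: the centre of voxel
#' `[i, j, k]` is `origin + (c(i, j, k) - 1) * spacing` (mm, LPS).
#'
#' @param voxels logical (or 0/1 numeric) 3D array of occupancy.
#' @param spacing numeric(3), voxel size in mm along each grid axis (> 0).
#' @param origin numeric(3), LPS coordinate (mm) of the centre of the
#'   first stored voxel.
#' @param axis_labels character(3), patient direction of increasing index
#'   along each stored grid axis, one of `"R","L","A","P","S","I"`; must
#'   cover all three anatomical axes.  Default `c("L","P","S")` (already
#'   canonical).
#' @return An object of class `voxel_mask` with fields `voxels` (logical
#'   array in canonical LPS order), `spacing`, `origin`.
#' @examples
#' m <- voxel_mask(array(TRUE, c(2, 2, 2)), spacing = c(1, 1, 2))
#' mask_volume(m)  # 8 voxels * 2 mm^3
#' @export
voxel_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       axis_labels = c("L", "P", "S")) {
  if (is.numeric(voxels)) {
    bad <- !(voxels %in% c(0, 1))
    if (any(bad)) stop("voxels must be binary (0/1 or logical)", call. = FALSE)
    voxels <- array(voxels != 0, dim(voxels))
  }
  if (!is.logical(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a logical 3D array", call. = FALSE)
  can <- canonicalize_axes(voxels, as.numeric(spacing), as.numeric(origin),
                           axis_labels)
  structure(list(voxels = can$voxels, spacing = can$spacing,
                 origin = can$origin),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  dm <- dim(x$voxels)
  cat(sprintf("<voxel_mask> %d x %d x %d voxels, spacing %s mm (LPS)\n",
              dm[1], dm[2], dm[3],
              paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  occupied: %d voxels, %.2f cc\n", sum(x$voxels),
              mask_volume(x) / 1000))
  invisible(x)
}

#' Mask volume
#'
#' Physical volume of the occupied voxels: `count * prod(spacing)`.
#'
#' @param mask a [voxel_mask].
#' @param units `"mm3"` (default) or `"cc"`.
#' @return numeric volume.
#' @export
mask_volume <- function(mask, units = c("mm3", "cc")) {
  units <- match.arg(units)
  v <- sum(mask$voxels) * prod(mask$spacing)
  if (units == "cc") v / 1000 else v
}

# error if two masks do not live on the same grid, naming the field
check_same_grid <- function(m1, m2) {
  if (!identical(dim(m1$voxels), dim(m2$voxels)))
    stop("grid mismatch: dims differ", call. = FALSE)
  if (max(abs(m1$spacing - m2$spacing)) > 1e-9)
    stop("grid mismatch: spacing differs", call. = FALSE)
  if (max(abs(m1$origin - m2$origin)) > 1e-6)
    stop("grid mismatch: origin differs", call. = FALSE)
  invisible(TRUE)
}

# voxel-centre coordinates along one canonical axis
axis_coords <- function(mask, a) {
  mask$origin[a] + (seq_len(dim(mask$voxels)[a]) - 1) * mask$spacing[a]
}

#' Union of respiratory phase masks (ITV construction)
#'
#' Voxelwise OR of structure masks sharing one grid.  Applied to the ten
#' respiratory-phase GTV masks of a 4DCT this yields the internal target
#' volume (ITV), the envelope of the tumour over the breathing cycle.
#'
#' @param masks list of [voxel_mask] objects on identical grids.
#' @return a [voxel_mask], the voxelwise union.
#' @export
union_phases <- function(masks) {
  if (!is.list(masks) || length(masks) < 1L)
    stop("need at least one mask", call. = FALSE)
  for (m in masks) {
    if (!inherits(m, "voxel_mask")) stop("all inputs must be voxel_mask",
                                         call. = FALSE)
    check_same_grid(masks[[1]], m)
  }
  out <- masks[[1]]
  if (length(masks) > 1L) {
    for (m in masks[-1]) out$voxels <- out$voxels | m$voxels
  }
  out
}

#' Isotropic margin expansion (PTV construction)
#'
#' Euclidean dilation in physical millimetres: a voxel belongs to the
#' output iff its centre lies within `margin_mm` of some occupied voxel
#' centre of the input.  With the conventional 5 mm margin this turns an
#' ITV into a planning target volume (PTV).  Expansion that would extend
#' beyond the grid is clipped with a warning (attribute `clipped`).
#'
#' @param mask a [voxel_mask].
#' @param margin_mm non-negative margin in mm.
#' @return expanded [voxel_mask]; `attr(, "clipped")` is TRUE when the
#'   expansion was truncated by the grid boundary.
#' @export
expand_isotropic <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L || margin_mm < 0)
    stop("margin_mm must be a single non-negative number", call. = FALSE)
  if (margin_mm == 0) return(mask)
  sp <- mask$spacing
  mi <- floor(margin_mm / sp + 1e-9)
  offs <- as.matrix(expand.grid(dx = -mi[1]:mi[1], dy = -mi[2]:mi[2],
                                dz = -mi[3]:mi[3]))
  d2 <- (offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 + (offs[, 3] * sp[3])^2
  offs <- offs[d2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  acc <- array(FALSE, dim(mask$voxels))
  clipped <- FALSE
  for (r in seq_len(nrow(offs))) {
    sh <- shift_logical(mask$voxels, offs[r, ])
    acc <- acc | sh$arr
    clipped <- clipped || sh$clipped
  }
  out <- mask
  out$voxels <- acc
  if (clipped) {
    warning("isotropic expansion clipped at grid boundary", call. = FALSE)
    attr(out, "clipped") <- TRUE
  }
  out
}

#' Anisotropic (six-direction) margin expansion
#'
#' Direction-dependent box dilation on patient axes: the mask grows by
#' `margins$r` mm toward Right, `margins$l` toward Left, and so on for
#' A/P/S/I.  A voxel belongs to the output iff some occupied voxel centre
#' lies within the axis-aligned box reaching `r` back toward L, `l`
#' toward R, etc. -- equivalently, occupied voxels are smeared toward each
#' direction by that direction's margin.  Used to re-evaluate a
#' conventional ITV after adding the derived six-direction margins.
#'
#' @param mask a [voxel_mask].
#' @param margins a [margin_vector].
#' @return expanded [voxel_mask]; `attr(, "clipped")` as in
#'   [expand_isotropic()].
#' @export
expand_anisotropic <- function(mask, margins) {
  stopifnot(inherits(mask, "voxel_mask"))
  margins <- as_margin_vector(margins)
  sp <- mask$spacing
  # steps toward the negative canonical direction (R, A, I) and positive
  # (L, P, S) per axis
  neg <- floor(c(margins[["r"]], margins[["a"]], margins[["i"]]) / sp + 1e-9)
  pos <- floor(c(margins[["l"]], margins[["p"]], margins[["s"]]) / sp + 1e-9)
  acc <- mask$voxels
  clipped <- FALSE
  for (a in 1:3) {
    cur <- acc
    for (k in seq_len(neg[a])) {
      d <- integer(3); d[a] <- -k
      sh <- shift_logical(cur, d)
      acc <- acc | sh$arr
      clipped <- clipped || sh$clipped
    }
    for (k in seq_len(pos[a])) {
      d <- integer(3); d[a] <- k
      sh <- shift_logical(cur, d)
      acc <- acc | sh$arr
      clipped <- clipped || sh$clipped
    }
  }
  out <- mask
  out$voxels <- acc
  if (clipped) {
    warning("anisotropic expansion clipped at grid boundary", call. = FALSE)
    attr(out, "clipped") <- TRUE
  }
  out
}

#' Translate a mask by whole voxels
#'
#' Shifts the occupied voxels by `round(shift_mm / spacing)` voxels along
#' each canonical LPS axis (+x toward L, +y toward P, +z toward S).
#' Errors if any occupied voxel would leave the grid.
#'
#' @param mask a [voxel_mask].
#' @param shift_mm numeric(3) LPS displacement in mm.
#' @return translated [voxel_mask].
#' @export
translate_mask <- function(mask, shift_mm) {
  stopifnot(inherits(mask, "voxel_mask"), length(shift_mm) == 3L)
  d <- as.integer(round(shift_mm / mask$spacing))
  sh <- shift_logical(mask$voxels, d)
  if (sh$clipped)
    stop("translation moves occupied voxels off the grid", call. = FALSE)
  out <- mask
  out$voxels <- sh$arr
  out
}

#' Six-direction margin vector
#'
#' Non-negative margins (mm) along the six patient directions Right,
#' Left, Anterior, Posterior, Superior, Inferior -- the format in which
#' directional ITV margins are reported clinically.
#'
#' @param r,l,a,p,s,i non-negative margins in mm.
#' @return named numeric of class `margin_vector` (order r, l, a, p, s, i).
#' @export
margin_vector <- function(r = 0, l = 0, a = 0, p = 0, s = 0, i = 0) {
  v <- c(r = unname(r), l = unname(l), a = unname(a), p = unname(p),
         s = unname(s), i = unname(i))
  if (any(!is.finite(v)) || any(v < 0))
    stop("margins must be finite and non-negative", call. = FALSE)
  structure(as.numeric(v), names = names(v), class = "margin_vector")
}

#' @rdname margin_vector
#' @param x numeric vector of length 6 (order r, l, a, p, s, i), possibly
#'   named, or an existing `margin_vector`.
#' @export
as_margin_vector <- function(x) {
  if (inherits(x, "margin_vector")) return(x)
  if (is.numeric(x) && length(x) == 6L) {
    if (!is.null(names(x))) x <- x[c("r", "l", "a", "p", "s", "i")]
    return(margin_vector(x[1], x[2], x[3], x[4], x[5], x[6]))
  }
  stop("cannot interpret as margin_vector", call. = FALSE)
}

#' @export
print.margin_vector <- function(x, ...) {
  cat("<margin_vector> mm:",
      paste(sprintf("%s=%.1f", toupper(names(x)), round_half_away(x, 1)),
            collapse = " "), "\n")
  invisible(x)
}

#' Gray-level CT volume
#'
#' Companion container to [voxel_mask] holding HU values rather than
#' occupancy, used for aortic ROI extraction.  Same canonical LPS
#' geometry.
#'
#' @param values numeric 3D array of HU values.
#' @param spacing,origin,axis_labels as in [voxel_mask()].
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      axis_labels = c("L", "P", "S")) {
  if (!is.numeric(values) || length(dim(values)) != 3L)
    stop("values must be a numeric 3D array", call. = FALSE)
  can <- canonicalize_axes(array(TRUE, dim(values)), as.numeric(spacing),
                           as.numeric(origin), axis_labels)
  reor <- reorient_numeric(values, as.numeric(spacing), axis_labels)
  structure(list(values = reor, spacing = can$spacing, origin = can$origin),
            class = "ct_volume")
}

# numeric-array counterpart of canonicalize_axes (values only)
reorient_numeric <- function(values, spacing, axis_labels) {
  info <- vapply(axis_labels, .axis_of_label, numeric(2))
  pax <- info["axis", ]
  sgn <- info["sign", ]
  dm <- dim(values)
  for (g in 1:3) {
    if (sgn[g] < 0) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[g]] <- dm[g]:1
      values <- do.call(`[`, c(list(values), idx, list(drop = FALSE)))
    }
  }
  aperm(values, order(pax))
}
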