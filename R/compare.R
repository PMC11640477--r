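#' Centroid of a mask
#'
#' Unweighted mean of the occupied voxel centres in patient (LPS)
#' coordinates.
#'
#' @param mask a non-empty [voxel_mask].
#' @return numeric(3), mm LPS.
#' @export
centroid <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sub <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(sub) == 0) stop("empty mask has no centroid", call. = FALSE)
  unname(mask$origin + (colMeans(sub) - 1) * mask$spacing)
}

#' Dice and Jaccard overlap indices
#'
#' `dice = 2|A∩B| / (|A| + |B|)`, `jaccard = |A∩B| / |A∪B|`, on voxel
#' counts of masks sharing a grid.  The degenerate both-empty case is
#' defined as perfect agreement (1, 1) with a warning.
#'
#' @param m1,m2 [voxel_mask] objects on the same grid.
#' @return list `(dice, jaccard)`.
#' @export
overlap_indices <- function(m1, m2) {
  check_same_grid(m1, m2)
  n1 <- sum(m1$voxels)
  n2 <- sum(m2$voxels)
  if (n1 == 0 && n2 == 0) {
    warning("both masks empty; overlap defined as perfect agreement",
            call. = FALSE)
    return(list(dice = 1, jaccard = 1))
  }
  ni <- sum(m1$voxels & m2$voxels)
  nu <- n1 + n2 - ni
  list(dice = 2 * ni / (n1 + n2), jaccard = ni / nu)
}

#' Mean distance agreement (symmetric mean surface distance)
#'
#' Boundary voxels are occupied voxels with at least one of their six
#' face neighbours unoccupied (grid-edge faces count as unoccupied).
#' For every boundary voxel of each mask the Euclidean distance (mm,
#' voxel centres) to the nearest boundary voxel of the other mask is
#' computed via an exact distance transform; MDA is the mean over both
#' directions pooled.
#'
#' @param m1,m2 non-empty [voxel_mask] objects on the same grid.
#' @return MDA in mm.
#' @export
mean_distance_agreement <- function(m1, m2) {
  check_same_grid(m1, m2)
  if (!any(m1$voxels) || !any(m2$voxels))
    stop("mean distance agreement needs two non-empty masks", call. = FALSE)
  b1 <- boundary_voxels(m1$voxels)
  b2 <- boundary_voxels(m2$voxels)
  d_to_b2 <- sqrt(edt_squared(b2, m1$spacing))
  d_to_b1 <- sqrt(edt_squared(b1, m1$spacing))
  mean(c(d_to_b2[b1], d_to_b1[b2]))
}

#' Percentage volume difference
#'
#' `(vol2 - vol1) / vol1 * 100`: the conventional ITV (`vol2`) relative
#' to the contrast-enhanced reference ITV (`vol1`).
#'
#' @param vol2,vol1 volumes in any common unit; `vol1 > 0`.
#' @return percentage.
#' @export
pct_volume_difference <- function(vol2, vol1) {
  if (vol1 <= 0) stop("reference volume must be positive", call. = FALSE)
  (vol2 - vol1) / vol1 * 100
}

# outermost occupied-voxel face coordinate along each of the six patient
# directions, as signed extent toward that direction (mm)
mask_extents <- function(mask) {
  sub <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(sub) == 0) stop("empty mask has no extent", call. = FALSE)
  ext <- numeric(6)
  names(ext) <- c("r", "l", "a", "p", "s", "i")
  for (a in 1:3) {
    rng <- range(sub[, a])
    lo_face <- mask$origin[a] + (rng[1] - 1) * mask$spacing[a] -
      mask$spacing[a] / 2
    hi_face <- mask$origin[a] + (rng[2] - 1) * mask$spacing[a] +
      mask$spacing[a] / 2
    ext[c("r", "a", "i")[a]] <- -lo_face
    ext[c("l", "p", "s")[a]] <- hi_face
  }
  ext
}

#' Six-direction margins for one ITV to encompass another
#'
#' Geometric margin derivation on patient axes: for each of the six
#' directions (R, L, A, P, S, I) the margin is the distance by which the
#' reference `itv1` extends beyond `itv2` along that direction,
#'
#'   `margin_d = max(0, extent_d(itv1) - extent_d(itv2))`
#'
#' where `extent_d` is the outermost occupied-voxel face coordinate
#' toward direction `d`.  Directions in which `itv2` already reaches or
#' exceeds `itv1` get a zero margin.  Applying these margins with
#' [expand_anisotropic()] makes `itv2` reach `itv1`'s extremes in all
#' six directions.
#'
#' @param itv2 the volume to be expanded (conventional ITV).
#' @param itv1 the reference volume to be encompassed.
#' @return a [margin_vector] (full precision; round at the reporting
#'   layer, conventionally to 0.1 mm).
#' @export
derive_margins <- function(itv2, itv1) {
  check_same_grid(itv2, itv1)
  e1 <- mask_extents(itv1)
  e2 <- mask_extents(itv2)
  as_margin_vector(pmax(e1 - e2, 0))
}

#' Full geometric comparison of two masks
#'
#' Computes the comparison battery used to judge agreement of two target
#' volumes: absolute volumes (cc), percentage difference (relative to
#' `m1`), centroid shift (mm), Dice and Jaccard indices, and mean
#' distance agreement (mm).
#'
#' @param m1 reference mask (e.g. the contrast-enhanced ITV1).
#' @param m2 comparison mask (e.g. the conventional ITV2).
#' @return object of class `comparison_report` with fields `vol1_cc,
#'   vol2_cc, pct_diff, centroid_shift_mm, dice, jaccard, mda_mm`.
#' @export
compare_masks <- function(m1, m2) {
  check_same_grid(m1, m2)
  ov <- overlap_indices(m1, m2)
  structure(list(
    vol1_cc = mask_volume(m1, "cc"),
    vol2_cc = mask_volume(m2, "cc"),
    pct_diff = pct_volume_difference(mask_volume(m2), mask_volume(m1)),
    centroid_shift_mm = sqrt(sum((centroid(m2) - centroid(m1))^2)),
    dice = ov$dice,
    jaccard = ov$jaccard,
    mda_mm = mean_distance_agreement(m1, m2)
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report>\n  vol1 %.2f cc | vol2 %.2f cc (%+.1f%%)\n",
              x$vol1_cc, x$vol2_cc, x$pct_diff))
  cat(sprintf("  centroid shift %.2f mm | Dice %.3f | Jaccard %.3f | MDA %.2f mm\n",
              x$centroid_shift_mm, x$dice, x$jaccard, x$mda_mm))
  if (!is.null(x$encompassed))
    cat(sprintf("  post-margin extremes encompassed: %s\n",
                if (all(x$encompassed)) "yes" else
                  paste(toupper(names(x$encompassed))[!x$encompassed],
                        collapse = " ")))
  invisible(x)
}

#' Re-evaluate agreement after adding directional margins
#'
#' Expands `itv2` by the given six-direction margins and recomputes the
#' comparison battery against `itv1`.  The report additionally records,
#' per direction, whether the expanded volume reaches the reference's
#' extreme face coordinate (`encompassed`); a warning is raised when it
#' does not (margins derived with [derive_margins()] always encompass).
#'
#' @param itv2 mask to expand.
#' @param margins a [margin_vector] (zero margins reproduce the plain
#'   comparison).
#' @param itv1 reference mask.
#' @return a `comparison_report` with extra fields `margins` and
#'   `encompassed`.
#' @export
evaluate_with_margins <- function(itv2, margins, itv1) {
  margins <- as_margin_vector(margins)
  expanded <- expand_anisotropic(itv2, margins)
  rep <- compare_masks(itv1, expanded)
  enc <- mask_extents(expanded) >= mask_extents(itv1) - 1e-9
  if (!all(enc))
    warning("expanded ITV2 does not reach ITV1's extremes toward: ",
            paste(toupper(names(enc))[!enc], collapse = ", "),
            call. = FALSE)
  rep$margins <- margins
  rep$encompassed <- enc
  rep
}
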