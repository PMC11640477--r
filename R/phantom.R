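#' Contrast-kinetics model for the phantom aorta
#'
#' First-pass bolus model used by the digital phantom: baseline
#' attenuation before contrast arrival, a gamma-variate rise to the
#' first-pass peak, then a smooth blend onto a constant recirculation
#' plateau.  The noiseless curve attains its maximum exactly at
#' `arrival_time + gamma_alpha * gamma_beta` and is constant at
#' `plateau_hu` from `plateau_onset` onward.
#'
#' Defaults emulate the enhancement pattern reported for slow-injection
#' (2.5 mL/s) abdominal protocols: peak near 54.5 s post injection at
#' about 292 HU, washout plateau near 70 s at about 169 HU.
#'
#' @param baseline_hu pre-contrast blood-pool attenuation (HU).
#' @param arrival_time bolus arrival in the aorta (s post injection).
#' @param gamma_alpha,gamma_beta gamma-variate shape (dimensionless) and
#'   scale (s); the peak occurs `gamma_alpha * gamma_beta` s after
#'   arrival.
#' @param peak_scale peak enhancement above baseline (HU).
#' @param plateau_hu recirculation plateau level (HU).
#' @param plateau_onset time (s) at which the curve becomes exactly
#'   constant at `plateau_hu`.
#' @return object of class `contrast_kinetics`.
#' @export
contrast_kinetics <- function(baseline_hu = 40, arrival_time = 10,
                              gamma_alpha = 3, gamma_beta = 14.8,
                              peak_scale = 252, plateau_hu = 169,
                              plateau_onset = 70.3) {
  k <- list(baseline_hu = baseline_hu, arrival_time = arrival_time,
            gamma_alpha = gamma_alpha, gamma_beta = gamma_beta,
            peak_scale = peak_scale, plateau_hu = plateau_hu,
            plateau_onset = plateau_onset)
  if (gamma_alpha <= 0 || gamma_beta <= 0)
    stop("gamma_alpha and gamma_beta must be positive", call. = FALSE)
  peak_hu <- baseline_hu + peak_scale
  if (!(peak_hu > plateau_hu && plateau_hu > baseline_hu))
    stop("need peak HU > plateau HU > baseline HU", call. = FALSE)
  t_pk <- arrival_time + gamma_alpha * gamma_beta
  if (plateau_onset <= t_pk)
    stop("plateau_onset must lie after the analytic peak (",
         format(t_pk), " s)", call. = FALSE)
  structure(k, class = "contrast_kinetics")
}

#' Evaluate the noiseless kinetics curve
#'
#' @param kinetics a [contrast_kinetics].
#' @param times numeric vector of seconds post injection.
#' @return HU values, same length as `times`.
#' @export
kinetics_curve <- function(kinetics, times) {
  stopifnot(inherits(kinetics, "contrast_kinetics"))
  k <- kinetics
  t_pk <- k$arrival_time + k$gamma_alpha * k$gamma_beta
  tau <- pmax(times - k$arrival_time, 0)
  tpk <- k$gamma_alpha * k$gamma_beta
  # gamma variate normalized to 1 at its mode
  g <- ifelse(tau > 0,
              (tau / tpk)^k$gamma_alpha * exp(k$gamma_alpha * (1 - tau / tpk)),
              0)
  first_pass <- k$baseline_hu + k$peak_scale * g
  # smoothstep blend from the descending first-pass limb onto the plateau
  u <- (times - t_pk) / (k$plateau_onset - t_pk)
  u <- pmin(pmax(u, 0), 1)
  w <- u * u * (3 - 2 * u)
  out <- (1 - w) * first_pass + w * k$plateau_hu
  out[times >= k$plateau_onset] <- k$plateau_hu
  out[times < k$arrival_time] <- k$baseline_hu
  out
}

#' Specification of the synthetic 4DCT phantom
#'
#' Describes the digital phantom that stands in for a patient scan: an
#' ellipsoidal lesion moving with respiration (split into `n_phases`
#' phase masks), an enhancing aorta with [contrast_kinetics], and a
#' helical acquisition timeline.  Defaults state the emulated world: a
#' ~14 mm-radius lesion (static ~11.5 cc; ITV with motion close to the
#' ~19 cc clinical median), 10 mm peak-to-peak superior-inferior motion
#' (abdominal motion is commonly 1-2 cm SI), ten respiratory phases,
#' 1 x 1 x 2 mm voxels, a 20 mm aorta, and about 88 s of acquisition
#' (clinical 4DCT durations span roughly 57-107 s).
#'
#' @param grid_dims integer(3) voxels per axis (canonical LPS order).
#' @param spacing numeric(3) mm per voxel.
#' @param lesion_center numeric(3) mm, LPS.
#' @param lesion_radii numeric(3) ellipsoid semi-axes, mm.
#' @param motion_amplitude numeric(3) peak-to-peak displacement, mm
#'   (dominant SI component by default).
#' @param n_phases number of respiratory phases (default 10).
#' @param breathing_period s.
#' @param aorta_center_xy numeric(2) mm, in-plane LPS centre of the aorta.
#' @param aorta_diameter mm.
#' @param kinetics a [contrast_kinetics].
#' @param scan_start_offset s, acquisition time of the first slice.
#' @param slice_interval s between successive slices.
#' @param noise_sd additive Gaussian HU noise SD.
#' @param seed integer RNG seed for noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(96, 96, 60),
                         spacing = c(1, 1, 2),
                         lesion_center = c(60, 48, 60),
                         lesion_radii = c(14, 14, 14),
                         motion_amplitude = c(0, 0, 10),
                         n_phases = 10,
                         breathing_period = 4,
                         aorta_center_xy = c(28, 48),
                         aorta_diameter = 20,
                         kinetics = contrast_kinetics(),
                         scan_start_offset = 0,
                         slice_interval = 1.5,
                         noise_sd = 10,
                         seed = 1L) {
  spec <- list(grid_dims = as.integer(grid_dims), spacing = spacing,
               lesion_center = lesion_center, lesion_radii = lesion_radii,
               motion_amplitude = motion_amplitude,
               n_phases = as.integer(n_phases),
               breathing_period = breathing_period,
               aorta_center_xy = aorta_center_xy,
               aorta_diameter = aorta_diameter,
               kinetics = kinetics,
               scan_start_offset = scan_start_offset,
               slice_interval = slice_interval,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (any(spec$grid_dims < 1L)) stop("grid_dims must be >= 1", call. = FALSE)
  if (any(spec$spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (spec$n_phases < 1L) stop("n_phases must be >= 1", call. = FALSE)
  if (spec$aorta_diameter <= 0) stop("aorta_diameter must be positive",
                                     call. = FALSE)
  if (any(spec$lesion_radii <= 0)) stop("lesion_radii must be positive",
                                        call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  # lesion plus motion extent must fit inside the physical grid
  lo <- spec$lesion_center - spec$lesion_radii - abs(spec$motion_amplitude) / 2
  hi <- spec$lesion_center + spec$lesion_radii + abs(spec$motion_amplitude) / 2
  gmin <- rep(0, 3) - spec$spacing / 2
  gmax <- (spec$grid_dims - 1) * spec$spacing + spec$spacing / 2
  if (any(lo < gmin) || any(hi > gmax))
    stop("lesion ellipsoid plus motion extent does not fit inside the grid",
         call. = FALSE)
  structure(spec, class = "phantom_spec")
}

#' Generate the respiratory phase masks of the phantom lesion
#'
#' Phase `p` (0-based) holds the lesion ellipsoid displaced by
#' `motion_amplitude * (cos(pi*p/n_phases)^4 - 1/2)`: a cos^4 profile so
#' that for even `n_phases` the sampled displacement spans exactly the
#' peak-to-peak amplitude and more phases sit near the exhale extreme.
#' Deterministic (masks carry no noise).
#'
#' @param spec a [phantom_spec].
#' @return list of `n_phases` [voxel_mask] objects on a common grid.
#' @export
generate_phase_masks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cx <- (seq_len(spec$grid_dims[1]) - 1) * spec$spacing[1]
  cy <- (seq_len(spec$grid_dims[2]) - 1) * spec$spacing[2]
  cz <- (seq_len(spec$grid_dims[3]) - 1) * spec$spacing[3]
  masks <- vector("list", spec$n_phases)
  for (p in seq_len(spec$n_phases) - 1L) {
    ctr <- spec$lesion_center +
      spec$motion_amplitude * (cos(pi * p / spec$n_phases)^4 - 0.5)
    qx <- ((cx - ctr[1]) / spec$lesion_radii[1])^2
    qy <- ((cy - ctr[2]) / spec$lesion_radii[2])^2
    qz <- ((cz - ctr[3]) / spec$lesion_radii[3])^2
    occ <- outer(outer(qx, qy, `+`), qz, `+`) <= 1
    if (!any(occ))
      stop("phantom lesion produced an empty mask; check radii vs spacing",
           call. = FALSE)
    masks[[p + 1L]] <- voxel_mask(occ, spacing = spec$spacing,
                                  origin = c(0, 0, 0))
  }
  masks
}

#' Generate a breathing surrogate trace
#'
#' Illustrative external respiratory signal matching the phantom's motion
#' profile (cos^4 of cycle time, SI amplitude).  Surrogate only; no claim
#' is made about any particular bellows or optical system.
#'
#' @param spec a [phantom_spec].
#' @param duration_s trace length in seconds.
#' @param dt sampling interval in seconds.
#' @return list with `times` (s) and `displacement` (mm).
#' @export
generate_breathing_trace <- function(spec, duration_s = 30, dt = 0.1) {
  stopifnot(inherits(spec, "phantom_spec"), duration_s > 0, dt > 0)
  times <- seq(0, duration_s, by = dt)
  amp <- sqrt(sum(spec$motion_amplitude^2))
  disp <- amp * (cos(pi * times / spec$breathing_period)^4 - 0.5)
  list(times = times, displacement = disp)
}

#' Generate an aortic time-density curve
#'
#' Samples the noiseless [kinetics_curve()] at `sample_times` and adds
#' independent Gaussian HU noise.
#'
#' @param kinetics a [contrast_kinetics].
#' @param sample_times strictly increasing seconds post injection.
#' @param noise_sd Gaussian noise SD in HU (0 for noiseless).
#' @param seed optional integer seed; when given the curve is
#'   reproducible.
#' @return a [time_density_curve].
#' @export
generate_aorta_tdc <- function(kinetics, sample_times, noise_sd = 0,
                               seed = NULL) {
  if (length(sample_times) == 0) stop("sample_times is empty", call. = FALSE)
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  hu <- kinetics_curve(kinetics, sample_times)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), sd = noise_sd)
  }
  time_density_curve(sample_times, hu)
}

#' Generate helical per-slice acquisition times
#'
#' One timestamp per axial slice, uniformly spaced: `ceil(length /
#' thickness)` slices starting at `start_time_s` and spanning
#' `duration_s` from first to last slice.
#'
#' @param scan_length_mm craniocaudal scan length (mm).
#' @param slice_thickness_mm slice thickness (mm).
#' @param duration_s time from first to last slice (s).
#' @param start_time_s acquisition time of the first slice (s).
#' @return numeric vector of slice times (s).
#' @export
generate_slice_timestamps <- function(scan_length_mm, slice_thickness_mm,
                                      duration_s, start_time_s = 0) {
  if (scan_length_mm <= 0 || slice_thickness_mm <= 0 || duration_s <= 0)
    stop("scan length, slice thickness and duration must be positive",
         call. = FALSE)
  n <- ceiling(scan_length_mm / slice_thickness_mm)
  if (n == 1L) return(start_time_s)
  start_time_s + seq(0, duration_s, length.out = n)
}

#' Generate the phantom CT volume with an enhancing aorta
#'
#' Builds a gray-level volume on the phantom grid in which each axial
#' slice is "acquired" at its slice time: aorta voxels (in-plane disc of
#' `aorta_diameter`) carry the kinetics curve evaluated at that slice's
#' time since injection, `t_delay + (slice_time - first slice time)`;
#' background tissue sits at 50 HU.  Optional Gaussian noise.
#'
#' @param spec a [phantom_spec].
#' @param slice_times acquisition time of each axial slice (s), length
#'   equal to the number of slices.
#' @param t_delay injection-to-scan-start delay (s); positive means the
#'   injection preceded the first slice.
#' @param noise_sd,seed noise model; defaults to noiseless.
#' @return a [ct_volume].
#' @export
generate_aorta_volume <- function(spec, slice_times, t_delay,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$grid_dims[3]
  if (length(slice_times) != nz)
    stop("need one slice time per axial slice (", nz, ")", call. = FALSE)
  cx <- (seq_len(spec$grid_dims[1]) - 1) * spec$spacing[1]
  cy <- (seq_len(spec$grid_dims[2]) - 1) * spec$spacing[2]
  disc <- outer((cx - spec$aorta_center_xy[1])^2,
                (cy - spec$aorta_center_xy[2])^2, `+`) <=
    (spec$aorta_diameter / 2)^2 + 1e-9
  t_inj <- t_delay + (slice_times - slice_times[1])
  hu_aorta <- kinetics_curve(spec$kinetics, t_inj)
  vol <- array(50, spec$grid_dims)
  for (k in seq_len(nz)) {
    sl <- vol[, , k]
    sl[disc] <- hu_aorta[k]
    vol[, , k] <- sl
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vol <- vol + array(stats::rnorm(length(vol), sd = noise_sd),
                       dim(vol))
  }
  ct_volume(vol, spacing = spec$spacing, origin = c(0, 0, 0))
}

#' Generate an ITV pair with known ground-truth margins
#'
#' Constructs the two internal target volumes compared by the analysis:
#' `itv1`, the union of all respiratory phases (the contrast-enhanced
#' reference), and `itv2`, a degraded conventional delineation built by
#' dropping a subset of phases and translating the remainder by a known
#' shift.  `expected_margins` is the brute-force per-direction extent
#' difference between the two -- the ground truth that
#' [derive_margins()] must recover.
#'
#' @param spec a [phantom_spec].
#' @param dropout_phases integer vector of 0-based phase indices excluded
#'   from `itv2`.
#' @param known_shift_mm numeric(3) LPS translation applied to `itv2`
#'   (snapped to whole voxels).
#' @return list with `itv1`, `itv2` ([voxel_mask]) and `expected_margins`
#'   ([margin_vector]).
#' @export
generate_itv_pair <- function(spec, dropout_phases = integer(0),
                              known_shift_mm = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  dropout_phases <- as.integer(dropout_phases)
  if (length(dropout_phases) &&
      (any(dropout_phases < 0) || any(dropout_phases >= spec$n_phases)))
    stop("dropout_phases must be 0-based phase indices", call. = FALSE)
  keep <- setdiff(seq_len(spec$n_phases) - 1L, dropout_phases)
  if (length(keep) == 0) stop("all phases dropped", call. = FALSE)
  masks <- generate_phase_masks(spec)
  itv1 <- union_phases(masks)
  itv2 <- union_phases(masks[keep + 1L])
  itv2 <- translate_mask(itv2, known_shift_mm)
  list(itv1 = itv1, itv2 = itv2,
       expected_margins = brute_force_margins(itv2, itv1))
}

# Ground-truth oracle for generate_itv_pair: outermost occupied face
# coordinate per direction from the raw subscript list, compared between
# the two masks.  Kept deliberately simple and separate from
# derive_margins().
brute_force_margins <- function(itv2, itv1) {
  face_extents <- function(m) {
    sub <- which(m$voxels, arr.ind = TRUE)
    if (nrow(sub) == 0) stop("empty mask", call. = FALSE)
    ext <- numeric(6)
    names(ext) <- c("r", "l", "a", "p", "s", "i")
    for (a in 1:3) {
      lo <- m$origin[a] + (min(sub[, a]) - 1) * m$spacing[a] - m$spacing[a] / 2
      hi <- m$origin[a] + (max(sub[, a]) - 1) * m$spacing[a] + m$spacing[a] / 2
      ext[c("r", "a", "i")[a]] <- -lo  # extent toward R / A / I
      ext[c("l", "p", "s")[a]] <- hi   # extent toward L / P / S
    }
    ext
  }
  e1 <- face_extents(itv1)
  e2 <- face_extents(itv2)
  as_margin_vector(pmax(e1 - e2, 0))
}

#' Write all phantom artifacts to a directory
#'
#' Phase masks (`phase_00.nrrd` ...), slice timestamps and aortic TDC as
#' CSV, and the spec itself as JSON.  Plumbing for the command-line
#' interface.
#'
#' @param spec a [phantom_spec].
#' @param dir output directory (created if needed).
#' @param t_delay delay used for the TDC time axis (s).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(spec, dir, t_delay = 20) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  masks <- generate_phase_masks(spec)
  for (p in seq_along(masks)) {
    write_mask(masks[[p]], file.path(dir, sprintf("phase_%02d.nrrd", p - 1)))
  }
  nz <- spec$grid_dims[3]
  ts <- spec$scan_start_offset + (seq_len(nz) - 1) * spec$slice_interval
  utils::write.csv(data.frame(slice = seq_len(nz) - 1L, time_s = ts),
                   file.path(dir, "slice_times.csv"), row.names = FALSE)
  tdc <- generate_aorta_tdc(spec$kinetics, t_delay + ts - ts[1],
                            noise_sd = spec$noise_sd, seed = spec$seed)
  write_tdc(tdc, file.path(dir, "aorta_tdc.csv"))
  sj <- unclass(spec)
  sj$kinetics <- unclass(sj$kinetics)
  jsonlite::write_json(sj, file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
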