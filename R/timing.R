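#' Time from scan start to the tumour's craniocaudal centre
#'
#' With `t0` the acquisition time of the first absolute slice and
#' `t1`/`t2` the times of the first and last slices containing the
#' tumour, the scanner needs `t_scan = (t1 + t2)/2 - t0` seconds to reach
#' the centre of the tumour.
#'
#' @param t0,t1,t2 slice times in seconds, `t0 <= t1 <= t2`.
#' @return `t_scan` in seconds (non-negative).
#' @export
compute_t_scan <- function(t0, t1, t2) {
  if (t1 < t0) stop("invalid slice times: t1 < t0", call. = FALSE)
  if (t2 < t1) stop("invalid slice times: t2 < t1", call. = FALSE)
  (t1 + t2) / 2 - t0
}

#' Personalized injection delay
#'
#' `t_delay = t_phase - t_scan`: how long before (positive) or after
#' (negative) scan start the contrast injection must begin so that the
#' scanner reaches the tumour centre at the desired contrast-phase time.
#' A positive delay can be automated by the scanner countdown
#' (`"automated"`); a negative delay needs a stopwatch-triggered
#' injection before the scan (`"manual"`).  Zero is classified as
#' automated (no stopwatch needed).
#'
#' @param t_phase desired post-injection contrast-phase time (s).
#' @param t_scan time to reach the tumour centre (s, >= 0), from
#'   [compute_t_scan()].
#' @return list with `t_delay` (s) and `sync_mode` (`"automated"` or
#'   `"manual"`).
#' @export
compute_t_delay <- function(t_phase, t_scan) {
  if (t_scan < 0) stop("t_scan must be non-negative", call. = FALSE)
  t_delay <- t_phase - t_scan
  list(t_delay = t_delay,
       sync_mode = if (t_delay >= 0) "automated" else "manual")
}

#' Default contrast-phase times
#'
#' Initial radiologist-recommended post-injection times: 50 s for the
#' arterial phase, 70 s for the portal phase.  See [refine_t_phase()] for
#' the population-based update.
#'
#' @param phase `"arterial"` or `"portal"`.
#' @return seconds.
#' @export
default_t_phase <- function(phase = c("arterial", "portal")) {
  phase <- match.arg(phase)
  c(arterial = 50, portal = 70)[[phase]]
}

#' Full per-patient timing record
#'
#' Bundles the measured slice times, the chosen contrast-phase time and
#' the derived quantities into one record.
#'
#' @param t0,t1,t2 slice times (s), see [compute_t_scan()].
#' @param t_phase desired contrast-phase time (s); when `NULL`, the
#'   default for `phase` is used.
#' @param phase `"arterial"` or `"portal"` (used when `t_phase` is NULL).
#' @return object of class `phase_timing` with fields `t0, t1, t2,
#'   t_phase, t_scan, t_delay, sync_mode`.
#' @export
phase_timing <- function(t0, t1, t2, t_phase = NULL,
                         phase = c("arterial", "portal")) {
  if (is.null(t_phase)) t_phase <- default_t_phase(match.arg(phase))
  t_scan <- compute_t_scan(t0, t1, t2)
  d <- compute_t_delay(t_phase, t_scan)
  structure(list(t0 = t0, t1 = t1, t2 = t2, t_phase = t_phase,
                 t_scan = t_scan, t_delay = d$t_delay,
                 sync_mode = d$sync_mode),
            class = "phase_timing")
}

#' @export
print.phase_timing <- function(x, ...) {
  cat(sprintf(
    "<phase_timing> t0=%g t1=%g t2=%g | t_phase=%g  t_scan=%g  t_delay=%+g (%s)\n",
    x$t0, x$t1, x$t2, x$t_phase, x$t_scan, x$t_delay, x$sync_mode))
  invisible(x)
}

#' Weight-based contrast volume
#'
#' `min(weight * factor, 140)` mL, with the per-kg factor restricted to
#' the protocol range 1.8-2.0 mL/kg and a hard 140 mL cap.
#'
#' @param weight_kg patient weight (kg, > 0).
#' @param volume_factor mL per kg, in `[1.8, 2.0]`.
#' @return volume in mL.
#' @export
compute_contrast_volume <- function(weight_kg, volume_factor) {
  if (weight_kg <= 0) stop("weight_kg must be positive", call. = FALSE)
  if (volume_factor < 1.8 || volume_factor > 2.0)
    stop("volume_factor must lie in [1.8, 2.0] mL/kg", call. = FALSE)
  min(weight_kg * volume_factor, 140)
}

#' Contrast injection protocol
#'
#' @param weight_kg patient weight (kg).
#' @param volume_factor mL/kg in `[1.8, 2.0]` (default 1.8).
#' @param flow_rate injection rate in mL/s; the protocol default of
#'   2.5 mL/s is deliberately slower than diagnostic practice to stretch
#'   the washout and widen the usable enhancement window.
#' @return object of class `contrast_protocol` with `volume_ml` and
#'   `injection_duration_s` derived.
#' @export
contrast_protocol <- function(weight_kg, volume_factor = 1.8,
                              flow_rate = 2.5) {
  if (flow_rate <= 0) stop("flow_rate must be positive", call. = FALSE)
  volume_ml <- compute_contrast_volume(weight_kg, volume_factor)
  structure(list(weight_kg = weight_kg, volume_factor = volume_factor,
                 volume_ml = volume_ml, flow_rate = flow_rate,
                 injection_duration_s = volume_ml / flow_rate),
            class = "contrast_protocol")
}

#' Locate the tumour-containing slices in time
#'
#' Takes the union of the respiratory phase masks (the tumour over its
#' full motion range) and maps the first and last occupied axial slices
#' to acquisition times: `t0` is the first timestamp, `t1`/`t2` the
#' timestamps of the first/last slice intersecting the union.  Slices run
#' along the canonical superior axis in array order; `timestamps[k]` is
#' the acquisition time of slice `k`.
#'
#' @param phase_masks list of [voxel_mask] on one grid.
#' @param timestamps numeric vector, one acquisition time per axial
#'   slice.
#' @return list `(t0, t1, t2)` in seconds.
#' @export
locate_tumor_slices <- function(phase_masks, timestamps) {
  u <- union_phases(phase_masks)
  nz <- dim(u$voxels)[3]
  if (length(timestamps) != nz)
    stop("need one timestamp per axial slice (", nz, " slices, ",
         length(timestamps), " timestamps)", call. = FALSE)
  occ <- apply(u$voxels, 3, any)
  if (!any(occ))
    stop("tumor not found in any slice; delineate from anatomical ",
         "markers instead", call. = FALSE)
  ks <- which(occ)
  list(t0 = timestamps[1], t1 = timestamps[min(ks)], t2 = timestamps[max(ks)])
}
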