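#' Aortic time-density curve
#'
#' Mean aortic attenuation as a function of time since contrast
#' injection.  Times must be strictly increasing; negative times are
#' permitted (slices acquired before the injection).
#'
#' @param times seconds since injection, strictly increasing.
#' @param mean_hu mean ROI attenuation (HU), same length.
#' @return object of class `time_density_curve`.
#' @export
time_density_curve <- function(times, mean_hu) {
  times <- as.numeric(times)
  mean_hu <- as.numeric(mean_hu)
  if (length(times) != length(mean_hu))
    stop("times and mean_hu must have equal length", call. = FALSE)
  if (length(times) == 0) stop("empty curve", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(mean_hu)) || any(!is.finite(times)))
    stop("times and mean_hu must be finite", call. = FALSE)
  structure(list(times = times, mean_hu = mean_hu),
            class = "time_density_curve")
}

#' @export
print.time_density_curve <- function(x, ...) {
  cat(sprintf("<time_density_curve> %d samples, t in [%.1f, %.1f] s, HU in [%.0f, %.0f]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$mean_hu), max(x$mean_hu)))
  invisible(x)
}

#' Read / write a time-density curve as CSV
#'
#' Two-column CSV with header `time_s,mean_hu`.
#'
#' @param path CSV file path.
#' @return [time_density_curve] for `read_tdc`; `path` invisibly for
#'   `write_tdc`.
#' @export
read_tdc <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "mean_hu") %in% names(d)))
    stop("TDC CSV must have columns time_s, mean_hu", call. = FALSE)
  time_density_curve(d$time_s, d$mean_hu)
}

#' @rdname read_tdc
#' @param tdc a [time_density_curve].
#' @export
write_tdc <- function(tdc, path) {
  stopifnot(inherits(tdc, "time_density_curve"))
  utils::write.csv(data.frame(time_s = tdc$times, mean_hu = tdc$mean_hu),
                   path, row.names = FALSE)
  invisible(path)
}

#' Aortic ROI under the geometric placement rules
#'
#' Circular axial-plane ROI on the aorta, sized to the vessel: the ROI
#' diameter is the aortic diameter minus a 2 mm margin on each side
#' (`aorta_diameter - 4`), and may never be smaller than 5 mm.  Vessels
#' narrower than 9 mm cannot satisfy both rules and are rejected for
#' manual review.
#'
#' @param aorta_diameter aortic diameter at this slice (mm).
#' @param slice_index axial slice index (1-based).
#' @param aorta_center numeric(2), in-plane LPS centre (mm).
#' @return object of class `aorta_roi` with `slice_index`, `center`,
#'   `diameter`.
#' @export
build_aorta_roi <- function(aorta_diameter, slice_index, aorta_center) {
  if (aorta_diameter <= 0) stop("aorta_diameter must be positive",
                                call. = FALSE)
  d <- aorta_diameter - 4
  if (d < 5)
    stop("aorta too narrow (", format(aorta_diameter), " mm): cannot keep ",
         "a 5 mm minimum ROI with a 2 mm edge margin; review manually",
         call. = FALSE)
  structure(list(slice_index = as.integer(slice_index),
                 center = as.numeric(aorta_center), diameter = d),
            class = "aorta_roi")
}

#' Extract the aortic time-density curve from a CT volume
#'
#' For each ROI, averages the HU of voxels whose in-plane centre lies
#' within the ROI disc on that slice, and places the sample on the
#' post-injection timeline: `time = t_delay + (slice_time - t0)`.
#' Pre-injection slices yield negative times.
#'
#' @param volume a [ct_volume].
#' @param rois list of [build_aorta_roi()] objects, one per analysed
#'   slice.
#' @param slice_times acquisition time of each axial slice (s), aligned
#'   with the volume.
#' @param t_delay injection delay (s) from [compute_t_delay()].
#' @param t0 acquisition time of the first absolute slice (s).
#' @return a [time_density_curve].
#' @export
extract_tdc <- function(volume, rois, slice_times, t_delay, t0) {
  stopifnot(inherits(volume, "ct_volume"))
  nz <- dim(volume$values)[3]
  if (length(slice_times) != nz)
    stop("need one slice time per axial slice", call. = FALSE)
  cx <- volume$origin[1] +
    (seq_len(dim(volume$values)[1]) - 1) * volume$spacing[1]
  cy <- volume$origin[2] +
    (seq_len(dim(volume$values)[2]) - 1) * volume$spacing[2]
  times <- numeric(length(rois))
  hu <- numeric(length(rois))
  for (j in seq_along(rois)) {
    roi <- rois[[j]]
    if (!inherits(roi, "aorta_roi")) stop("rois must be aorta_roi objects",
                                          call. = FALSE)
    k <- roi$slice_index
    if (k < 1 || k > nz) stop("ROI slice_index out of range", call. = FALSE)
    disc <- outer((cx - roi$center[1])^2, (cy - roi$center[2])^2, `+`) <=
      (roi$diameter / 2)^2 + 1e-9
    if (!any(disc))
      stop("ROI on slice ", k, " contains no voxel centers (under-resolved ",
           "for this grid spacing)", call. = FALSE)
    hu[j] <- mean(volume$values[, , k][disc])
    times[j] <- t_delay + (slice_times[k] - t0)
  }
  ord <- order(times)
  time_density_curve(times[ord], hu[ord])
}

#' Detect the first-pass contrast peak
#'
#' Smooths the curve with a centred moving average (default 3 samples,
#' partial windows at the edges) and takes the argmax; ties break to the
#' earliest time.  Returns the unsmoothed HU at the detected sample.
#'
#' @param tdc a [time_density_curve] with at least 5 samples.
#' @param smoothing_window moving-average width in samples (odd).
#' @return list `(t_peak, hu_peak)`.
#' @export
detect_peak <- function(tdc, smoothing_window = 3) {
  stopifnot(inherits(tdc, "time_density_curve"))
  n <- length(tdc$times)
  if (n < 5) stop("need at least 5 samples", call. = FALSE)
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("smoothing_window must be a positive odd number", call. = FALSE)
  if (diff(range(tdc$mean_hu)) == 0)
    stop("no enhancement detected (constant curve)", call. = FALSE)
  h <- (smoothing_window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    mean(tdc$mean_hu[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  idx <- which.max(sm)  # which.max returns the earliest maximum
  list(t_peak = tdc$times[idx], hu_peak = tdc$mean_hu[idx])
}

#' Detect the washout plateau
#'
#' The plateau is the earliest time after the peak at which the
#' least-squares slope of the curve over the trailing `window` seconds
#' falls to `|slope| <= slope_threshold`; the window must lie wholly
#' after the peak (a window straddling the peak averages rise against
#' fall and fakes a flat segment).  The plateau HU is the mean over that
#' window.  Both knobs are deliberate modelling choices: a
#' 10 s window with a 0.5 HU/s threshold reproduces what a reader would
#' call visually flat.
#'
#' @param tdc a [time_density_curve].
#' @param t_peak peak time from [detect_peak()] (must lie within the
#'   curve support).
#' @param slope_threshold HU/s.
#' @param window trailing window length (s).
#' @return list `(t_plateau, hu_plateau)`.
#' @export
detect_plateau <- function(tdc, t_peak, slope_threshold = 0.5, window = 10) {
  stopifnot(inherits(tdc, "time_density_curve"))
  if (t_peak < min(tdc$times) || t_peak > max(tdc$times))
    stop("t_peak outside curve support", call. = FALSE)
  # the trailing window must lie wholly after the peak: a window straddling
  # the peak averages rise against fall and fakes a zero slope
  for (i in which(tdc$times - window >= t_peak - 1e-9)) {
    j <- which(tdc$times >= tdc$times[i] - window & tdc$times <= tdc$times[i])
    if (length(j) < 2) next
    tt <- tdc$times[j]
    hh <- tdc$mean_hu[j]
    slope <- stats::cov(tt, hh) / stats::var(tt)
    if (abs(slope) <= slope_threshold)
      return(list(t_plateau = tdc$times[i], hu_plateau = mean(hh)))
  }
  stop("plateau not reached within scan", call. = FALSE)
}

#' Per-patient kinetics summary
#'
#' Runs peak and plateau detection on one curve and bundles the result.
#'
#' @param tdc a [time_density_curve].
#' @param smoothing_window see [detect_peak()].
#' @param slope_threshold,window see [detect_plateau()].
#' @return object of class `kinetics_summary` with `t_peak, hu_peak,
#'   t_plateau, hu_plateau, outlier` (outlier is set by
#'   [summarize_population()]).
#' @export
analyze_tdc <- function(tdc, smoothing_window = 3, slope_threshold = 0.5,
                        window = 10) {
  pk <- detect_peak(tdc, smoothing_window)
  pl <- detect_plateau(tdc, pk$t_peak, slope_threshold, window)
  structure(list(t_peak = pk$t_peak, hu_peak = pk$hu_peak,
                 t_plateau = pl$t_plateau, hu_plateau = pl$hu_plateau,
                 outlier = FALSE),
            class = "kinetics_summary")
}

#' Population contrast-kinetics statistics
#'
#' Medians and ranges of peak/plateau times and mean +/- SD of peak/
#' plateau HU across patients, reported both for all patients and with
#' anomalous-kinetics outliers excluded.  Outliers are flagged by Tukey
#' fences (1.5 x IQR beyond the quartiles, type-7 quantiles) on the peak
#' time -- a standard, parameter-free stand-in for the clinical judgment
#' call of "anomalous kinetics".
#'
#' @param summaries list of [analyze_tdc()] results (class
#'   `kinetics_summary`).
#' @param exclude_outliers when FALSE the excluded block simply repeats
#'   the full-cohort statistics.
#' @return list with `n`, `outlier` (logical per patient), `all` and
#'   `excluded` blocks, each holding `t_peak_median`, `t_peak_range`,
#'   `t_plateau_median`, `t_plateau_range`, `hu_peak_mean`, `hu_peak_sd`,
#'   `hu_plateau_mean`, `hu_plateau_sd`.
#' @export
summarize_population <- function(summaries, exclude_outliers = TRUE) {
  if (length(summaries) == 0) stop("empty input", call. = FALSE)
  tp <- vapply(summaries, function(s) s$t_peak, numeric(1))
  tl <- vapply(summaries, function(s) s$t_plateau, numeric(1))
  hp <- vapply(summaries, function(s) s$hu_peak, numeric(1))
  hl <- vapply(summaries, function(s) s$hu_plateau, numeric(1))
  q <- stats::quantile(tp, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  out <- tp < q[1] - 1.5 * iqr | tp > q[2] + 1.5 * iqr
  block <- function(keep) {
    list(t_peak_median = stats::median(tp[keep]),
         t_peak_range = range(tp[keep]),
         t_plateau_median = stats::median(tl[keep]),
         t_plateau_range = range(tl[keep]),
         hu_peak_mean = mean(hp[keep]),
         hu_peak_sd = if (sum(keep) > 1) stats::sd(hp[keep]) else NA_real_,
         hu_plateau_mean = mean(hl[keep]),
         hu_plateau_sd = if (sum(keep) > 1) stats::sd(hl[keep]) else NA_real_)
  }
  keep <- if (exclude_outliers) !out else rep(TRUE, length(tp))
  if (!any(keep)) keep <- rep(TRUE, length(tp))  # never exclude everyone
  list(n = length(tp), outlier = out,
       all = block(rep(TRUE, length(tp))), excluded = block(keep))
}

#' Population-refined contrast-phase time
#'
#' Updates the default contrast-phase time from observed kinetics: the
#' arterial phase targets the outlier-excluded median peak time, the
#' portal phase the outlier-excluded median plateau time.  With no data
#' the initial defaults (50 s arterial, 70 s portal) are returned.
#'
#' @param population result of [summarize_population()], or NULL.
#' @param phase `"arterial"` or `"portal"`.
#' @return refined `t_phase` in seconds.
#' @export
refine_t_phase <- function(population = NULL,
                           phase = c("arterial", "portal")) {
  phase <- match.arg(phase)
  if (is.null(population) || population$n == 0)
    return(default_t_phase(phase))
  if (phase == "arterial") population$excluded$t_peak_median
  else population$excluded$t_plateau_median
}
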