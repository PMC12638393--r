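#' Flow curve through an ROI
#'
#' Sums voxel velocities over the ROI at each cardiac phase and scales by
#' voxel area: `q(k) = sum_{x in roi} v(x,k) * pixel_area`. With velocities
#' in cm/s and areas in mm^2 the flow rate comes out in uL/s
#' (1 cm/s * mm^2 = 10 uL/s).
#'
#' @param field a `velocity_field`.
#' @param roi an `roi_mask` lying within the field bounds.
#' @return Object of class `flow_curve`: list with `q` (uL/s, one value per
#'   cardiac phase), `period_s`, `site`.
#' @export
compute_flow_curve <- function(field, roi) {
  stopifnot(inherits(field, "velocity_field"), inherits(roi, "roi_mask"))
  d <- dim(field$velocity)
  if (!all(dim(roi$mask) == d[1:2]))
    stop("ROI shape does not match the velocity field")
  if (!any(roi$mask)) stop("empty ROI")
  q <- apply(field$velocity, 3, function(fr) sum(fr[roi$mask])) *
    roi$pixel_area_mm2 * 10
  flow_curve(q, period_s = field$period_s, site = roi$site)
}

#' Flow curve constructor
#'
#' @param q flow rate samples (uL/s), one per cardiac phase, finite.
#' @param period_s cardiac period (s).
#' @param site site label.
#' @return Object of class `flow_curve`.
#' @export
flow_curve <- function(q, period_s, site = "aqu") {
  if (!all(is.finite(q))) stop("flow curve must be finite")
  structure(list(q = as.numeric(q), period_s = period_s,
                 site = normalize_site(site), n_phases = length(q)),
            class = "flow_curve")
}

#' Resample a flow curve onto uniform cardiac phases
#'
#' Periodic linear interpolation onto `n_out` uniform phases (sample k sits
#' at t = k*T/n, k = 0 .. n-1, for both grids).
#'
#' @param curve a `flow_curve` of length >= 8.
#' @param n_out output length (default 32, the routine gated frame count).
#' @return Resampled `flow_curve`.
#' @export
resample_phases <- function(curve, n_out = 32L) {
  stopifnot(inherits(curve, "flow_curve"))
  n_in <- curve$n_phases
  if (n_in < 8L) stop("curve too short to resample")
  if (n_out == n_in) return(curve)
  t_in <- (seq_len(n_in + 1L) - 1L) / n_in        # wrap last point
  q_in <- c(curve$q, curve$q[1])
  t_out <- (seq_len(n_out) - 1L) / n_out
  q_out <- stats::approx(t_in, q_in, xout = t_out)$y
  flow_curve(q_out, period_s = curve$period_s, site = curve$site)
}

#' Stroke volume and net volume from a flow curve
#'
#' Splits the periodic flow waveform into its positive and negative parts,
#' integrates each with a trapezoidal rule after inserting the linear
#' zero crossings as extra nodes (plain trapezoids on a coarse 32-sample
#' grid systematically clip the directional volumes near sign changes), and
#' reports
#' \deqn{SV = (V^+ + V^-)/2, \qquad net = V^+ - V^-,}
#' the mean of the two directional displaced volumes and the signed bulk
#' flow. SV is the field's standard summary for oscillatory CSF flow; for a
#' purely unidirectional waveform it equals half the total displaced
#' volume.
#'
#' @param curve a `flow_curve`.
#' @return Object of class `stroke_volume_result`: `sv_ul_per_cc`,
#'   `net_volume_ul`, `v_plus_ul`, `v_minus_ul`, `site`.
#' @export
stroke_volume <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  n <- curve$n_phases
  t <- (seq_len(n + 1L) - 1L) * curve$period_s / n
  q <- c(curve$q, curve$q[1])
  # subdivide each interval at its linear zero crossing
  tt <- t[1]; qq <- q[1]
  for (i in seq_len(n)) {
    q0 <- q[i]; q1 <- q[i + 1]
    if (q0 * q1 < 0) {
      tc <- t[i] + (t[i + 1] - t[i]) * q0 / (q0 - q1)
      tt <- c(tt, tc); qq <- c(qq, 0)
    }
    tt <- c(tt, t[i + 1]); qq <- c(qq, q1)
  }
  v_plus <- pracma::trapz(tt, pmax(qq, 0))
  v_minus <- pracma::trapz(tt, pmax(-qq, 0))
  structure(list(sv_ul_per_cc = (v_plus + v_minus) / 2,
                 net_volume_ul = v_plus - v_minus,
                 v_plus_ul = v_plus, v_minus_ul = v_minus,
                 site = curve$site),
            class = "stroke_volume_result")
}

#' @export
print.stroke_volume_result <- function(x, ...) {
  cat("stroke volume (", x$site, "): ", signif(x$sv_ul_per_cc, 4),
      " uL/CC  (V+ ", signif(x$v_plus_ul, 4), ", V- ",
      signif(x$v_minus_ul, 4), ", net ", signif(x$net_volume_ul, 4),
      " uL)\n", sep = "")
  invisible(x)
}

#' End-to-end stroke-volume quantification at one site
#'
#' Composes the full measurement chain on a cine phase series: phase ->
#' velocity calibration, temporal aliasing correction, static-background
#' offset removal, pulsatility-driven ROI segmentation from a seed voxel,
#' flow-curve computation, resampling to 32 phases, and integration into a
#' stroke-volume result. Each stage can be switched off to mimic a minimal
#' processing chain.
#'
#' @param series a `cine_phase_series`.
#' @param seed `c(row, col)` 0-based seed voxel inside the pulsatile lumen.
#' @param site site label.
#' @param threshold_frac region-growing threshold (see [segment_roi()]).
#' @param unalias apply [unalias_temporal()]?
#' @param background apply [background_correct()]?
#' @param static_mask logical matrix of static tissue; defaults to a 2-voxel
#'   border frame.
#' @param background_mode passed to [background_correct()].
#' @param n_phases_out output flow-curve length.
#' @return A `stroke_volume_result` with attribute `"artifacts"` holding
#'   the intermediate velocity field, pulsatility map, ROI and flow curve.
#' @export
quantify_site <- function(series, seed, site = "aqu", threshold_frac = 0.2,
                          unalias = TRUE, background = TRUE,
                          static_mask = NULL,
                          background_mode = c("scalar", "per_frame"),
                          n_phases_out = 32L) {
  stopifnot(inherits(series, "cine_phase_series"))
  background_mode <- match.arg(background_mode)
  field <- phase_to_velocity(series)
  if (unalias) field <- unalias_temporal(field)
  if (background) {
    if (is.null(static_mask))
      static_mask <- border_mask(dim(series$phase)[1:2])
    field <- background_correct(field, static_mask, mode = background_mode)
  }
  pmap <- pulsatility_map(field)
  roi <- segment_roi(pmap, seed, threshold_frac = threshold_frac,
                     site = site)
  curve <- resample_phases(compute_flow_curve(field, roi),
                           n_out = n_phases_out)
  res <- stroke_volume(curve)
  attr(res, "artifacts") <- list(field = field, pulsatility = pmap,
                                 roi = roi, flow_curve = curve,
                                 flags = list(
                                   aliasing_corrected = field$aliasing_corrected,
                                   background_corrected = field$background_corrected,
                                   threshold_frac = threshold_frac))
  res
}
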