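#' Measurement-site vocabulary
#'
#' The five craniospinal planes at which CSF stroke volume is quantified:
#' aqueduct of Sylvius (`aqu`), prepontine cistern (`ppc`), foramen magnum
#' (`fm`), cerebellar tonsils / neuraxis level (`nevrax`, alias `tonsils`),
#' and the C2-C3 subarachnoid space (`c2c3`).
#'
#' @return Character vector of canonical site keys.
#' @export
csf_sites <- function() c("aqu", "ppc", "fm", "nevrax", "c2c3")

#' Normalise a measurement-site name
#'
#' Lower-cases, maps the `tonsils` alias onto `nevrax`, and validates
#' against [csf_sites()].
#'
#' @param site character scalar.
#' @return Canonical site key.
#' @export
normalize_site <- function(site) {
  stopifnot(is.character(site), length(site) == 1L)
  s <- tolower(site)
  if (s == "tonsils") s <- "nevrax"
  s <- sub("^c2-?c3$", "c2c3", s)
  if (!s %in% csf_sites())
    stop("unknown site '", site, "'; expected one of ",
         paste(csf_sites(), collapse = ", "), " (or 'tonsils')")
  s
}

#' Specification of a pulsatile-flow phase-contrast phantom
#'
#' Describes a 2-D imaging plane through a small fluid lumen (circular or
#' annular) surrounded by static tissue, with a periodic mean-lumen velocity
#' waveform written as a sum of sinusoidal harmonics. From this a cine
#' phase-contrast series with analytically known flow can be synthesised.
#'
#' The mean-lumen velocity over the cardiac cycle of period `period_s` is
#' \deqn{\bar v(t) = \sum_j A_j \sin(2\pi h_j t / T + \phi_j)}
#' in cm/s, sampled at `n_phases` uniform time points starting at t = 0.
#'
#' @param geometry `"circle"` or `"annulus"`.
#' @param center_mm lumen centre, `c(row, col)` in mm (voxel centre (i, j),
#'   0-based, sits at physical position `(i, j) * pixel_spacing_mm`).
#' @param radius_mm circle radius (mm); ignored for annuli.
#' @param inner_radius_mm,outer_radius_mm annulus radii (mm).
#' @param profile `"plug"` (uniform) or `"poiseuille"` (laminar parabolic,
#'   scaled so the cross-section mean equals the waveform value).
#' @param waveform data frame or list with columns/fields `amplitude_cms`,
#'   `harmonic`, `phase_rad` — one row per sinusoidal term.
#' @param period_s cardiac period (s).
#' @param n_phases number of cardiac time frames (>= 8; 32 in routine
#'   cardiac-gated acquisitions).
#' @param venc_cms velocity encoding (cm/s): the velocity mapped to a phase
#'   of +/- pi. 10 cm/s is typical for the aqueduct, 5 cm/s for the wider
#'   cervical planes.
#' @param pixel_spacing_mm in-plane spacing, `c(row, col)` mm (scalar
#'   recycled).
#' @param grid_shape `c(rows, cols)` of the simulated raster.
#' @param noise_sd_rad SD of i.i.d. Gaussian phase noise (radians), applied
#'   uniformly to lumen and static tissue.
#' @param background_offset_rad constant phase offset added everywhere,
#'   emulating an uncorrected eddy-current baseline.
#' @param seed integer RNG seed for the noise (`NULL` for unseeded).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("circle", "annulus"),
                         center_mm = c(8, 8),
                         radius_mm = 1.5,
                         inner_radius_mm = NULL,
                         outer_radius_mm = NULL,
                         profile = c("plug", "poiseuille"),
                         waveform = list(amplitude_cms = 1, harmonic = 1,
                                         phase_rad = 0),
                         period_s = 1,
                         n_phases = 32L,
                         venc_cms = 10,
                         pixel_spacing_mm = 0.25,
                         grid_shape = c(64L, 64L),
                         noise_sd_rad = 0,
                         background_offset_rad = 0,
                         seed = NULL) {
  geometry <- match.arg(geometry)
  profile <- match.arg(profile)
  wf <- as.data.frame(waveform)
  if (nrow(wf) == 0L) stop("waveform must contain at least one term")
  stopifnot(all(c("amplitude_cms", "harmonic", "phase_rad") %in% names(wf)))
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (geometry == "circle") {
    if (!is.numeric(radius_mm) || radius_mm <= 0) stop("radius_mm must be > 0")
  } else {
    if (is.null(inner_radius_mm) || is.null(outer_radius_mm))
      stop("annulus requires inner_radius_mm and outer_radius_mm")
    if (inner_radius_mm <= 0 || outer_radius_mm <= inner_radius_mm)
      stop("annulus radii must satisfy 0 < inner < outer")
  }
  if (n_phases < 8L) stop("n_phases must be >= 8")
  if (venc_cms <= 0) stop("venc_cms must be > 0")
  if (period_s <= 0) stop("period_s must be > 0")
  if (noise_sd_rad < 0) stop("noise_sd_rad must be >= 0")
  structure(list(geometry = geometry, center_mm = center_mm,
                 radius_mm = radius_mm, inner_radius_mm = inner_radius_mm,
                 outer_radius_mm = outer_radius_mm, profile = profile,
                 waveform = wf, period_s = period_s,
                 n_phases = as.integer(n_phases), venc_cms = venc_cms,
                 pixel_spacing_mm = pixel_spacing_mm,
                 grid_shape = as.integer(grid_shape),
                 noise_sd_rad = noise_sd_rad,
                 background_offset_rad = background_offset_rad,
                 seed = seed),
            class = "phantom_spec")
}

#' Evaluate the phantom's mean-lumen velocity waveform
#'
#' @param spec a [phantom_spec()].
#' @param t time points (s); defaults to the `n_phases` uniform cardiac
#'   phases `k * T / n_phases`, k = 0 .. n_phases - 1.
#' @return Numeric vector of mean-lumen velocities (cm/s).
#' @export
generate_waveform <- function(spec, t = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(t))
    t <- (seq_len(spec$n_phases) - 1L) * spec$period_s / spec$n_phases
  wf <- spec$waveform
  v <- numeric(length(t))
  for (j in seq_len(nrow(wf)))
    v <- v + wf$amplitude_cms[j] *
      sin(2 * pi * wf$harmonic[j] * t / spec$period_s + wf$phase_rad[j])
  v
}

# Analytic lumen cross-sectional area in mm^2.
lumen_area_mm2 <- function(spec) {
  if (spec$geometry == "circle") pi * spec$radius_mm^2
  else pi * (spec$outer_radius_mm^2 - spec$inner_radius_mm^2)
}

# Radial profile factor f(r) with cross-section average 1, so that
# v(x, t) = vbar(t) * f(r(x)) inside the lumen.
profile_factor <- function(spec, r) {
  if (spec$profile == "plug") return(rep(1, length(r)))
  if (spec$geometry == "circle") {
    R <- spec$radius_mm
    2 * (1 - (r / R)^2)
  } else {
    # annular Poiseuille shape, normalised numerically to unit area-mean
    Ro <- spec$outer_radius_mm; k <- spec$inner_radius_mm / Ro
    w <- function(rho) 1 - rho^2 + (1 - k^2) / log(1 / k) * log(rho)
    rho_fine <- seq(k, 1, length.out = 4096L)
    mean_w <- 2 * pracma::trapz(rho_fine, w(rho_fine) * rho_fine) / (1 - k^2)
    w(pmax(r / Ro, k)) / mean_w
  }
}

# Binary lumen mask (voxel centre inside geometry) and radius map (mm).
lumen_geometry <- function(spec) {
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  row_mm <- (seq_len(nr) - 1L) * spec$pixel_spacing_mm[1]
  col_mm <- (seq_len(nc) - 1L) * spec$pixel_spacing_mm[2]
  r <- sqrt(outer((row_mm - spec$center_mm[1])^2,
                  (col_mm - spec$center_mm[2])^2, "+"))
  mask <- if (spec$geometry == "circle") r <= spec$radius_mm
          else r >= spec$inner_radius_mm & r <= spec$outer_radius_mm
  list(mask = mask, r = r)
}

# Wrap phase values into [-pi, pi).
wrap_phase <- function(phi) ((phi + pi) %% (2 * pi)) - pi

#' Analytic stroke volume of a phantom
#'
#' Integrates the analytic flow waveform Q(t) = A_lumen * vbar(t) over one
#' period by high-resolution trapezoidal quadrature and returns the stroke
#' volume (V+ + V-) / 2, the mean of the two directional displaced volumes.
#'
#' @param spec a [phantom_spec()].
#' @param n_samples quadrature resolution (>= 4096).
#' @return Stroke volume in microlitres per cardiac cycle.
#' @export
analytic_stroke_volume <- function(spec, n_samples = 4096L) {
  q <- analytic_flow_curve(spec, n_samples)
  t <- seq(0, spec$period_s, length.out = n_samples + 1L)
  qc <- c(q, q[1])  # close the period
  v_plus <- pracma::trapz(t, pmax(qc, 0))
  v_minus <- pracma::trapz(t, pmax(-qc, 0))
  (v_plus + v_minus) / 2
}

# Analytic flow rate Q(t_k) in uL/s at n uniform phases (t = 0 .. T(1-1/n)).
# 1 cm/s over 1 mm^2 is 10 uL/s.
analytic_flow_curve <- function(spec, n = spec$n_phases) {
  t <- (seq_len(n) - 1L) * spec$period_s / n
  lumen_area_mm2(spec) * generate_waveform(spec, t) * 10
}

#' Synthesise a cine phase-contrast series from a phantom specification
#'
#' Builds magnitude and phase rasters over one cardiac cycle. Inside the
#' lumen the voxel velocity is the waveform value times the spatial profile
#' factor; static tissue has velocity zero. The stored phase is
#' `pi * v / venc + background_offset_rad + noise`, wrapped to `[-pi, pi)` —
#' velocities beyond venc therefore alias, exactly as in an acquisition.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `series` (a `cine_phase_series`) and `truth`
#'   (a `phantom_truth` carrying the analytic flow curve in uL/s, the
#'   analytic stroke and net volumes in uL, and the true lumen mask).
#' @export
generate_cine_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- lumen_geometry(spec)
  if (!any(geo$mask))
    stop("grid too small (or spacing too coarse) to contain the lumen")
  extent_mm <- (spec$grid_shape - 1L) * spec$pixel_spacing_mm
  outer_r <- if (spec$geometry == "circle") spec$radius_mm
             else spec$outer_radius_mm
  if (any(spec$center_mm - outer_r < 0) ||
      any(spec$center_mm + outer_r > extent_mm))
    stop("grid too small to contain the lumen geometry")

  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]; np <- spec$n_phases
  vbar <- generate_waveform(spec)
  fac <- matrix(0, nr, nc)
  fac[geo$mask] <- profile_factor(spec, geo$r[geo$mask])

  if (!is.null(spec$seed)) set.seed(spec$seed)
  phase <- array(0, dim = c(nr, nc, np))
  for (k in seq_len(np)) {
    phi <- pi * (vbar[k] * fac) / spec$venc_cms + spec$background_offset_rad
    if (spec$noise_sd_rad > 0)
      phi <- phi + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd_rad), nr, nc)
    phase[, , k] <- wrap_phase(phi)
  }
  magnitude <- array(rep(ifelse(geo$mask, 1, 0.5), np), dim = c(nr, nc, np))

  series <- cine_phase_series(phase, magnitude, venc_cms = spec$venc_cms,
                              pixel_spacing_mm = spec$pixel_spacing_mm,
                              period_s = spec$period_s)
  q_true <- analytic_flow_curve(spec)
  t_fine <- seq(0, spec$period_s, length.out = 4097L)
  q_fine <- lumen_area_mm2(spec) * generate_waveform(spec, t_fine) * 10
  v_plus <- pracma::trapz(t_fine, pmax(q_fine, 0))
  v_minus <- pracma::trapz(t_fine, pmax(-q_fine, 0))
  truth <- structure(list(flow_curve_true = q_true,
                          sv_true_ul = (v_plus + v_minus) / 2,
                          net_volume_true_ul = v_plus - v_minus,
                          lumen_mask_true = geo$mask,
                          lumen_area_true_mm2 = lumen_area_mm2(spec)),
                     class = "phantom_truth")
  list(series = series, truth = truth)
}

#' Container for a cine phase-contrast series
#'
#' @param phase 3-D array (row, col, cardiac phase) of wrapped phase in
#'   radians, values in `[-pi, pi)`.
#' @param magnitude 3-D array of the same shape, arbitrary units.
#' @param venc_cms velocity encoding (cm/s).
#' @param pixel_spacing_mm in-plane spacing `c(row, col)` in mm.
#' @param period_s cardiac period (s).
#' @return An object of class `cine_phase_series`.
#' @export
cine_phase_series <- function(phase, magnitude, venc_cms, pixel_spacing_mm,
                              period_s) {
  stopifnot(length(dim(phase)) == 3L, all(dim(phase) == dim(magnitude)))
  if (any(phase < -pi - 1e-9) || any(phase >= pi + 1e-9))
    stop("phase values must lie in [-pi, pi)")
  if (dim(phase)[3] < 8L) stop("need at least 8 cardiac phases")
  if (venc_cms <= 0) stop("venc_cms must be > 0")
  if (length(pixel_spacing_mm) == 1L)
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  structure(list(phase = phase, magnitude = magnitude, venc_cms = venc_cms,
                 pixel_spacing_mm = pixel_spacing_mm, period_s = period_s,
                 n_phases = dim(phase)[3]),
            class = "cine_phase_series")
}

#' @export
print.cine_phase_series <- function(x, ...) {
  cat("cine phase-contrast series: ", dim(x$phase)[1], " x ",
      dim(x$phase)[2], " voxels, ", x$n_phases, " cardiac phases\n",
      "  venc ", x$venc_cms, " cm/s, period ", x$period_s, " s, spacing ",
      paste(signif(x$pixel_spacing_mm, 3), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' Write / read a cine series as 4-D NIfTI plus JSON sidecar
#'
#' The phase volume is stored in radians as float; acquisition metadata
#' (venc, period, spacing, frame count) goes into a JSON sidecar since NIfTI
#' headers carry none of it.
#'
#' @param series a `cine_phase_series`.
#' @param prefix output path prefix; writes `<prefix>_phase.nii.gz`,
#'   `<prefix>_mag.nii.gz` and `<prefix>_meta.json`.
#' @return `write_cine_series`: the three paths, invisibly.
#' @export
write_cine_series <- function(series, prefix) {
  stopifnot(inherits(series, "cine_phase_series"))
  d <- dim(series$phase)
  ph <- array(series$phase, dim = c(d[1], d[2], 1L, d[3]))
  mg <- array(series$magnitude, dim = c(d[1], d[2], 1L, d[3]))
  paths <- c(phase = paste0(prefix, "_phase.nii.gz"),
             mag = paste0(prefix, "_mag.nii.gz"),
             sidecar = paste0(prefix, "_meta.json"))
  pd <- c(series$pixel_spacing_mm, 1, series$period_s / series$n_phases)
  RNifti::writeNifti(RNifti::asNifti(ph, datatype = "float",
                                     pixdim = pd), paths["phase"])
  RNifti::writeNifti(RNifti::asNifti(mg, datatype = "float",
                                     pixdim = pd), paths["mag"])
  jsonlite::write_json(list(venc_cms = series$venc_cms,
                            period_s = series$period_s,
                            pixel_spacing_mm = series$pixel_spacing_mm,
                            n_phases = series$n_phases),
                       paths["sidecar"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_cine_series
#' @param phase_path,mag_path,sidecar_path files written by
#'   [write_cine_series()].
#' @return `read_cine_series`: a `cine_phase_series`.
#' @export
read_cine_series <- function(phase_path, mag_path, sidecar_path) {
  meta <- validate_inputs(phase_path, mag_path, sidecar_path)
  ph <- drop(as.array(RNifti::readNifti(phase_path)))
  mg <- drop(as.array(RNifti::readNifti(mag_path)))
  ph <- array(as.numeric(ph), dim = dim(ph))
  mg <- array(as.numeric(mg), dim = dim(mg))
  # float storage may nudge a value onto the open upper bound; fold it back
  ph <- wrap_phase(ph)
  cine_phase_series(ph, mg, venc_cms = meta$venc_cms,
                    pixel_spacing_mm = meta$pixel_spacing_mm,
                    period_s = meta$period_s)
}
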