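#' Convert a cine phase series to a voxel-wise velocity field
#'
#' Standard phase-contrast calibration: a stored phase of +/- pi corresponds
#' to +/- venc, so `v = venc * phi / pi` (cm/s). Positive phase is taken as
#' flow toward the feet (cranio-caudal); the stroke-volume convention used
#' downstream is symmetric in flow direction, so results do not depend on
#' this choice.
#'
#' @param series a `cine_phase_series`.
#' @return Object of class `velocity_field`: list with `velocity` (3-D
#'   array, cm/s), acquisition metadata, and provenance flags
#'   `aliasing_corrected`, `background_corrected`.
#' @export
phase_to_velocity <- function(series) {
  stopifnot(inherits(series, "cine_phase_series"))
  if (series$venc_cms <= 0) stop("venc_cms must be > 0")
  structure(list(velocity = series$venc_cms * series$phase / pi,
                 venc_cms = series$venc_cms,
                 pixel_spacing_mm = series$pixel_spacing_mm,
                 period_s = series$period_s, n_phases = series$n_phases,
                 aliasing_corrected = FALSE, background_corrected = FALSE),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("velocity field: ", dim(x$velocity)[1], " x ", dim(x$velocity)[2],
      " voxels, ", x$n_phases, " cardiac phases (venc ", x$venc_cms,
      " cm/s)\n  aliasing_corrected=", x$aliasing_corrected,
      ", background_corrected=", x$background_corrected, "\n", sep = "")
  invisible(x)
}

# Unwrap one voxel's velocity time series over the cardiac cycle: velocity
# wraps with period 2*venc, so any frame-to-frame jump larger than venc is
# taken as an alias crossing and subsequent samples are shifted by the
# corresponding multiple of 2*venc. The whole series is then shifted by the
# multiple of 2*venc that minimises |temporal mean| (CSF flow is near
# zero-mean over the cycle), preferring the smaller shift on ties.
unwrap_series <- function(v, venc) {
  d <- diff(v)
  jumps <- round(d / (2 * venc))  # |d| > venc  <=>  jumps != 0
  if (any(jumps != 0)) v <- v - c(0, cumsum(jumps)) * 2 * venc
  m <- mean(v)
  shift <- round(m / (2 * venc))
  cand <- (shift + c(0, -1, 1)) * 2 * venc
  resid <- abs(m - cand)
  best <- cand[order(resid, abs(cand))][1]
  if (best != 0) v <- v - best
  v
}

#' Correct temporal velocity aliasing
#'
#' Velocities beyond the encoding limit wrap by multiples of 2*venc. This
#' cyclic 1-D unwrap along the cardiac dimension restores them per voxel,
#' keeping the branch with minimal total variation and minimal absolute
#' temporal mean. Series with no frame-to-frame jump above venc are
#' returned unchanged; the operation is idempotent.
#'
#' @param field a `velocity_field`.
#' @param venc_cms velocity encoding (defaults to the field's own).
#' @return The corrected `velocity_field` with `aliasing_corrected = TRUE`.
#' @export
unalias_temporal <- function(field, venc_cms = field$venc_cms) {
  stopifnot(inherits(field, "velocity_field"))
  v <- field$velocity
  d <- dim(v)
  flat <- matrix(v, d[1] * d[2], d[3])
  jump <- matrixStats_rowMaxs(abs(flat[, -1, drop = FALSE] -
                                  flat[, -d[3], drop = FALSE]))
  needs <- which(jump > venc_cms |
                 abs(flat[, 1] - flat[, d[3]]) > venc_cms)
  for (i in needs) flat[i, ] <- unwrap_series(flat[i, ], venc_cms)
  field$velocity <- array(flat, dim = d)
  field$aliasing_corrected <- TRUE
  field
}

# Row-wise max without a matrixStats dependency.
matrixStats_rowMaxs <- function(m) {
  if (ncol(m) == 0L) return(rep(-Inf, nrow(m)))
  do.call(pmax, as.data.frame(m))
}

#' Remove the static-tissue background velocity offset
#'
#' Eddy currents leave a constant phase (hence velocity) baseline even in
#' static tissue. The default subtracts a single scalar — the median
#' velocity over the static mask and all frames — which models a constant
#' offset without touching genuine pulsatility; `mode = "per_frame"`
#' subtracts a per-frame median instead.
#'
#' @param field a `velocity_field`.
#' @param static_mask logical matrix marking static tissue; must be
#'   non-empty and should not intersect the lumen of interest.
#' @param mode `"scalar"` (default) or `"per_frame"`.
#' @return Corrected `velocity_field` with `background_corrected = TRUE`.
#' @export
background_correct <- function(field, static_mask,
                               mode = c("scalar", "per_frame")) {
  stopifnot(inherits(field, "velocity_field"))
  mode <- match.arg(mode)
  static_mask <- as.logical(static_mask)
  dim(static_mask) <- dim(field$velocity)[1:2]
  if (!any(static_mask)) stop("static_mask is empty")
  v <- field$velocity
  if (mode == "scalar") {
    off <- stats::median(apply(v, 3, function(fr) fr[static_mask]))
    v <- v - off
  } else {
    for (k in seq_len(dim(v)[3]))
      v[, , k] <- v[, , k] - stats::median(v[, , k][static_mask])
  }
  field$velocity <- v
  field$background_corrected <- TRUE
  field
}

#' Border static-tissue mask
#'
#' Convenience default for [background_correct()]: a frame of voxels along
#' the image border, far from any central lumen.
#'
#' @param grid_shape `c(rows, cols)`.
#' @param width border width in voxels.
#' @return Logical matrix.
#' @export
border_mask <- function(grid_shape, width = 2L) {
  m <- matrix(FALSE, grid_shape[1], grid_shape[2])
  w <- seq_len(width)
  m[c(w, grid_shape[1] + 1L - w), ] <- TRUE
  m[, c(w, grid_shape[2] + 1L - w)] <- TRUE
  m
}
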