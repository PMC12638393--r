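#' Peak-to-peak pulsatility map
#'
#' Per-voxel amplitude of the velocity waveform over the cardiac cycle,
#' `max_k v(x,k) - min_k v(x,k)` (cm/s). Pulsatile CSF lumens stand out
#' against static tissue, which is what makes seed-driven region growing a
#' workable stand-in for the semi-automatic segmentation step of clinical
#' flow software.
#'
#' @param field a `velocity_field` with at least two frames.
#' @return Object of class `pulsatility_map`: list with `amplitude`
#'   (matrix, cm/s) and `pixel_spacing_mm`.
#' @export
pulsatility_map <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if (dim(field$velocity)[3] < 2L) stop("need at least 2 cardiac phases")
  amp <- apply(field$velocity, c(1, 2), function(v) max(v) - min(v))
  structure(list(amplitude = amp,
                 pixel_spacing_mm = field$pixel_spacing_mm),
            class = "pulsatility_map")
}

#' Semi-automatic ROI segmentation by pulsatility region growing
#'
#' Grows a 4-connected region from a user-placed seed voxel, keeping every
#' connected voxel whose pulsatility amplitude is at least
#' `threshold_frac` times the amplitude at the seed. One interpretable
#' parameter; 4-connectivity avoids diagonal leakage through thin septa
#' between CSF spaces.
#'
#' @param map a [pulsatility_map()].
#' @param seed `c(row, col)`, 0-based voxel coordinate of a pulsatile voxel.
#' @param threshold_frac fraction of the seed amplitude, in (0, 1).
#' @param site measurement-site label (see [csf_sites()]).
#' @return Object of class `roi_mask`: list with logical `mask`, `site`,
#'   `pixel_area_mm2`, and the parameters used.
#' @export
segment_roi <- function(map, seed, threshold_frac = 0.2, site = "aqu") {
  stopifnot(inherits(map, "pulsatility_map"))
  stopifnot(length(seed) == 2L, threshold_frac > 0, threshold_frac < 1)
  amp <- map$amplitude
  r0 <- as.integer(seed[1]) + 1L; c0 <- as.integer(seed[2]) + 1L
  if (r0 < 1L || r0 > nrow(amp) || c0 < 1L || c0 > ncol(amp))
    stop("seed outside image bounds")
  if (amp[r0, c0] <= 0) stop("seed not pulsatile")
  thr <- threshold_frac * amp[r0, c0]
  eligible <- amp >= thr
  mask <- matrix(FALSE, nrow(amp), ncol(amp))
  # BFS flood fill, 4-connected
  queue <- matrix(c(r0, c0), ncol = 2L)
  mask[r0, c0] <- TRUE
  while (nrow(queue) > 0L) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- cur[1] + d[1]; cc <- cur[2] + d[2]
      if (rr >= 1L && rr <= nrow(amp) && cc >= 1L && cc <= ncol(amp) &&
          eligible[rr, cc] && !mask[rr, cc]) {
        mask[rr, cc] <- TRUE
        queue <- rbind(queue, c(rr, cc))
      }
    }
  }
  roi_mask(mask, site = site,
           pixel_area_mm2 = prod(map$pixel_spacing_mm),
           params = list(seed = as.integer(seed),
                         threshold_frac = threshold_frac))
}

#' Manual polygonal ROI
#'
#' Rasterises a hand-drawn polygon: a voxel belongs to the ROI iff its
#' centre lies inside the polygon (even-odd rule). Used for the narrowest
#' aqueductal cross-section, which the study delineated manually.
#'
#' @param polygon numeric matrix (or 2-column data frame) of vertices,
#'   `(row, col)` in voxel units (0-based, voxel centres at integers);
#'   at least 3 vertices.
#' @param grid_shape `c(rows, cols)`.
#' @param pixel_area_mm2 area of one voxel, mm^2.
#' @param site site label.
#' @return An `roi_mask`.
#' @export
manual_roi <- function(polygon, grid_shape, pixel_area_mm2, site = "aqu") {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  area2 <- abs(sum(polygon[, 1] * c(polygon[-1, 2], polygon[1, 2]) -
                   polygon[, 2] * c(polygon[-1, 1], polygon[1, 1])))
  if (area2 == 0) stop("degenerate polygon (zero area)")
  centers <- expand.grid(row = seq_len(grid_shape[1]) - 1L,
                         col = seq_len(grid_shape[2]) - 1L)
  inside <- pracma::inpolygon(centers$row, centers$col,
                              polygon[, 1], polygon[, 2],
                              boundary = TRUE)
  mask <- matrix(inside, grid_shape[1], grid_shape[2])
  if (!any(mask)) stop("polygon contains no voxel centre")
  roi_mask(mask, site = site, pixel_area_mm2 = pixel_area_mm2,
           params = list(polygon = polygon))
}

#' ROI mask constructor
#'
#' @param mask logical matrix, non-empty.
#' @param site site label, validated via [normalize_site()].
#' @param pixel_area_mm2 area of one voxel (mm^2).
#' @param params provenance: parameters that produced the mask.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(mask, site = "aqu", pixel_area_mm2 = 1,
                     params = list()) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask is empty")
  structure(list(mask = mask, site = normalize_site(site),
                 pixel_area_mm2 = pixel_area_mm2, params = params),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("ROI mask (", x$site, "): ", sum(x$mask), " voxels, ",
      signif(sum(x$mask) * x$pixel_area_mm2, 4), " mm^2\n", sep = "")
  invisible(x)
}

#' Write an ROI mask as PNG plus JSON metadata
#'
#' @param roi an `roi_mask`.
#' @param prefix path prefix; writes `<prefix>_mask.png` (0/255) and
#'   `<prefix>_mask.json`.
#' @export
write_roi_mask <- function(roi, prefix) {
  stopifnot(inherits(roi, "roi_mask"))
  png_path <- paste0(prefix, "_mask.png")
  json_path <- paste0(prefix, "_mask.json")
  png::writePNG(roi$mask * 1, png_path)
  jsonlite::write_json(list(site = roi$site,
                            pixel_area_mm2 = roi$pixel_area_mm2,
                            n_voxels = sum(roi$mask),
                            area_mm2 = sum(roi$mask) * roi$pixel_area_mm2),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(mask = png_path, meta = json_path))
}

#' Dice overlap between two masks
#'
#' @param a,b logical matrices of equal shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
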