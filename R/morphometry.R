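#' Evans index
#'
#' Ratio of the maximum frontal-horn width to the maximum inner biparietal
#' diameter, a standard ventriculomegaly marker (values above ~0.3 are read
#' as abnormal). Consumes the two caliper measurements directly, as a
#' manual reading would.
#'
#' @param frontal_horn_width_mm maximum frontal-horn width (mm), > 0.
#' @param biparietal_diameter_mm maximum biparietal diameter (mm), > width.
#' @return Dimensionless ratio in (0, 1).
#' @export
evans_index <- function(frontal_horn_width_mm, biparietal_diameter_mm) {
  if (any(frontal_horn_width_mm <= 0) || any(biparietal_diameter_mm <= 0))
    stop("measurements must be positive")
  if (any(frontal_horn_width_mm >= biparietal_diameter_mm))
    stop("frontal-horn width must be smaller than the biparietal diameter")
  frontal_horn_width_mm / biparietal_diameter_mm
}

#' Area of an ROI mask
#'
#' @param roi an `roi_mask`.
#' @return Area in mm^2 (`voxel count * pixel_area_mm2`).
#' @export
mask_area <- function(roi) {
  stopifnot(inherits(roi, "roi_mask"))
  if (!any(roi$mask)) stop("empty mask")
  sum(roi$mask) * roi$pixel_area_mm2
}

#' Narrowest cross-section in a slice stack
#'
#' Given per-slice aqueductal areas, returns the slice with the minimal
#' area; ties resolve to the smallest slice index.
#'
#' @param areas data frame (or 2-column matrix) with columns `slice_index`
#'   and `area_mm2`; non-empty.
#' @return List with `slice_index` and `area_mm2`.
#' @export
narrowest_slice <- function(areas) {
  areas <- as.data.frame(areas)
  if (nrow(areas) == 0L) stop("empty slice list")
  names(areas)[1:2] <- c("slice_index", "area_mm2")
  ord <- order(areas$area_mm2, areas$slice_index)
  list(slice_index = areas$slice_index[ord[1]],
       area_mm2 = areas$area_mm2[ord[1]])
}
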