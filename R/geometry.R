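#' Scan geometry for a wide-field acquisition
#'
#' A wide-field scan is composed of one central and an even number of
#' lateral ("half ring") subscans, each acquired with the same detector but
#' at a laterally shifted sample position. The geometry fixes the global
#' signed detector coordinate frame: `s = 0` lies on the rotation axis and
#' subscan `i` samples `s` in `[offset_i - D/2, offset_i + D/2)`.
#'
#' @param detector_width_px Detector width `D` in pixels.
#' @param n_subscans Odd number of subscans (1 = conventional scan).
#' @param overlaps_px Overlap between laterally adjacent subscans, in
#'   pixels; either a single value recycled to all `n_subscans - 1` seams
#'   or a vector of per-seam overlaps. Each must lie in `[0, D)`.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param desired_fov_px Nominal target field of view in pixels (defaults
#'   to the covered width).
#'
#' @return An object of class `scan_geometry`: a list with fields
#'   `detector_width_px`, `n_subscans`, `overlaps_px`, `offsets_px`
#'   (signed, symmetric about 0, central subscan first in spatial order),
#'   `pixel_size_um` and `desired_fov_px`.
#' @seealso [plan_widefield()], [covered_width()], [reference_total()]
#' @export
#' @examples
#' g <- scan_geometry(1024, 3, 100)
#' covered_width(g)   # 3 * 1024 - 2 * 100 = 2872
scan_geometry <- function(detector_width_px, n_subscans = 1, overlaps_px = 0,
                          pixel_size_um = 1.48, desired_fov_px = NULL) {
  detector_width_px <- as.integer(detector_width_px)
  n_subscans <- as.integer(n_subscans)
  if (detector_width_px < 1) stop("`detector_width_px` must be positive")
  if (n_subscans < 1 || n_subscans %% 2 == 0)
    stop("`n_subscans` must be an odd positive integer")
  n_seams <- n_subscans - 1L
  if (n_seams == 0L) {
    overlaps_px <- integer(0)
  } else {
    if (length(overlaps_px) == 1L) overlaps_px <- rep(overlaps_px, n_seams)
    if (length(overlaps_px) != n_seams)
      stop("`overlaps_px` must have length n_subscans - 1")
  }
  if (any(overlaps_px < 0) || any(overlaps_px >= detector_width_px))
    stop("each overlap must lie in [0, detector_width_px)")
  # spatial order left..right; offsets symmetric when overlaps are equal
  step <- detector_width_px - overlaps_px
  pos <- c(0, cumsum(step))            # left edge positions relative to first
  offsets <- pos - pos[(n_subscans + 1L) / 2L]
  covered <- n_subscans * detector_width_px - sum(overlaps_px)
  if (is.null(desired_fov_px)) desired_fov_px <- covered
  structure(
    list(
      detector_width_px = detector_width_px,
      n_subscans = n_subscans,
      overlaps_px = as.numeric(overlaps_px),
      offsets_px = as.numeric(offsets),
      pixel_size_um = pixel_size_um,
      desired_fov_px = as.integer(desired_fov_px)
    ),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry>\n")
  cat("  detector width : ", x$detector_width_px, " px (",
      format(fov_mm(x$detector_width_px, x$pixel_size_um), nsmall = 2),
      " mm)\n", sep = "")
  cat("  subscans       : ", x$n_subscans, "\n", sep = "")
  if (x$n_subscans > 1)
    cat("  overlaps (px)  : ", paste(x$overlaps_px, collapse = ", "), "\n",
        sep = "")
  cat("  offsets (px)   : ", paste(x$offsets_px, collapse = ", "), "\n",
      sep = "")
  cat("  covered width  : ", covered_width(x), " px (",
      format(fov_mm(covered_width(x), x$pixel_size_um), nsmall = 2),
      " mm)\n", sep = "")
  invisible(x)
}

#' Width of the field of view covered by a geometry
#'
#' @param geometry A [scan_geometry()].
#' @return Covered width in pixels: `n * D - sum(overlaps)`.
#' @export
covered_width <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  as.integer(geometry$n_subscans * geometry$detector_width_px -
               sum(geometry$overlaps_px))
}

#' Plan a wide-field scan layout
#'
#' Chooses the smallest odd number of laterally offset subscans whose
#' merged width `n * D - (n - 1) * overlap` covers the desired field of
#' view, with symmetric offsets spaced by `D - overlap`.
#'
#' @param desired_fov_px Target field of view in pixels (>= detector width).
#' @param detector_width_px Detector width in pixels.
#' @param overlap_px Overlap between adjacent subscans in pixels, in
#'   `[0, detector_width_px)`.
#' @inheritParams scan_geometry
#' @return A [scan_geometry()].
#' @export
#' @examples
#' plan_widefield(3072, 1024, 0)$n_subscans    # 3
#' plan_widefield(7168, 1024, 0)$n_subscans    # 7
plan_widefield <- function(desired_fov_px, detector_width_px, overlap_px,
                           pixel_size_um = 1.48) {
  if (overlap_px >= detector_width_px || overlap_px < 0)
    stop("`overlap_px` must lie in [0, detector_width_px)")
  if (desired_fov_px < detector_width_px)
    stop("`desired_fov_px` must be at least the detector width")
  n <- 1L
  while (n * detector_width_px - (n - 1L) * overlap_px < desired_fov_px)
    n <- n + 2L
  scan_geometry(detector_width_px, n, overlap_px,
                pixel_size_um = pixel_size_um,
                desired_fov_px = desired_fov_px)
}

#' Physical field of view
#'
#' @param width_px Width in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @return Field of view in millimetres, rounded to 2 decimals.
#' @export
#' @examples
#' fov_mm(1024, 1.48)  # 1.52
#' fov_mm(2792, 1.48)  # 4.13
fov_mm <- function(width_px, pixel_size_um) {
  if (width_px < 0 || pixel_size_um <= 0)
    stop("`width_px` must be >= 0 and `pixel_size_um` > 0")
  round(width_px * pixel_size_um / 1000, 2)
}
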