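#' Construct a subscan projection set
#'
#' @param projections Matrix `[P x W]` (one detector row) or array
#'   `[P x n_rows x W]` of projection values, one slab per angle.
#' @param angles_deg Strictly increasing, equiangular angles in
#'   `[0, 180)` (or `[0, 360)` for off-center mode).
#' @param offset_px Signed lateral offset of the subscan center from the
#'   rotation axis, in pixels.
#' @param darks,flats Optional lists of dark/flat frames (matrices with
#'   `W` columns), as produced by [make_flats_darks()].
#' @param mode `"absorption"` (line integrals) or `"transmittance"`
#'   (detector counts needing [normalize_projections()]).
#' @return An object of class `subscan_set`.
#' @export
subscan_set <- function(projections, angles_deg, offset_px = 0,
                        darks = NULL, flats = NULL,
                        mode = c("absorption", "transmittance")) {
  mode <- match.arg(mode)
  if (is.matrix(projections)) {
    if (nrow(projections) != length(angles_deg))
      stop("projection row count must equal the number of angles")
  } else if (length(dim(projections)) == 3) {
    if (dim(projections)[1] != length(angles_deg))
      stop("projection slab count must equal the number of angles")
  } else stop("`projections` must be a [P x W] matrix or [P x n_rows x W] array")
  if (length(angles_deg) > 1) {
    d <- diff(angles_deg)
    if (any(d <= 0) || max(abs(d - d[1])) > 1e-8)
      stop("`angles_deg` must be strictly increasing and equiangular")
  }
  width <- if (is.matrix(projections)) ncol(projections) else
    dim(projections)[3]
  for (fr in c(darks, flats))
    if (ncol(fr) != width) stop("dark/flat frames must match projection width")
  structure(list(projections = projections, angles_deg = angles_deg,
                 offset_px = offset_px, darks = darks, flats = flats,
                 mode = mode),
            class = "subscan_set")
}

#' @export
print.subscan_set <- function(x, ...) {
  w <- if (is.matrix(x$projections)) ncol(x$projections) else
    dim(x$projections)[3]
  cat("<subscan_set> ", length(x$angles_deg), " projections x ", w,
      " px, offset ", x$offset_px, " px, ", x$mode, " domain\n", sep = "")
  invisible(x)
}

#' Equiangular acquisition angles
#'
#' @param n Number of projections.
#' @param full_circle If `TRUE`, angles cover `[0, 360)` (off-center
#'   flip-and-stitch mode); otherwise `[0, 180)`.
#' @return Numeric vector of `n` angles in degrees.
#' @export
subscan_angles <- function(n, full_circle = FALSE) {
  span <- if (full_circle) 360 else 180
  seq(0, span, length.out = n + 1)[seq_len(n)]
}

# global detector coordinates (pixel centers) of a subscan's columns
detector_coords <- function(detector_width_px, offset_px) {
  offset_px - detector_width_px / 2 + seq_len(detector_width_px) - 0.5
}

#' Parallel-beam forward projection of a phantom
#'
#' Computes the discrete Radon transform of a phantom for a laterally
#' offset detector. The rotation axis sits at global detector coordinate
#' `s = 0` (the phantom's center); the subscan samples rays at
#' `s` in `[offset - W/2, offset + W/2)` on a 1-pixel lattice, and each
#' value is the line integral along the ray (bilinear sampling, 1-pixel
#' ray step), in units of pixel x image value.
#'
#' @param phantom A [shepp_logan()] phantom or plain numeric matrix.
#' @param angles_deg Projection angles in degrees (`theta = 0` integrates
#'   along +y).
#' @param offset_px Signed lateral offset of the detector center.
#' @param detector_width_px Detector width; defaults to the phantom width.
#' @return A [subscan_set()] in absorption mode.
#' @export
#' @examples
#' p <- shepp_logan(64)
#' s <- forward_project(p, subscan_angles(8))
#' dim(s$projections)  # 8 x 64
forward_project <- function(phantom, angles_deg, offset_px = 0,
                            detector_width_px = NULL) {
  img <- if (inherits(phantom, "wf_phantom")) phantom$image else phantom
  if (!is.matrix(img) || !all(is.finite(img)))
    stop("phantom image must be a finite numeric matrix")
  if (is.null(detector_width_px)) detector_width_px <- ncol(img)
  s <- detector_coords(detector_width_px, offset_px)
  half <- max(dim(img)) / 2
  if (min(abs(s)) >= sqrt(2) * half)
    warning("detector band lies entirely outside the phantom support; ",
            "projections are zero")
  proj <- cpp_forward_project(img, angles_deg * pi / 180, s)
  subscan_set(proj, angles_deg, offset_px = offset_px, mode = "absorption")
}

#' Simulate the subscans of a wide-field acquisition
#'
#' Forward-projects a phantom once per subscan of a geometry, each at its
#' lateral offset and with its own projection count, optionally converting
#' to the transmittance domain
#' (`I = (flat - dark) * exp(-mu_scale * line) + dark`, so a blank beam
#' reads the flat level and normalizes to exactly 1)
#' and adding Gaussian noise and flat/dark frames, so the full
#' normalize-merge-reconstruct chain can be exercised on synthetic data.
#'
#' @param phantom A [shepp_logan()] phantom or numeric matrix; its width
#'   should equal the geometry's covered width so the support fills the
#'   field of view.
#' @param geometry A [scan_geometry()].
#' @param per_subscan Integer vector of projection counts, one per subscan
#'   (a row of a [make_protocol_ladder()] ladder).
#' @param noise_sd Gaussian noise sd added to the projections (in the
#'   emitted domain).
#' @param mode `"absorption"` (default) or `"transmittance"`.
#' @param flat_level,dark_level,n_flats Flat/dark frame parameters
#'   (transmittance mode).
#' @param mu_scale Attenuation per unit line integral (transmittance mode).
#' @param seed Optional integer seed.
#' @return A list of [subscan_set()]s in spatial order (left to right).
#' @export
simulate_subscans <- function(phantom, geometry, per_subscan, noise_sd = 0,
                              mode = c("absorption", "transmittance"),
                              flat_level = 1000, dark_level = 50,
                              n_flats = 5, mu_scale = 0.005, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "scan_geometry"))
  if (length(per_subscan) != geometry$n_subscans)
    stop("`per_subscan` must give one projection count per subscan")
  with_seed(seed, {
    purrr::map(seq_len(geometry$n_subscans), function(i) {
      ss <- forward_project(phantom, subscan_angles(per_subscan[i]),
                            offset_px = geometry$offsets_px[i],
                            detector_width_px = geometry$detector_width_px)
      if (mode == "transmittance") {
        fd <- make_flats_darks(geometry$detector_width_px, n_flats,
                               flat_level, dark_level, noise_sd)
        proj <- (flat_level - dark_level) *
          exp(-mu_scale * ss$projections) + dark_level
        if (noise_sd > 0) proj <- add_gaussian_noise(proj, noise_sd)
        subscan_set(proj, ss$angles_deg, offset_px = ss$offset_px,
                    darks = fd$darks, flats = fd$flats,
                    mode = "transmittance")
      } else {
        if (noise_sd > 0)
          ss$projections <- add_gaussian_noise(ss$projections, noise_sd)
        ss
      }
    })
  })
}
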