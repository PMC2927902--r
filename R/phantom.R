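# run code under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# canonical head phantom: one row per ellipse
# columns: a, b, x0, y0, phi_deg, intensity (additive)
shepp_logan_ellipses <- function() {
  matrix(c(
    0.6900, 0.9200,  0.00,  0.0000,   0,  2.00,
    0.6624, 0.8740,  0.00, -0.0184,   0, -0.98,
    0.1100, 0.3100,  0.22,  0.0000, -18, -0.02,
    0.1600, 0.4100, -0.22,  0.0000,  18, -0.02,
    0.2100, 0.2500,  0.00,  0.3500,   0,  0.01,
    0.0460, 0.0460,  0.00,  0.1000,   0,  0.01,
    0.0460, 0.0460,  0.00, -0.1000,   0,  0.01,
    0.0460, 0.0230, -0.08, -0.6050,   0,  0.01,
    0.0230, 0.0230,  0.00, -0.6060,   0,  0.01,
    0.0230, 0.0460,  0.06, -0.6050,   0,  0.01
  ), ncol = 6, byrow = TRUE,
  dimnames = list(NULL, c("a", "b", "x0", "y0", "phi_deg", "intensity")))
}

#' Shepp-Logan head phantom
#'
#' The standard 10-ellipse head phantom (original 1974 parameters),
#' rendered on a square pixel grid. Intensities are the summed additive
#' contributions of all ellipses containing each pixel center; the support
#' lies inside the inscribed circle of the image.
#'
#' @param width_px Image width in pixels (>= 16).
#' @param pixel_size_um Physical pixel size in micrometres (metadata only).
#' @return An object of class `wf_phantom`: a list with `image`
#'   (`width_px` x `width_px` matrix), `width_px` and `pixel_size_um`.
#' @export
#' @examples
#' p <- shepp_logan(64)
#' range(p$image)
shepp_logan <- function(width_px, pixel_size_um = 1.48) {
  width_px <- as.integer(width_px)
  if (width_px < 16) stop("`width_px` must be at least 16")
  # unit coordinates: x right, y up, origin at the image center
  ax <- (seq_len(width_px) - (width_px + 1) / 2) * (2 / width_px)
  x <- matrix(ax, width_px, width_px, byrow = TRUE)
  y <- matrix(rev(ax), width_px, width_px)
  img <- matrix(0, width_px, width_px)
  e <- shepp_logan_ellipses()
  for (k in seq_len(nrow(e))) {
    phi <- e[k, "phi_deg"] * pi / 180
    xr <- (x - e[k, "x0"]) * cos(phi) + (y - e[k, "y0"]) * sin(phi)
    yr <- -(x - e[k, "x0"]) * sin(phi) + (y - e[k, "y0"]) * cos(phi)
    inside <- (xr / e[k, "a"])^2 + (yr / e[k, "b"])^2 <= 1
    img[inside] <- img[inside] + e[k, "intensity"]
  }
  structure(list(image = img, width_px = width_px,
                 pixel_size_um = pixel_size_um),
            class = "wf_phantom")
}

#' Additive Gaussian noise
#'
#' @param image Numeric matrix or array.
#' @param sd Noise standard deviation (>= 0; 0 is the identity).
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return `image + N(0, sd)` element-wise, same shape.
#' @export
add_gaussian_noise <- function(image, sd, seed = NULL) {
  if (sd < 0) stop("`sd` must be non-negative")
  if (sd == 0) return(image)
  noise <- with_seed(seed, rnorm(length(image), 0, sd))
  image + array(noise, dim = dim(image) %||% length(image))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate flat and dark detector frames
#'
#' Flat frames record the blank beam (sample out), dark frames the
#' detector baseline (beam off); both are needed for projection
#' normalization. Frames are drawn as Gaussian fields around the two
#' levels.
#'
#' @param detector_width_px Detector width in pixels.
#' @param n Number of frames of each kind.
#' @param flat_level,dark_level Mean intensities; `flat_level > dark_level
#'   >= 0`.
#' @param noise_sd Per-pixel Gaussian noise standard deviation.
#' @param seed Optional integer seed for reproducibility.
#' @param n_rows Number of detector rows per frame (1 for single-slice
#'   work).
#' @return A list with `flats` and `darks`, each a list of `n` matrices of
#'   size `n_rows` x `detector_width_px`.
#' @export
make_flats_darks <- function(detector_width_px, n, flat_level, dark_level,
                             noise_sd = 0, seed = NULL, n_rows = 1) {
  if (flat_level <= dark_level || dark_level < 0)
    stop("need `flat_level` > `dark_level` >= 0")
  if (n < 1) stop("`n` must be >= 1")
  with_seed(seed, {
    mk <- function(level) lapply(seq_len(n), function(i) {
      matrix(level + rnorm(n_rows * detector_width_px, 0, noise_sd),
             n_rows, detector_width_px)
    })
    list(flats = mk(flat_level), darks = mk(dark_level))
  })
}
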