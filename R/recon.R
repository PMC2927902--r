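# frequency response of the reconstruction filters on n FFT bins.
# The ramp is the DFT of the discrete Ram-Lak kernel (h(0) = 1/4,
# h(n) = -1/(pi^2 n^2) for odd n), not the ideal ramp 2|f|: sampling the
# continuous ramp directly underweights the DC term and biases every
# reconstruction by a constant offset.
recon_filter <- function(n, name = c("ram-lak", "shepp-logan", "hann")) {
  name <- match.arg(name)
  f <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) / n  # |fftfreq|
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))    # lags
  h <- ifelse(k == 0, 0.25, ifelse(k %% 2 == 0, 0, -1 / (pi^2 * k^2)))
  ramp <- 2 * Re(fft(h))
  switch(name,
    "ram-lak" = ramp,
    "shepp-logan" = {
      w <- rep(1, n); nz <- f > 0
      w[nz] <- sin(pi * f[nz]) / (pi * f[nz])
      ramp * w
    },
    "hann" = ramp * (0.5 + 0.5 * cos(2 * pi * f))
  )
}

#' Reconstruct one slice by filtered backprojection
#'
#' Ramp-filtered backprojection of a parallel-beam sinogram: each row is
#' zero-padded to the next power of two (at least twice the width),
#' filtered in the frequency domain, and backprojected with linear
#' detector interpolation, scaled by `pi / (2 * n_angles)`. The
#' reconstruction is linear in the sinogram and deterministic; values
#' outside the inscribed circle are set to zero.
#'
#' @param sinogram `[P x W]` matrix, one row per angle.
#' @param angles_deg `P` angles in degrees spanning `[0, 180)`.
#' @param filter_name `"ram-lak"` (default), `"shepp-logan"` or `"hann"`.
#' @param pixel_size_um Pixel size carried to the output (metadata).
#' @return An object of class `recon_slice`: list with `image` (`W x W`
#'   matrix), `pixel_size_um` and `filter`.
#' @export
#' @examples
#' p <- shepp_logan(64)
#' s <- forward_project(p, subscan_angles(101))
#' r <- reconstruct_slice(s$projections, s$angles_deg)
reconstruct_slice <- function(sinogram, angles_deg,
                              filter_name = c("ram-lak", "shepp-logan",
                                              "hann"),
                              pixel_size_um = 1.48) {
  filter_name <- match.arg(filter_name)
  if (!is.matrix(sinogram)) stop("`sinogram` must be a [P x W] matrix")
  if (nrow(sinogram) != length(angles_deg))
    stop("sinogram row count must equal the number of angles")
  if (length(angles_deg) < 2)
    stop("at least two projection angles are required")
  if (anyNA(sinogram) || !all(is.finite(sinogram)))
    stop("sinogram contains NA or non-finite values")
  P <- nrow(sinogram); W <- ncol(sinogram)
  npad <- 2^ceiling(log2(max(64, 2 * W)))
  H <- recon_filter(npad, filter_name)
  padded <- matrix(0, P, npad)
  padded[, seq_len(W)] <- sinogram
  filtered <- t(apply(padded, 1, function(row)
    Re(fft(fft(row) * H, inverse = TRUE)) / npad))[, seq_len(W),
                                                   drop = FALSE]
  s <- seq_len(W) - (W + 1) / 2          # detector coords, axis at 0
  img <- cpp_backproject(filtered, angles_deg * pi / 180, s, W) *
    (pi / (2 * P))
  ax <- seq_len(W) - (W + 1) / 2
  rr <- outer(ax^2, ax^2, `+`)
  img[sqrt(rr) > W / 2] <- 0
  structure(list(image = img, pixel_size_um = pixel_size_um,
                 filter = filter_name),
            class = "recon_slice")
}

#' Reconstruct a volume slice by slice
#'
#' @param stack A `sinogram_stack` from [build_sinograms()].
#' @param angles_deg Angles in degrees; defaults to the stack's own.
#' @inheritParams reconstruct_slice
#' @return List of `recon_slice` objects, in row order.
#' @export
reconstruct_volume <- function(stack, angles_deg = NULL,
                               filter_name = "ram-lak",
                               pixel_size_um = 1.48) {
  stopifnot(inherits(stack, "sinogram_stack"))
  angles_deg <- angles_deg %||% stack$angles_deg
  n <- dim(stack$sinograms)[1]
  purrr::map(seq_len(n), function(k)
    reconstruct_slice(stack$sinograms[k, , ], angles_deg,
                      filter_name = filter_name,
                      pixel_size_um = pixel_size_um))
}

#' Window a reconstructed slice to 8-bit gray values
#'
#' @param slice A `recon_slice` or numeric matrix.
#' @param window Optional `c(lo, hi)` window; defaults to the data range.
#' @return Integer matrix of values in 0..255.
#' @export
to_gray8 <- function(slice, window = NULL) {
  img <- if (inherits(slice, "recon_slice")) slice$image else slice
  window <- window %||% range(img)
  if (diff(window) <= 0) stop("degenerate gray window")
  scaled <- (img - window[1]) / diff(window)
  matrix(as.integer(round(pmin(pmax(scaled, 0), 1) * 255)),
         nrow(img), ncol(img))
}
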