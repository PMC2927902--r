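#' Otsu threshold
#'
#' Gray-value threshold maximizing the between-class variance of the image
#' histogram, computed on 256 equal-width bins spanning the data range.
#' The returned value is the upper edge of the chosen bin: pixels with
#' `value > threshold` form the foreground class.
#'
#' @param image Numeric matrix/array with at least two distinct values.
#' @param n_bins Number of histogram bins.
#' @return The threshold as a single numeric value.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) == 0) stop("constant image: no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)                    # class-0 mass up to each bin
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  k <- which.max(sigma_b)
  edges[k + 1]
}

#' Binarize an image with the Otsu threshold
#'
#' @inheritParams otsu_threshold
#' @return 0/1 matrix/array of the same shape (1 = above threshold).
#' @export
binarize_otsu <- function(image, n_bins = 256) {
  (image > otsu_threshold(image, n_bins)) * 1L
}

#' Disagreement count between two binarized slices
#'
#' `E = sum(|slice_i - slice_B|)`: the number of pixels on which the two
#' binary slices disagree (an L1 metric on binary images).
#'
#' @param slice_i,slice_b Binary (0/1) matrices of the same shape.
#' @return Non-negative integer-valued count.
#' @export
slice_difference <- function(slice_i, slice_b) {
  if (!identical(dim(slice_i), dim(slice_b)))
    stop("slices must have the same shape")
  if (!all(slice_i %in% c(0, 1)) || !all(slice_b %in% c(0, 1)))
    stop("slices must be binarized (0/1) before comparison")
  sum(abs(slice_i - slice_b))
}

# slice k of a volume stored as [w x w x n] array or list of matrices
get_slice <- function(volume, k) {
  if (is.list(volume)) {
    s <- volume[[k]]
    if (inherits(s, "recon_slice")) s$image else s
  } else volume[, , k]
}

n_slices <- function(volume)
  if (is.list(volume)) length(volume) else dim(volume)[3]

#' Slice-difference quality of a volume against a gold standard
#'
#' Samples slices `1, 1 + stride, 1 + 2*stride, ...`, Otsu-binarizes each
#' test/reference pair independently, and records the per-slice
#' disagreement count `E`. With stride 5 on a 1024-slice volume, 205
#' slices are evaluated.
#'
#' @param volume_i,volume_b Test and reference volumes: `[w x w x n]`
#'   arrays or lists of matrices/`recon_slice`s, same shape.
#' @param slice_stride Evaluate every `slice_stride`-th slice (>= 1).
#' @param label Optional protocol label carried into the report.
#' @return A tibble of class `wf_quality_report` with one row: `label`,
#'   `n_slices_evaluated`, `mean_E`, `std_E`, and `per_slice_E`
#'   (list-column).
#' @export
protocol_error <- function(volume_i, volume_b, slice_stride = 5,
                           label = NA_character_) {
  if (slice_stride < 1) stop("`slice_stride` must be >= 1")
  n <- n_slices(volume_i)
  if (n != n_slices(volume_b)) stop("volumes must have the same depth")
  idx <- seq(1, n, by = slice_stride)
  if (!length(idx)) stop("no slices selected")
  E <- vapply(idx, function(k)
    slice_difference(binarize_otsu(get_slice(volume_i, k)),
                     binarize_otsu(get_slice(volume_b, k))),
    numeric(1))
  out <- tibble::tibble(label = label,
                        n_slices_evaluated = length(idx),
                        mean_E = mean(E),
                        std_E = if (length(E) > 1) sd(E) else 0,
                        per_slice_E = list(E))
  class(out) <- c("wf_quality_report", class(out))
  out
}

#' Map mean difference values onto a quality scale
#'
#' Affine, order-reversing map: the worst (largest) mean `E` goes to the
#' low end of the range and the best (smallest) to the high end, so
#' quality increases as the difference from the gold standard shrinks.
#'
#' @param mean_E Numeric vector of mean difference values (>= 2 values).
#' @param range Quality range endpoints, low then high (default the
#'   16--116 dose-ladder span).
#' @return Numeric vector of qualities in `range`.
#' @export
normalize_quality <- function(mean_E, range = c(16, 116)) {
  if (length(mean_E) < 2) stop("need at least two protocols to normalize")
  lo <- min(mean_E); hi <- max(mean_E)
  if (hi == lo) stop("all difference values are equal: degenerate scale")
  range[1] + (hi - mean_E) / (hi - lo) * (range[2] - range[1])
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors of equal length; `x` must contain at least
#'   two distinct values.
#' @return An object of class `wf_linefit`: list with `slope`,
#'   `intercept`, `r_squared` and the underlying `lm` fit.
#' @export
#' @examples
#' fit_line(c(0, 1), c(1, 3))  # slope 2, intercept 1
fit_line <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(unique(x)) < 2) stop("`x` is degenerate: need >= 2 values")
  fit <- lm(y ~ x)
  ssr <- sum((fitted(fit) - mean(y))^2)
  sst <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (sst > 0) ssr / sst else 0,
                 fit = fit),
            class = "wf_linefit")
}

#' @export
print.wf_linefit <- function(x, ...) {
  cat(sprintf("<wf_linefit> y = %.4f x + %.4f (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wf_linefit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.wf_linefit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 slope = x$slope, intercept = x$intercept)
}

#' Simulated quality-versus-dose curve for a protocol ladder
#'
#' For each protocol of a ladder: simulate the subscans of a noisy phantom,
#' interpolate every subscan to the merged projection count, stitch,
#' assemble the sinogram, reconstruct by filtered backprojection, and
#' score the reconstruction against the reference image. The default
#' score is the summed absolute gray-value difference from the reference
#' image; `metric = "binarized"` instead Otsu-binarizes both images and
#' counts disagreeing pixels (the volume-comparison convention of
#' [protocol_error()]). Qualities are normalized over the ladder onto
#' `quality_range`.
#'
#' @param geometry A [scan_geometry()].
#' @param ladder A [make_protocol_ladder()] tibble.
#' @param phantom_width_px Phantom width; defaults to the covered width.
#' @param noise_sd Gaussian noise sd added to the reference image.
#' @param seed Integer seed (noise reproducibility).
#' @param quality_range Endpoints of the normalized quality scale.
#' @param filter_name Reconstruction filter.
#' @param metric `"l1"` (summed absolute gray-value difference, default)
#'   or `"binarized"` (Otsu-binarized disagreement count).
#' @return A tibble of class `wf_quality_curve`: one row per protocol with
#'   `label`, `total_projections`, `dose_fraction_pct`, `mean_E` and
#'   `quality_pct`.
#' @export
simulate_quality_curve <- function(geometry, ladder,
                                   phantom_width_px = covered_width(geometry),
                                   noise_sd = 0.02, seed = NULL,
                                   quality_range = c(16, 116),
                                   filter_name = "ram-lak",
                                   metric = c("l1", "binarized")) {
  stopifnot(inherits(geometry, "scan_geometry"))
  metric <- match.arg(metric)
  phantom <- shepp_logan(phantom_width_px,
                         pixel_size_um = geometry$pixel_size_um)
  reference <- add_gaussian_noise(phantom$image, noise_sd, seed = seed)
  rows <- purrr::pmap(
    list(ladder$label, ladder$per_subscan, ladder$total_projections,
         ladder$dose_fraction_pct, ladder$merged_projection_count),
    function(lab, counts, total, dose, pmax_) {
      subs <- simulate_subscans(reference, geometry, counts)
      subs <- purrr::map(subs, interpolate_missing, target_count = pmax_)
      wide <- stitch_projections(subs, geometry)
      rec <- reconstruct_slice(wide$projections, wide$angles_deg,
                               filter_name = filter_name,
                               pixel_size_um = geometry$pixel_size_um)
      E <- if (metric == "binarized")
        slice_difference(binarize_otsu(rec$image), binarize_otsu(reference))
      else sum(abs(rec$image - reference))
      tibble::tibble(label = lab, total_projections = total,
                     dose_fraction_pct = dose, mean_E = E)
    })
  out <- dplyr::bind_rows(rows)
  out$quality_pct <- normalize_quality(out$mean_E, quality_range)
  class(out) <- c("wf_quality_curve", class(out))
  out
}

#' Plot a quality-versus-dose curve
#'
#' Scatter of normalized quality against dose fraction with the OLS trend
#' line, one point per protocol.
#'
#' @param object A `wf_quality_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wf_quality_curve <- function(object, ...) {
  fit <- fit_line(object$dose_fraction_pct, object$quality_pct)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose_fraction_pct,
                               y = .data$quality_pct)) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       nudge_y = 2, size = 3) +
    ggplot2::labs(x = "Time / radiation dose (%)",
                  y = "Simulated quality (%)",
                  title = "Reconstruction quality vs dose") +
    ggplot2::theme_minimal()
}
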