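# neighbour offsets for 3-D connectivity (matrix [n x 3])
neighbour_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  g
}

as_volume <- function(volume) {
  if (is.matrix(volume)) volume <- array(volume, c(dim(volume), 1L))
  if (length(dim(volume)) != 3) stop("expected a 3-D volume (or a matrix)")
  volume
}

# breadth-first growth from seed coordinates over a candidate mask
flood_fill <- function(candidate, seed_idx, connectivity = 26) {
  dims <- dim(candidate)
  off <- neighbour_offsets(connectivity)
  visited <- array(FALSE, dims)
  visited[seed_idx] <- TRUE
  frontier <- matrix(arrayInd(seed_idx, dims), ncol = 3)
  while (nrow(frontier) > 0) {
    n <- nrow(frontier)
    nb <- frontier[rep(seq_len(n), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), times = n), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    if (!nrow(nb)) break
    lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] +
      (nb[, 3] - 1L) * dims[1] * dims[2]
    keep <- candidate[lin] & !visited[lin]
    lin <- unique(lin[keep])
    if (!length(lin)) break
    visited[lin] <- TRUE
    frontier <- matrix(arrayInd(lin, dims), ncol = 3)
  }
  visited
}

#' Threshold-interval region growing
#'
#' Grows a connected region from a seed voxel through all voxels whose
#' gray values lie within a closed interval; the result is the connected
#' component (26- or 6-connectivity) of the in-interval set containing
#' the seed. Deterministic, so a fixed seed coordinate can be reused
#' across volumes of the same sample scanned with different protocols.
#'
#' @param volume Numeric 3-D array (a matrix is treated as one slice).
#' @param seed Integer coordinates `c(x, y, z)` of the seed voxel
#'   (`x` = row, `y` = column, `z` = slice).
#' @param interval Numeric `c(low, high)` gray-value bounds.
#' @param connectivity 26 (default) or 6.
#' @return An object of class `segmented_region`: list with `mask`
#'   (logical array), `seed` and `interval`.
#' @export
region_grow <- function(volume, seed, interval, connectivity = 26) {
  volume <- as_volume(volume)
  dims <- dim(volume)
  seed <- as.integer(seed)
  if (length(seed) == 2) seed <- c(seed, 1L)
  if (any(seed < 1) || any(seed > dims))
    stop("seed lies outside the volume")
  sval <- volume[seed[1], seed[2], seed[3]]
  if (sval < interval[1] || sval > interval[2])
    stop("seed value ", sval, " lies outside the interval [",
         interval[1], ", ", interval[2], "]")
  candidate <- volume >= interval[1] & volume <= interval[2]
  seed_idx <- seed[1] + (seed[2] - 1L) * dims[1] +
    (seed[3] - 1L) * dims[1] * dims[2]
  mask <- flood_fill(candidate, seed_idx, connectivity)
  structure(list(mask = mask, seed = seed, interval = interval),
            class = "segmented_region")
}

#' Label connected components of a binary volume
#'
#' @param mask Logical/0-1 3-D array (a matrix is treated as one slice).
#' @param connectivity 26 (default) or 6.
#' @return Integer array of component labels (0 = background), labelled in
#'   first-voxel order.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_volume(mask) > 0
  labels <- array(0L, dim(mask))
  remaining <- mask
  lab <- 0L
  repeat {
    idx <- which(remaining)
    if (!length(idx)) break
    lab <- lab + 1L
    comp <- flood_fill(mask, idx[1], connectivity)
    labels[comp] <- lab
    remaining[comp] <- FALSE
  }
  labels
}

#' Remove small connected components
#'
#' Connected-component cleanup: components with fewer than `min_voxels`
#' voxels are deleted, larger ones left untouched.
#'
#' @inheritParams label_components
#' @param min_voxels Minimum component size to keep.
#' @return Logical array of the same shape.
#' @export
remove_small_components <- function(mask, min_voxels, connectivity = 26) {
  m <- as_volume(mask) > 0
  if (min_voxels <= 1) return(m)
  labels <- label_components(m, connectivity)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_voxels)
  out <- array(labels %in% keep, dim(m))
  out
}

# 1-D squared-distance transform (lower envelope of parabolas)
dt1d <- function(f) {
  n <- length(f)
  v <- integer(n); z <- numeric(n + 1)
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  k <- 1L
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  out <- numeric(n)
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    out[q] <- (q - v[k])^2 + f[v[k]]
  }
  out
}

#' Euclidean distance transform of a binary volume
#'
#' Each foreground voxel receives the exact Euclidean distance (in
#' micrometres) to the nearest background voxel; background voxels carry
#' 0. Computed by the separable lower-envelope algorithm, exact for
#' isotropic voxels.
#'
#' @param mask Logical/0-1 3-D array (a matrix is treated as one slice).
#' @param voxel_size_um Isotropic voxel edge length in micrometres.
#' @return Numeric array of distances, same shape as `mask`.
#' @export
euclidean_distance_transform <- function(mask, voxel_size_um = 1) {
  m <- as_volume(mask) > 0
  if (all(m)) stop("all-foreground mask: no background voxel to measure to")
  dims <- dim(m)
  # large finite sentinel: Inf would give NaN in the envelope intersections
  d2 <- array(ifelse(m, 1e20, 0), dims)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    d2[, y, z] <- dt1d(d2[, y, z])
  for (z in seq_len(dims[3])) for (x in seq_len(dims[1]))
    d2[x, , z] <- dt1d(d2[x, , z])
  if (dims[3] > 1)
    for (y in seq_len(dims[2])) for (x in seq_len(dims[1]))
      d2[x, y, ] <- dt1d(d2[x, y, ])
  sqrt(d2) * voxel_size_um
}

#' Histogram of a distance-transform volume
#'
#' Counts foreground voxels (distance > 0) per distance bin; the counts
#' sum to the number of foreground voxels.
#'
#' @param distance_volume Output of [euclidean_distance_transform()].
#' @param bin_width_um Bin width in micrometres (> 0).
#' @param roi_id Optional identifier carried into the result.
#' @return A tibble of class `wf_distance_histogram` with `bin_lo`,
#'   `bin_hi` (micrometres), `count` and `roi_id`.
#' @export
distance_histogram <- function(distance_volume, bin_width_um = 1,
                               roi_id = NA_character_) {
  if (bin_width_um <= 0) stop("`bin_width_um` must be positive")
  d <- as.numeric(distance_volume)
  d <- d[d > 0]
  n_bins <- max(1L, ceiling(if (length(d)) max(d) / bin_width_um else 1))
  edges <- seq(0, n_bins * bin_width_um, by = bin_width_um)
  counts <- if (length(d))
    tabulate(pmin(findInterval(d, edges, left.open = TRUE,
                               rightmost.closed = TRUE) , n_bins), n_bins)
  else rep(0L, n_bins)
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        count = counts, roi_id = roi_id)
  class(out) <- c("wf_distance_histogram", class(out))
  out
}

#' Extract a cubic region of interest
#'
#' Pure cropping: gray values are preserved bit-exactly.
#'
#' @param volume 3-D array.
#' @param corner Integer `c(x, y, z)` of the ROI's low corner.
#' @param size ROI edge length(s) in voxels (scalar or length 3).
#' @return The cropped array.
#' @export
extract_roi <- function(volume, corner, size) {
  volume <- as_volume(volume)
  if (length(size) == 1) size <- rep(size, 3)
  to <- corner + size - 1L
  if (any(corner < 1) || any(to > dim(volume)))
    stop("ROI exceeds the volume bounds")
  volume[corner[1]:to[1], corner[2]:to[2], corner[3]:to[3], drop = FALSE]
}

#' Plot distance-transform histograms
#'
#' Log-scale counts per distance bin, one line per ROI.
#'
#' @param object A `wf_distance_histogram` tibble (rows from several ROIs
#'   may be bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.wf_distance_histogram <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$count > 0),
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count,
                               colour = .data$roi_id)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Distance to nearest background (µm)",
                  y = "Voxel count", colour = "ROI",
                  title = "Euclidean distance-transform histogram") +
    ggplot2::theme_minimal()
}
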