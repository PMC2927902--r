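# mean of a list of frames (or a single matrix/vector)
frame_mean <- function(frames) {
  if (is.list(frames)) Reduce(`+`, frames) / length(frames) else frames
}

#' Flat/dark-field normalization of projections
#'
#' Corrects raw transmittance projections for detector baseline and beam
#' profile: `(I_Pr - I_D) / (I_F - I_D)`, where `I_D` and `I_F` are the
#' averaged dark and flat frames. A blank-beam projection maps to 1.
#' Results are clipped to `[0, clip_max]`.
#'
#' @param x A [subscan_set()] in transmittance mode (its own dark/flat
#'   frames are used) or a numeric matrix of projections `[P x W]`.
#' @param darks,flats Dark/flat frames (lists of matrices, a single
#'   matrix, or a numeric vector per detector column); required when `x`
#'   is a plain matrix.
#' @param clip_max Upper clip bound for the normalized transmittance.
#' @return Same shape as the input projections; for a `subscan_set`, a new
#'   set in `"transmittance"` mode with normalized values.
#' @export
normalize_projections <- function(x, darks = NULL, flats = NULL,
                                  clip_max = 2) {
  if (inherits(x, "subscan_set")) {
    darks <- darks %||% x$darks
    flats <- flats %||% x$flats
    proj <- x$projections
  } else proj <- x
  if (is.null(darks) || is.null(flats))
    stop("dark and flat frames are required for normalization")
  d <- frame_mean(darks); f <- frame_mean(flats)
  denom <- f - d
  bad <- which(apply(matrix(denom <= 1e-12, nrow = NROW(denom)), 2, any))
  if (length(bad))
    stop("dead detector columns (flat - dark <= 0): ",
         paste(bad, collapse = ", "))
  dv <- as.numeric(d); fv <- as.numeric(f)
  # frames are [n_rows x W]; broadcast along the angle dimension
  if (is.matrix(proj)) {
    out <- sweep(sweep(proj, 2, colMeans(matrix(dv, ncol = ncol(proj)))),
                 2, colMeans(matrix(fv, ncol = ncol(proj))) -
                   colMeans(matrix(dv, ncol = ncol(proj))), "/")
  } else {
    out <- proj
    dmat <- matrix(dv, dim(proj)[2], dim(proj)[3])
    fmat <- matrix(fv, dim(proj)[2], dim(proj)[3])
    for (a in seq_len(dim(proj)[1]))
      out[a, , ] <- (proj[a, , ] - dmat) / (fmat - dmat)
  }
  out <- pmin(pmax(out, 0), clip_max)
  if (inherits(x, "subscan_set"))
    subscan_set(out, x$angles_deg, offset_px = x$offset_px,
                mode = "transmittance")
  else out
}

#' Line integrals from normalized transmittance
#'
#' @param x Normalized transmittance values (matrix/array or
#'   `subscan_set`).
#' @param mu_scale Attenuation per unit line integral used in the
#'   simulation (see [simulate_subscans()]).
#' @param floor Smallest transmittance admitted before the log (guards
#'   zero-clipped pixels).
#' @return Absorption-domain line integrals, same shape.
#' @export
absorption_from_transmittance <- function(x, mu_scale = 1, floor = 1e-6) {
  if (inherits(x, "subscan_set")) {
    out <- x
    out$projections <- -log(pmax(x$projections, floor)) / mu_scale
    out$mode <- "absorption"
    return(out)
  }
  -log(pmax(x, floor)) / mu_scale
}

#' Merge a 360-degree off-center scan into 180-degree wide projections
#'
#' In off-center acquisition the rotation axis sits near one edge of the
#' detector and the sample is rotated over 360 degrees. The projection at
#' `theta + 180` degrees, flipped horizontally about the axis, covers the
#' detector band mirrored through the axis, so each pair is stitched into
#' one projection of up to twice the detector width.
#'
#' @param x A [subscan_set()] with an even number of equiangular
#'   projections over `[0, 360)`, or a projection matrix.
#' @param axis_offset_px Signed integer offset of the detector center from
#'   the rotation axis (the subscan's `offset_px` when `x` is a set);
#'   `|offset| < W/2` so the two halves overlap.
#' @return A [subscan_set()] of `P/2` projections over `[0, 180)`, width
#'   `W + 2 * |axis_offset_px|`, centered on the axis.
#' @export
flip_stitch_360 <- function(x, axis_offset_px = NULL) {
  if (inherits(x, "subscan_set")) {
    proj <- x$projections
    axis_offset_px <- axis_offset_px %||% x$offset_px
    if (max(x$angles_deg) <= 180)
      stop("subscan does not cover [0, 360)")
  } else proj <- x
  if (is.null(axis_offset_px)) stop("`axis_offset_px` is required")
  if (axis_offset_px != round(axis_offset_px))
    stop("`axis_offset_px` must be an integer number of pixels")
  P <- nrow(proj); W <- ncol(proj)
  if (P %% 2 != 0) stop("odd projection count: need pairs theta/theta+180")
  o <- abs(axis_offset_px)
  if (o >= W / 2)
    stop("no overlap between the flipped projection pair ",
         "(|axis offset| >= W/2): cannot register the halves")
  half <- P / 2L
  first <- proj[seq_len(half), , drop = FALSE]
  second <- proj[half + seq_len(half), rev(seq_len(W)), drop = FALSE]
  # the flipped theta+180 rows sample the band mirrored through the axis:
  # strips at offsets -o (left) and +o (right), overlapping by W - 2o
  if (axis_offset_px >= 0) { left <- second; right <- first }
  else                     { left <- first;  right <- second }
  ov <- W - 2L * o
  cut <- as.integer(ceiling(ov / 2))
  wide <- cbind(left[, seq_len(W - ov + cut), drop = FALSE],
                right[, (cut + 1L):W, drop = FALSE])
  subscan_set(wide, subscan_angles(half), offset_px = 0, mode = "absorption")
}

#' Angular interpolation of missing projections
#'
#' Subscans acquired with fewer projections than the merged set are
#' brought to the target count by pixel-wise linear interpolation between
#' angular neighbours (midpoint insertion per doubling). Original rows are
#' preserved exactly at their angles. Across the 180-degree wrap, a
#' centered subscan uses the mirrored first projection as the upper
#' neighbour (parallel-beam identity); a laterally offset subscan repeats
#' its last row, as the mirrored band lies outside its detector window.
#'
#' @param subscan A [subscan_set()] with `P` projections over `[0, 180)`.
#' @param target_count Target projection count; must be `P` times a power
#'   of two.
#' @return A [subscan_set()] with `target_count` projections.
#' @export
interpolate_missing <- function(subscan, target_count) {
  stopifnot(inherits(subscan, "subscan_set"))
  proj <- subscan$projections
  if (!is.matrix(proj)) stop("angular interpolation expects [P x W] sets")
  P <- nrow(proj)
  ratio <- target_count / P
  if (ratio < 1 || abs(log2(ratio) - round(log2(ratio))) > 1e-9)
    stop("`target_count` must be the current count times a power of two")
  while (nrow(proj) < target_count) {
    n <- nrow(proj)
    wrap <- if (abs(subscan$offset_px) < 1e-9)
      proj[1, rev(seq_len(ncol(proj)))] else proj[n, ]
    upper <- rbind(proj[-1, , drop = FALSE], wrap)
    mid <- (proj + upper) / 2
    out <- matrix(0, 2 * n, ncol(proj))
    out[seq(1, 2 * n, by = 2), ] <- proj
    out[seq(2, 2 * n, by = 2), ] <- mid
    proj <- out
  }
  subscan_set(proj, subscan_angles(target_count),
              offset_px = subscan$offset_px, mode = subscan$mode)
}

#' Locate the cutline between two overlapping projection strips
#'
#' Over lateral shifts within `search_radius_px` of the nominal
#' registration, the mean-squared difference (MSD) between the overlapping
#' bands is minimized; at the best shift the per-column MSD then selects
#' the cut column (ties broken toward the overlap center). The returned
#' shift is the lag to apply to the right strip's columns to restore
#' registration (0 when the nominal overlap is correct).
#'
#' @param left_strip,right_strip Matrices with equal row count (angles x
#'   detector columns); the last `nominal_overlap_px` columns of the left
#'   strip nominally coincide with the first `nominal_overlap_px` columns
#'   of the right strip.
#' @param nominal_overlap_px Nominal overlap width in pixels (>= 8 of true
#'   overlap should fall inside the search window).
#' @param search_radius_px Maximum absolute lateral shift explored.
#' @return A list with `shift_px`, `cut_col` (1-based column within the
#'   overlap window), and `msd` (MSD at the chosen shift).
#' @export
find_cutline <- function(left_strip, right_strip, nominal_overlap_px,
                         search_radius_px = 5) {
  ov <- as.integer(nominal_overlap_px)
  if (ov < 1) stop("`nominal_overlap_px` must be >= 1")
  if (nrow(left_strip) != nrow(right_strip))
    stop("strips must have the same number of rows")
  wl <- ncol(left_strip)
  lcols <- left_strip[, wl - ov + seq_len(ov), drop = FALSE]
  shifts <- -search_radius_px:search_radius_px
  msd <- vapply(shifts, function(L) {
    k <- seq_len(ov)
    valid <- k + L >= 1 & k + L <= ov
    if (sum(valid) < 1) return(Inf)
    mean((lcols[, k[valid], drop = FALSE] -
            right_strip[, k[valid] + L, drop = FALSE])^2)
  }, numeric(1))
  if (max(msd[is.finite(msd)]) - min(msd[is.finite(msd)]) < 1e-12) {
    warning("flat overlap region: cutline defaults to the nominal ",
            "overlap center")
    return(list(shift_px = 0L, cut_col = as.integer(ceiling(ov / 2)),
                msd = msd[shifts == 0]))
  }
  best <- shifts[which.min(msd)]
  k <- seq_len(ov)
  valid <- k + best >= 1 & k + best <= ov
  colmsd <- colMeans((lcols[, k[valid], drop = FALSE] -
                        right_strip[, k[valid] + best, drop = FALSE])^2)
  kv <- k[valid]
  ties <- kv[colmsd <= min(colmsd) + 1e-15]
  cut <- ties[which.min(abs(ties - (ov + 1) / 2))]
  list(shift_px = as.integer(best), cut_col = as.integer(cut),
       msd = min(msd))
}

#' Stitch subscan projections into wide-field projections
#'
#' Concatenates angle-aligned subscan projections at per-seam cutlines
#' (hard cut, no feathering): the cut column and everything left of it
#' come from the left subscan, everything right of it from the right
#' subscan. The merged width is `sum(widths) - sum(overlaps)` regardless
#' of where each cut falls.
#'
#' @param subscans List of [subscan_set()]s in spatial order (left to
#'   right), all with identical angle grids (interpolate first; see
#'   [interpolate_missing()]).
#' @param geometry The [scan_geometry()] (supplies nominal overlaps).
#' @param cutlines Optional integer vector of cut columns (1-based within
#'   each overlap window); when `NULL` they are located with
#'   [find_cutline()].
#' @param search_radius_px Search radius for cutline detection.
#' @return An object of class `wide_projections`: list with `projections`
#'   `[P x merged_width]`, `angles_deg`, `cutlines_px` (global merged
#'   column of each cut), `provenance` (source subscan per column) and
#'   `geometry`.
#' @export
stitch_projections <- function(subscans, geometry, cutlines = NULL,
                               search_radius_px = 5) {
  stopifnot(inherits(geometry, "scan_geometry"))
  n <- length(subscans)
  if (n != geometry$n_subscans)
    stop("expected ", geometry$n_subscans, " subscans, got ", n)
  if (n == 1L) {
    s <- subscans[[1]]
    return(structure(list(projections = s$projections,
                          angles_deg = s$angles_deg,
                          cutlines_px = integer(0),
                          provenance = rep(1L, ncol(s$projections)),
                          geometry = geometry),
                     class = "wide_projections"))
  }
  angs <- subscans[[1]]$angles_deg
  for (s in subscans) {
    if (length(s$angles_deg) != length(angs) ||
        max(abs(s$angles_deg - angs)) > 1e-8)
      stop("subscans must share one angle grid; interpolate first")
    if (!is.matrix(s$projections)) stop("expected [P x W] projection sets")
    if (ncol(s$projections) != geometry$detector_width_px)
      stop("inconsistent projection widths")
  }
  ovs <- as.integer(geometry$overlaps_px)
  if (is.null(cutlines)) {
    cutlines <- integer(n - 1L)
    for (i in seq_len(n - 1L)) {
      cl <- find_cutline(subscans[[i]]$projections,
                         subscans[[i + 1]]$projections, ovs[i],
                         search_radius_px)
      if (cl$shift_px != 0L)
        warning("seam ", i, ": residual lateral misregistration of ",
                cl$shift_px, " px detected; stitching at nominal overlap")
      cutlines[i] <- cl$cut_col
    }
  }
  if (any(cutlines < 1L | cutlines > ovs))
    stop("cutlines must lie within their overlap windows")
  W <- geometry$detector_width_px
  pieces <- vector("list", n)
  prov <- integer(0)
  for (i in seq_len(n)) {
    from <- if (i == 1L) 1L else cutlines[i - 1L] + 1L
    to <- if (i == n) W else W - ovs[i] + cutlines[i]
    pieces[[i]] <- subscans[[i]]$projections[, from:to, drop = FALSE]
    prov <- c(prov, rep(i, to - from + 1L))
  }
  merged <- do.call(cbind, pieces)
  stopifnot(ncol(merged) == covered_width(geometry))
  widths <- vapply(pieces, ncol, integer(1))
  structure(list(projections = merged, angles_deg = angs,
                 cutlines_px = cumsum(widths)[seq_len(n - 1L)],
                 provenance = prov, geometry = geometry),
            class = "wide_projections")
}

#' @export
print.wide_projections <- function(x, ...) {
  cat("<wide_projections> ", nrow(x$projections), " projections x ",
      ncol(x$projections), " px, cutlines at ",
      paste(x$cutlines_px, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Rearrange projections into sinograms
#'
#' The n-th sinogram collects the n-th detector row of every projection in
#' angle order; it is a pure re-indexing and [projections_from_sinograms()]
#' inverts it exactly.
#'
#' @param wide A `wide_projections` object whose `projections` field is a
#'   `[P x n_rows x W]` array, or a `[P x W]` matrix (treated as one
#'   detector row).
#' @return An object of class `sinogram_stack`: list with `sinograms`
#'   (`[n_rows x P x W]` array) and `angles_deg`.
#' @export
build_sinograms <- function(wide) {
  proj <- if (inherits(wide, "wide_projections") ||
              inherits(wide, "subscan_set")) wide$projections else wide
  angles <- if (is.list(wide)) wide$angles_deg else NULL
  if (is.matrix(proj)) proj <- array(proj, c(nrow(proj), 1L, ncol(proj)))
  if (length(dim(proj)) != 3)
    stop("expected a [P x W] matrix or [P x n_rows x W] array")
  structure(list(sinograms = aperm(proj, c(2, 1, 3)), angles_deg = angles),
            class = "sinogram_stack")
}

#' @rdname build_sinograms
#' @param stack A `sinogram_stack`.
#' @export
projections_from_sinograms <- function(stack) {
  stopifnot(inherits(stack, "sinogram_stack"))
  aperm(stack$sinograms, c(2, 1, 3))
}
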