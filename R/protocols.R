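# nearest-integer with halves away from zero; R's round() is half-to-even,
# which does not reproduce counts like 874 * 1.25 -> 1093
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Projections required by the CT sampling theorem
#'
#' For parallel-beam tomography over 180 degrees, a reconstruction of width
#' `D` pixels requires about `P = D * pi / 2` equiangular projections. The
#' value is returned unrounded; round only final reported totals.
#'
#' @param width_px Reconstruction width in pixels (>= 0).
#' @return `width_px * pi / 2` as a double.
#' @export
#' @examples
#' round(required_projections(3072))      # 4825
#' round(9 * required_projections(1024))  # 14476
required_projections <- function(width_px) {
  if (any(width_px < 0)) stop("`width_px` must be non-negative")
  width_px * pi / 2
}

#' Total projections of the gold-standard wide-field protocol
#'
#' The gold standard satisfies the sampling theorem everywhere in the
#' covered field of view: each of the `n` subscans acquires as many
#' projections as the full merged width requires, so the total is
#' `round(n * (n * D - sum(overlaps)) * pi / 2)`, rounded once at the end.
#'
#' @param geometry A [scan_geometry()].
#' @return Integer total projection count.
#' @export
#' @examples
#' reference_total(scan_geometry(1024, 3, 100))  # 13534
#' reference_total(scan_geometry(1024, 1))       # 1608
reference_total <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  as.integer(round_half_up(
    geometry$n_subscans * required_projections(covered_width(geometry))
  ))
}

#' Generate a dose/quality protocol ladder
#'
#' Scanning protocols assign each subscan a projection count that is a
#' multiple (integers or half-integers) of a base unit. To keep angular
#' interpolation trivial, the central subscan's count must equal the
#' lateral count or half of it, and lateral counts must be equal; merged
#' projection sets then have `max(P_i)` projections.
#'
#' @param geometry A [scan_geometry()].
#' @param base_unit Base projection count (e.g. 874).
#' @param steps A list of numeric vectors, one per protocol, each of length
#'   `n_subscans`, giving the per-subscan multiples of `base_unit`.
#' @param labels Optional protocol labels; defaults to `LETTERS` starting
#'   at "B" (protocol "A" conventionally denotes the unscanned reference).
#' @param reference Reference total used for dose fractions; defaults to
#'   [reference_total()] of `geometry`.
#' @return A tibble with one row per protocol: `label`, `per_subscan`
#'   (list-column of integer counts), `total_projections`,
#'   `merged_projection_count` and `dose_fraction_pct`.
#' @export
#' @examples
#' g <- scan_geometry(1024, 3, 100)
#' make_protocol_ladder(g, 874, list(c(6, 6, 6), c(3, 3, 3), c(1, 0.5, 1)),
#'                      labels = c("B", "L", "T"))
make_protocol_ladder <- function(geometry, base_unit, steps, labels = NULL,
                                 reference = reference_total(geometry)) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (base_unit < 1) stop("`base_unit` must be >= 1")
  if (!is.list(steps)) steps <- list(steps)
  n <- geometry$n_subscans
  if (is.null(labels)) labels <- head(LETTERS[-1], length(steps))
  if (length(labels) != length(steps))
    stop("`labels` must match `steps` in length")
  rows <- purrr::map2(steps, labels, function(step, lab) {
    if (length(step) != n)
      stop("each step must give one multiple per subscan (", n, ")")
    mid <- (n + 1L) / 2L
    lateral <- step[-mid]
    if (length(lateral) && (any(lateral != lateral[1]) ||
        !(step[mid] == lateral[1] || step[mid] == lateral[1] / 2)))
      stop("protocol ", lab, ": central count must equal the lateral ",
           "count or half of it, and lateral counts must be equal")
    counts <- as.integer(round_half_up(step * base_unit))
    tibble::tibble(
      label = lab,
      per_subscan = list(counts),
      total_projections = sum(counts),
      merged_projection_count = max(counts),
      dose_fraction_pct = as.numeric(
        round_half_up(100 * sum(counts) / reference))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wf_protocol_ladder", class(out))
  attr(out, "reference_total") <- as.integer(reference)
  out
}

#' Dose reduction of a protocol relative to the gold standard
#'
#' Dose is modeled as proportional to the total number of acquired
#' projections, so the reduction is `100 * (1 - total / reference)`,
#' rounded to the nearest integer for reporting. Negative values indicate
#' a protocol exceeding the reference dose.
#'
#' @param total_projections Total projection count of the protocol (or a
#'   ladder row's `total_projections`).
#' @param reference_total Total projection count of the gold standard.
#' @return Dose reduction in percent (integer-valued double).
#' @export
#' @examples
#' dose_reduction_pct(2185, 13534)   # 84
#' dose_reduction_pct(15732, 13534)  # -16
dose_reduction_pct <- function(total_projections, reference_total) {
  if (reference_total <= 0) stop("`reference_total` must be positive")
  round_half_up(100 * (1 - total_projections / reference_total))
}

#' Reference beamline protocol ladder
#'
#' The 19-protocol ladder (labels B--T, base unit 874 projections) used to
#' scan one rat-lung sample with a three-subscan, 1024-px-detector
#' wide-field layout, as printed at acquisition time, together with the
#' measured per-protocol quality. A handful of printed per-subscan counts
#' differ by one from exact nearest-integer multiples of 874; this table
#' records the printed values verbatim, while [make_protocol_ladder()]
#' recomputes counts by consistent rounding.
#'
#' @return A tibble with columns `label`, `s1`, `s2`, `s3` (per-subscan
#'   projection counts), `total_projections`, `dose_fraction_pct` and
#'   `measured_quality_pct` (NA for the unscanned reference protocol A).
#' @export
reference_ladder <- function() {
  path <- system.file("extdata", "tomcat_protocol_ladder.csv",
                      package = "widefieldct", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @exportS3Method generics::tidy
tidy.wf_protocol_ladder <- function(x, ...) {
  dplyr::mutate(
    tibble::as_tibble(x),
    per_subscan = purrr::map_chr(.data$per_subscan, paste, collapse = "/")
  )
}

#' Serialize / read a protocol ladder preference file
#'
#' The preference file is a YAML document with one section per protocol
#' (label, per-subscan projection counts, total, dose fraction) plus the
#' geometry (detector width, overlaps, offsets), mirroring the scan
#' configuration consumed by an acquisition system.
#'
#' @param ladder A ladder from [make_protocol_ladder()].
#' @param geometry The [scan_geometry()] the ladder was built for.
#' @param path Output file path.
#' @return `path`, invisibly (`write_protocol_config`); a list with
#'   `geometry` and `ladder` (`read_protocol_config`).
#' @export
write_protocol_config <- function(ladder, geometry, path) {
  stopifnot(inherits(geometry, "scan_geometry"))
  doc <- list(
    geometry = list(
      detector_width_px = geometry$detector_width_px,
      n_subscans = geometry$n_subscans,
      overlaps_px = as.numeric(geometry$overlaps_px),
      offsets_px = as.numeric(geometry$offsets_px),
      pixel_size_um = geometry$pixel_size_um,
      desired_fov_px = geometry$desired_fov_px
    ),
    reference_total = attr(ladder, "reference_total"),
    protocols = purrr::pmap(
      list(ladder$label, ladder$per_subscan, ladder$total_projections,
           ladder$dose_fraction_pct),
      function(lab, counts, total, dose)
        list(label = lab, per_subscan = as.integer(counts),
             total_projections = as.integer(total),
             dose_fraction_pct = dose)
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  doc <- yaml::read_yaml(path)
  g <- doc$geometry
  geometry <- scan_geometry(g$detector_width_px, g$n_subscans,
                            unlist(g$overlaps_px),
                            pixel_size_um = g$pixel_size_um,
                            desired_fov_px = g$desired_fov_px)
  ladder <- dplyr::bind_rows(purrr::map(doc$protocols, function(p) {
    counts <- as.integer(unlist(p$per_subscan))
    tibble::tibble(label = p$label, per_subscan = list(counts),
                   total_projections = p$total_projections,
                   merged_projection_count = max(counts),
                   dose_fraction_pct = p$dose_fraction_pct)
  }))
  class(ladder) <- c("wf_protocol_ladder", class(ladder))
  attr(ladder, "reference_total") <- doc$reference_total
  list(geometry = geometry, ladder = ladder)
}
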