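# scale a float matrix to [0,1] for 16-bit TIFF storage; returns the
# window so reading can undo it exactly (up to 16-bit quantization)
tiff_window <- function(x) {
  rng <- range(unlist(lapply(x, range)))
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  rng
}

#' Write / read a stack of float images as 16-bit grayscale TIFF
#'
#' Images are min-max windowed to 16-bit; the window is stored in a YAML
#' sidecar (`<path>.yml`) so [read_tiff_stack()] restores the original
#' scale (up to 16-bit quantization).
#'
#' @param images A list of numeric matrices, a single matrix, or a
#'   `[n x rows x cols]` array.
#' @param path Output TIFF file (multi-page).
#' @return `path`, invisibly (`write_tiff_stack`); a list of matrices
#'   (`read_tiff_stack`).
#' @export
write_tiff_stack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3)
    images <- purrr::map(seq_len(dim(images)[1]), function(i) images[i, , ])
  win <- tiff_window(images)
  scaled <- purrr::map(images, function(m) (m - win[1]) / diff(win))
  tiff::writeTIFF(scaled, path, bits.per.sample = 16, compression = "none")
  yaml::write_yaml(list(window = as.numeric(win), n = length(images)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  win <- unlist(meta$window)
  purrr::map(imgs, function(m) m * diff(win) + win[1])
}

#' Write / read one subscan acquisition directory
#'
#' The on-disk layout mirrors a beamline acquisition: a multi-page 16-bit
#' TIFF of projections plus optional dark and flat stacks, and a
#' `scanlog.yml` naming the angles, lateral offset, domain and intensity
#' windows. [read_subscan_dir()] restores the [subscan_set()].
#'
#' @param subscan A [subscan_set()].
#' @param dir Directory to create/fill.
#' @return `dir`, invisibly (`write_subscan_dir`); a [subscan_set()]
#'   (`read_subscan_dir`).
#' @export
write_subscan_dir <- function(subscan, dir) {
  stopifnot(inherits(subscan, "subscan_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proj <- subscan$projections
  if (!is.matrix(proj)) stop("only [P x W] subscans are written to disk")
  rows <- purrr::map(seq_len(nrow(proj)), function(i)
    matrix(proj[i, ], nrow = 1))
  write_tiff_stack(rows, file.path(dir, "projections.tif"))
  if (!is.null(subscan$darks))
    write_tiff_stack(subscan$darks, file.path(dir, "darks.tif"))
  if (!is.null(subscan$flats))
    write_tiff_stack(subscan$flats, file.path(dir, "flats.tif"))
  yaml::write_yaml(list(angles_deg = as.numeric(subscan$angles_deg),
                        offset_px = subscan$offset_px,
                        mode = subscan$mode),
                   file.path(dir, "scanlog.yml"))
  invisible(dir)
}

#' @rdname write_subscan_dir
#' @export
read_subscan_dir <- function(dir) {
  log <- yaml::read_yaml(file.path(dir, "scanlog.yml"))
  rows <- read_tiff_stack(file.path(dir, "projections.tif"))
  proj <- do.call(rbind, rows)
  darks <- if (file.exists(file.path(dir, "darks.tif")))
    read_tiff_stack(file.path(dir, "darks.tif")) else NULL
  flats <- if (file.exists(file.path(dir, "flats.tif")))
    read_tiff_stack(file.path(dir, "flats.tif")) else NULL
  subscan_set(proj, unlist(log$angles_deg), offset_px = log$offset_px,
              darks = darks, flats = flats, mode = log$mode)
}
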