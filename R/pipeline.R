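#' Build a validated pipeline run configuration
#'
#' A run configuration fully determines a pipeline run: geometry, protocol
#' ladder, phantom/noise/seed settings and stage selection. It is
#' serializable to YAML, so a run is reproducible from its configuration
#' alone.
#'
#' @param out_dir Run directory (created if missing).
#' @param detector_width_px,overlap_px,desired_fov_px,pixel_size_um Scan
#'   geometry parameters (see [plan_widefield()]).
#' @param base_unit,steps,labels Protocol ladder parameters (see
#'   [make_protocol_ladder()]).
#' @param protocol Label of the protocol to acquire.
#' @param phantom_width_px Phantom width; defaults to the covered width.
#' @param noise_sd Gaussian noise sd added to the reference image.
#' @param seed Integer seed.
#' @param slice_stride Stride of the quality evaluation.
#' @param stages Stages to run, a subset of
#'   `c("plan", "simulate", "merge", "reconstruct", "evaluate", "morph")`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, detector_width_px = 160, overlap_px = 48,
                       desired_fov_px = 384, pixel_size_um = 1.48,
                       base_unit = 100,
                       steps = list(c(6, 6, 6), c(1, 0.5, 1)),
                       labels = NULL, protocol = NULL,
                       phantom_width_px = NULL, noise_sd = 0.02, seed = 1,
                       slice_stride = 5,
                       stages = c("plan", "simulate", "merge",
                                  "reconstruct", "evaluate", "morph")) {
  known <- c("plan", "simulate", "merge", "reconstruct", "evaluate",
             "morph")
  if (!all(stages %in% known))
    stop("unknown stage(s): ",
         paste(setdiff(stages, known), collapse = ", "))
  if (overlap_px >= detector_width_px)
    stop("`overlap_px` must be smaller than the detector width")
  geometry <- plan_widefield(desired_fov_px, detector_width_px, overlap_px,
                             pixel_size_um = pixel_size_um)
  ladder <- make_protocol_ladder(geometry, base_unit, steps,
                                 labels = labels)
  protocol <- protocol %||% ladder$label[1]
  if (!protocol %in% ladder$label)
    stop("protocol ", protocol, " is not in the ladder")
  structure(list(out_dir = out_dir, geometry = geometry, ladder = ladder,
                 protocol = protocol,
                 phantom_width_px = phantom_width_px %||%
                   covered_width(geometry),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 slice_stride = slice_stride, stages = stages),
            class = "run_config")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

stage_log <- function(dir, params, outputs) {
  yaml::write_yaml(list(params = params,
                        outputs = as.list(tools::md5sum(outputs))),
                   file.path(dir, "stage.yml"))
}

stage_done <- function(config, stage)
  file.exists(file.path(config$out_dir, stage, "stage.yml"))

#' Run the wide-field pipeline
#'
#' Executes the enabled stages in order (plan, simulate, merge,
#' reconstruct, evaluate, morph), each writing its outputs and a
#' `stage.yml` log (parameters plus MD5 digests of the outputs) into its
#' own subdirectory of the run directory. With `resume = TRUE`, stages
#' whose log already exists are skipped, so a partial run can be
#' continued; a stage never modifies another stage's outputs.
#'
#' @param config A [run_config()].
#' @param resume Skip stages whose outputs already exist.
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- config$geometry
  row <- dplyr::filter(config$ladder, .data$label == config$protocol)
  counts <- row$per_subscan[[1]]
  phantom <- shepp_logan(config$phantom_width_px,
                         pixel_size_um = g$pixel_size_um)
  reference <- add_gaussian_noise(phantom$image, config$noise_sd,
                                  seed = config$seed)

  run_stage <- function(stage, body) {
    if (!stage %in% config$stages) return(invisible(NULL))
    if (resume && stage_done(config, stage)) {
      message("stage ", stage, ": outputs present, skipped")
      return(invisible(NULL))
    }
    message("stage ", stage)
    ok <- try(body(stage_dir(config, stage)), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("stage ", stage, " failed: ", attr(ok, "condition")$message)
    invisible(NULL)
  }

  run_stage("plan", function(d) {
    write_protocol_config(config$ladder, g, file.path(d, "protocols.yml"))
    stage_log(d, list(reference_total = reference_total(g)),
              file.path(d, "protocols.yml"))
  })

  run_stage("simulate", function(d) {
    subs <- simulate_subscans(reference, g, counts)
    dirs <- character(0)
    for (i in seq_along(subs)) {
      sd_i <- file.path(d, sprintf("subscan_%02d", i))
      write_subscan_dir(subs[[i]], sd_i)
      dirs <- c(dirs, list.files(sd_i, full.names = TRUE))
    }
    stage_log(d, list(protocol = config$protocol, counts = counts,
                      seed = config$seed, noise_sd = config$noise_sd),
              dirs)
  })

  run_stage("merge", function(d) {
    sim <- file.path(config$out_dir, "simulate")
    subs <- purrr::map(sort(list.dirs(sim, recursive = FALSE)),
                       read_subscan_dir)
    pmax_ <- max(purrr::map_int(subs, ~ length(.x$angles_deg)))
    subs <- purrr::map(subs, interpolate_missing, target_count = pmax_)
    wide <- stitch_projections(subs, g)
    write_tiff_stack(wide$projections, file.path(d, "merged.tif"))
    yaml::write_yaml(list(angles_deg = as.numeric(wide$angles_deg),
                          cutlines_px = as.integer(wide$cutlines_px)),
                     file.path(d, "merged_log.yml"))
    stage_log(d, list(merged_width = ncol(wide$projections)),
              file.path(d, c("merged.tif", "merged_log.yml")))
  })

  run_stage("reconstruct", function(d) {
    md <- file.path(config$out_dir, "merge")
    proj <- do.call(rbind, read_tiff_stack(file.path(md, "merged.tif")))
    log <- yaml::read_yaml(file.path(md, "merged_log.yml"))
    rec <- reconstruct_slice(proj, unlist(log$angles_deg),
                             pixel_size_um = g$pixel_size_um)
    write_tiff_stack(rec$image, file.path(d, "slices.tif"))
    stage_log(d, list(filter = rec$filter),
              file.path(d, "slices.tif"))
  })

  run_stage("evaluate", function(d) {
    rec <- read_tiff_stack(file.path(config$out_dir, "reconstruct",
                                     "slices.tif"))
    rep_ <- protocol_error(rec, list(reference),
                           slice_stride = config$slice_stride,
                           label = config$protocol)
    utils::write.csv(dplyr::select(rep_, -"per_slice_E"),
                     file.path(d, "quality.csv"), row.names = FALSE)
    stage_log(d, list(slice_stride = config$slice_stride),
              file.path(d, "quality.csv"))
  })

  run_stage("morph", function(d) {
    rec <- read_tiff_stack(file.path(config$out_dir, "reconstruct",
                                     "slices.tif"))[[1]]
    mask <- remove_small_components(binarize_otsu(rec), 9)
    dist <- euclidean_distance_transform(mask, g$pixel_size_um)
    hist <- distance_histogram(dist, bin_width_um = g$pixel_size_um,
                               roi_id = "slice")
    utils::write.csv(hist, file.path(d, "distance_histogram.csv"),
                     row.names = FALSE)
    stage_log(d, list(min_voxels = 9), file.path(d,
                                                 "distance_histogram.csv"))
  })

  invisible(config$out_dir)
}
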