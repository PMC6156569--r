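.config_schema <- list(
  geometry = c("n_euler_poses", "n_tomo_angles", "detector_nu",
               "detector_nv", "detector_pitch_mm", "seed"),
  phantom = c("name", "size", "voxel_mm", "max_degree"),
  forward = c("kernel", "noise_sigma", "seed"),
  reconstruction = c("max_degree", "n_iterations", "tikhonov_weight"),
  extraction = c("grid_subdivisions", "relative_threshold",
                 "min_separation_deg", "magnitude_quantile",
                 "anisotropy_threshold"),
  tracking = c("step_voxels", "max_angle_deg", "min_magnitude",
               "max_steps", "n_seeds", "seed")
)

.default_config <- function() {
  list(
    geometry = list(n_euler_poses = 80L, n_tomo_angles = 1L,
                    detector_nu = 49L, detector_nv = 49L,
                    detector_pitch_mm = 0.25, seed = 1L),
    phantom = list(name = "straight", size = 16L, voxel_mm = 0.5,
                   max_degree = 2L),
    forward = list(kernel = "cos2", noise_sigma = 0, seed = 1L),
    reconstruction = list(max_degree = 2L, n_iterations = 50L,
                          tikhonov_weight = 0),
    extraction = list(grid_subdivisions = 4L, relative_threshold = 0.5,
                      min_separation_deg = 15, magnitude_quantile = 0.7,
                      anisotropy_threshold = 0.05),
    tracking = list(step_voxels = 0.5, max_angle_deg = 60,
                    min_magnitude = 0, max_steps = 1000L, n_seeds = 25L,
                    seed = 1L)
  )
}

#' Read and validate a pipeline configuration (YAML)
#'
#' Unknown sections or keys are rejected; missing keys fall back to the
#' documented defaults. Units: mm for lengths, degrees for angles.
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @param overrides Named list of `section$key` overrides applied last.
#' @return The fully resolved configuration list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (x in list(user, overrides)) {
    bad_sec <- setdiff(names(x), names(.config_schema))
    if (length(bad_sec)) {
      .axdt_stop("axdt_invalid_config", "unknown config section(s): %s",
                 paste(bad_sec, collapse = ", "))
    }
    for (sec in names(x)) {
      bad <- setdiff(names(x[[sec]]), .config_schema[[sec]])
      if (length(bad)) {
        .axdt_stop("axdt_invalid_config", "unknown key(s) in '%s': %s",
                   sec, paste(bad, collapse = ", "))
      }
      cfg[[sec]] <- modifyList(cfg[[sec]], x[[sec]])
    }
  }
  cfg
}

#' Write a resolved configuration next to pipeline outputs
#' @param config Configuration list from [read_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Run the full synthetic pipeline: simulate, reconstruct, extract, track
#'
#' Chains the four stages on a synthetic phantom and writes all artifacts
#' (sinogram, coefficient volume, orientation maps, streamlines, resolved
#' config and a run log) under `out_dir`. This is the programmatic
#' counterpart of the command-line `pipeline` subcommand.
#'
#' @param config Configuration list from [read_config()].
#' @param out_dir Output directory (created if missing).
#' @param verbose Print stage progress?
#' @return List with the in-memory stage results and the artifact paths.
#' @export
run_pipeline <- function(config = read_config(), out_dir = tempfile("axdt_"),
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    if (verbose) message(msg)
  }
  t0 <- Sys.time()

  say("simulate: phantom '%s' (%d^3), %d x %d poses",
      config$phantom$name, config$phantom$size,
      config$geometry$n_euler_poses, config$geometry$n_tomo_angles)
  fx <- make_fixture(config$phantom$name, config$phantom$size,
                     seed = config$forward$seed,
                     noise_sigma = config$forward$noise_sigma,
                     max_degree = config$phantom$max_degree,
                     n_euler_poses = config$geometry$n_euler_poses,
                     n_tomo_angles = config$geometry$n_tomo_angles,
                     detector = detector_spec(config$geometry$detector_nu,
                                              config$geometry$detector_nv,
                                              config$geometry$detector_pitch_mm))
  protocol <- fx$protocol
  sino_path <- file.path(out_dir, "sinogram.nii.gz")
  write_sinogram(fx$sinogram, protocol, sino_path)
  write_volume(fx$volume, file.path(out_dir, "phantom.nii.gz"),
               extra = list(kernel = config$forward$kernel))

  say("reconstruct: L=%d, %d CGLS iterations, lambda=%g",
      config$reconstruction$max_degree, config$reconstruction$n_iterations,
      config$reconstruction$tikhonov_weight)
  basis <- sh_basis(config$reconstruction$max_degree)
  rec <- reconstruct(fx$sinogram, protocol, rep(config$phantom$size, 3),
                     basis,
                     n_iterations = config$reconstruction$n_iterations,
                     tikhonov_weight = config$reconstruction$tikhonov_weight,
                     spacing = fx$volume$spacing,
                     kernel = config$forward$kernel)
  say("reconstruct: final relative residual %.3e",
      rec$residual_history[length(rec$residual_history)])
  neg <- negativity_report(rec$volume)
  say("negativity report: %d voxels (%.1f%%) dip below zero",
      neg$n_negative_voxels, 100 * neg$fraction)
  write_volume(rec$volume, file.path(out_dir, "reconstruction.nii.gz"),
               extra = list(kernel = config$forward$kernel,
                            solver = rec$config))
  utils::write.csv(
    data.frame(iteration = seq_along(rec$residual_history),
               relative_residual = rec$residual_history),
    file.path(out_dir, "residual_history.csv"), row.names = FALSE)

  say("extract: Funk-Radon + peaks on subdiv-%d grid",
      config$extraction$grid_subdivisions)
  frt <- funk_radon_volume(rec$volume)
  grid <- icosphere(config$extraction$grid_subdivisions, TRUE)
  field <- principal_orientation_field(
    frt, grid,
    relative_threshold = config$extraction$relative_threshold,
    min_separation_deg = config$extraction$min_separation_deg,
    magnitude_quantile = config$extraction$magnitude_quantile,
    anisotropy_threshold = config$extraction$anisotropy_threshold)
  paths <- write_orientation_field(field, file.path(out_dir, "orientation"),
                                   peaks_csv = TRUE)

  say("track: seeding %d streamlines", config$tracking$n_seeds)
  seeded <- which(!is.na(field$principal[, 1]))
  set.seed(config$tracking$seed)
  seeds_idx <- seeded[sample.int(length(seeded),
                                 min(config$tracking$n_seeds,
                                     length(seeded)))]
  ctr <- .grid_centers(field$dims, field$spacing, field$origin)$all
  streamlines <- if (length(seeds_idx)) {
    track_streamlines(field, ctr[seeds_idx, , drop = FALSE],
                      step_mm = config$tracking$step_voxels * field$spacing,
                      max_angle_deg = config$tracking$max_angle_deg,
                      min_magnitude = config$tracking$min_magnitude,
                      max_steps = config$tracking$max_steps)
  } else {
    list()
  }
  tck_path <- file.path(out_dir, "tracts.tck")
  write_tck(streamlines, tck_path)

  write_config(config, file.path(out_dir, "config.yaml"))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(fixture = fx, reconstruction = rec, field = field,
                 streamlines = streamlines, out_dir = out_dir,
                 negativity = neg))
}
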