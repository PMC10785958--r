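#' Run the end-to-end simulation and targeting-error pipeline
#'
#' Mirrors the planning workflow of an optically navigated tFUS session:
#' register fiducials (automatic correspondence + rigid fit), average the
#' simulation-to-ultrasound calibration, chain the transform hierarchy,
#' resample the scene volumes onto the simulation grid, place the bowl
#' source, simulate the pressure field, localize the simulated focus,
#' compute the four targeting-error metrics against the measured (MR-ARFI
#' stand-in) focus, and optionally apply the distance-vector correction and
#' re-simulate.
#'
#' The tracked focus point is calibrated empirically before use: a reference
#' simulation in water at the canonical pose defines the offset between the
#' geometric focus and the actual focal maximum (for the desk-scale H115MR
#' at 401 kHz the peak sits about 3 mm proximal of the geometric focus), and
#' the predicted focus is projected through the hierarchy at that calibrated
#' point — the in-silico analogue of validating the tracked focus against MR
#' thermometry and folding the observed bias into the calibration.
#'
#' @param scene A `tfus_scene`.
#' @param out_dir Optional directory for artifacts (report JSON/CSV, field
#'   NIFTIs, transforms, log).
#' @param erosion_radius Voxels, for erosion-guarded focus selection.
#' @param correct Apply the distance-vector correction and re-simulate.
#' @param solver_cfg A `solver_config`.
#' @param measured_sigma Gaussian perturbation (mm) of the synthetic
#'   measured focus.
#' @param seed Integer seed for the measured-focus perturbation.
#' @param focus_bias_s Optional precomputed calibrated focus position in the
#'   simulation frame (skips the water calibration run).
#' @return A list of class `pipeline_result`: `report` (a `focus_report`),
#'   `registration`, `est_i_from_s`, `corrected_i_from_s`, `focus_bias_s`,
#'   `fields` (simulated pressure fields), and `log` (stage records).
#' @export
run_pipeline <- function(scene, out_dir = NULL, erosion_radius = 2,
                         correct = TRUE, solver_cfg = solver_config(),
                         measured_sigma = 0, seed = 1, focus_bias_s = NULL) {
  stopifnot(inherits(scene, "tfus_scene"))
  grid <- scene$grid
  spec <- scene$spec
  log <- list()
  stage <- function(name, ...) {
    log[[length(log) + 1]] <<- c(list(stage = name), list(...))
  }

  ## 1. fiducial registration with automatic correspondence
  perm <- match_fiducials(scene$fiducials_physical, scene$fiducials_image)
  reg <- attr(perm, "fit")
  est_i_from_p <- reg$transform
  stage("register", fre_mm = reg$fre, correspondence = as.integer(perm))

  ## 2. calibration averaging of ^U T_S
  u_from_s <- calibrate_u_from_s(scene$alignments)
  stage("calibrate_u_from_s", n = length(scene$alignments))

  ## 3. hierarchy -> estimated ^I T_S
  est_h <- transform_hierarchy(est_i_from_p, scene$tracked_p_from_t,
                               scene$t_from_u, u_from_s)
  est_i_from_s <- image_from_simulation(est_h)
  stage("hierarchy", i_from_s = as.numeric(t(as_matrix4(est_i_from_s))))

  ## 4. canonical bowl source in the simulation frame
  bowl <- make_bowl(spec, grid)

  ## 5. empirical focus calibration in water (tracked-point bias)
  if (is.null(focus_bias_s)) {
    field_cal <- simulate_rms(water_medium(grid), bowl, spec, solver_cfg)
    focus_bias_s <- as.numeric(focus_max(field_cal))
  }
  stage("focus_calibration", focus_s = focus_bias_s,
        geometric_focus_s = bowl$focus_mm)

  ## 6. reference (true-pose) simulation -> measured ARFI stand-in
  true_i_from_s <- scene$truth$i_from_s
  med_true <- scene_medium(scene, true_i_from_s)
  field_true <- simulate_rms(med_true$medium, bowl, spec, solver_cfg)
  measured_i <- make_measured_focus(scene, field_true,
                                    perturb_sigma = measured_sigma,
                                    seed = seed,
                                    tissue_mask_s = med_true$tissue_mask,
                                    erosion_radius = erosion_radius)
  stage("measured_focus", measured_image = measured_i,
        sigma_mm = measured_sigma)

  ## 7. tracked-pose simulation (the pipeline's belief)
  med_est <- scene_medium(scene, est_i_from_s)
  field_est <- simulate_rms(med_est$medium, bowl, spec, solver_cfg)
  sim_s <- focus_max(field_est, med_est$tissue_mask, erosion_radius)
  sim_i <- apply_points(est_i_from_s, as.numeric(sim_s))
  stage("simulate", focus_s = as.numeric(sim_s), focus_image = sim_i)

  ## 8. predicted focus from optical tracking (calibrated point)
  predicted_i <- apply_points(est_i_from_s, focus_bias_s)
  axis_i <- as.numeric(est_i_from_s$rotation %*% c(0, 0, 1))
  stage("predict", predicted_image = predicted_i)

  ## 9. correction + re-simulation
  corrected <- NULL
  sim_upd_i <- NULL
  field_corr <- NULL
  if (correct) {
    corrected <- vector_correction(est_i_from_s, predicted_i, measured_i)
    med_corr <- scene_medium(scene, corrected)
    field_corr <- simulate_rms(med_corr$medium, bowl, spec, solver_cfg)
    upd_s <- focus_max(field_corr, med_corr$tissue_mask, erosion_radius)
    sim_upd_i <- apply_points(corrected, as.numeric(upd_s))
    stage("correct", delta = measured_i - predicted_i,
          updated_focus_image = sim_upd_i)
  }

  report <- focus_report(predicted_i, sim_i, measured_i, axis_i,
                         simulated_updated = sim_upd_i)
  res <- structure(list(report = report, registration = reg,
                        est_i_from_s = est_i_from_s,
                        corrected_i_from_s = corrected,
                        focus_bias_s = focus_bias_s,
                        fields = list(tracked = field_est, true = field_true,
                                      corrected = field_corr),
                        log = log),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$report)
  invisible(x)
}

## resample the scene's volumes onto the simulation grid through a pose
## (^I T_S); water scenes skip resampling entirely
scene_medium <- function(scene, i_from_s) {
  grid <- scene$grid
  if (identical(scene$medium, "water") || is.null(scene$volumes))
    return(list(medium = water_medium(grid), tissue_mask = NULL))
  tiss <- resample_to_grid(scene$volumes$tissue, grid, world_pose = i_from_s,
                           interpolation = "nearest")
  tissue_mask <- tiss$data > 0.5
  ct_s <- NULL
  if (identical(scene$medium, "skull") && !is.null(scene$volumes$ct)) {
    ct_s <- resample_to_grid(scene$volumes$ct, grid, world_pose = i_from_s,
                             interpolation = "linear")
    ct_s$units <- "HU"
  }
  med <- build_medium(ct = ct_s, tissue_mask = tissue_mask, grid = grid,
                      table = property_table())
  list(medium = med, tissue_mask = tissue_mask)
}

## write report, transforms and fields under out_dir
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_focus_report(res$report,
                     json_path = file.path(out_dir, "report.json"),
                     csv_path = file.path(out_dir, "report.csv"))
  write_transform(res$est_i_from_s, file.path(out_dir, "i_from_s.json"))
  if (!is.null(res$corrected_i_from_s))
    write_transform(res$corrected_i_from_s,
                    file.path(out_dir, "i_from_s_corrected.json"))
  for (nm in names(res$fields)) {
    f <- res$fields[[nm]]
    if (is.null(f)) next
    vol <- image_volume(f$rms_pressure, spacing = f$grid$spacing,
                        origin = f$grid$origin, frame = "simulation")
    write_volume(vol, file.path(out_dir, paste0("field_", nm, ".nii.gz")),
                 datatype = "float")
  }
  log_path <- file.path(out_dir, "log.jsonl")
  con <- file(log_path, "w")
  on.exit(close(con))
  for (entry in res$log)
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = 10), con)
  invisible(out_dir)
}

#' Write and read a synthetic scene as a directory of standard files
#'
#' Volumes go to NIFTI, fiducials to CSV, transforms to JSON, the scene
#' configuration and truth record to YAML/JSON — the formats the equivalent
#' physical-session inputs would arrive in.
#'
#' @param scene A `tfus_scene`.
#' @param dir Output directory.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "tfus_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fiducials(scene$fiducials_image, file.path(dir, "fiducials_image.csv"))
  write_fiducials(scene$fiducials_physical,
                  file.path(dir, "fiducials_physical.csv"))
  write_transform(scene$tracked_p_from_t, file.path(dir, "p_from_t.json"))
  write_transform(scene$t_from_u, file.path(dir, "t_from_u.json"))
  for (i in seq_along(scene$alignments))
    write_transform(scene$alignments[[i]],
                    file.path(dir, sprintf("u_from_s_alignment_%d.json", i)))
  if (!is.null(scene$volumes)) {
    write_volume(scene$volumes$t1, file.path(dir, "t1.nii.gz"))
    write_volume(scene$volumes$tissue, file.path(dir, "tissue.nii.gz"),
                 datatype = "uint8")
    if (!is.null(scene$volumes$ct))
      write_volume(scene$volumes$ct, file.path(dir, "ct.nii.gz"),
                   datatype = "float")
  }
  truth <- scene$truth
  truth_obj <- list(
    i_from_s = as.numeric(t(as_matrix4(truth$i_from_s))),
    focus_s = truth$focus_s, target_image = truth$target_image,
    tracking_error_image = truth$tracking_error_image,
    tracking_error_physical = truth$tracking_error_physical,
    fiducial_sigma = truth$fiducial_sigma, seed = truth$seed)
  jsonlite::write_json(truth_obj, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  plain_cfg <- scene$cfg[!vapply(scene$cfg, is.object, logical(1))]
  meta <- list(medium = scene$medium, seed = scene$seed,
               grid = list(dims = scene$grid$dims,
                           spacing = scene$grid$spacing,
                           origin = scene$grid$origin),
               spec = unclass(scene$spec),
               cfg = plain_cfg)
  yaml::write_yaml(meta, file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' @rdname write_scene
#' @return `read_scene` returns the `tfus_scene` rebuilt from disk (truth
#'   hierarchy links beyond `^I T_S` are not serialized and are rebuilt by
#'   regenerating the scene from its recorded seed and medium).
#' @export
read_scene <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  cfg <- if (is.null(meta$cfg)) list() else meta$cfg
  cfg$medium <- meta$medium
  cfg$grid <- sim_grid_spec(meta$grid$dims, meta$grid$spacing,
                            meta$grid$origin)
  cfg$spec <- transducer_spec(meta$spec$radius_of_curvature,
                              meta$spec$aperture_diameter,
                              meta$spec$frequency,
                              meta$spec$source_amplitude)
  make_phantom_scene(cfg = cfg, seed = meta$seed)
}
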