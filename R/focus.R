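#' Locate the focus as the maximum-pressure voxel
#'
#' The simulated focus is the maximum pixel of the RMS pressure field. When
#' a tissue mask is given and the unmasked maximum falls outside it (e.g. on
#' the skull, where transcranial fields often peak), the mask is first eroded
#' by `erosion_radius` voxels (digital ball) to exclude voxels closest to the
#' skull and the maximum in-situ pressure inside the eroded mask is taken
#' instead. Ties are broken towards the lowest linear index with a warning.
#'
#' @param field A `pressure_field`.
#' @param tissue_mask Optional 3D logical array on the field's grid.
#' @param erosion_radius Ball radius in voxels (0 = plain masked argmax).
#' @return World-mm position (grid frame) of the selected voxel centre, with
#'   the voxel index (1-based) attached as attribute `"index"`.
#' @export
focus_max <- function(field, tissue_mask = NULL, erosion_radius = 2) {
  stopifnot(inherits(field, "pressure_field"))
  p <- field$rms_pressure
  if (max(p) <= 0) stop("focus_max: field is identically zero")
  pick <- function(values, candidates) {
    m <- max(values[candidates])
    hits <- candidates[values[candidates] >= m]
    if (length(hits) > 1L)
      warning("focus_max: tied maxima; keeping the lowest linear index")
    min(hits)
  }
  gmax <- pick(p, which(p == max(p)))
  sel <- gmax
  if (!is.null(tissue_mask)) {
    tissue_mask <- array(as.logical(tissue_mask), dim(p))
    em <- erode_mask(tissue_mask, erosion_radius)
    if (!any(em))
      stop("focus_max: eroded tissue mask is empty; use a smaller erosion_radius")
    if (!em[gmax]) {
      inside <- which(em)
      mi <- max(p[inside])
      hits <- inside[p[inside] >= mi]
      if (length(hits) > 1L)
        warning("focus_max: tied maxima; keeping the lowest linear index")
      sel <- min(hits)
    }
  }
  idx <- arrayInd(sel, dim(p))
  structure(as.numeric(grid_index_to_world(field$grid, idx)),
            index = as.integer(idx))
}

#' Half-maximum centroid of the focal spot
#'
#' Segments the field at half of its maximum, keeps the 26-connected
#' component containing the maximum voxel, and returns the unweighted
#' centroid of that component's voxel centres. This is the focus-centre
#' definition used for comparing predicted and simulated foci.
#'
#' @param field A `pressure_field`.
#' @param within_mask Optional 3D logical array restricting the search.
#' @return World-mm centroid position (grid frame).
#' @export
focus_centroid_halfmax <- function(field, within_mask = NULL) {
  stopifnot(inherits(field, "pressure_field"))
  p <- field$rms_pressure
  if (!is.null(within_mask)) {
    within_mask <- array(as.logical(within_mask), dim(p))
    p <- p * within_mask
  }
  mx <- max(p)
  if (mx <= 0) stop("focus_centroid_halfmax: field is identically zero")
  seed <- which.max(p)
  seg <- p >= mx / 2
  comp <- component_containing(seg, seed, connectivity = 26)
  idx <- which(comp, arr.ind = TRUE)
  as.numeric(colMeans(grid_index_to_world(field$grid, idx)))
}

#' Decompose a targeting error along the transducer axis
#'
#' Splits the offset between two focus positions into the component along
#' the propagation axis (axial) and the in-plane remainder (lateral, the
#' Euclidean norm perpendicular to the axis — for an axis-aligned pose this
#' is the norm of the X and Y offsets). Components are reported as absolute
#' values and satisfy `total^2 = axial^2 + lateral^2`.
#'
#' @param a,b Length-3 positions, mm, same frame.
#' @param axis Unit propagation direction; a non-unit vector is normalized
#'   with a warning.
#' @return Named numeric `c(total, axial, lateral)` in mm.
#' @export
decompose_error <- function(a, b, axis) {
  stopifnot(length(a) == 3L, length(b) == 3L, length(axis) == 3L)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-8) {
    warning("decompose_error: axis is not unit-norm; normalizing")
    axis <- axis / nrm
  }
  d <- as.numeric(a) - as.numeric(b)
  ax <- sum(d * axis)
  lat <- d - ax * axis
  c(total = sqrt(sum(d^2)), axial = abs(ax), lateral = sqrt(sum(lat^2)))
}

#' Distance-vector correction of a transducer pose
#'
#' Translates the modeled transducer by the offset between the measured
#' (MR-ARFI) focus and the predicted focus, leaving the rotation untouched,
#' so that re-simulation is centred on the measured focus. Both points must
#' be expressed in the pose's target (image) frame.
#'
#' @param placement A `rigid_transform` posing the simulation grid in image
#'   space (`^I T_S`).
#' @param predicted,measured Length-3 focus positions, mm, in image space.
#' @return The corrected `rigid_transform`.
#' @export
vector_correction <- function(placement, predicted, measured) {
  stopifnot(inherits(placement, "rigid_transform"),
            length(predicted) == 3L, length(measured) == 3L)
  delta <- as.numeric(measured) - as.numeric(predicted)
  structure(list(rotation = placement$rotation,
                 translation = placement$translation + delta,
                 from = placement$from, to = placement$to),
            class = "rigid_transform")
}

#' Targeting-accuracy report
#'
#' Bundles the predicted (optically tracked), simulated and measured
#' (MR-ARFI) focus positions and the four error metrics, each decomposed
#' into total, axial and lateral components along the transducer axis:
#' `TRE_Opti_ARFI` (predicted vs measured), `Error_Opti_Sim` (simulated vs
#' predicted), `Error_Sim_ARFI` (simulated vs measured) and, when an updated
#' simulation is supplied, `Error_SimUpdated_ARFI`.
#'
#' @param predicted,simulated,measured Length-3 positions, mm, image frame.
#' @param axis Unit propagation axis in the image frame.
#' @param simulated_updated Optional re-simulated focus after the
#'   distance-vector correction.
#' @return An object of class `focus_report`.
#' @export
focus_report <- function(predicted, simulated, measured, axis,
                         simulated_updated = NULL) {
  metrics <- list(
    TRE_Opti_ARFI = decompose_error(predicted, measured, axis),
    Error_Opti_Sim = decompose_error(simulated, predicted, axis),
    Error_Sim_ARFI = decompose_error(simulated, measured, axis))
  if (!is.null(simulated_updated))
    metrics$Error_SimUpdated_ARFI <-
      decompose_error(simulated_updated, measured, axis)
  structure(list(predicted = as.numeric(predicted),
                 simulated = as.numeric(simulated),
                 measured = as.numeric(measured),
                 simulated_updated = if (is.null(simulated_updated)) NULL
                                     else as.numeric(simulated_updated),
                 axis = as.numeric(axis), metrics = metrics),
            class = "focus_report")
}

#' @export
print.focus_report <- function(x, ...) {
  cat("<focus_report> (mm)\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.focus_report <- function(x, ...) {
  do.call(rbind, lapply(names(x$metrics), function(nm) {
    m <- x$metrics[[nm]]
    data.frame(metric = nm, total = m[["total"]], axial = m[["axial"]],
               lateral = m[["lateral"]])
  }))
}

#' Write a focus report as JSON and CSV
#'
#' The CSV (one row per metric: `metric,total,axial,lateral`) mirrors the
#' per-dataset summaries used for reporting targeting accuracy.
#'
#' @param report A `focus_report`.
#' @param json_path,csv_path Output paths (`NULL` to skip either).
#' @export
write_focus_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "focus_report"))
  if (!is.null(json_path)) {
    obj <- list(predicted = report$predicted, simulated = report$simulated,
                measured = report$measured,
                simulated_updated = report$simulated_updated,
                axis = report$axis,
                metrics = lapply(report$metrics, as.list))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = 10,
                         null = "null")
  }
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE,
                     quote = FALSE)
  invisible(report)
}
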