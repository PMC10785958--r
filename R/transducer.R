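#' Spherically curved (bowl) transducer specification
#'
#' Geometry and drive of a single-element focused bowl. Defaults are the
#' H115MR: radius of curvature 63.2 mm, active aperture diameter 64 mm. The
#' default frequency is the desk-scale 401 kHz drive; the hardware third
#' harmonic is 802 kHz.
#'
#' @param radius_of_curvature mm; distance from the bowl surface to the
#'   geometric focus.
#' @param aperture_diameter mm; must satisfy
#'   `0 < aperture_diameter <= 2 * radius_of_curvature`.
#' @param frequency Hz.
#' @param source_amplitude Source pressure amplitude, Pa (the simulated field
#'   is linear in this value).
#' @return An object of class `transducer_spec`.
#' @export
transducer_spec <- function(radius_of_curvature = 63.2, aperture_diameter = 64,
                            frequency = 401e3, source_amplitude = 1) {
  stopifnot(radius_of_curvature > 0, frequency > 0, source_amplitude >= 0)
  if (aperture_diameter <= 0 || aperture_diameter > 2 * radius_of_curvature)
    stop("transducer_spec: aperture_diameter must lie in (0, 2 * radius_of_curvature]")
  structure(list(radius_of_curvature = radius_of_curvature,
                 aperture_diameter = aperture_diameter,
                 frequency = frequency,
                 source_amplitude = source_amplitude),
            class = "transducer_spec")
}

## aperture half-angle (radians) subtended at the geometric focus
cap_half_angle <- function(spec) asin(spec$aperture_diameter / 2 / spec$radius_of_curvature)

## analytic spherical-cap area 2*pi*R*h_cap (mm^2)
cap_area <- function(spec) {
  roc <- spec$radius_of_curvature
  2 * pi * roc * roc * (1 - cos(cap_half_angle(spec)))
}

#' Rasterize a bowl transducer into a simulation grid
#'
#' Marks the voxels of a thin spherical-cap shell of radius
#' `radius_of_curvature` about the geometric focus, restricted to the aperture
#' half-angle, opening along `-axis` so that propagation is along `+axis`.
#' The rasterization uses a supercover criterion (a voxel is part of the cap
#' when the sphere passes within half of the voxel's extent measured along
#' the local surface normal), which keeps the shell one to two voxels thick
#' without through-holes; every selected voxel centre lies within half a voxel
#' diagonal of the sphere. A 3 x 3 x 3 focus-marker cube at the geometric
#' focus is kept separate from the acoustic source and is intended for
#' visual alignment only.
#'
#' @param spec A `transducer_spec`.
#' @param grid A `sim_grid_spec`.
#' @param focus_mm World position (grid frame) of the geometric focus; by
#'   default laterally centred, with the bowl apex `apex_margin` mm above the
#'   grid floor, snapped to a voxel centre.
#' @param axis Unit propagation direction (default `+z`).
#' @param apex_margin mm clearance between the bowl apex and the grid
#'   boundary used when `focus_mm` is `NULL`.
#' @return An object of class `transducer_model`: `bowl_mask` and
#'   `focus_marker` logical arrays, `grid`, `spec`, `focus_mm`, `axis`.
#' @export
make_bowl <- function(spec, grid, focus_mm = NULL, axis = c(0, 0, 1),
                      apex_margin = 6) {
  stopifnot(inherits(spec, "transducer_spec"), inherits(grid, "sim_grid_spec"))
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  h <- grid$spacing
  roc <- spec$radius_of_curvature
  if (is.null(focus_mm)) focus_mm <- default_focus(spec, grid, apex_margin)
  focus_mm <- as.numeric(focus_mm)
  rasterize_cap(spec, grid, focus_mm, axis)
}

## canonical focus placement: laterally centred on a voxel centre, apex
## apex_margin mm above the grid floor (snapped to the voxel lattice)
default_focus <- function(spec, grid, apex_margin = 6) {
  h <- grid$spacing
  ctr <- grid$origin + floor(grid$dims / 2) * h
  fz <- grid$origin[3] + round((apex_margin + spec$radius_of_curvature) / h) * h
  c(ctr[1], ctr[2], fz)
}

## shared cap rasterizer (used by make_bowl and place_transducer)
rasterize_cap <- function(spec, grid, focus_mm, axis) {
  h <- grid$spacing
  roc <- spec$radius_of_curvature
  ct_max <- cos(cap_half_angle(spec))
  ax <- grid_axes(grid)
  dims <- grid$dims
  ## bounding box of the cap (sphere cap on the -axis side of the focus)
  lo <- focus_mm - roc - h
  hi <- focus_mm + roc + h
  ir <- lapply(1:3, function(i) which(ax[[i]] >= lo[i] & ax[[i]] <= hi[i]))
  if (any(lengths(ir) == 0))
    stop("make_bowl: bowl lies entirely outside the grid")
  glo <- grid$origin
  ghi <- grid$origin + (dims - 1) * h
  nx <- length(ir[[1]]); ny <- length(ir[[2]]); nz <- length(ir[[3]])
  xs <- ax[[1]][ir[[1]]]; ys <- ax[[2]][ir[[2]]]; zs <- ax[[3]][ir[[3]]]
  dx <- array(rep(xs - focus_mm[1], times = ny * nz), c(nx, ny, nz))
  dy <- array(rep(rep(ys - focus_mm[2], each = nx), times = nz), c(nx, ny, nz))
  dz <- array(rep(zs - focus_mm[3], each = nx * ny), c(nx, ny, nz))
  r <- sqrt(dx^2 + dy^2 + dz^2)
  r[r == 0] <- .Machine$double.eps
  along <- (dx * axis[1] + dy * axis[2] + dz * axis[3]) / r
  in_cap <- along <= -ct_max + 1e-12
  l1 <- (abs(dx) + abs(dy) + abs(dz)) / r
  sel <- in_cap & abs(r - roc) <= 0.5 * h * l1
  ## did the cap need voxels outside the grid? test the analytic surface
  th <- cap_half_angle(spec)
  probe_t <- seq(0, th, length.out = 64)
  u <- perpendicular_basis(axis)
  for (phi in seq(0, 2 * pi, length.out = 33)[-33]) {
    dirv <- -cos(probe_t) %o% axis +
      sin(probe_t) %o% (cos(phi) * u$e1 + sin(phi) * u$e2)
    pts <- rep(focus_mm, each = length(probe_t)) + roc * dirv
    if (any(pts < rep(glo - h / 2, each = nrow(pts))) ||
        any(pts > rep(ghi + h / 2, each = nrow(pts)))) {
      lim <- apply(pts, 2, range)
      stop(sprintf(paste0("make_bowl: bowl clipped by grid (cap spans x[%.1f,%.1f] ",
                          "y[%.1f,%.1f] z[%.1f,%.1f] mm)"),
                   lim[1, 1], lim[2, 1], lim[1, 2], lim[2, 2], lim[1, 3], lim[2, 3]))
    }
  }
  bowl <- array(FALSE, dims)
  bowl[ir[[1]], ir[[2]], ir[[3]]] <- sel
  ## focus marker: 3x3x3 voxel cube centred on the voxel nearest the focus
  marker <- array(FALSE, dims)
  fi <- round(grid_world_to_index(grid, focus_mm))
  mi <- lapply(1:3, function(i) max(1, fi[i] - 1):min(dims[i], fi[i] + 1))
  marker[mi[[1]], mi[[2]], mi[[3]]] <- TRUE
  structure(list(bowl_mask = bowl, focus_marker = marker, grid = grid,
                 spec = spec, focus_mm = focus_mm, axis = axis),
            class = "transducer_model")
}

#' @export
print.transducer_model <- function(x, ...) {
  cat(sprintf("<transducer_model: %d bowl voxels, focus at (%.2f, %.2f, %.2f) mm, axis (%.2f, %.2f, %.2f)>\n",
              sum(x$bowl_mask), x$focus_mm[1], x$focus_mm[2], x$focus_mm[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

## orthonormal basis perpendicular to a unit vector
perpendicular_basis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Estimate the bowl surface area from its rasterization
#'
#' Sums, over bowl voxels, the voxel cross-section corrected by the local
#' surface orientation (`spacing^2 / |n|_L1` with `n` the unit surface
#' normal). A raw voxel count times `spacing^2` systematically overestimates
#' the area of a digitized surface by the mean L1 norm of the normal; the
#' corrected estimator converges to the analytic cap area
#' `2 * pi * ROC * h_cap` as spacing shrinks.
#'
#' @param model A `transducer_model`.
#' @return Estimated area in mm^2.
#' @export
bowl_area_estimate <- function(model) {
  grid <- model$grid
  idx <- which(model$bowl_mask, arr.ind = TRUE)
  w <- grid_index_to_world(grid, idx)
  d <- sweep(w, 2, model$focus_mm)
  r <- sqrt(rowSums(d^2))
  l1 <- rowSums(abs(d)) / r
  sum(grid$spacing^2 / l1)
}

#' Average repeated simulation-to-ultrasound alignments
#'
#' The one-time `^U T_S` calibration aligns the transducer model to several
#' (typically three) independent manual alignments; the final transform is
#' the average: arithmetic mean of the translations and the chordal
#' (quaternion) mean of the rotations, computed as the principal eigenvector
#' of the sign-aligned quaternion outer-product accumulation. Rotations more
#' than 30 degrees apart indicate an outlier alignment and are refused.
#'
#' @param alignments List of `rigid_transform`s, all with the same
#'   `from`/`to` frames.
#' @param max_spread_deg Refusal threshold on the pairwise rotation angle.
#' @return A `rigid_transform` with averaged rotation and translation.
#' @export
calibrate_u_from_s <- function(alignments, max_spread_deg = 30) {
  stopifnot(is.list(alignments), length(alignments) >= 2L)
  for (a in alignments) stopifnot(inherits(a, "rigid_transform"))
  frm <- alignments[[1]]$from; to <- alignments[[1]]$to
  for (a in alignments)
    if (!identical(a$from, frm) || !identical(a$to, to))
      stop("calibrate_u_from_s: alignments mix frames")
  n <- length(alignments)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ang <- rotation_angle_deg(alignments[[i]]$rotation, alignments[[j]]$rotation)
    if (ang > max_spread_deg)
      stop(sprintf("calibrate_u_from_s: alignments %d and %d differ by %.1f deg (> %g); refusing to average an outlier",
                   i, j, ang, max_spread_deg))
  }
  tr <- rowMeans(vapply(alignments, function(a) a$translation, numeric(3)))
  q0 <- rot_to_quat(alignments[[1]]$rotation)
  m <- matrix(0, 4, 4)
  for (a in alignments) {
    q <- rot_to_quat(a$rotation)
    if (sum(q * q0) < 0) q <- -q
    m <- m + tcrossprod(q)
  }
  q_mean <- eigen(m, symmetric = TRUE)$vectors[, 1]
  if (sum(q_mean * q0) < 0) q_mean <- -q_mean
  rigid_transform(quat_to_rot(q_mean), tr, from = frm, to = to)
}

#' Place a transducer model under a rigid pose
#'
#' Re-rasterizes the analytic cap at the transformed focus and axis rather
#' than rotating the voxel mask, which would open aliasing holes in the
#' source surface. The pose maps the model's grid frame onto the target grid
#' frame.
#'
#' @param model A `transducer_model`.
#' @param pose A `rigid_transform` applied to the model (focus and axis).
#' @param grid Target `sim_grid_spec` (defaults to the model's own grid).
#' @return A new `transducer_model` in `grid`.
#' @export
place_transducer <- function(model, pose, grid = NULL) {
  stopifnot(inherits(model, "transducer_model"), inherits(pose, "rigid_transform"))
  if (is.null(grid)) grid <- model$grid
  new_focus <- apply_points(pose, model$focus_mm)
  new_axis <- as.numeric(pose$rotation %*% model$axis)
  rasterize_cap(model$spec, grid, new_focus, new_axis)
}
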