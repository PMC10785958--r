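#' Synthetic tracked-tFUS scene with known ground truth
#'
#' Generates a complete, self-consistent phantom scene emulating the inputs
#' of an optically navigated tFUS session: a T1-like anatomical volume
#' containing a cylindrical agar phantom, six fiducials on the mold surface
#' localized in image space (exact) and physical space (with optional
#' isotropic localization noise), a tracked transducer pose carrying an
#' injected targeting error, the true transform hierarchy, and three noisy
#' copies of the simulation-to-ultrasound alignment for calibration
#' averaging. All randomness comes from `seed`; regenerating with the same
#' seed reproduces the scene bit-exactly.
#'
#' The target sits at the image-frame origin with the transducer firing
#' along `+z`. The default injected tracking error is a 3.5 mm translation
#' (the middle of the 1.9-5.5 mm range reported for optically tracked tFUS
#' navigation), applied to the tracked link `^P T_T` where real tracking
#' error enters; `tracking_error_mm` expresses it in image-frame
#' coordinates.
#'
#' @param cfg Named list of overrides; see Details.
#' @param seed Integer RNG seed.
#' @details Configurable fields (defaults in parentheses): `grid`
#'   (desk-scale 144 x 144 x 192 at 0.5 mm), `spec` (H115MR geometry at
#'   401 kHz), `medium` (`"phantom"`; also `"water"`, `"skull"`),
#'   `fiducial_sigma` (0 mm), `tracking_error_mm` (3.5 mm along
#'   `(2, -1, 3)`), `n_alignments` (3), `alignment_sigma_mm` (0.3),
#'   `alignment_sigma_deg` (0.5), `volumes` (`TRUE`; `FALSE` skips volume
#'   rasterization for fast registration-only studies), `image_dims`
#'   (`c(80, 80, 100)`), `image_spacing` (1 mm), `phantom_radius` (24 mm),
#'   `phantom_z` (`c(-30, 20)` mm), `skull` (list passed to
#'   [make_skullcap_ct()]).
#' @return An object of class `tfus_scene`.
#' @export
make_phantom_scene <- function(cfg = list(), seed = 1) {
  defaults <- list(
    grid = desk_grid(),
    spec = transducer_spec(),
    medium = "phantom",
    fiducial_sigma = 0,
    tracking_error_mm = 3.5 * c(2, -1, 3) / sqrt(14),
    n_alignments = 3L,
    alignment_sigma_mm = 0.3,
    alignment_sigma_deg = 0.5,
    volumes = TRUE,
    image_dims = c(80L, 80L, 100L),
    image_spacing = 1,
    image_origin = c(-40, -40, -70),
    phantom_radius = 24,
    phantom_z = c(-30, 20),
    t1_noise_sd = 10,
    skull = list())
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot(cfg$medium %in% c("water", "phantom", "skull"))
  set.seed(as.integer(seed))
  grid <- cfg$grid
  spec <- cfg$spec

  ## canonical bowl placement in the simulation frame (geometric focus);
  ## the mask itself is rasterized on demand by the pipeline
  focus_s <- default_focus(spec, grid)

  ## fixed true hierarchy links (arbitrary but general rigid placements)
  i_from_p <- rigid_transform(rot_z(25), c(12, -7, 33),
                              from = "physical", to = "image")
  p_from_t <- rigid_transform(rot_y(15) %*% rot_x(-10), c(85, -40, 120),
                              from = "tracker", to = "physical")
  t_from_u <- rigid_transform(diag(3), c(2, 0, 4),
                              from = "ultrasound", to = "tracker")
  ## the simulation grid is posed so the geometric focus hits the target
  ## (image origin) with the propagation axis along image +z
  i_from_s_true <- rigid_transform(diag(3), -focus_s,
                                   from = "simulation", to = "image")
  u_from_s <- compose(invert(t_from_u),
                      compose(invert(p_from_t),
                              compose(invert(i_from_p), i_from_s_true)))
  truth_h <- transform_hierarchy(i_from_p, p_from_t, t_from_u, u_from_s)

  ## injected tracking error: translation of the tracked link, expressed so
  ## its image-frame effect is exactly cfg$tracking_error_mm
  e_img <- as.numeric(cfg$tracking_error_mm)
  d_phys <- as.numeric(t(i_from_p$rotation) %*% e_img)
  delta <- rigid_transform(diag(3), d_phys, from = "physical", to = "physical")
  p_from_t_tracked <- compose(delta, p_from_t)

  ## six fiducials on the mold surface (general position, no symmetry)
  ang <- c(10, 55, 130, 200, 275, 330) * pi / 180
  fz <- c(-15, 5, 18, -8, 12, -20)
  mold_r <- cfg$phantom_radius + 6
  fid_img <- cbind(mold_r * cos(ang), mold_r * sin(ang), fz)
  fid_phys_true <- apply_points(invert(i_from_p), fid_img)
  fid_phys <- fid_phys_true +
    matrix(stats::rnorm(18, 0, cfg$fiducial_sigma), ncol = 3)

  ## noisy repeated alignments of ^U T_S for calibration averaging
  ## misalignment rotations pivot about the geometric focus (the cube the
  ## manual alignment is anchored to), not the grid corner
  alignments <- lapply(seq_len(cfg$n_alignments), function(i) {
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang_deg <- stats::rnorm(1, 0, cfg$alignment_sigma_deg)
    dt <- stats::rnorm(3, 0, cfg$alignment_sigma_mm)
    r <- axis_angle_rotation(axis, ang_deg)
    tr <- dt + focus_s - as.numeric(r %*% focus_s)
    pert <- rigid_transform(r, tr, from = "simulation", to = "simulation")
    compose(u_from_s, pert)
  })

  volumes <- NULL
  if (isTRUE(cfg$volumes)) {
    d <- as.integer(cfg$image_dims)
    sp <- cfg$image_spacing
    org <- cfg$image_origin
    ax <- lapply(1:3, function(i) org[i] + (seq_len(d[i]) - 1) * sp)
    xg <- array(rep(ax[[1]], times = d[2] * d[3]), d)
    yg <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
    zg <- array(rep(ax[[3]], each = d[1] * d[2]), d)
    cyl <- (xg^2 + yg^2 <= cfg$phantom_radius^2) &
      zg >= cfg$phantom_z[1] & zg <= cfg$phantom_z[2]
    t1 <- array(0, d)
    t1[cyl] <- 800
    t1 <- t1 + array(stats::rnorm(prod(d), 0, cfg$t1_noise_sd), d)
    volumes <- list(
      t1 = image_volume(t1, spacing = sp, origin = org, frame = "image"),
      tissue = image_volume(array(as.numeric(cyl), d), spacing = sp,
                            origin = org, frame = "image"))
    if (identical(cfg$medium, "skull"))
      volumes$ct <- make_skullcap_ct(cfg$skull, seed = seed + 1L)
  }

  structure(list(
    grid = grid, spec = spec, medium = cfg$medium,
    volumes = volumes,
    fiducials_image = fiducial_set(fid_img, frame = "image"),
    fiducials_physical = fiducial_set(fid_phys, frame = "physical"),
    tracked_p_from_t = p_from_t_tracked,
    t_from_u = t_from_u,
    alignments = alignments,
    truth = list(hierarchy = truth_h,
                 i_from_s = i_from_s_true,
                 focus_s = focus_s,
                 target_image = c(0, 0, 0),
                 tracking_error_image = e_img,
                 tracking_error_physical = d_phys,
                 fiducial_sigma = cfg$fiducial_sigma,
                 seed = as.integer(seed)),
    cfg = cfg, seed = as.integer(seed)),
    class = "tfus_scene")
}

#' @export
print.tfus_scene <- function(x, ...) {
  cat(sprintf("<tfus_scene '%s', seed %d, injected error %.2f mm%s>\n",
              x$medium, x$seed,
              sqrt(sum(x$truth$tracking_error_image^2)),
              if (is.null(x$volumes)) ", no volumes" else ""))
  invisible(x)
}

## rotation about a unit axis by an angle in degrees (Rodrigues)
axis_angle_rotation <- function(axis, deg) {
  a <- deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * kx + (1 - cos(a)) * (kx %*% kx)
}

#' Synthetic skull-cap CT volume
#'
#' A spherical-shell segment standing in for an ex vivo skull cap: cortical
#' tables (~1400 HU) at the outer and inner surfaces with a trabecular dip
#' (~700 HU) mid-shell, plus Gaussian HU noise; water (0 HU) elsewhere. The
#' cap faces the transducer (opens towards `-z` of the image frame) and is
#' deliberately not concentric with the focus so the beam crosses it at
#' varying thickness and obliquity.
#'
#' @param cfg Named overrides: `center` (mm, image frame; `c(3, -2, 6)`),
#'   `radius` (40 mm, outer surface), `thickness` (6 mm; must cover at least
#'   2 voxels), `half_angle_deg` (55), `hu_table` (1400), `hu_trabecular`
#'   (700), `hu_noise_sd` (50), `dims` (`c(80, 80, 100)`), `spacing` (1 mm),
#'   `origin` (`c(-40, -40, -70)`).
#' @param seed Integer RNG seed.
#' @return An `image_volume` in Hounsfield units (frame `"image"`).
#' @export
make_skullcap_ct <- function(cfg = list(), seed = 1) {
  defaults <- list(center = c(3, -2, 6), radius = 40, thickness = 6,
                   half_angle_deg = 55, hu_table = 1400, hu_trabecular = 700,
                   hu_noise_sd = 50, dims = c(80L, 80L, 100L), spacing = 1,
                   origin = c(-40, -40, -70))
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$thickness < 2 * cfg$spacing)
    stop("make_skullcap_ct: shell thinner than 2 voxels at this spacing")
  set.seed(as.integer(seed))
  d <- as.integer(cfg$dims)
  ax <- lapply(1:3, function(i) cfg$origin[i] + (seq_len(d[i]) - 1) * cfg$spacing)
  xg <- array(rep(ax[[1]] - cfg$center[1], times = d[2] * d[3]), d)
  yg <- array(rep(rep(ax[[2]] - cfg$center[2], each = d[1]), times = d[3]), d)
  zg <- array(rep(ax[[3]] - cfg$center[3], each = d[1] * d[2]), d)
  r <- sqrt(xg^2 + yg^2 + zg^2)
  r[r == 0] <- .Machine$double.eps
  in_shell <- r <= cfg$radius & r >= cfg$radius - cfg$thickness
  facing <- (-zg / r) >= cos(cfg$half_angle_deg * pi / 180)
  shell <- in_shell & facing
  hu <- array(0, d)
  u <- (cfg$radius - r[shell]) / cfg$thickness      # 0 outer .. 1 inner
  hu[shell] <- cfg$hu_table - (cfg$hu_table - cfg$hu_trabecular) * sin(pi * u)
  if (cfg$hu_noise_sd > 0)
    hu[shell] <- hu[shell] + stats::rnorm(sum(shell), 0, cfg$hu_noise_sd)
  image_volume(hu, spacing = cfg$spacing, origin = cfg$origin,
               frame = "image", units = "HU")
}

#' Synthetic measured (MR-ARFI stand-in) focus
#'
#' The measured focus is the maximum of the reference pressure field
#' simulated at the true transducer pose, mapped into image space through
#' the true hierarchy, optionally perturbed by isotropic Gaussian noise
#' modelling ARFI voxel size and manual focus selection.
#'
#' @param scene A `tfus_scene`.
#' @param field_at_true_pose A `pressure_field` simulated at the scene's
#'   true pose (simulation frame).
#' @param perturb_sigma Per-axis noise, mm.
#' @param seed Integer RNG seed for the perturbation.
#' @param tissue_mask_s Optional tissue mask on the simulation grid for
#'   erosion-guarded maximum selection.
#' @param erosion_radius Voxels; see [focus_max()].
#' @return Length-3 position, mm, image frame.
#' @export
make_measured_focus <- function(scene, field_at_true_pose, perturb_sigma = 0,
                                seed = 1, tissue_mask_s = NULL,
                                erosion_radius = 2) {
  stopifnot(inherits(scene, "tfus_scene"),
            inherits(field_at_true_pose, "pressure_field"))
  m_s <- focus_max(field_at_true_pose, tissue_mask_s, erosion_radius)
  m_i <- apply_points(scene$truth$i_from_s, as.numeric(m_s))
  if (perturb_sigma > 0) {
    set.seed(as.integer(seed))
    m_i <- m_i + stats::rnorm(3, 0, perturb_sigma)
  }
  m_i
}
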