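#' Acoustic property table
#'
#' Reference acoustic properties used for all simulations: water background,
#' agar-graphite "tissue" absorption, and the cortical-bone endpoints of the
#' porosity interpolation. Speeds in m/s, densities in kg/m^3, absorption in
#' dB/cm/MHz. `hu_max` is the Hounsfield value mapped to zero porosity
#' (fully mineralized bone) by the linear HU-to-porosity model; 1000 HU is
#' the conventional choice of the CT-property literature and is configurable
#' here because it is a modelling constant, not a measured one.
#' `absorption_exponent` is the exponent on porosity in the bone-absorption
#' interpolation (1 = linear).
#'
#' @param ... Named overrides of the defaults.
#' @param yaml_file Optional YAML file whose entries override the defaults.
#' @return An object of class `property_table`.
#' @export
property_table <- function(..., yaml_file = NULL) {
  tab <- list(c_water = 1500, rho_water = 1000, alpha_water = 0,
              alpha_tissue = 0.2,
              c_bone = 3100, rho_bone = 2200,
              alpha_bone_min = 0.02, alpha_bone_max = 2.7,
              hu_max = 1000, absorption_exponent = 1)
  if (!is.null(yaml_file)) {
    ov <- yaml::read_yaml(yaml_file)
    tab[names(ov)] <- ov
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(tab))
    if (length(bad)) stop("property_table: unknown fields: ", paste(bad, collapse = ", "))
    tab[names(dots)] <- dots
  }
  if (tab$alpha_bone_min >= tab$alpha_bone_max)
    stop("property_table: alpha_bone_min must be below alpha_bone_max")
  structure(tab, class = "property_table")
}

#' Convert measured attenuation to simulation absorption
#'
#' Attenuation measured in agar-graphite phantom material (0.6 dB/cm/MHz for
#' the recipe used here) includes scattering; the absorbed fraction entered
#' into the simulation is taken as one third of the attenuation, giving the
#' 0.2 dB/cm/MHz assigned to the phantom tissue mask.
#'
#' @param attenuation dB/cm/MHz.
#' @param fraction Absorbed fraction of the attenuation (default 1/3).
#' @return Absorption in dB/cm/MHz.
#' @export
attenuation_to_absorption <- function(attenuation = 0.6, fraction = 1 / 3) {
  stopifnot(attenuation >= 0, fraction > 0, fraction <= 1)
  attenuation * fraction
}

#' Otsu threshold of a numeric array
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram;
#' returns the bin-edge threshold value.
#'
#' @param x Numeric vector or array.
#' @param nbins Number of histogram bins.
#' @return Scalar threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), nbins),
                     nbins)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cmu <- cumsum(w * mids)
  mu_t <- cmu[nbins]
  ## between-class variance for threshold after bin t
  valid <- cw > 0 & cw < 1
  sigma_b <- rep(-Inf, nbins)
  sigma_b[valid] <- (mu_t * cw[valid] - cmu[valid])^2 / (cw[valid] * (1 - cw[valid]))
  ## ties (e.g. a gap between two well-separated modes) resolve to the
  ## middle of the tied run, placing the threshold between the modes
  hits <- which(sigma_b >= max(sigma_b) - 1e-12 * abs(max(sigma_b)))
  t_best <- round(mean(hits))
  edges[t_best + 1]
}

#' Extract the skull from a CT volume
#'
#' Thresholds the Hounsfield-unit volume at the Otsu threshold (256-bin
#' between-class-variance maximizer) and keeps the largest 26-connected
#' component. A volume without bone-like intensities (constant, or Otsu
#' threshold below `min_bone_hu`) yields an empty mask with a warning.
#'
#' @param ct An `image_volume` with `units == "HU"`.
#' @param min_bone_hu Plausibility floor for a bone/soft-tissue threshold.
#' @param keep_largest Keep only the largest connected component.
#' @return 3D logical skull mask, with the threshold attached as attribute
#'   `"threshold"`.
#' @export
extract_skull <- function(ct, min_bone_hu = 150, keep_largest = TRUE) {
  stopifnot(inherits(ct, "image_volume"))
  if (!identical(ct$units, "HU"))
    warning("extract_skull: volume units are not HU")
  thr <- otsu_threshold(ct$data)
  if (is.na(thr) || thr < min_bone_hu) {
    warning("extract_skull: no bone-like intensity mode found; returning empty mask")
    return(structure(array(FALSE, dim(ct$data)), threshold = NA_real_))
  }
  mask <- ct$data > thr
  if (keep_largest && any(mask)) mask <- largest_component(mask, 26)
  structure(mask, threshold = thr)
}

#' Linear Hounsfield-to-porosity mapping
#'
#' Porosity is the fraction of a voxel not occupied by mineralized bone:
#' `phi = 1 - clamp(hu, 0, hu_max) / hu_max`, so water (0 HU) maps to
#' porosity 1 and fully mineralized bone (`hu_max`) to porosity 0.
#'
#' @param hu Scalar or array of Hounsfield units.
#' @param hu_max HU mapped to zero porosity (> 0).
#' @return Porosity in `[0, 1]`, same shape as `hu`.
#' @export
hu_to_porosity <- function(hu, hu_max = 1000) {
  if (hu_max <= 0) stop("hu_to_porosity: hu_max must be positive")
  1 - pmin(pmax(hu, 0), hu_max) / hu_max
}

#' Interpolate acoustic properties from porosity
#'
#' Sound speed and density interpolate linearly between the water and bone
#' endpoints with bone fraction `1 - phi`; absorption interpolates from
#' `alpha_bone_min` (dense cortical bone) to `alpha_bone_max` (fully porous)
#' with exponent `table$absorption_exponent` on the porosity.
#'
#' @param phi Porosity array in `[0, 1]` (values outside are clamped with a
#'   warning).
#' @param table A `property_table`.
#' @return List of arrays `c` (m/s), `rho` (kg/m^3), `alpha` (dB/cm/MHz).
#' @export
porosity_to_properties <- function(phi, table = property_table()) {
  stopifnot(inherits(table, "property_table"))
  if (any(phi < 0 | phi > 1)) {
    warning("porosity_to_properties: porosity outside [0, 1]; clamping")
    phi <- pmin(pmax(phi, 0), 1)
  }
  solid <- 1 - phi
  list(c = table$c_water + (table$c_bone - table$c_water) * solid,
       rho = table$rho_water + (table$rho_bone - table$rho_water) * solid,
       alpha = table$alpha_bone_min +
         (table$alpha_bone_max - table$alpha_bone_min) *
         phi^table$absorption_exponent)
}

#' Assemble the heterogeneous acoustic medium on a simulation grid
#'
#' Background voxels are water. Voxels of the tissue mask (agar-graphite
#' phantom) keep water speed and density but receive the tissue absorption.
#' If a CT volume (already resampled onto the grid) is supplied, skull voxels
#' get porosity-mapped speed, density and absorption; where skull and tissue
#' masks overlap, skull takes precedence.
#'
#' @param ct Optional `image_volume` in HU, on `grid`.
#' @param tissue_mask Optional 3D logical array on `grid`.
#' @param grid A `sim_grid_spec`.
#' @param table A `property_table`.
#' @param skull_mask Optional precomputed skull mask; default
#'   `extract_skull(ct)`.
#' @return An object of class `acoustic_medium`: arrays `sound_speed`,
#'   `density`, `absorption`, masks, and the grid.
#' @export
build_medium <- function(ct = NULL, tissue_mask = NULL, grid,
                         table = property_table(), skull_mask = NULL) {
  stopifnot(inherits(grid, "sim_grid_spec"))
  dims <- grid$dims
  cs <- array(table$c_water, dims)
  rho <- array(table$rho_water, dims)
  alpha <- array(table$alpha_water, dims)
  if (is.null(tissue_mask)) tissue_mask <- array(FALSE, dims)
  tissue_mask <- array(as.logical(tissue_mask), dims)
  if (!is.null(ct)) {
    stopifnot(inherits(ct, "image_volume"))
    if (!identical(dim(ct$data), as.integer(dims)))
      stop("build_medium: CT volume is not on the simulation grid; resample first")
    if (is.null(skull_mask)) skull_mask <- extract_skull(ct)
    skull_mask <- array(as.logical(skull_mask), dims)
  } else {
    skull_mask <- array(FALSE, dims)
  }
  if (any(skull_mask & tissue_mask)) {
    warning("build_medium: skull and tissue masks overlap; skull takes precedence")
    tissue_mask <- tissue_mask & !skull_mask
  }
  alpha[tissue_mask] <- table$alpha_tissue
  if (any(skull_mask)) {
    phi <- hu_to_porosity(ct$data[skull_mask], table$hu_max)
    pr <- porosity_to_properties(phi, table)
    cs[skull_mask] <- pr$c
    rho[skull_mask] <- pr$rho
    alpha[skull_mask] <- pr$alpha
  }
  med <- structure(list(sound_speed = cs, density = rho, absorption = alpha,
                        skull_mask = skull_mask, tissue_mask = tissue_mask,
                        grid = grid, table = table),
                   class = "acoustic_medium")
  assert_medium(med)
  med
}

## type invariants: property grids within table bounds
assert_medium <- function(med) {
  tab <- med$table
  stopifnot(all(med$sound_speed >= tab$c_water - 1e-9),
            all(med$sound_speed <= tab$c_bone + 1e-9),
            all(med$density >= tab$rho_water - 1e-9),
            all(med$density <= tab$rho_bone + 1e-9),
            all(med$absorption >= 0))
  invisible(med)
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium %dx%dx%d @ %.3g mm: %d skull, %d tissue voxels>\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3], x$grid$spacing,
              sum(x$skull_mask), sum(x$tissue_mask)))
  invisible(x)
}

#' Uniform water medium
#'
#' @param grid A `sim_grid_spec`.
#' @param table A `property_table`.
#' @return An `acoustic_medium` of pure water.
#' @export
water_medium <- function(grid, table = property_table()) {
  build_medium(ct = NULL, tissue_mask = NULL, grid = grid, table = table)
}
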