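#' Points per wavelength on the simulation grid
#'
#' The spatial sampling rate of the continuous wave: `(c / f) / spacing`.
#' Simulation requires at least 7 points per wavelength in water; the full
#' scale (1500 m/s, 802 kHz, 0.25 mm) and the desk scale (401 kHz, 0.5 mm)
#' both give about 7.48.
#'
#' @param c Sound speed, m/s.
#' @param f Frequency, Hz.
#' @param spacing Grid spacing, mm.
#' @return Dimensionless points-per-wavelength ratio.
#' @export
points_per_wavelength <- function(c, f, spacing) {
  if (any(c <= 0) || any(f <= 0) || any(spacing <= 0))
    stop("points_per_wavelength: all inputs must be positive")
  (c / f) * 1000 / spacing
}

#' Solver configuration
#'
#' Knobs of the one-way split-step angular-spectrum solver.
#'
#' @param ppw_min Minimum points per wavelength in the background medium;
#'   the solver refuses to run below this (7, the stability/accuracy rule
#'   used for all simulations).
#' @param boundary_layer Width, in voxels, of the raised-cosine absorbing
#'   apodization applied at the lateral grid edges every marching step to
#'   suppress wrap-around (>= 10).
#' @param angular_cutoff Fraction of the wavenumber `k` above which lateral
#'   spatial frequencies are discarded (evanescent and near-grazing
#'   components); 0.95 keeps propagating waves up to ~72 degrees.
#' @param reference_speed Background speed (m/s) for the homogeneous
#'   propagator; heterogeneity is applied as per-voxel phase and absorption
#'   screens. `NULL` uses the property-table water speed of the medium.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(ppw_min = 7, boundary_layer = 10,
                          angular_cutoff = 0.95, reference_speed = NULL) {
  stopifnot(ppw_min > 0, boundary_layer >= 0,
            angular_cutoff > 0, angular_cutoff <= 1)
  structure(list(ppw_min = ppw_min, boundary_layer = as.integer(boundary_layer),
                 angular_cutoff = angular_cutoff,
                 reference_speed = reference_speed),
            class = "solver_config")
}

#' Steady-state RMS pressure field of a placed bowl source
#'
#' Solves the continuous-wave field at the drive frequency by one-way
#' split-step angular-spectrum marching along `+z`: at each plane the source
#' voxels of the bowl are injected spectrally (with the `k/kz` obliquity
#' weight that makes a voxel sheet radiate as a monopole layer, so the
#' homogeneous-water field reproduces the Rayleigh integral), the field is
#' propagated one voxel with the exact non-paraxial transfer function
#' `exp(i kz dz)`, and medium heterogeneity is applied as per-voxel phase
#' screens (local wavenumber minus background) and absorption screens
#' (dB/cm/MHz x f[MHz], converted to Np/mm). The RMS pressure of the
#' time-harmonic field, `|p| / sqrt(2)`, is recorded on the whole grid.
#'
#' The scheme neglects reflected (backward-travelling) waves, so standing
#' waves and skull reverberation are not modelled; transmitted-beam
#' refraction, aberration and absorption are. Fields are linear in the
#' source amplitude.
#'
#' @param medium An `acoustic_medium`.
#' @param source A placed `transducer_model` on the same grid (its
#'   `focus_marker` is not part of the acoustic source).
#' @param spec A `transducer_spec` (frequency and source amplitude).
#' @param cfg A `solver_config`.
#' @return An object of class `pressure_field`: `rms_pressure` array (Pa),
#'   `grid`, `frequency`, `axis`.
#' @export
simulate_rms <- function(medium, source, spec = source$spec,
                         cfg = solver_config()) {
  stopifnot(inherits(medium, "acoustic_medium"),
            inherits(source, "transducer_model"),
            inherits(spec, "transducer_spec"),
            inherits(cfg, "solver_config"))
  grid <- medium$grid
  if (!identical(as.integer(grid$dims), as.integer(source$grid$dims)) ||
      grid$spacing != source$grid$spacing)
    stop("simulate_rms: source and medium grids differ")
  h <- grid$spacing
  c0 <- if (is.null(cfg$reference_speed)) medium$table$c_water else cfg$reference_speed
  ppw <- points_per_wavelength(c0, spec$frequency, h)
  if (ppw < cfg$ppw_min)
    stop(sprintf("simulate_rms: %.2f points per wavelength < required %.2f; refine the grid or lower the frequency",
                 ppw, cfg$ppw_min))
  if (source$axis[3] <= 0)
    stop("simulate_rms: the one-way solver marches along +z; source axis must have a positive z component")
  if (source$axis[3] < cos(45 * pi / 180))
    warning("simulate_rms: source axis tilted more than 45 degrees from +z; one-way accuracy degrades")
  dims <- grid$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  field <- array(0, dims)
  if (spec$source_amplitude == 0)
    return(structure(list(rms_pressure = field, grid = grid,
                          frequency = spec$frequency, axis = source$axis),
                     class = "pressure_field"))
  k0 <- 2 * pi * spec$frequency / (c0 * 1000)       # rad/mm
  kx <- 2 * pi * fft_freqs(nx) / (nx * h)
  ky <- 2 * pi * fft_freqs(ny) / (ny * h)
  k2 <- outer(kx^2, rep(1, ny)) + outer(rep(1, nx), ky^2)
  keep <- k2 < (cfg$angular_cutoff * k0)^2
  kzv <- sqrt(pmax(k0^2 - k2, 0))
  prop <- ifelse(keep, exp(1i * kzv * h), 0)
  srcw <- ifelse(keep, k0 / pmax(kzv, 1e-12), 0)
  win <- edge_window(nx, ny, cfg$boundary_layer)
  ## heterogeneity screens
  het <- any(medium$sound_speed != c0) || any(medium$absorption != 0)
  f_mhz <- spec$frequency / 1e6
  np_per_db <- 1 / (20 / log(10))   # 1 Np = 8.6859 dB
  amp <- spec$source_amplitude
  a <- matrix(0 + 0i, nx, ny)
  bowl <- source$bowl_mask
  for (iz in seq_len(nz)) {
    s <- bowl[, , iz]
    if (any(s)) a <- a + stats::fft(stats::fft(s + 0i) * srcw, inverse = TRUE) / (nx * ny)
    pf <- Mod(a)
    if (any(!is.finite(pf)))
      stop("simulate_rms: non-finite field detected at plane ", iz)
    field[, , iz] <- pf
    ## propagate to the next plane through the slab [iz, iz+1]
    if (iz < nz) {
      a <- stats::fft(stats::fft(a * win) * prop, inverse = TRUE) / (nx * ny)
      if (het) {
        cl <- medium$sound_speed[, , iz + 1]
        al <- medium$absorption[, , iz + 1]
        dk <- 2 * pi * spec$frequency / (cl * 1000) - k0
        att <- al * f_mhz * 0.1 * np_per_db          # dB/cm -> Np/mm
        a <- a * exp((1i * dk - att) * h)
      }
    }
  }
  structure(list(rms_pressure = field * (amp / sqrt(2)), grid = grid,
                 frequency = spec$frequency, axis = source$axis),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  mx <- which.max(x$rms_pressure)
  idx <- arrayInd(mx, dim(x$rms_pressure))
  mm <- grid_index_to_world(x$grid, idx)
  cat(sprintf("<pressure_field %dx%dx%d, f = %.0f kHz, peak %.3g Pa at (%.1f, %.1f, %.1f) mm>\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$frequency / 1e3, max(x$rms_pressure), mm[1], mm[2], mm[3]))
  invisible(x)
}

## FFT sample frequencies in cycles (integer index convention)
fft_freqs <- function(n) {
  half <- floor(n / 2)
  c(0:half, -(n - half - 1):-1)[1:n]
}

## separable raised-cosine edge apodization window
edge_window <- function(nx, ny, bl) {
  mk <- function(n) {
    w <- rep(1, n)
    if (bl > 0) {
      ramp <- 0.5 * (1 - cos(pi * (0:(bl - 1)) / bl))
      w[1:bl] <- ramp
      w[n:(n - bl + 1)] <- ramp
    }
    w
  }
  outer(mk(nx), mk(ny))
}
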