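#' Rayleigh-integral oracle for a focused bowl in homogeneous media
#'
#' Numerically evaluates the Rayleigh–Sommerfeld integral of a uniformly
#' vibrating spherical cap over a fine surface discretization. Used as an
#' independent reference for the field solver; the integral sums
#' `exp((ik - a) r) / r` monopole contributions over cap elements of arc
#' size `lambda / elements_per_wavelength`. Coordinates: geometric focus at
#' the origin, propagation along `+z`, bowl apex at `(0, 0, -ROC)`.
#'
#' @param spec A `transducer_spec`.
#' @param points n x 3 matrix (or length-3 vector) of field points, mm.
#' @param c Sound speed, m/s.
#' @param rho Density, kg/m^3.
#' @param alpha Absorption, dB/cm/MHz.
#' @param elements_per_wavelength Cap discretization density (>= 20 for
#'   converged fields).
#' @return Complex pressure at each point, for unit normal velocity
#'   (`p = -i rho c k / (2 pi) * integral`). Points closer to the cap than
#'   one element are excluded (returned as `NA`) with a warning.
#' @export
rayleigh_oracle <- function(spec, points, c = 1500, rho = 1000, alpha = 0,
                            elements_per_wavelength = 20) {
  stopifnot(inherits(spec, "transducer_spec"))
  pts <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  roc <- spec$radius_of_curvature
  lambda <- c / spec$frequency * 1000                # mm
  step <- lambda / elements_per_wavelength
  th_max <- cap_half_angle(spec)
  n_th <- max(2L, ceiling(roc * th_max / step))
  dth <- th_max / n_th
  th <- (seq_len(n_th) - 0.5) * dth
  ## assemble cap elements ring by ring
  el <- vector("list", n_th)
  for (i in seq_len(n_th)) {
    ring_r <- roc * sin(th[i])
    n_ph <- max(1L, ceiling(2 * pi * ring_r / step))
    ph <- (seq_len(n_ph) - 0.5) * 2 * pi / n_ph
    da <- roc^2 * sin(th[i]) * dth * (2 * pi / n_ph)
    el[[i]] <- cbind(ring_r * cos(ph), ring_r * sin(ph),
                     rep(-roc * cos(th[i]), n_ph), rep(da, n_ph))
  }
  el <- do.call(rbind, el)
  k <- 2 * pi * spec$frequency / (c * 1000)          # rad/mm
  att <- alpha * (spec$frequency / 1e6) * 0.1 * log(10) / 20  # Np/mm
  pref <- -1i * rho * c * k / (2 * pi)               # per mm: consistent scale
  out <- complex(nrow(pts))
  excluded <- FALSE
  for (p in seq_len(nrow(pts))) {
    dx <- pts[p, 1] - el[, 1]; dy <- pts[p, 2] - el[, 2]; dz <- pts[p, 3] - el[, 3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(r < step)) {
      excluded <- TRUE
      out[p] <- NA_complex_
      next
    }
    out[p] <- pref * sum(exp((1i * k - att) * r) / r * el[, 4])
  }
  if (excluded)
    warning("rayleigh_oracle: field point(s) on the cap surface excluded (NA)")
  out
}

#' Closed-form on-axis pressure of a focused bowl (O'Neil)
#'
#' Magnitude of the on-axis pressure of a uniformly vibrating lossless
#' spherical cap: `|p| = 2 rho c |R / (R - zeta)| |sin(k (r_edge - zeta)/2)|`
#' with `zeta` the axial distance from the apex and `r_edge` the distance to
#' the cap rim. The removable singularity at the geometric focus
#' (`zeta = R`) is evaluated by its limit `rho c k R (1 - cos(theta_max))`.
#' Serves as the closed-form cross-check of [rayleigh_oracle()] on axis.
#'
#' @param spec A `transducer_spec`.
#' @param z Axial positions, mm, relative to the geometric focus (0 = focus,
#'   negative towards the transducer).
#' @param c Sound speed, m/s.
#' @param rho Density, kg/m^3.
#' @return On-axis pressure magnitude per unit normal velocity (Pa).
#' @export
oneil_axial <- function(spec, z, c = 1500, rho = 1000) {
  roc <- spec$radius_of_curvature
  zeta <- z + roc                                    # distance from apex
  k <- 2 * pi * spec$frequency / (c * 1000)
  ct <- cos(cap_half_angle(spec))
  r_edge <- sqrt(roc^2 + (roc - zeta)^2 - 2 * roc * (roc - zeta) * ct)
  u <- roc - zeta
  p <- ifelse(abs(u) < 1e-9,
              rho * c * k * roc * (1 - ct),
              2 * rho * c * abs(roc / u) * abs(sin(k * (r_edge - zeta) / 2)))
  p
}
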