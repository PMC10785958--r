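#' Neuronavigation transform hierarchy
#'
#' Bundles the four rigid links of the tracked-tFUS coordinate chain:
#' simulation (S) -> ultrasound (U) -> tracker (T) -> physical (P) -> image (I).
#' `i_from_p` is the fiducial-registration result, `p_from_t` the tracked tool
#' pose reported by the optical camera, `t_from_u` the focus calibration of the
#' transducer relative to its tracker (any empirical bias correction, such as
#' the [2, 0, 4] mm offset used with the H115MR transducer, is folded into this
#' link as a translation expressed in the ultrasound frame), and `u_from_s`
#' the one-time alignment of the simulation grid to the ultrasound frame.
#'
#' @param i_from_p,p_from_t,t_from_u,u_from_s `rigid_transform` links with
#'   consistent frame labels.
#' @return An object of class `transform_hierarchy`.
#' @export
transform_hierarchy <- function(i_from_p, p_from_t, t_from_u, u_from_s) {
  links <- list(i_from_p = i_from_p, p_from_t = p_from_t,
                t_from_u = t_from_u, u_from_s = u_from_s)
  want <- list(i_from_p = c("physical", "image"),
               p_from_t = c("tracker", "physical"),
               t_from_u = c("ultrasound", "tracker"),
               u_from_s = c("simulation", "ultrasound"))
  for (nm in names(links)) {
    l <- links[[nm]]
    if (is.null(l)) stop("transform_hierarchy: missing link ", nm)
    if (!inherits(l, "rigid_transform"))
      stop("transform_hierarchy: ", nm, " is not a rigid_transform")
    if (!identical(c(l$from, l$to), want[[nm]]))
      stop(sprintf("transform_hierarchy: %s must map %s -> %s, got %s -> %s",
                   nm, want[[nm]][1], want[[nm]][2], l$from, l$to))
  }
  structure(links, class = "transform_hierarchy")
}

#' Full image-from-simulation transform
#'
#' Chains the hierarchy into the single transform that carries simulation-grid
#' coordinates into image space: `^I T_S = ^I T_P  ^P T_T  ^T T_U  ^U T_S`.
#' This is the transform applied to the transducer model (and, inverted, used
#' to resample image volumes onto the simulation grid).
#'
#' @param h A `transform_hierarchy`.
#' @return A `rigid_transform` from `"simulation"` to `"image"`.
#' @export
image_from_simulation <- function(h) {
  stopifnot(inherits(h, "transform_hierarchy"))
  compose(compose(h$i_from_p, h$p_from_t), compose(h$t_from_u, h$u_from_s))
}
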