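#' Rigid-body transform between two named coordinate frames
#'
#' A `rigid_transform` maps points expressed in `from` coordinates into `to`
#' coordinates: `p_to = R %*% p_from + t`. Frames follow the neuronavigation
#' convention used throughout the package: image (`"image"`), physical
#' (`"physical"`), optical tracker (`"tracker"`), ultrasound (`"ultrasound"`,
#' origin at the transducer's geometric focus, +z along the propagation axis)
#' and simulation (`"simulation"`). All translations are in millimetres; world
#' axes are right-handed RAS. Any LPS input (DICOM-derived) must be converted
#' at the I/O boundary.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length-3, mm.
#' @param from,to Frame labels.
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(rot_z(90), c(1, 2, 3), from = "physical", to = "image")
#' apply_points(t1, c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            from = "a", to = "b") {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite rotation or translation")
  drift <- max(abs(crossprod(rotation) - diag(3)))
  if (drift > 1e-6)
    stop("rigid_transform: rotation is not orthonormal (drift ", format(drift), ")")
  if (drift > 1e-9) rotation <- orthonormalize(rotation)
  if (det(rotation) < 0)
    stop("rigid_transform: rotation has determinant -1 (reflection)")
  structure(list(rotation = rotation, translation = translation,
                 from = from, to = to),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform %s -> %s>\n", x$from, x$to))
  m <- as_matrix4(x)
  print(round(m, 6))
  invisible(x)
}

## nearest orthonormal matrix (polar factor via SVD)
orthonormalize <- function(r) {
  s <- svd(r)
  u <- s$u %*% t(s$v)
  if (det(u) < 0) {
    s$v[, 3] <- -s$v[, 3]
    u <- s$u %*% t(s$v)
  }
  u
}

#' Elementary rotations (degrees)
#'
#' @param theta Angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(theta) {
  a <- theta * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(theta) {
  a <- theta * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(theta) {
  a <- theta * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Convert a rigid transform to/from a 4x4 homogeneous matrix
#'
#' @param t A `rigid_transform`.
#' @return `as_matrix4`: a 4x4 matrix. `from_matrix4`: a `rigid_transform`.
#' @export
as_matrix4 <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' @rdname as_matrix4
#' @param m 4x4 homogeneous rigid matrix.
#' @param from,to Frame labels.
#' @export
from_matrix4 <- function(m, from = "a", to = "b") {
  rigid_transform(m[1:3, 1:3], m[1:3, 4], from = from, to = to)
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` maps `b$from` coordinates to `a$to` coordinates, i.e. the
#' result acts as `a` after `b` (matrix product `A %*% B`). Frame labels must
#' chain: `a$from == b$to`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform` from `b$from` to `a$to`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (!identical(a$from, b$to))
    stop(sprintf("compose: frame chain broken: '%s -> %s' cannot follow '%s -> %s'",
                 b$from, b$to, a$from, a$to))
  r <- a$rotation %*% b$rotation
  drift <- max(abs(crossprod(r) - diag(3)))
  if (drift > 1e-9) r <- orthonormalize(r)
  structure(list(rotation = r,
                 translation = as.numeric(a$rotation %*% b$translation + a$translation),
                 from = b$from, to = a$to),
            class = "rigid_transform")
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse transform, with frames swapped.
#' @export
invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rt <- t(t$rotation)
  structure(list(rotation = rt,
                 translation = as.numeric(-rt %*% t$translation),
                 from = t$to, to = t$from),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param pts Numeric length-3 vector or an n x 3 matrix of points (mm).
#' @return Points in the target frame, same shape as the input.
#' @export
apply_points <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(as.numeric(pts), 1, 3) else as.matrix(pts)
  if (ncol(p) != 3L) stop("apply_points: points must be length-3 or n x 3")
  if (!all(is.finite(p))) stop("apply_points: non-finite input point")
  out <- p %*% t(t$rotation) + rep(t$translation, each = nrow(p))
  if (vec) as.numeric(out) else out
}

#' Serialize rigid transforms as JSON
#'
#' The on-disk format is a JSON object with the 16 entries of the homogeneous
#' matrix in row-major order plus the `from`/`to` frame labels.
#'
#' @param t A `rigid_transform`.
#' @param path File path.
#' @return `read_transform` returns a `rigid_transform`; `write_transform`
#'   returns `path` invisibly.
#' @export
write_transform <- function(t, path) {
  stopifnot(inherits(t, "rigid_transform"))
  obj <- list(matrix = as.numeric(t(as_matrix4(t))), from = t$from, to = t$to)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(obj$matrix), 4, 4, byrow = TRUE)
  from_matrix4(m, from = obj$from, to = obj$to)
}

## -- quaternion helpers (used transiently for rotation averaging) ----------

rot_to_quat <- function(r) {
  tr <- r[1, 1] + r[2, 2] + r[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else if (r[1, 1] > r[2, 2] && r[1, 1] > r[3, 3]) {
    s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
    q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s, (r[1, 2] + r[2, 1]) / s,
           (r[1, 3] + r[3, 1]) / s)
  } else if (r[2, 2] > r[3, 3]) {
    s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
    q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s, 0.25 * s,
           (r[2, 3] + r[3, 2]) / s)
  } else {
    s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
    q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
           (r[2, 3] + r[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

## angle (degrees) between two rotations
rotation_angle_deg <- function(r1, r2) {
  r <- crossprod(r1, r2)
  c <- (sum(diag(r)) - 1) / 2
  acos(max(-1, min(1, c))) * 180 / pi
}
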