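#' Fiducial point set
#'
#' A set of fiducial marker positions in a named frame. Six doughnut-shaped
#' skin fiducials are typical for phantom and cranial navigation; at least
#' three non-collinear points are needed for rigid registration.
#'
#' @param points n x 3 matrix of positions (mm).
#' @param frame Frame label.
#' @param labels Optional character names, one per point.
#' @return An object of class `fiducial_set`.
#' @export
fiducial_set <- function(points, frame = "image", labels = NULL) {
  p <- as.matrix(points)
  if (is.null(dim(points)) && length(points) == 3L) p <- matrix(points, 1, 3)
  stopifnot(ncol(p) == 3L, all(is.finite(p)))
  if (is.null(labels)) labels <- paste0("F", seq_len(nrow(p)))
  stopifnot(length(labels) == nrow(p))
  structure(list(points = unname(p), frame = frame, labels = labels),
            class = "fiducial_set")
}

#' Read and write fiducial sets as CSV
#'
#' CSV columns are `label,x,y,z,frame` (mm).
#'
#' @param fs A `fiducial_set`.
#' @param path File path.
#' @export
write_fiducials <- function(fs, path) {
  stopifnot(inherits(fs, "fiducial_set"))
  df <- data.frame(label = fs$labels, x = fs$points[, 1], y = fs$points[, 2],
                   z = fs$points[, 3], frame = fs$frame)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fiducial_set(as.matrix(df[, c("x", "y", "z")]), frame = df$frame[1],
               labels = df$label)
}

## rank check: points must span a plane (not collinear)
assert_noncollinear <- function(p) {
  if (nrow(p) < 3L) stop("registration needs at least 3 fiducials")
  c0 <- sweep(p, 2, colMeans(p))
  sv <- svd(c0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("fiducials are collinear (rank-deficient); registration is degenerate")
}

#' Paired-point rigid registration (Kabsch/Umeyama)
#'
#' Least-squares rigid fit of `moving` onto `fixed` with known point
#' correspondence, solved in closed form by SVD of the cross-covariance with
#' the usual determinant-sign correction so the solution is a proper rotation,
#' never a reflection. The fiducial registration error (FRE) is the
#' root-mean-square distance between the registered moving points and the
#' fixed points.
#'
#' @param moving,fixed `fiducial_set` objects with equal counts (>= 3,
#'   non-collinear) and corresponding order.
#' @return A `registration_result`: list with `transform` (a
#'   `rigid_transform` from `moving$frame` to `fixed$frame`), `fre` (mm),
#'   `residuals` (per-point mm) and `correspondence` (the permutation used;
#'   identity here).
#' @export
fit_rigid <- function(moving, fixed) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  a <- moving$points; b <- fixed$points
  if (nrow(a) != nrow(b)) stop("fit_rigid: point counts differ")
  assert_noncollinear(a)
  assert_noncollinear(b)
  ca <- colMeans(a); cb <- colMeans(b)
  h <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cb - as.numeric(r %*% ca)
  tf <- rigid_transform(r, tr, from = moving$frame, to = fixed$frame)
  res <- sqrt(rowSums((apply_points(tf, a) - b)^2))
  structure(list(transform = tf, fre = sqrt(mean(res^2)), residuals = res,
                 correspondence = seq_len(nrow(a))),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result %s -> %s, FRE = %.4f mm, n = %d>\n",
              x$transform$from, x$transform$to, x$fre, length(x$residuals)))
  invisible(x)
}

## all permutations of 1..n (n <= 8)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Automatic fiducial correspondence by exhaustive search
#'
#' Finds the correspondence between two unordered fiducial sets that minimizes
#' the post-fit FRE, scoring every permutation with [fit_rigid()]. Exhaustive
#' search is exact and affordable at navigation fiducial counts (720
#' permutations for the usual six markers); sets larger than 8 are refused.
#' If two correspondences tie within 1e-9 mm (symmetric constellations), a
#' warning is emitted and the lexicographically first permutation is kept.
#'
#' @param moving,fixed `fiducial_set` objects with equal counts (3..8).
#' @return Integer permutation `perm` such that `moving$points[i, ]`
#'   corresponds to `fixed$points[perm[i], ]`. The best-fit
#'   `registration_result` is attached as attribute `"fit"`.
#' @export
match_fiducials <- function(moving, fixed) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  n <- nrow(moving$points)
  if (nrow(fixed$points) != n) stop("match_fiducials: point counts differ")
  if (n > 8L) stop("match_fiducials: exhaustive search limited to n <= 8")
  perms <- permutations(n)
  fres <- numeric(nrow(perms))
  fits <- vector("list", nrow(perms))
  for (i in seq_len(nrow(perms))) {
    fx <- fiducial_set(fixed$points[perms[i, ], , drop = FALSE],
                       frame = fixed$frame)
    fits[[i]] <- fit_rigid(moving, fx)
    fres[i] <- fits[[i]]$fre
  }
  best <- which.min(fres)
  if (sum(fres <= fres[best] + 1e-9) > 1L)
    warning("match_fiducials: ambiguous correspondence (FRE tie within 1e-9 mm); ",
            "keeping the first permutation")
  perm <- perms[best, ]
  structure(perm, fit = fits[[best]])
}

#' Point-to-point targeting error
#'
#' Euclidean distance between a predicted target position and a measured one
#' (e.g. the optically predicted focus versus the MR-ARFI focus), both in the
#' same frame.
#'
#' @param predicted,measured Length-3 positions (mm).
#' @param frame_predicted,frame_measured Optional frame labels; if both given
#'   they must match.
#' @return Scalar distance in mm.
#' @export
target_registration_error <- function(predicted, measured,
                                      frame_predicted = NULL,
                                      frame_measured = NULL) {
  stopifnot(length(predicted) == 3L, length(measured) == 3L,
            all(is.finite(predicted)), all(is.finite(measured)))
  if (!is.null(frame_predicted) && !is.null(frame_measured) &&
      !identical(frame_predicted, frame_measured))
    stop("target_registration_error: points are in different frames (",
         frame_predicted, " vs ", frame_measured, ")")
  sqrt(sum((as.numeric(predicted) - as.numeric(measured))^2))
}
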