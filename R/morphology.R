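## Small 3D binary-morphology helpers (ball-kernel erosion, connected
## components). Kept internal: no installed package offers 3D morphology.

## integer offsets of a digital ball of given radius (voxels)
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  g <- g[g$i^2 + g$j^2 + g$k^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Erode a 3D mask with a digital ball
#'
#' A voxel survives when every voxel within `radius` (Euclidean, in voxels)
#' is inside the mask. Voxels outside the array are treated as background, so
#' erosion also retreats from the grid boundary. `radius = 0` is the
#' identity.
#'
#' @param mask 3D logical array.
#' @param radius Ball radius in voxels.
#' @return Eroded logical array.
#' @export
erode_mask <- function(mask, radius) {
  stopifnot(length(dim(mask)) == 3L, radius >= 0)
  if (radius == 0) return(mask)
  d <- dim(mask)
  off <- ball_offsets(radius)
  out <- array(TRUE, d)
  for (n in seq_len(nrow(off))) {
    sh <- shift_array(mask, off[n, ], fill = FALSE)
    out <- out & sh
  }
  out & mask
}

## shift a logical array by integer offset, filling exposed voxels
shift_array <- function(a, off, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (i in 1:3) {
    o <- off[i]
    if (o >= d[i] || -o >= d[i]) return(out)
    if (o >= 0) { src[[i]] <- (1 + o):d[i]; dst[[i]] <- 1:(d[i] - o) }
    else { src[[i]] <- 1:(d[i] + o); dst[[i]] <- (1 - o):d[i] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## neighbour linear-index offsets for 6- or 26-connectivity
neighbour_offsets <- function(d, connectivity) {
  g <- expand.grid(i = -1:1, j = -1:1, k = -1:1)
  g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
  if (connectivity == 6) g <- g[abs(g$i) + abs(g$j) + abs(g$k) == 1, ]
  g
}

## flood fill: logical array marking the connected component containing seed
## (linear index); frontier-vectorized BFS
component_containing <- function(mask, seed, connectivity = 26) {
  d <- dim(mask)
  offs <- neighbour_offsets(d, connectivity)
  nb <- offs$i + offs$j * d[1] + offs$k * d[1] * d[2]
  n <- length(mask)
  lab <- logical(n)
  if (!mask[seed]) return(array(lab, d))
  lab[seed] <- TRUE
  frontier <- seed
  ## guard against wrap-around across the i/j faces
  ii <- function(lin) (lin - 1) %% d[1] + 1
  jj <- function(lin) ((lin - 1) %/% d[1]) %% d[2] + 1
  while (length(frontier)) {
    cand <- rep(frontier, each = length(nb)) + rep(nb, times = length(frontier))
    di <- rep(offs$i, times = length(frontier))
    dj <- rep(offs$j, times = length(frontier))
    oi <- ii(rep(frontier, each = length(nb)))
    oj <- jj(rep(frontier, each = length(nb)))
    ok <- cand >= 1 & cand <= n &
      (oi + di) >= 1 & (oi + di) <= d[1] &
      (oj + dj) >= 1 & (oj + dj) <= d[2]
    cand <- unique(cand[ok])
    cand <- cand[mask[cand] & !lab[cand]]
    lab[cand] <- TRUE
    frontier <- cand
  }
  array(lab, d)
}

## largest connected component of a mask (26-connectivity)
largest_component <- function(mask, connectivity = 26) {
  d <- dim(mask)
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- which.max(remaining)  # first TRUE
    comp <- component_containing(remaining, seed, connectivity)
    nc <- sum(comp)
    if (nc > best_n) { best <- comp; best_n <- nc }
    remaining <- remaining & !comp
    if (best_n >= sum(remaining)) break  # nothing bigger possible
  }
  if (is.null(best)) array(FALSE, d) else best
}
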