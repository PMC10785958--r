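test_that("make_bowl rasterizes a thin cap on the ROC sphere", {
  spec <- transducer_spec()          # ROC 63.2, aperture 64
  grid <- desk_grid()
  model <- make_bowl(spec, grid)
  idx <- which(model$bowl_mask, arr.ind = TRUE)
  expect_gt(nrow(idx), 1000)
  w <- sweep((idx - 1) * grid$spacing, 2, grid$origin, "+")
  d <- sweep(w, 2, model$focus_mm)
  r <- sqrt(rowSums(d^2))
  half_diag <- sqrt(3) / 2 * grid$spacing
  # every voxel centre within half a voxel diagonal of the ROC sphere
  expect_lt(max(abs(r - spec$radius_of_curvature)), half_diag + 1e-9)
  # and within the aperture half-angle of the -z cap
  cosang <- -d[, 3] / r
  expect_gte(min(cosang), cos(tfusnav:::cap_half_angle(spec)) - 1e-6)
  # focus marker is a 3x3x3 cube centred on the focus voxel, disjoint extent
  expect_equal(sum(model$focus_marker), 27)
  mi <- which(model$focus_marker, arr.ind = TRUE)
  ctr <- colMeans(mi)
  expect_equal(as.numeric(sweep((matrix(ctr, 1) - 1) * grid$spacing, 2,
                                grid$origin, "+")),
               model$focus_mm, tolerance = grid$spacing)
})

test_that("bowl voxel count scales as spacing^-2 and the corrected area converges", {
  spec <- transducer_spec(radius_of_curvature = 12, aperture_diameter = 16,
                          frequency = 1e6)
  g1 <- sim_grid_spec(c(40, 40, 40), 1)
  g2 <- sim_grid_spec(c(80, 80, 80), 0.5)
  g3 <- sim_grid_spec(c(160, 160, 160), 0.25)
  f <- c(20, 20, 20)
  m1 <- make_bowl(spec, g1, focus_mm = f)
  m2 <- make_bowl(spec, g2, focus_mm = f)
  m3 <- make_bowl(spec, g3, focus_mm = f)
  ratio <- sum(m2$bowl_mask) / sum(m1$bowl_mask)
  expect_lt(abs(ratio - 4), 4 * 0.15)
  # orientation-corrected area estimate converges to the analytic cap area
  area <- tfusnav:::cap_area(spec)
  e1 <- abs(bowl_area_estimate(m1) - area)
  e2 <- abs(bowl_area_estimate(m2) - area)
  e3 <- abs(bowl_area_estimate(m3) - area)
  expect_lt(e2, e1)
  expect_lt(e3, e2)
  expect_lt(e3 / area, 0.05)
})

test_that("aperture limits are enforced", {
  expect_error(transducer_spec(radius_of_curvature = 30, aperture_diameter = 61),
               "aperture")
  # full hemisphere is the limiting valid case
  spec <- transducer_spec(radius_of_curvature = 10, aperture_diameter = 20,
                          frequency = 1e6)
  m <- make_bowl(spec, sim_grid_spec(c(40, 40, 40), 1), focus_mm = c(20, 20, 20))
  idx <- which(m$bowl_mask, arr.ind = TRUE)
  z <- (idx[, 3] - 1) * 1
  expect_lte(max(z), 20 + 1)   # no voxels beyond the equator plane
  # hemisphere has more voxels than a narrower cap of the same ROC
  spec_half <- transducer_spec(radius_of_curvature = 10, aperture_diameter = 10,
                               frequency = 1e6)
  m2 <- make_bowl(spec_half, sim_grid_spec(c(40, 40, 40), 1),
                  focus_mm = c(20, 20, 20))
  expect_gt(sum(m$bowl_mask), sum(m2$bowl_mask))
})

test_that("a bowl that exits the grid is refused with its extent", {
  spec <- transducer_spec()
  grid <- desk_grid()
  expect_error(make_bowl(spec, grid, focus_mm = c(10, 36, 69)), "clipped")
})

test_that("calibrate_u_from_s averages translations and rotations", {
  t1 <- rigid_transform(diag(3), c(1, 0, 0), "simulation", "ultrasound")
  t2 <- rigid_transform(diag(3), c(3, 0, 0), "simulation", "ultrasound")
  avg <- calibrate_u_from_s(list(t1, t2))
  expect_equal(avg$translation, c(2, 0, 0))

  t3 <- rigid_transform(rot_z(10), c(5, -2, 1), "simulation", "ultrasound")
  same <- calibrate_u_from_s(list(t3, t3, t3))
  expect_equal(as_matrix4(same), as_matrix4(t3), tolerance = 1e-9)

  # symmetric small-angle spread averages to the identity rotation
  eps <- 2
  rots <- list(rigid_transform(rot_z(eps), c(0, 0, 0), "simulation", "ultrasound"),
               rigid_transform(rot_z(-eps), c(0, 0, 0), "simulation", "ultrasound"),
               rigid_transform(diag(3), c(0, 0, 0), "simulation", "ultrasound"))
  avg2 <- calibrate_u_from_s(rots)
  expect_lt(max(abs(avg2$rotation - diag(3))), 1e-6)
})

test_that("the rotation average matches an independent chordal-mean oracle", {
  set.seed(22)
  base <- random_rotation()
  alignments <- lapply(1:3, function(i) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    rigid_transform(base %*% tfusnav:::axis_angle_rotation(ax, runif(1, 0.5, 3)),
                    rnorm(3), "simulation", "ultrasound")
  })
  avg <- calibrate_u_from_s(alignments)
  # oracle: minimize the summed squared Frobenius (chordal) distance over
  # an axis-angle perturbation of the returned rotation
  obj <- function(v) {
    r <- tfusnav:::axis_angle_rotation(v[1:3] / max(sqrt(sum(v[1:3]^2)), 1e-12),
                                       sqrt(sum(v[1:3]^2)) * 180 / pi) %*%
      avg$rotation
    sum(vapply(alignments,
               function(a) sum((r - a$rotation)^2), numeric(1)))
  }
  at0 <- obj(c(1e-9, 0, 0))
  opt <- optim(c(0.01, -0.01, 0.01), obj, method = "Nelder-Mead")
  expect_lt(at0, opt$value + 1e-6)
  # order invariance
  avg_rev <- calibrate_u_from_s(rev(alignments))
  expect_equal(as_matrix4(avg), as_matrix4(avg_rev), tolerance = 1e-9)
})

test_that("calibrate_u_from_s refuses outlier rotations", {
  t1 <- rigid_transform(diag(3), c(0, 0, 0), "simulation", "ultrasound")
  t2 <- rigid_transform(rot_z(45), c(0, 0, 0), "simulation", "ultrasound")
  expect_error(calibrate_u_from_s(list(t1, t2)), "outlier")
})

test_that("place_transducer re-rasterizes exactly under lattice translations", {
  spec <- transducer_spec(radius_of_curvature = 12, aperture_diameter = 16,
                          frequency = 1e6)
  grid <- sim_grid_spec(c(48, 48, 48), 1)
  m <- make_bowl(spec, grid, focus_mm = c(24, 24, 20))
  id <- rigid_transform(from = "simulation", to = "simulation")
  expect_identical(place_transducer(m, id)$bowl_mask, m$bowl_mask)

  sh <- rigid_transform(diag(3), c(3, -2, 4), "simulation", "simulation")
  m2 <- place_transducer(m, sh)
  idx1 <- which(m$bowl_mask, arr.ind = TRUE)
  idx2 <- which(m2$bowl_mask, arr.ind = TRUE)
  idx1s <- idx1 + rep(c(3, -2, 4), each = nrow(idx1))
  expect_equal(idx2[order(idx2[, 1], idx2[, 2], idx2[, 3]), ],
               idx1s[order(idx1s[, 1], idx1s[, 2], idx1s[, 3]), ])
})

test_that("a rotated cap stays hole-free and keeps its voxel count", {
  spec <- transducer_spec(radius_of_curvature = 12, aperture_diameter = 16,
                          frequency = 1e6)
  grid <- sim_grid_spec(c(48, 48, 48), 1)
  m <- make_bowl(spec, grid, focus_mm = c(24, 24, 24))
  rot <- rigid_transform(rot_x(30), c(24, 24, 24) - rot_x(30) %*% c(24, 24, 24),
                         "simulation", "simulation")
  m2 <- place_transducer(m, rot)
  expect_lt(abs(sum(m2$bowl_mask) / sum(m$bowl_mask) - 1), 0.10)
  # single 6-connected component: no aliasing holes splitting the surface
  seed <- which.max(m2$bowl_mask)
  comp <- tfusnav:::component_containing(m2$bowl_mask, seed, connectivity = 6)
  expect_equal(sum(comp), sum(m2$bowl_mask))
  # axis rotated with the pose
  expect_equal(m2$axis, as.numeric(rot_x(30) %*% c(0, 0, 1)), tolerance = 1e-9)
})
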