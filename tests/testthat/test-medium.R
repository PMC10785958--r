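test_that("resampling preserves data under identity and lattice shifts", {
  set.seed(33)
  arr <- array(rnorm(16^3), c(16, 16, 16))
  vol <- image_volume(arr, spacing = 1, frame = "image")
  grid <- sim_grid_spec(c(16, 16, 16), 1)
  out <- resample_to_grid(vol, grid)
  expect_equal(out$data, arr, tolerance = 1e-12)

  # pose translating the grid by exactly one voxel shifts data one index
  sh <- rigid_transform(diag(3), c(1, 0, 0), "simulation", "image")
  out1 <- resample_to_grid(vol, grid, world_pose = sh)
  expect_equal(out1$data[1:15, , ], arr[2:16, , ], tolerance = 1e-12)
  expect_true(all(out1$data[16, , ] == 0))   # background fill

  # downsampling a constant volume preserves the constant
  cvol <- image_volume(array(7, c(32, 32, 32)), spacing = 0.5, frame = "image")
  gdown <- sim_grid_spec(c(16, 16, 16), 1)
  outc <- resample_to_grid(cvol, gdown)
  expect_true(all(outc$data == 7))

  # nearest-neighbour keeps masks binary
  mask <- image_volume(array(as.numeric(arr > 0), c(16, 16, 16)),
                       spacing = 1, frame = "image")
  outm <- resample_to_grid(mask, grid, interpolation = "nearest")
  expect_true(all(outm$data %in% c(0, 1)))
})

test_that("otsu threshold matches an exhaustive between-class-variance scan", {
  # two-valued volume: threshold strictly between the values
  x <- c(rep(0, 500), rep(1500, 300))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0)
  expect_lt(thr, 1500)

  # bimodal Gaussian mixture: compare against a brute-force oracle
  set.seed(34)
  hu <- c(rnorm(4000, 0, 50), rnorm(2000, 1200, 100))
  thr2 <- otsu_threshold(hu)
  expect_gt(thr2, 300)
  expect_lt(thr2, 900)
  # oracle: scan all 256 bin edges, recomputing class stats from scratch;
  # exact ties (the empty gap between the modes) resolve to their midpoint
  edges <- seq(min(hu), max(hu), length.out = 257)
  mids <- (edges[-1] + edges[-257]) / 2
  cl <- findInterval(hu, edges, rightmost.closed = TRUE)
  cl[cl > 256] <- 256
  m <- mids[cl]
  sb <- vapply(edges[2:256], function(t) {
    lo <- m[hu <= t]; hi <- m[hu > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    w0 <- length(lo) / length(hu)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  tied <- which(sb >= max(sb) * (1 - 1e-12))
  best_t <- mean(edges[2:256][tied])
  bin_w <- diff(edges)[1]
  expect_lt(abs(thr2 - best_t), bin_w)
})

test_that("extract_skull finds the shell and warns on boneless volumes", {
  d <- c(24, 24, 24)
  hu <- array(0, d)
  hu[8:16, 8:16, 8:16] <- 1500
  ct <- image_volume(hu, spacing = 1, frame = "image", units = "HU")
  mask <- extract_skull(ct)
  expect_equal(array(as.logical(mask), d), hu > 750)
  expect_true(attr(mask, "threshold") > 0 && attr(mask, "threshold") < 1500)

  empty <- image_volume(array(0, d), spacing = 1, frame = "image", units = "HU")
  expect_warning(m2 <- extract_skull(empty), "empty mask")
  expect_false(any(m2))

  # noise-only (unimodal) volume: no bone-like mode
  set.seed(35)
  noise <- image_volume(array(rnorm(prod(d), 0, 30), d), spacing = 1,
                        frame = "image", units = "HU")
  expect_warning(m3 <- extract_skull(noise), "empty mask")
  expect_false(any(m3))
})

test_that("HU-porosity mapping is the clamped linear model", {
  expect_equal(hu_to_porosity(0), 1)
  expect_equal(hu_to_porosity(1000), 0)
  expect_equal(hu_to_porosity(500), 0.5)
  expect_equal(hu_to_porosity(-200), 1)     # clamped below
  expect_equal(hu_to_porosity(2500), 0)     # clamped above
  expect_error(hu_to_porosity(100, hu_max = 0), "positive")
  # porosity -> HU inverse identity on [0, hu_max]
  hu <- seq(0, 1000, by = 125)
  expect_equal((1 - hu_to_porosity(hu)) * 1000, hu, tolerance = 1e-12)
})

test_that("porosity maps to the reference property endpoints", {
  tab <- property_table()
  p0 <- porosity_to_properties(0, tab)
  expect_equal(p0$c, 3100)
  expect_equal(p0$rho, 2200)
  expect_equal(p0$alpha, 0.02)
  p1 <- porosity_to_properties(1, tab)
  expect_equal(p1$c, 1500)
  expect_equal(p1$rho, 1000)
  expect_equal(p1$alpha, 2.7)
  ph <- porosity_to_properties(0.5, tab)
  expect_equal(ph$c, 2300)
  expect_equal(ph$rho, 1600)
  expect_warning(porosity_to_properties(c(-0.1, 0.5)), "clamping")
})

test_that("build_medium assigns water, tissue and skull correctly", {
  grid <- sim_grid_spec(c(24, 24, 32), 1)
  tab <- property_table()
  med0 <- build_medium(grid = grid, table = tab)
  expect_true(all(med0$sound_speed == tab$c_water))
  expect_true(all(med0$density == tab$rho_water))
  expect_true(all(med0$absorption == 0))

  # cylindrical tissue mask: absorption only, speed/density stay water
  ax <- tfusnav:::grid_axes(grid)
  xg <- array(rep(ax[[1]] - 12, times = 24 * 32), c(24, 24, 32))
  yg <- array(rep(rep(ax[[2]] - 12, each = 24), times = 32), c(24, 24, 32))
  cyl <- xg^2 + yg^2 <= 64
  med1 <- build_medium(tissue_mask = cyl, grid = grid, table = tab)
  expect_true(all(med1$absorption[cyl] == tab$alpha_tissue))
  expect_true(all(med1$absorption[!cyl] == 0))
  expect_true(all(med1$sound_speed == tab$c_water))

  # skull shell: properties bounded by the table endpoints
  hu <- array(0, c(24, 24, 32))
  hu[, , 10:13] <- 1100
  hu[, , 11:12] <- 700
  ct <- image_volume(hu, spacing = 1, frame = "simulation", units = "HU")
  med2 <- suppressWarnings(   # cylinder deliberately overlaps the slab
    build_medium(ct = ct, tissue_mask = cyl, grid = grid, table = tab))
  sk <- med2$skull_mask
  expect_true(any(sk))
  expect_true(all(med2$sound_speed[sk] >= tab$c_water &
                  med2$sound_speed[sk] <= tab$c_bone))
  expect_true(all(med2$density[sk] >= tab$rho_water &
                  med2$density[sk] <= tab$rho_bone))
  expect_true(all(med2$absorption >= 0))
  # trabecular (lower HU) voxels are more porous, hence slower and lighter
  expect_lt(max(med2$sound_speed[hu == 700 & sk]),
            min(med2$sound_speed[hu == 1100 & sk]))
})

test_that("overlapping skull and tissue masks resolve to skull with a warning", {
  grid <- sim_grid_spec(c(16, 16, 16), 1)
  hu <- array(0, c(16, 16, 16))
  hu[6:10, 6:10, 6:10] <- 1400
  ct <- image_volume(hu, spacing = 1, frame = "simulation", units = "HU")
  tiss <- hu > 0
  expect_warning(med <- build_medium(ct = ct, tissue_mask = tiss, grid = grid),
                 "precedence")
  expect_true(all(med$sound_speed[med$skull_mask] > 1500))
  expect_false(any(med$tissue_mask & med$skull_mask))
})

test_that("property tables validate and accept overrides", {
  expect_error(property_table(alpha_bone_min = 3), "below")
  expect_error(property_table(nonsense = 1), "unknown")
  tab <- property_table(hu_max = 800)
  expect_equal(tab$hu_max, 800)
  # YAML override
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("c_bone: 2800", path)
  expect_equal(property_table(yaml_file = path)$c_bone, 2800)
})
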