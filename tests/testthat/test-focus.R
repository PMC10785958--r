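test_that("focus_max returns the argmax voxel centre in world mm", {
  grid <- small_grid(16, 1)
  arr <- array(0, rep(16, 3))
  arr[5, 9, 12] <- 1
  fld <- as_field(arr, grid)
  expect_equal(as.numeric(focus_max(fld)), c(4, 8, 11))   # 0-based * 1 mm
  expect_equal(attr(focus_max(fld), "index"), c(5L, 9L, 12L))
})

test_that("erosion guards against skull-surface maxima", {
  grid <- small_grid(24, 1)
  arr <- array(0, rep(24, 3))
  mask <- array(FALSE, rep(24, 3))
  mask[6:18, 6:18, 6:18] <- TRUE          # "tissue"
  arr[6, 12, 12] <- 2                     # hot spot on the mask boundary ("skull")
  arr[12, 12, 12] <- 1                    # interior focal spot
  fld <- as_field(arr, grid)
  # without a mask the boundary maximum wins
  expect_equal(attr(focus_max(fld), "index"), c(6L, 12L, 12L))
  # erosion excludes the boundary voxel; interior max selected
  got <- focus_max(fld, tissue_mask = mask, erosion_radius = 2)
  expect_equal(attr(got, "index"), c(12L, 12L, 12L))
  # radius 0 equals a plain masked argmax (boundary voxel is inside the mask)
  got0 <- focus_max(fld, tissue_mask = mask, erosion_radius = 0)
  expect_equal(attr(got0, "index"), c(6L, 12L, 12L))
  # oracle: erosion-masked argmax computed from first principles
  em <- tfusnav:::erode_mask(mask, 2)
  oracle <- arrayInd(which(em)[which.max(arr[em])], rep(24L, 3))
  expect_equal(attr(got, "index"), as.integer(oracle))
  # the selected point is strictly inside the tissue mask
  expect_true(em[got[1] + 1, got[2] + 1, got[3] + 1])
})

test_that("focus_max flags ties and empty erosions", {
  grid <- small_grid(16, 1)
  arr <- array(0, rep(16, 3))
  arr[4, 4, 4] <- 1
  arr[10, 10, 10] <- 1
  expect_warning(got <- focus_max(as_field(arr, grid)), "tied")
  expect_equal(attr(got, "index"), c(4L, 4L, 4L))   # lowest linear index

  mask <- array(FALSE, rep(16, 3))
  mask[8, 8, 8] <- TRUE
  arr2 <- array(1, rep(16, 3)) + 0 * arr
  arr2[1, 1, 1] <- 2
  expect_error(focus_max(as_field(arr2, grid), mask, erosion_radius = 3),
               "smaller erosion_radius")
  expect_error(focus_max(as_field(array(0, rep(16, 3)), grid)), "zero")
})

test_that("half-max centroid tracks the component containing the maximum", {
  grid <- small_grid(24, 1)
  ax <- seq(0, 23)
  g <- function(c0, s) {
    outer(outer(exp(-(ax - c0[1])^2 / (2 * s^2)),
                exp(-(ax - c0[2])^2 / (2 * s^2))),
          exp(-(ax - c0[3])^2 / (2 * s^2)))
  }
  # symmetric Gaussian blob: centroid at the blob centre within half a voxel
  blob <- g(c(10, 12, 14), 2.5)
  cen <- focus_centroid_halfmax(as_field(blob, grid))
  expect_lt(max(abs(cen - c(10, 12, 14))), 0.5)

  # two disjoint half-max blobs: only the component holding the global max counts
  two <- g(c(6, 6, 6), 1.8) + 0.9 * g(c(17, 17, 17), 1.8)
  cen2 <- focus_centroid_halfmax(as_field(two, grid))
  expect_lt(max(abs(cen2 - c(6, 6, 6))), 0.75)
  # oracle: connected component of the half-max segmentation at the argmax
  seg <- two >= max(two) / 2
  comp <- tfusnav:::component_containing(seg, which.max(two), 26)
  idx <- which(comp, arr.ind = TRUE)
  expect_equal(cen2, as.numeric(colMeans(idx - 1)), tolerance = 1e-9)

  # uniform field: centroid at the grid centre
  cu <- focus_centroid_halfmax(as_field(array(1, rep(24, 3)), grid))
  expect_equal(cu, rep(mean(ax), 3), tolerance = 1e-9)
})

test_that("error decomposition is Pythagorean and axis-aware", {
  expect_equal(decompose_error(c(3, 4, 0), c(0, 0, 0), c(0, 0, 1)),
               c(total = 5, axial = 0, lateral = 5))
  expect_equal(decompose_error(c(0, 0, 2), c(0, 0, 0), c(0, 0, 1)),
               c(total = 2, axial = 2, lateral = 0))
  expect_warning(out <- decompose_error(c(1, 1, 1), c(0, 0, 0), c(0, 0, 2)),
                 "normalizing")
  expect_equal(out[["axial"]], 1)

  set.seed(55)
  for (i in 1:200) {
    a <- rnorm(3, 0, 20); b <- rnorm(3, 0, 20)
    ax2 <- rnorm(3); ax2 <- ax2 / sqrt(sum(ax2^2))
    d <- decompose_error(a, b, ax2)
    expect_lt(abs(d[["total"]]^2 - d[["axial"]]^2 - d[["lateral"]]^2), 1e-9)
    expect_equal(d[["total"]], sqrt(sum((a - b)^2)), tolerance = 1e-9)
  }
})

test_that("vector_correction translates the pose by measured minus predicted", {
  pose <- rigid_transform(rot_z(15), c(10, -5, 30), "simulation", "image")
  same <- vector_correction(pose, c(1, 2, 3), c(1, 2, 3))
  expect_equal(as_matrix4(same), as_matrix4(pose))
  shifted <- vector_correction(pose, c(0, 0, 0), c(2, -1, 3))
  expect_equal(shifted$translation, pose$translation + c(2, -1, 3))
  expect_equal(shifted$rotation, pose$rotation)
})

test_that("focus reports carry consistent metrics and serialize", {
  rep1 <- focus_report(predicted = c(1, 0, 0), simulated = c(0, 1, 0),
                       measured = c(0, 0, 1), axis = c(0, 0, 1),
                       simulated_updated = c(0, 0, 1.5))
  for (m in rep1$metrics)
    expect_lt(abs(m[["total"]]^2 - m[["axial"]]^2 - m[["lateral"]]^2), 1e-9)
  expect_equal(rep1$metrics$Error_SimUpdated_ARFI[["total"]], 0.5)
  df <- as.data.frame(rep1)
  expect_equal(nrow(df), 4)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_focus_report(rep1, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$metrics$TRE_Opti_ARFI$total,
               rep1$metrics$TRE_Opti_ARFI[["total"]], tolerance = 1e-8)
  expect_equal(nrow(utils::read.csv(cp)), 4)
})
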