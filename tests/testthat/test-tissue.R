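test_that("homogeneous volumes are constant and validated", {
  vol <- homogeneous_volume(100, 0.5, 0.123)
  expect_equal(dim(vol$sigma), c(200, 200, 200))
  expect_true(all(vol$sigma == 0.123))
  expect_error(homogeneous_volume(100, 0.5, 0), "positive")
  expect_error(homogeneous_volume(40, 0.5, 0.123), ">= 60")
})

test_that("intensity classification interpolates between class means", {
  means <- c(wm = 80, gm = 140, blood = 220, csf = 280)
  img <- array(c(80, 140, 220, 280, 110, 50, 400, 250), c(2, 2, 2))
  cv <- classify_intensities(img, means, voxel_mm = 0.5)
  expect_equal(cv$sigma[1, 1, 1], 0.075)   # at the WM mean
  expect_equal(cv$sigma[2, 1, 1], 0.123)   # at the GM mean
  expect_equal(cv$sigma[1, 2, 1], 0.7)     # blood
  expect_equal(cv$sigma[2, 2, 1], 2.0)     # CSF
  # midpoint of WM and GM means -> (0.075 + 0.123)/2 = 0.099
  expect_equal(cv$sigma[1, 1, 2], 0.099)
  # clamped outside the extreme means
  expect_equal(cv$sigma[2, 1, 2], 0.075)
  expect_equal(cv$sigma[1, 2, 2], 2.0)
  expect_equal(cv$class_map[1, 1, 1], "wm")
  expect_equal(cv$class_map[1, 1, 2], "mixed")
  expect_error(classify_intensities(img, c(gm = 100, wm = 100)),
               "degenerate")
})

test_that("classification is monotone in intensity between WM and GM", {
  means <- c(wm = 80, gm = 140)
  xs <- seq(60, 160, by = 1)
  cv <- classify_intensities(array(xs, c(length(xs), 1, 1)), means)
  expect_false(is.unsorted(as.numeric(cv$sigma)))
  # idempotent: re-running on the same input gives the same sigma
  cv2 <- classify_intensities(array(xs, c(length(xs), 1, 1)), means)
  expect_identical(cv$sigma, cv2$sigma)
})

test_that("apply_lead overlays PES, metal and insulator correctly", {
  lead <- build_lead("3389")
  g <- fv_grid(6.25, 100, fine_mm = 0.2, fine_halfwidth_mm = 2)
  occ <- voxelize_lead(lead, g)
  sig <- array(0.123, g$dim)
  emb <- apply_lead(sig, occ)
  expect_true(all(emb$sigma[occ$labels == 1L] == 0.075))
  expect_true(all(is.na(emb$sigma[occ$labels == 2L])))
  expect_true(all(emb$sigma[occ$labels >= 10L] == 1e6))
  expect_true(all(emb$sigma[occ$labels == 0L] == 0.123))
  expect_error(apply_lead(array(0.1, c(2, 2, 2)), occ), "mismatch")
})

test_that("labelled PES volume matches the analytic shell volume", {
  lead <- build_lead("3389")
  g <- fv_grid(6.25, 100, fine_mm = 0.1, fine_halfwidth_mm = 3)
  occ <- voxelize_lead(lead, g)
  co <- dbsfield:::grid_coords(g)
  vols <- dbsfield:::grid_cell_volumes(g)
  sel <- occ$labels == 1L & co$z > 4 & co$z < 8
  shell <- pi * ((1.27 / 2 + 0.25)^2 - (1.27 / 2)^2) * 4
  expect_equal(sum(vols[sel]), shell, tolerance = 0.1)
})

test_that("conductivity volumes round-trip through NIfTI-1", {
  means <- c(wm = 80, gm = 140, blood = 220, csf = 280)
  set.seed(42)
  img <- array(runif(10^3, 50, 300), c(10, 10, 10))
  cv <- classify_intensities(img, means, voxel_mm = 0.5)
  f <- tempfile(fileext = ".nii.gz")
  fc <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(cv, f, fc)
  back <- read_intensity_nifti(f)
  expect_equal(as.numeric(back), as.numeric(cv$sigma), tolerance = 1e-6)
  expect_equal(unname(RNifti::pixdim(back)), rep(0.5, 3))
  cls <- read_intensity_nifti(fc)
  expect_true(all(as.integer(cls) %in% 0:5))
  unlink(c(f, fc))
})
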