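test_that("isolevel volume and extension match the sphere closed form", {
  fx <- sphere_fixture()
  L <- 0.2
  rL <- sqrt(fx$V0 * fx$a / (1 - fx$a / fx$R) / L)
  vol_an <- 4 * pi / 3 * (rL^3 - fx$a^3)
  expect_lt(abs(isosurface_volume(fx$as_solution, L) / vol_an - 1), 0.03)
  for (p in c("axial", "sagittal", "coronal")) {
    expect_lt(abs(max_extension(fx$as_solution, p, L) / rL - 1), 0.03)
  }
})

test_that("relative differences follow the stated convention", {
  expect_equal(relative_difference(118.0, 144), -18.06, tolerance = 1e-3)
  expect_equal(relative_difference(177.4, 144), 23.19, tolerance = 1e-3)
  expect_equal(relative_difference(5, 5), 0)
  expect_error(relative_difference(1, 0), "zero baseline")
})

test_that("extension grows with amplitude and contours are well-formed", {
  base <- hom_unit()
  e3 <- max_extension(at_amplitude(base, "voltage", 3))
  e2 <- max_extension(at_amplitude(base, "voltage", 2))
  expect_gte(e3, e2)
  ic <- isocontours(at_amplitude(base, "voltage", 3), "axial")
  expect_named(ic, c("plane", "piece", "u", "v"))
  expect_gt(nrow(ic), 20)
  # outermost axial isocontour of a ring contact is nearly circular (the
  # zero-field lead interior contributes an inner contour around the shaft)
  rad_by_piece <- tapply(sqrt(ic$u^2 + ic$v^2), ic$piece, mean)
  outer_piece <- names(which.max(rad_by_piece))
  r <- sqrt(ic$u^2 + ic$v^2)[ic$piece == as.integer(outer_piece)]
  expect_lt((max(r) - min(r)) / mean(r), 0.05)
  expect_error(isocontours(at_amplitude(base, "voltage", 3),
                           "axial", isolevel = 50), "no 50")
})

test_that("the isolevel volume rejects a domain-clipping isosurface", {
  expect_error(isosurface_volume(hom_unit(), 1e-7), "boundary")
})

test_that("ring configurations are azimuthally symmetric, steering is not", {
  ring <- at_amplitude(hom_unit(), "voltage", 3)
  sp <- steering_profile(ring)
  expect_lt(sp$asymmetry_index, 1.05)
  expect_false(sp$steering_visible)
})
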