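small_spec <- function(seed = 7, ...) {
  synthetic_brain_spec(side_mm = 60, voxel_mm = 1, seed = seed, ...)
}

test_that("generation is deterministic for a given spec and seed", {
  v1 <- generate_brain(small_spec())
  v2 <- generate_brain(small_spec())
  expect_identical(v1$sigma, v2$sigma)
  expect_identical(v1$class_map, v2$class_map)
  v3 <- generate_brain(small_spec(seed = 8))
  expect_false(identical(v1$sigma, v3$sigma))
})

test_that("a degenerate spec yields homogeneous grey matter", {
  sp <- small_spec(wm_tract_count = 0, vessel_count = 0,
                   csf_gap = list(enable = FALSE),
                   partial_volume_blur_mm = 0)
  v <- generate_brain(sp)
  expect_true(all(v$sigma == 0.123))
  expect_true(all(v$class_map == "gm"))
})

test_that("generated volumes contain all tissue classes and partial volumes", {
  v <- generate_brain(synthetic_brain_spec(side_mm = 80, voxel_mm = 0.5,
                                           seed = 3))
  cls <- table(v$class_map)
  expect_true(all(c("gm", "wm", "csf", "mixed") %in% names(cls)))
  expect_gt(cls[["wm"]] / sum(cls), 0.01)
  # conductivities stay in the physical range of the class table
  expect_gte(min(v$sigma), 0.075)
  expect_lte(max(v$sigma), 2.0)
  # partial-volume voxels: values strictly between the class conductivities
  pure <- c(0.075, 0.123, 0.7, 2.0)
  is_pure <- Reduce(`|`, lapply(pure, function(p) abs(v$sigma - p) < 1e-6))
  expect_gt(mean(!is_pure), 0.01)
  # histogram modes sit at the class conductivities
  expect_gt(mean(abs(v$sigma - 0.123) < 1e-6), 0.5)   # GM background
  expect_gt(sum(abs(v$sigma - 0.075) < 1e-6), 100)    # pure WM interior
  expect_gt(sum(abs(v$sigma - 2.0) < 1e-6), 100)      # pure CSF interior
})

test_that("the centre region around the lead is below grey-matter sigma", {
  v <- generate_brain(synthetic_brain_spec(side_mm = 80, voxel_mm = 0.5,
                                           seed = 1))
  n <- dim(v$sigma)[1]
  ctr <- (n %/% 2 - 6):(n %/% 2 + 6)
  expect_lt(mean(v$sigma[ctr, ctr, ctr]), 0.123)
})

test_that("virtual targets are 4 mm apart and respect the margin", {
  sp <- synthetic_brain_spec(side_mm = 100, voxel_mm = 1)
  tg <- virtual_targets(sp)
  expect_equal(sqrt(sum((tg$zi - tg$vim)^2)), 4)
  expect_error(virtual_targets(sp, margin_mm = 49.5), "margin")
})
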