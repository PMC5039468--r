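test_that("potential line sets follow the sampling convention", {
  sol <- at_amplitude(hom_unit(), "voltage", 3)
  ln <- extract_potential_lines(sol, "posterior")
  expect_equal(ncol(ln$potential_V), 62)
  expect_equal(diff(ln$radius_mm)[1], 0.1)
  expect_equal(ln$radius_mm[1], sol$lead$body_diameter / 2)  # lead surface
  # homogeneous model: axisymmetric, so all four directions agree
  la <- extract_potential_lines(sol, "anterior")
  lm <- extract_potential_lines(sol, "medial")
  expect_equal(ln$potential_V, la$potential_V, tolerance = 1e-6)
  expect_equal(ln$potential_V, lm$potential_V, tolerance = 1e-6)
  # profiles decay with radial distance at the contact level
  mid <- which.min(abs(ln$z_mm - ln$center_z))
  expect_false(is.unsorted(rev(ln$potential_V[mid, ])))
  expect_error(extract_potential_lines(sol, "posterior", n_lines = 5000),
               "beyond the solver grid")
})

test_that("fibre morphometry interpolates the published table", {
  g57 <- mrg_fibre_geometry(5.7)
  expect_equal(g57$internode_um, 500)
  expect_equal(g57$node_diam_um, 1.9)
  expect_equal(g57$axon_diam_um, 3.4)
  expect_equal(g57$lamellae, 80)
  expect_equal(mrg_fibre_geometry(7.3)$internode_um, 750)
  # monotone growth with diameter
  ds <- seq(1.5, 7.5, by = 0.5)
  internodes <- vapply(ds, function(d) mrg_fibre_geometry(d)$internode_um,
                       numeric(1))
  expect_false(is.unsorted(internodes))
  expect_error(axon_spec(1.0), "1.5")
  expect_error(axon_spec(8.0), "7.5")
})

test_that("activation distance is zero without drive and stable under dt/2", {
  sol <- at_amplitude(hom_unit(), "voltage", 3)
  ln <- extract_potential_lines(sol, "posterior")
  expect_equal(activation_distance(ln, axon_spec(4), 0), 0)
  d1 <- activation_distance(ln, axon_spec(4, dt_us = 1), 3)
  d2 <- activation_distance(ln, axon_spec(4, dt_us = 0.5), 3)
  expect_equal(d1, d2, tolerance = 0.101 / d1)  # within one line spacing
})

test_that("activation distance is monotone in amplitude and diameter", {
  tb <- sweep_table()
  amps <- attr(tb, "amplitudes")
  dcols <- sprintf("dist_%g", amps)
  # along amplitude, every curve is non-decreasing
  m <- as.matrix(tb[, dcols])
  expect_true(all(m[, -1] - m[, -ncol(m)] >= -1e-9))
  # along diameter, at fixed everything else
  keys <- interaction(tb$lead, tb$tissue_model, tb$mode, tb$direction)
  for (k in levels(keys)) {
    sub <- tb[keys == k, ]
    sub <- sub[order(sub$diameter_um), ]
    for (dc in dcols) {
      expect_true(all(diff(sub[[dc]]) >= -1e-9))
    }
  }
})

test_that("the built-in sweep has the full factorial structure", {
  tb <- sweep_table()
  expect_equal(nrow(tb), 832)  # 4 leads x 2 tissues x 2 modes x 4 dir x 13
  expect_equal(length(unique(tb$lead)), 4)
  expect_equal(length(unique(tb$diameter_um)), 13)
  lg <- activation_long(tb)
  expect_equal(nrow(lg), 8320)
  expect_named(lg, c("lead", "tissue_model", "mode", "direction",
                     "diameter_um", "amplitude",
                     "activation_distance_mm"))
  # homogeneous rows: the four directions agree within one line spacing
  hom <- tb[tb$tissue_model == "homogeneous" & tb$lead == "3389" &
              tb$mode == "voltage" & tb$diameter_um == 4, ]
  expect_equal(nrow(hom), 4)
  expect_lt(max(hom$dist_3) - min(hom$dist_3), 0.101)
  # heterogeneous rows: directions differ somewhere in the table
  het <- tb[tb$tissue_model == "heterogeneous" & tb$mode == "voltage" &
              tb$diameter_um == 4, ]
  spread <- tapply(het$dist_3, het$lead, function(x) max(x) - min(x))
  expect_gt(max(spread), 0.05)
})

test_that("the field at the activation distance is nearly constant", {
  # near-constancy across amplitudes is what justifies a single isolevel:
  # every EF-at-activation value over 1-5 V stays within the same +-25%
  # band around the sweep median that the isolevel itself is quoted to
  tb <- sweep_table()
  sols <- sweep_solutions()
  sol <- sols[["3389|homogeneous|voltage"]]
  row <- tb[tb$lead == "3389" & tb$tissue_model == "homogeneous" &
              tb$mode == "voltage" & tb$direction == "posterior" &
              tb$diameter_um == 4, ]
  amps <- seq(1, 5, by = 0.5)
  zc <- sol$contact_center_local[3]
  efs <- vapply(amps, function(a) {
    d <- row[[sprintf("dist_%g", a)]]
    e <- dbsfield:::grid_interp(sol$grid, sol$ef, cbind(0, -d, zc))
    e * a / sol$amplitude
  }, numeric(1))
  expect_true(all(abs(efs / stats::median(efs) - 1) < 0.25))
})

test_that("calibrated isolevel decreases for larger fibres", {
  tb <- sweep_table()
  sols <- sweep_solutions()
  sub <- list(tb[tb$tissue_model == "homogeneous" & tb$mode == "voltage" &
                   tb$lead == "3389", ])[[1]]
  attr(sub, "amplitudes") <- attr(tb, "amplitudes")
  class(sub) <- class(tb)
  c4 <- calibrate_isolevel(sub, sols, 4)
  c65 <- calibrate_isolevel(sub, sols, 6.5)
  expect_lt(c65, c4)
  # doubling the amplitudes leaves the calibration at the same order
  expect_error(calibrate_isolevel(sub, sols, 5.25), "not in the table")
})
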