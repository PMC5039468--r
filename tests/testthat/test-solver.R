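# small concentric-sphere problem for cheap scaling checks
tiny_sphere <- function(sigma_S_per_m, h = 0.25) {
  g <- fv_grid(0, 60, fine_mm = h, fine_halfwidth_mm = 2, coarse_mm = 4)
  co <- dbsfield:::grid_coords(g)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  lab <- array(0L, g$dim)
  lab[r <= 1] <- 1L
  lab[r >= 25] <- 3L
  list(grid = g, sigma = array(sigma_S_per_m, g$dim), labels = lab)
}

test_that("the solver matches the concentric-sphere closed form within 3%", {
  fx <- sphere_fixture()
  expect_lt(abs(fx$sol$total_current_mA / fx$i_analytic_mA - 1), 0.03)
  # potential along an oblique ray, beyond 2a from the surface
  for (r in c(1.5, 2, 3, 4)) {
    p <- dbsfield:::grid_interp(fx$grid, fx$sol$potential,
                                matrix(r / sqrt(3), 1, 3))
    expect_lt(abs(p / fx$v_analytic(r) - 1), 0.03)
  }
})

test_that("total current is linear in conductivity and amplitude", {
  t1 <- tiny_sphere(0.123)
  t2 <- tiny_sphere(0.246)
  s1 <- solve_labelled(t1$grid, t1$sigma, t1$labels, amplitude = 1)
  s2 <- solve_labelled(t2$grid, t2$sigma, t2$labels, amplitude = 1)
  expect_equal(s2$total_current_mA, 2 * s1$total_current_mA,
               tolerance = 1e-8)
  s3 <- solve_labelled(t1$grid, t1$sigma, t1$labels, amplitude = 2)
  expect_equal(s3$total_current_mA, 2 * s1$total_current_mA,
               tolerance = 1e-10)
  # zero amplitude: identically zero field
  s0 <- solve_labelled(t1$grid, t1$sigma, t1$labels, amplitude = 0)
  expect_true(all(abs(s0$potential) < 1e-14, na.rm = TRUE))
})

test_that("voltage-mode solutions obey the maximum principle", {
  sol <- hom_unit()
  v <- sol$potential
  expect_gte(min(v, na.rm = TRUE), -1e-8)
  expect_lte(max(v, na.rm = TRUE), sol$amplitude + 1e-8)
  expect_true(all(sol$ef >= 0, na.rm = TRUE))
})

test_that("net flux through a source-free box vanishes", {
  sol <- hom_unit()
  # box in tissue, to one side of the lead, away from the contact
  flux <- box_flux(sol, c(2, 5), c(-1.5, 1.5), c(3.5, 9))
  itot <- sol$total_current_mA * 1e-3
  expect_lt(abs(flux) / itot, 1e-3)
})

test_that("current mode reproduces the voltage-mode field (duality)", {
  base <- hom_unit()
  i_eq <- equivalent_current(base)
  dual <- at_amplitude(base, "current", i_eq)
  expect_equal(dual$potential, base$potential, tolerance = 1e-12)
  expect_equal(dual$total_current_mA, i_eq)
  expect_equal(dual$contact_potential_V, base$amplitude,
               tolerance = 1e-12)
  # a fresh current-mode solve agrees with the rescaled voltage solve
  lead <- build_lead("3389")
  opts <- solver_options(fine_mm = 0.25, fine_halfwidth_mm = 3)
  sv <- solve_field(test_volumes()$homogeneous, lead,
                    standard_config(lead, "ring_equivalent", "voltage", 3),
                    opts)
  si <- solve_field(test_volumes()$homogeneous, lead,
                    standard_config(lead, "ring_equivalent", "current",
                                    sv$total_current_mA), opts)
  expect_equal(si$potential, sv$potential, tolerance = 1e-6)
})

test_that("the isolevel volume is mesh-converged at the study resolution", {
  v_coarse <- isosurface_volume(at_amplitude(hom_unit(), "voltage", 3))
  v_fine <- isosurface_volume(hom_fine())
  expect_lt(abs(v_fine - v_coarse) / v_fine, 0.02)
})

test_that("solving is independent of the lead axis orientation", {
  opts <- solver_options(fine_mm = 0.25, fine_halfwidth_mm = 2)
  vol <- test_volumes()$homogeneous
  sols <- lapply(list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3)),
                 function(ax) {
    lead <- build_lead("3389", axis = ax)
    solve_field(vol, lead, standard_config(lead, "ring_equivalent",
                                           "voltage", 3), opts)
  })
  expect_identical(sols[[1]]$potential, sols[[2]]$potential)
  expect_identical(sols[[1]]$potential, sols[[3]]$potential)
})

test_that("heterogeneous volumes are sampled through the lead frame", {
  # sigma varies linearly with world x; a lead along +x must see that
  # gradient along its own axis
  n <- 50
  sig <- array(rep(seq(0.1, 0.2, length.out = n), times = n * n),
               c(n, n, n))
  vol <- dbsfield:::new_conductivity_volume(sig, voxel_mm = 2,
                                            origin = rep(-49, 3))
  lead <- build_lead("3389", tip_position = c(-20, 0, 0),
                     axis = c(1, 0, 0))
  g <- fv_grid(6.25, 60, fine_mm = 0.25, fine_halfwidth_mm = 2)
  samp <- dbsfield:::sample_sigma(vol, lead, g)
  co <- dbsfield:::grid_coords(g)
  # world x = tip_x + local z
  expected <- approx(seq(-49, 49, by = 2), seq(0.1, 0.2, length.out = n),
                     xout = pmin(pmax(-20 + co$z, -49), 49),
                     rule = 2)$y
  expect_lt(max(abs(samp - expected)), 0.002)  # nearest-voxel quantisation
})

test_that("solver failure modes raise informative errors", {
  t1 <- tiny_sphere(0.123)
  expect_error(solve_labelled(t1$grid, t1$sigma, t1$labels, maxit = 2),
               "did not converge")
  lead <- build_lead("3389")
  expect_error(
    solve_field(test_volumes()$homogeneous, lead,
                stimulus_config(99L, "voltage", 3),
                solver_options(fine_mm = 0.25, fine_halfwidth_mm = 2)),
    "no active contacts")
})

test_that("the grounded boundary at 100 mm is effectively far", {
  vol60 <- homogeneous_volume(60, 1.0, 0.123)
  lead <- build_lead("3389")
  s60 <- solve_field(vol60, lead,
                     standard_config(lead, "ring_equivalent", "voltage", 3),
                     opts_coarse())
  s100 <- at_amplitude(hom_unit(), "voltage", 3)
  expect_lt(abs(s60$total_current_mA - s100$total_current_mA) /
              s100$total_current_mA, 0.05)
})
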