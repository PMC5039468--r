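# Shared fixtures, computed once per test run and reused across files.
# Everything is generated in code (seeded); nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

opts_coarse <- function() solver_options(fine_mm = 0.2)

# study volumes: homogeneous grey matter + seeded synthetic heterogeneous
test_volumes <- function() cached("vols", campaign_volumes(seed = 1))

# 3389, homogeneous, ring contact, unit voltage, 0.2 mm fine grid
hom_unit <- function() cached("hom_unit", {
  lead <- build_lead("3389")
  solve_field(test_volumes()$homogeneous, lead,
              standard_config(lead, "ring_equivalent", "voltage", 1),
              opts_coarse())
})

# same geometry at the study resolution (0.1 mm), 3 V
hom_fine <- function() cached("hom_fine", {
  lead <- build_lead("3389")
  solve_field(test_volumes()$homogeneous, lead,
              standard_config(lead, "ring_equivalent", "voltage", 3),
              solver_options(fine_mm = 0.1))
})

# concentric-sphere analytic fixture: source radius a at V0, grounded
# shell at R, homogeneous sigma; exact solution V = V0*a*(1/r-1/R)/(1-a/R)
sphere_fixture <- function() cached("sphere", {
  a <- 1; R <- 45; V0 <- 1; sig <- 0.123
  g <- fv_grid(0, 100, fine_mm = 0.06, fine_halfwidth_mm = 2.8,
               coarse_mm = 5, grow = 1.4)
  co <- dbsfield:::grid_coords(g)
  r <- sqrt(co$x^2 + co$y^2 + co$z^2)
  lab <- array(0L, g$dim)
  lab[r <= a] <- 1L
  lab[r >= R] <- 3L
  sol <- solve_labelled(g, array(sig, g$dim), lab, amplitude = V0)
  fake <- structure(list(
    grid = g, potential = sol$potential, ef = sol$ef,
    lead = list(body_diameter = 2 * a), contact_center_local = c(0, 0, 0),
    mode = "voltage", amplitude = V0, config = list(label = "sphere"),
    scale = 1, unit_current_A = sol$unit_current_A,
    total_current_mA = sol$total_current_mA), class = "field_solution")
  list(a = a, R = R, V0 = V0, sig = sig, grid = g, sol = sol,
       as_solution = fake,
       v_analytic = function(r) V0 * a * (1 / r - 1 / R) / (1 - a / R),
       i_analytic_mA = 4 * pi * sig * 1e-3 * a * V0 / (1 - a / R) * 1e3)
})

# unit solves for all four leads in both tissue models (16 keyed entries)
sweep_solutions <- function() cached("sweep_sols", {
  neuron_campaign_solutions(test_volumes(), opts_coarse())
})

# the full built-in activation sweep (832 curves)
sweep_table <- function() cached("sweep_table", {
  run_sweep(sweep_solutions())
})

# the full built-in EF campaign, bookkeeping resolution
ef_campaign <- function() cached("ef_campaign", {
  run_campaign(campaign_spec("ef"), test_volumes(),
               solver_options(fine_mm = 0.25))
})

# net outward current (A) through an axis-aligned box of cell indices;
# recomputes the discrete face conductances of the scheme
box_flux <- function(sol, xr, yr, zr) {
  g <- sol$grid
  pot <- sol$potential
  sig <- dbsfield:::sample_sigma(test_volumes()$homogeneous, sol$lead, g)
  MM <- 1e-3
  ix <- which(g$x$centers >= xr[1] & g$x$centers <= xr[2])
  iy <- which(g$y$centers >= yr[1] & g$y$centers <= yr[2])
  iz <- which(g$z$centers >= zr[1] & g$z$centers <= zr[2])
  gface <- function(s1, s2, d1, d2, area) {
    area / (0.5 * d1 / s1 + 0.5 * d2 / s2)
  }
  flux <- 0
  for (side in c(-1, 1)) {
    i <- if (side < 0) min(ix) else max(ix)
    io <- i + side
    for (j in iy) for (k in iz) {
      gf <- gface(sig[i, j, k], sig[io, j, k], g$x$widths[i] * MM,
                  g$x$widths[io] * MM,
                  g$y$widths[j] * g$z$widths[k] * MM^2)
      flux <- flux + gf * (pot[i, j, k] - pot[io, j, k])
    }
    j <- if (side < 0) min(iy) else max(iy)
    jo <- j + side
    for (i2 in ix) for (k in iz) {
      gf <- gface(sig[i2, j, k], sig[i2, jo, k], g$y$widths[j] * MM,
                  g$y$widths[jo] * MM,
                  g$x$widths[i2] * g$z$widths[k] * MM^2)
      flux <- flux + gf * (pot[i2, j, k] - pot[i2, jo, k])
    }
    k <- if (side < 0) min(iz) else max(iz)
    ko <- k + side
    for (i2 in ix) for (j2 in iy) {
      gf <- gface(sig[i2, j2, k], sig[i2, j2, ko], g$z$widths[k] * MM,
                  g$z$widths[ko] * MM,
                  g$x$widths[i2] * g$y$widths[j2] * MM^2)
      flux <- flux + gf * (pot[i2, j2, k] - pot[i2, j2, ko])
    }
  }
  flux
}
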