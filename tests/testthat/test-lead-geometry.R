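test_that("the four lead designs reproduce the published contact areas", {
  l3389 <- build_lead("3389")
  expect_equal(nrow(l3389$contacts), 4)
  expect_equal(l3389$body_diameter, 1.27)
  expect_true(all(abs(l3389$contacts$area - 6) / 6 < 0.03))

  l6148 <- build_lead("6148")
  expect_equal(l6148$body_diameter, 1.4)
  expect_true(all(abs(l6148$contacts$area[2:4] - 6.6) / 6.6 < 0.03))
  expect_equal(l6148$contacts$shape[1], "ring_tip")
  expect_equal(l6148$contacts$axial_hi[1], 3)  # 3 mm distal covers the tip

  l6180 <- build_lead("6180")
  expect_equal(nrow(l6180$contacts), 8)
  seg <- l6180$contacts[l6180$contacts$shape == "split_segment", ]
  expect_equal(nrow(seg), 6)
  expect_true(all(abs(seg$area - 1.8) < 1e-9))

  lss <- build_lead("SureStim1")
  expect_equal(nrow(lss$contacts), 40)
  expect_true(all(abs(lss$contacts$area - 0.39) / 0.39 < 0.03))
  # 10 rows of 4 at alternating azimuths
  expect_equal(length(unique(lss$contacts$axial_center)), 10)
})

test_that("contacts on one lead do not overlap axially or angularly", {
  for (m in c("3389", "6148", "6180", "SureStim1")) {
    ct <- build_lead(m)$contacts
    for (i in seq_len(nrow(ct) - 1)) {
      for (j in (i + 1):nrow(ct)) {
        ax_olap <- ct$axial_lo[j] < ct$axial_hi[i] &&
          ct$axial_lo[i] < ct$axial_hi[j]
        if (!ax_olap) next
        dth <- abs(((ct$angular_center[i] - ct$angular_center[j] + 180) %%
                      360) - 180)
        halfwidth <- function(k) {
          if (ct$shape[k] == "ellipse") {
            ct$ax_azimuthal[k] / (build_lead(m)$body_diameter / 2) *
              180 / pi
          } else ct$arc_deg[k] / 2
        }
        expect_gt(dth, halfwidth(i) + halfwidth(j))
      }
    }
  }
})

test_that("standard configurations select the documented contact sets", {
  l3389 <- build_lead("3389")
  cfg <- standard_config(l3389, "ring_equivalent")
  expect_equal(cfg$active_contacts, 2L)       # third contact, C2
  expect_equal(cfg$active_labels, "C2")
  expect_equal(cfg$amplitude, 3)              # voltage default
  expect_equal(standard_config(l3389, "ring_equivalent", "current")$amplitude,
               3.4)
  expect_equal(active_area(l3389, cfg), 6, tolerance = 0.03)

  l6148 <- build_lead("6148")
  cfg <- standard_config(l6148, "ring_equivalent")
  expect_equal(cfg$active_contacts, 2L)       # vendor C3
  expect_equal(cfg$active_labels, "C3")
  expect_equal(active_area(l6148, cfg), 6.6, tolerance = 0.03)

  l6180 <- build_lead("6180")
  cfg <- standard_config(l6180, "ring_equivalent")
  expect_equal(cfg$active_contacts, 4:6)      # third ring, C5 C6 C7
  expect_equal(cfg$active_labels, c("C5", "C6", "C7"))
  expect_equal(active_area(l6180, cfg), 5.4, tolerance = 1e-6)
  expect_equal(standard_config(l6180, "steering")$active_contacts, 4L)

  lss <- build_lead("SureStim1")
  cfg <- standard_config(lss, "ring_equivalent")
  expect_length(cfg$active_contacts, 8)       # rows 6 and 7
  expect_equal(active_area(lss, cfg), 3.12, tolerance = 0.03)
  st <- standard_config(lss, "steering")
  expect_length(st$active_contacts, 4)        # diamond
  expect_equal(active_area(lss, st), 1.6, tolerance = 0.05)
})

test_that("invalid lead or scheme requests fail loudly", {
  expect_error(build_lead("9999"), "unknown lead model")
  expect_error(build_lead("3389", axis = c(0, 0, 2)), "unit vector")
  expect_error(standard_config(build_lead("3389"), "steering"),
               "not applicable")
  expect_error(stimulus_config(integer(0), "voltage", 3))
  expect_error(stimulus_config(2L, "voltage", -1))
})

test_that("voxelization labels the PES shell and is frame-independent", {
  lead <- build_lead("3389")
  g <- fv_grid(6.25, 100, fine_mm = 0.1, fine_halfwidth_mm = 3)
  occ <- voxelize_lead(lead, g)
  co <- dbsfield:::grid_coords(g)
  r <- sqrt(co$x^2 + co$y^2)
  pes <- occ$labels == 1L
  band <- pes & co$z > 4 & co$z < 8
  # shell spans body surface to +0.25 mm: outer diameter 1.77 mm
  expect_lt(max(r[band]), 1.77 / 2 + g$fine_mm)
  expect_gt(max(r[band]), 1.77 / 2 - g$fine_mm)
  expect_gt(min(r[band]), 1.27 / 2 - g$fine_mm)

  # occupancy is computed in the lead frame: rotating the lead axis leaves
  # the labelling identical
  lead_x <- build_lead("3389", axis = c(1, 0, 0))
  expect_identical(occ$labels, voxelize_lead(lead_x, g)$labels)

  # lead must be inside the grid
  g_off <- fv_grid(60, 100, fine_mm = 0.25, fine_halfwidth_mm = 3)
  expect_error(voxelize_lead(lead, g_off), "inside the grid")
})

test_that("voxelized contact area converges to the analytic area", {
  lead <- build_lead("3389")
  a_true <- lead$contacts$area[3]
  g1 <- fv_grid(6.25, 100, fine_mm = 0.2, fine_halfwidth_mm = 3)
  g2 <- fv_grid(6.25, 100, fine_mm = 0.1, fine_halfwidth_mm = 3)
  a1 <- voxelized_contact_area(voxelize_lead(lead, g1), 2)
  a2 <- voxelized_contact_area(voxelize_lead(lead, g2), 2)
  expect_lt(abs(a2 - a_true) / a_true, 0.05)
  expect_lt(abs(a2 - a_true), abs(a1 - a_true))  # refinement improves it
})

test_that("zero PES thickness leaves no PES cells", {
  lead <- build_lead("3389")
  lead$pes_thickness <- 0
  g <- fv_grid(6.25, 100, fine_mm = 0.25, fine_halfwidth_mm = 2)
  occ <- voxelize_lead(lead, g)
  expect_equal(sum(occ$labels == 1L), 0)
})
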