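#' Volume inside an electric-field isolevel
#'
#' Integrates the volume of the region where the EF magnitude meets or
#' exceeds the isolevel (default 0.2 V/mm), excluding the lead interior.
#' Cells cut by the isosurface contribute a sub-voxel fraction estimated
#' from the local EF gradient, so the estimate converges under grid
#' refinement.
#'
#' @param solution a `field_solution`.
#' @param isolevel EF magnitude in V/mm (default 0.2).
#' @return volume in mm^3.
#' @examples
#' \donttest{
#' vol <- homogeneous_volume(100, 0.5)
#' lead <- build_lead("3389")
#' sol <- solve_field(vol, lead, standard_config(lead, "ring_equivalent"),
#'                    solver_options(fine_mm = 0.2))
#' isosurface_volume(sol)  # ~144 mm^3
#' }
#' @export
isosurface_volume <- function(solution, isolevel = 0.2) {
  stopifnot(isolevel > 0)
  ef <- solution$ef
  grid <- solution$grid
  d <- grid$dim
  border <- c(ef[c(1, d[1]), , ], ef[, c(1, d[2]), ], ef[, , c(1, d[3])])
  if (any(border >= isolevel, na.rm = TRUE)) {
    stop("isosurface touches the grid boundary; domain too small")
  }
  vols <- grid_cell_volumes(grid)
  # local cell extent (mm) along each axis for the sub-voxel smearing width
  h <- vols^(1 / 3)
  gmag <- ef_magnitude_grid(grid, ef)  # |grad |E||, (V/mm)/mm
  frac <- 0.5 + (ef - isolevel) / pmax(gmag * h, 1e-12)
  frac <- pmin(pmax(frac, 0), 1)
  inside_lead <- is.na(ef)
  sum(vols[!inside_lead] * frac[!inside_lead])
}

# EF sampled on one of the lead-local planes through the active-contact
# centre. Returns plane axes (mm) and the EF matrix.
ef_plane_slice <- function(solution, plane = c("axial", "sagittal",
                                               "coronal"),
                           spacing = NULL, halfwidth = NULL) {
  plane <- match.arg(plane)
  grid <- solution$grid
  zc <- solution$contact_center_local[3]
  if (is.null(spacing)) spacing <- grid$fine_mm
  if (is.null(halfwidth)) halfwidth <- grid$fine_halfwidth
  # keep the raster inside the grid
  hw <- min(halfwidth, max(grid$x$centers) - 1e-6)
  u <- seq(-hw, hw, by = spacing)
  if (plane == "axial") {
    v <- u
    pts <- cbind(rep(u, times = length(v)), rep(v, each = length(u)), zc)
    center <- c(0, 0)
  } else {
    vlo <- max(min(grid$z$centers), zc - hw)
    vhi <- min(max(grid$z$centers), zc + hw)
    v <- seq(vlo, vhi, by = spacing)
    if (plane == "sagittal") {
      # plane containing the axis and the anterior (+y) direction
      pts <- cbind(0, rep(u, times = length(v)), rep(v, each = length(u)))
    } else {
      # coronal: axis and the lateral (+x) direction
      pts <- cbind(rep(u, times = length(v)), 0, rep(v, each = length(u)))
    }
    center <- c(0, zc)
  }
  ef <- solution$ef
  ef[is.na(ef)] <- 0  # lead interior: no field, never part of a contour hit
  m <- matrix(grid_interp(grid, ef, pts), nrow = length(u))
  list(u = u, v = v, ef = m, center = center, plane = plane)
}

#' Isocontours of the EF magnitude in a plane
#'
#' Extracts sub-voxel isolines of the EF magnitude on one of the lead-local
#' planes through the middle of the active contacts: `axial` (perpendicular
#' to the lead axis), `sagittal` (containing the axis and the
#' anterior-posterior direction) or `coronal` (axis and medial-lateral).
#'
#' @inheritParams isosurface_volume
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param spacing raster spacing (mm) used before contour tracing.
#' @return data frame with `plane`, `piece`, `u`, `v` polyline vertices (mm,
#'   plane-local; the contact centre projects to (0,0) axial / (0, zc)
#'   otherwise).
#' @export
isocontours <- function(solution, plane = "axial", isolevel = 0.2,
                        spacing = NULL) {
  sl <- ef_plane_slice(solution, plane, spacing)
  cl <- grDevices::contourLines(sl$u, sl$v, sl$ef, levels = isolevel)
  if (length(cl) == 0) stop("no ", isolevel, " V/mm isocontour in the ",
                            plane, " plane")
  do.call(rbind, lapply(seq_along(cl), function(i) {
    data.frame(plane = plane, piece = i, u = cl[[i]]$x, v = cl[[i]]$y)
  }))
}

#' Maximal isocontour extension in a plane
#'
#' Maximum Euclidean distance from the active-contact centre to the EF
#' isocontour in the given plane. Contour vertices inside a thin guard band
#' around the lead surface (default one encapsulation thickness, 0.25 mm)
#' are ignored: the field-concentration slivers at the metal contact edges
#' make the contour within that sheath resolution-dependent, while the
#' outer lobe of the isocontour is stable under refinement.
#'
#' @inheritParams isocontours
#' @param guard_mm near-surface guard band excluded from the measurement.
#' @return distance in mm.
#' @export
max_extension <- function(solution, plane = "axial", isolevel = 0.2,
                          spacing = NULL, guard_mm = 0.25) {
  sl <- ef_plane_slice(solution, plane, spacing)
  cl <- grDevices::contourLines(sl$u, sl$v, sl$ef, levels = isolevel)
  if (length(cl) == 0) stop("no ", isolevel, " V/mm isocontour in the ",
                            plane, " plane")
  rb <- solution$lead$body_diameter / 2
  dmax <- -Inf
  for (p in cl) {
    keep <- inplane_lead_distance(p$x, p$y, sl$plane, rb) > guard_mm
    if (!any(keep)) next
    dmax <- max(dmax, sqrt((p$x[keep] - sl$center[1])^2 +
                             (p$y[keep] - sl$center[2])^2))
  }
  if (!is.finite(dmax)) stop("isocontour lies entirely inside the guard ",
                             "band in the ", plane, " plane")
  dmax
}

# in-plane distance (mm) from plane points to the lead body surface
inplane_lead_distance <- function(u, v, plane, rb) {
  if (plane == "axial") return(sqrt(u^2 + v^2) - rb)
  # sagittal/coronal: u transverse, v along the axis; shaft occupies
  # |u| <= rb for v >= rb, tip cap centred at (0, rb)
  ifelse(v >= rb, abs(u) - rb, sqrt(u^2 + (v - rb)^2) - rb)
}

#' Relative difference in percent
#'
#' @param a value to compare.
#' @param b baseline (non-zero).
#' @return `100 * (a - b) / b`.
#' @examples
#' relative_difference(118.0, 144)  # -18.1
#' @export
relative_difference <- function(a, b) {
  if (any(b == 0)) stop("zero baseline in relative difference")
  100 * (a - b) / b
}

#' Steering asymmetry profile
#'
#' Quantifies the azimuthal asymmetry of the EF at the isolevel in the
#' lead-perpendicular plane: per-azimuth radial extension, the asymmetry
#' index (max/min extension over azimuths), and a flag for a visible
#' steering effect (index > 1.2). Optionally reports the same index for a
#' reference ring-mode solution.
#'
#' @param solution_steer steering-mode `field_solution`.
#' @param solution_ring optional symmetric reference `field_solution`.
#' @param isolevel EF isolevel (V/mm).
#' @param n_azimuth number of rays.
#' @return list with `profile` (azimuth_deg, extension_mm), `asymmetry_index`,
#'   `steering_visible`, and `ring_asymmetry_index` when a reference is given.
#' @export
steering_profile <- function(solution_steer, solution_ring = NULL,
                             isolevel = 0.2, n_azimuth = 180) {
  prof <- azimuthal_extension(solution_steer, isolevel, n_azimuth)
  idx <- max(prof$extension_mm) / min(prof$extension_mm)
  out <- list(profile = prof, asymmetry_index = idx,
              steering_visible = idx > 1.2, isolevel = isolevel)
  if (!is.null(solution_ring)) {
    pr <- azimuthal_extension(solution_ring, isolevel, n_azimuth)
    out$ring_asymmetry_index <- max(pr$extension_mm) / min(pr$extension_mm)
  }
  out
}

azimuthal_extension <- function(solution, isolevel, n_azimuth) {
  grid <- solution$grid
  zc <- solution$contact_center_local[3]
  rb <- solution$lead$body_diameter / 2
  rmax <- max(grid$x$centers) - 1e-6
  rr <- seq(rb + 1e-3, rmax, by = grid$fine_mm / 2)
  az <- seq(0, 360 - 360 / n_azimuth, by = 360 / n_azimuth)
  ef <- solution$ef
  ef[is.na(ef)] <- 0
  ext <- vapply(az, function(a) {
    th <- a * pi / 180
    pts <- cbind(rr * cos(th), rr * sin(th), zc)
    e <- grid_interp(grid, ef, pts)
    hit <- which(e >= isolevel)
    # a steered field may not exceed the isolevel at all on the far side:
    # zero penetration beyond the lead surface
    if (length(hit) == 0) return(rb)
    k <- max(hit)
    if (k < length(rr)) {
      # linear sub-sample interpolation of the outermost crossing
      f <- (e[k] - isolevel) / max(e[k] - e[k + 1], 1e-12)
      rr[k] + f * (rr[k + 1] - rr[k])
    } else rr[k]
  }, numeric(1))
  data.frame(azimuth_deg = az, extension_mm = ext)
}
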