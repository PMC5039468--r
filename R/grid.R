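#' @useDynLib dbsfield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# One axis of a graded tensor-product grid: uniform fine cells across
# [fine_lo, fine_hi], geometric coarsening (ratio `grow`, capped at `h_max`)
# out to the domain ends. Returns cell centres, widths and edges.
graded_axis <- function(fine_lo, fine_hi, h_fine, dom_lo, dom_hi,
                        grow = 1.3, h_max = 3) {
  stopifnot(fine_lo < fine_hi, dom_lo <= fine_lo, fine_hi <= dom_hi,
            h_fine > 0, grow > 1)
  n_fine <- max(1L, round((fine_hi - fine_lo) / h_fine))
  edges <- seq(fine_lo, fine_hi, length.out = n_fine + 1L)
  grow_out <- function(x0, lim, sign) {
    h <- h_fine
    out <- numeric(0)
    x <- x0
    while ((lim - x) * sign > 1e-9) {
      h <- min(h * grow, h_max, abs(lim - x))
      h <- max(h, min(h_fine, abs(lim - x)))
      x <- x + sign * h
      out <- c(out, x)
    }
    out
  }
  up <- grow_out(fine_hi, dom_hi, +1)
  dn <- grow_out(fine_lo, dom_lo, -1)
  edges <- c(rev(dn), edges, up)
  widths <- diff(edges)
  keep <- widths > 1e-9
  widths <- widths[keep]
  centers <- (edges[-length(edges)] + edges[-1])[keep] / 2
  list(centers = centers, widths = widths,
       edges = c(edges[-length(edges)][keep], edges[length(edges)]))
}

#' Locally refined solver grid in the lead frame
#'
#' Builds a rectilinear finite-volume grid in lead-local coordinates (lead
#' axis = +z, tip at z = 0). Spacing is uniform and fine inside a box around
#' the active contacts and coarsens geometrically towards the grounded outer
#' boundary of the cuboid domain.
#'
#' @param center_z axial position (mm from the tip) on which the fine box and
#'   the domain are centred; typically the active-contact centre.
#' @param domain_mm side length of the cuboid domain (mm).
#' @param fine_mm fine cell size (mm) inside the refinement box.
#' @param fine_halfwidth_mm half-width (mm) of the refinement box.
#' @param grow geometric growth ratio of cell widths outside the fine box.
#' @param coarse_mm maximal cell width (mm) far from the lead.
#' @return an `fv_grid` object (cell centres, widths, edges per axis).
#' @export
fv_grid <- function(center_z, domain_mm = 100, fine_mm = 0.1,
                    fine_halfwidth_mm = 6, grow = 1.3, coarse_mm = 3) {
  half <- domain_mm / 2
  ax_xy <- graded_axis(-fine_halfwidth_mm, fine_halfwidth_mm, fine_mm,
                       -half, half, grow, coarse_mm)
  ax_z <- graded_axis(center_z - fine_halfwidth_mm,
                      center_z + fine_halfwidth_mm, fine_mm,
                      center_z - half, center_z + half, grow, coarse_mm)
  g <- list(x = ax_xy, y = ax_xy, z = ax_z,
            dim = c(length(ax_xy$centers), length(ax_xy$centers),
                    length(ax_z$centers)),
            fine_mm = fine_mm, fine_halfwidth = fine_halfwidth_mm,
            domain_mm = domain_mm, center_z = center_z)
  class(g) <- "fv_grid"
  g
}

#' @export
print.fv_grid <- function(x, ...) {
  cat(sprintf(
    "<fv_grid> %d x %d x %d cells (%.2g total), fine %.3g mm, domain %g mm\n",
    x$dim[1], x$dim[2], x$dim[3], prod(x$dim), x$fine_mm, x$domain_mm))
  invisible(x)
}

# Full 3-D arrays of cell-centre coordinates (lead-local mm)
grid_coords <- function(grid) {
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  list(
    x = array(rep(grid$x$centers, times = ny * nz), grid$dim),
    y = array(rep(rep(grid$y$centers, each = nx), times = nz), grid$dim),
    z = array(rep(grid$z$centers, each = nx * ny), grid$dim))
}

# Cell volumes (mm^3), full array
grid_cell_volumes <- function(grid) {
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  vx <- grid$x$widths
  vy <- grid$y$widths
  vz <- grid$z$widths
  array(rep(vx, times = ny * nz) *
        rep(rep(vy, each = nx), times = nz) *
        rep(vz, each = nx * ny), grid$dim)
}

# Trilinear interpolation of a grid array at points (lead-local mm).
# pts: matrix n x 3. Values outside the grid are clamped to the border.
grid_interp <- function(grid, values, pts) {
  interp_axis <- function(cent, p) {
    n <- length(cent)
    i <- findInterval(p, cent, all.inside = TRUE)
    i <- pmin(pmax(i, 1L), n - 1L)
    w <- (p - cent[i]) / (cent[i + 1L] - cent[i])
    w <- pmin(pmax(w, 0), 1)
    list(i = i, w = w)
  }
  ax <- interp_axis(grid$x$centers, pts[, 1])
  ay <- interp_axis(grid$y$centers, pts[, 2])
  az <- interp_axis(grid$z$centers, pts[, 3])
  nx <- grid$dim[1]; ny <- grid$dim[2]
  idx <- function(ix, iy, iz) ix + nx * (iy - 1L) + nx * ny * (iz - 1L)
  v <- values
  dim(v) <- NULL
  out <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx) ax$w else 1 - ax$w) *
          (if (cy) ay$w else 1 - ay$w) *
          (if (cz) az$w else 1 - az$w)
    out <- out + wt * v[idx(ax$i + cx, ay$i + cy, az$i + cz)]
  }
  out
}

# Orthonormal frame for a unit lead axis: columns (u, v, axis); deterministic
# choice of the transverse directions (u = "lateral", v = "anterior").
lead_frame <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(ref[2] * a[3] - ref[3] * a[2],
         ref[3] * a[1] - ref[1] * a[3],
         ref[1] * a[2] - ref[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  cbind(u, v, a, deparse.level = 0)
}
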