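#' Specification for a synthetic heterogeneous brain volume
#'
#' Describes a seeded generator of conductivity volumes that emulate the
#' statistical structure of an intensity-classified tissue model: a grey
#' matter background with embedded white-matter tracts (capsules), a curved
#' CSF slab, thin blood vessels, and partial-volume voxels produced by
#' Gaussian blurring of the class fractions before mapping to conductivity.
#'
#' @param side_mm cuboid side length (mm).
#' @param voxel_mm isotropic voxel size (mm).
#' @param wm_tract_count number of white-matter tract capsules.
#' @param wm_radius_mm range of tract radii (mm).
#' @param wm_tract_through_center place the first tract through the centre
#'   region of the volume (default TRUE): the deep targets of interest lie
#'   among fibre tracts, so the neighbourhood of the lead contains
#'   lower-than-grey conductivity.
#' @param csf_gap placement of the CSF slab: list with `enable`, `offset_mm`
#'   (minimum distance of the slab from the volume centre, default 5 mm so
#'   the lead region stays clear), `thickness_mm`, `curvature`.
#' @param vessel_count number of blood-vessel capsules.
#' @param vessel_radius_mm range of vessel radii (mm).
#' @param partial_volume_blur_mm Gaussian blur width applied to class
#'   fractions (creates mixed voxels).
#' @param seed integer seed; generation is deterministic given (spec, seed).
#' @param table conductivity table.
#' @return a `synthetic_brain_spec`.
#' @export
synthetic_brain_spec <- function(side_mm = 100, voxel_mm = 0.5,
                                 wm_tract_count = 25,
                                 wm_radius_mm = c(2, 5),
                                 wm_tract_through_center = TRUE,
                                 csf_gap = list(enable = TRUE,
                                                offset_mm = 12,
                                                thickness_mm = 2.5,
                                                curvature = 0.012),
                                 vessel_count = 30,
                                 vessel_radius_mm = c(0.4, 0.9),
                                 partial_volume_blur_mm = 0.25,
                                 seed = 1L,
                                 table = conductivity_defaults()) {
  stopifnot(side_mm >= 60, voxel_mm > 0, wm_tract_count >= 0,
            vessel_count >= 0, partial_volume_blur_mm >= 0)
  structure(as.list(environment()), class = "synthetic_brain_spec")
}

# separable Gaussian blur along the three array dimensions
gauss_blur3 <- function(a, sd_vox) {
  if (sd_vox <= 0) return(a)
  half <- max(1L, ceiling(3 * sd_vox))
  k <- stats::dnorm(-half:half, sd = sd_vox)
  k <- k / sum(k)
  blur_dim <- function(a, dim_i) {
    d <- dim(a)
    perm <- c(dim_i, setdiff(1:3, dim_i))
    m <- aperm(a, perm)
    dm <- dim(m)
    m <- matrix(m, nrow = dm[1])
    # reflect-pad then convolve columns
    pad <- rbind(m[half:1, , drop = FALSE], m,
                 m[nrow(m):(nrow(m) - half + 1), , drop = FALSE])
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[j:(j + nrow(m) - 1), , drop = FALSE]
    }
    aperm(array(out, dm), order(perm))
  }
  for (i in 1:3) a <- blur_dim(a, i)
  a
}

# paint a capsule (segment p0-p1, radius rad) into the class array,
# restricted to the capsule's bounding box for speed
paint_capsule <- function(cls, cent, p0, p1, rad, value) {
  rng <- lapply(1:3, function(a) {
    which(cent >= min(p0[a], p1[a]) - rad - 1e-9 &
          cent <= max(p0[a], p1[a]) + rad + 1e-9)
  })
  if (any(lengths(rng) == 0)) return(cls)
  nx <- length(rng[[1]]); ny <- length(rng[[2]]); nz <- length(rng[[3]])
  x <- array(rep(cent[rng[[1]]], times = ny * nz), c(nx, ny, nz))
  y <- array(rep(rep(cent[rng[[2]]], each = nx), times = nz), c(nx, ny, nz))
  z <- array(rep(cent[rng[[3]]], each = nx * ny), c(nx, ny, nz))
  v <- p1 - p0
  t <- ((x - p0[1]) * v[1] + (y - p0[2]) * v[2] + (z - p0[3]) * v[3]) /
    sum(v^2)
  t <- pmin(pmax(t, 0), 1)
  m <- (x - p0[1] - t * v[1])^2 + (y - p0[2] - t * v[2])^2 +
    (z - p0[3] - t * v[3])^2 <= rad^2
  sub <- cls[rng[[1]], rng[[2]], rng[[3]]]
  sub[m] <- value
  cls[rng[[1]], rng[[2]], rng[[3]]] <- sub
  cls
}

#' Generate a synthetic heterogeneous conductivity volume
#'
#' @param spec a [synthetic_brain_spec()].
#' @return a `conductivity_volume` with a `class_map`; conductivities lie in
#'   the physical range spanned by the class values, with partial-volume
#'   voxels strictly between them.
#' @examples
#' vol <- generate_brain(synthetic_brain_spec(side_mm = 60, voxel_mm = 1,
#'                                            seed = 7))
#' @export
generate_brain <- function(spec) {
  stopifnot(inherits(spec, "synthetic_brain_spec"))
  set.seed(spec$seed)
  n <- max(2L, round(spec$side_mm / spec$voxel_mm))
  half <- spec$side_mm / 2
  cent <- seq(-half + spec$voxel_mm / 2, half - spec$voxel_mm / 2,
              length.out = n)
  cls <- array(1L, c(n, n, n))  # 1 gm, 2 wm, 3 blood, 4 csf

  rand_capsule <- function(rad_range, margin) {
    for (try in 1:50) {
      p0 <- stats::runif(3, -half + margin, half - margin)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      len <- stats::runif(1, 0.4, 1.2) * spec$side_mm
      p1 <- p0 + dir * len
      p1 <- pmin(pmax(p1, -half + margin), half - margin)
      if (sqrt(sum((p1 - p0)^2)) > 5) {
        return(list(p0 = p0, p1 = p1,
                    rad = stats::runif(1, rad_range[1], rad_range[2])))
      }
    }
    stop("could not place a capsule inside the volume bounds")
  }
  if (spec$wm_tract_count > 0) {
    for (i in seq_len(spec$wm_tract_count)) {
      if (i == 1 && isTRUE(spec$wm_tract_through_center)) {
        # tract brushing the centre region (targets sit among fibre tracts)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        mid <- stats::runif(3, -2, 2)
        cp <- list(p0 = mid - dir * spec$side_mm * 0.45,
                   p1 = mid + dir * spec$side_mm * 0.45,
                   rad = max(spec$wm_radius_mm))
        cp$p0 <- pmin(pmax(cp$p0, -half + 2), half - 2)
        cp$p1 <- pmin(pmax(cp$p1, -half + 2), half - 2)
      } else {
        cp <- rand_capsule(spec$wm_radius_mm, margin = 2)
      }
      cls <- paint_capsule(cls, cent, cp$p0, cp$p1, cp$rad, 2L)
    }
  }
  if (isTRUE(spec$csf_gap$enable)) {
    # curved slab kept `offset_mm` away from the centre (lead region)
    off <- spec$csf_gap$offset_mm
    th <- spec$csf_gap$thickness_mm
    curv <- spec$csf_gap$curvature
    side <- sample(c(-1, 1), 1)
    xg <- array(rep(cent, times = n * n), c(n, n, n))
    yg <- array(rep(rep(cent, each = n), times = n), c(n, n, n))
    zg <- array(rep(cent, each = n * n), c(n, n, n))
    d <- side * xg - (off + curv * (yg^2 + zg^2))
    cls[d >= 0 & d <= th] <- 4L
  }
  if (spec$vessel_count > 0) {
    for (i in seq_len(spec$vessel_count)) {
      cp <- rand_capsule(spec$vessel_radius_mm, margin = 1)
      cls <- paint_capsule(cls, cent, cp$p0, cp$p1, cp$rad, 3L)
    }
  }
  tab <- spec$table
  sig_cls <- c(tab$gm, tab$wm, tab$blood, tab$csf)
  sd_vox <- spec$partial_volume_blur_mm / spec$voxel_mm
  if (sd_vox > 0) {
    num <- array(0, dim(cls))
    den <- array(0, dim(cls))
    frac_max <- array(-Inf, dim(cls))
    cls_maj <- cls
    for (c_i in 1:4) {
      f <- gauss_blur3(array(as.numeric(cls == c_i), dim(cls)), sd_vox)
      num <- num + f * sig_cls[c_i]
      den <- den + f
      upd <- f > frac_max
      frac_max[upd] <- f[upd]
      cls_maj[upd] <- c_i
    }
    sigma <- num / den
    # majority class; call a voxel mixed only when no class clearly
    # dominates after the partial-volume blur
    mixed <- frac_max / den < 0.9
  } else {
    sigma <- array(sig_cls[cls], dim(cls))
    cls_maj <- cls
    mixed <- array(FALSE, dim(cls))
  }
  cmap <- array(c("gm", "wm", "blood", "csf")[cls_maj], dim(cls))
  cmap[mixed] <- "mixed"
  vol <- new_conductivity_volume(sigma, spec$voxel_mm,
                                 origin = rep(cent[1], 3), class_map = cmap)
  vol$spec <- spec
  vol$class_raw <- cls
  vol
}

#' Two virtual target placements along one trajectory
#'
#' Returns two lead placements ("ZI-like" and "VIM-like") differing only by
#' a 4 mm translation along a common trajectory through the volume centre,
#' both keeping the lead at least `margin_mm` from every domain boundary.
#'
#' @param spec_or_volume a `synthetic_brain_spec` or `conductivity_volume`.
#' @param axis trajectory direction (unit vector, tip-to-entry).
#' @param separation_mm distance between the two target points (default 4).
#' @param margin_mm minimal distance of both placements from the boundary.
#' @return list with `zi` and `vim` tip positions (mm) and the `axis`.
#' @export
virtual_targets <- function(spec_or_volume, axis = c(0, 0, 1),
                            separation_mm = 4, margin_mm = 20) {
  side <- if (inherits(spec_or_volume, "synthetic_brain_spec")) {
    spec_or_volume$side_mm
  } else {
    dim(spec_or_volume$sigma)[1] * spec_or_volume$voxel_mm
  }
  axis <- axis / sqrt(sum(axis^2))
  zi <- -axis * separation_mm / 2
  vim <- axis * separation_mm / 2
  lim <- side / 2 - margin_mm
  if (any(abs(zi) > lim) || any(abs(vim) > lim)) {
    stop("target placement violates the boundary margin")
  }
  list(zi = zi, vim = vim, axis = axis, separation_mm = separation_mm)
}
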