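#' Tissue conductivity table
#'
#' Default electrical conductivities (S/m) used throughout: grey matter
#' 0.123, white matter 0.075, blood 0.7, cerebrospinal fluid 2.0. The
#' peri-electrode space is assigned the white-matter value, reflecting the
#' fibrous tissue encapsulating the lead at the chronic stage. Values are
#' the tabulated low-frequency conductivities weighted for the stimulus
#' pulse spectrum; they can be overridden per call.
#'
#' @param gm,wm,blood,csf,pes conductivities in S/m.
#' @return named list of conductivities.
#' @export
conductivity_defaults <- function(gm = 0.123, wm = 0.075, blood = 0.7,
                                  csf = 2.0, pes = 0.075) {
  stopifnot(gm > 0, wm > 0, blood > 0, csf > 0, pes > 0)
  list(gm = gm, wm = wm, blood = blood, csf = csf, pes = pes)
}

new_conductivity_volume <- function(sigma, voxel_mm, origin, class_map = NULL,
                                    affine = NULL) {
  stopifnot(length(dim(sigma)) == 3, all(sigma > 0))
  structure(list(sigma = sigma, voxel_mm = voxel_mm, origin = origin,
                 class_map = class_map, affine = affine),
            class = "conductivity_volume")
}

#' Homogeneous conductivity volume
#'
#' A cuboid of constant conductivity, centred on the world origin, used as
#' the homogeneous grey-matter tissue model.
#'
#' @param side_mm side length of the cuboid (>= 60 mm so the grounded outer
#'   boundary is far from the lead).
#' @param voxel_mm isotropic voxel size in mm.
#' @param sigma conductivity in S/m.
#' @return a `conductivity_volume`.
#' @examples
#' vol <- homogeneous_volume(100, 0.5, 0.123)
#' @export
homogeneous_volume <- function(side_mm = 100, voxel_mm = 0.5,
                               sigma = conductivity_defaults()$gm) {
  if (sigma <= 0) stop("conductivity must be positive")
  if (side_mm < 60) stop("side_mm must be >= 60 mm")
  n <- max(2L, round(side_mm / voxel_mm))
  vol <- new_conductivity_volume(
    array(sigma, c(n, n, n)), voxel_mm = voxel_mm,
    origin = rep(-side_mm / 2 + voxel_mm / 2, 3))
  vol$homogeneous <- TRUE
  vol
}

#' @export
print.conductivity_volume <- function(x, ...) {
  d <- dim(x$sigma)
  cat(sprintf(
    "<conductivity_volume> %d x %d x %d voxels @ %.3g mm, sigma [%.3g, %.3g] S/m\n",
    d[1], d[2], d[3], x$voxel_mm, min(x$sigma), max(x$sigma)))
  if (!is.null(x$class_map)) {
    tb <- table(x$class_map)
    cat("  classes:", paste(names(tb), format(as.numeric(tb) / sum(tb),
                                              digits = 2), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Classify MR intensities into a conductivity volume
#'
#' Maps a T2-weighted intensity volume to conductivity by piecewise-linear
#' interpolation between per-class reference mean intensities (partial-volume
#' handling): a voxel at a class mean receives that class's conductivity; a
#' voxel between the grey- and white-matter means receives an intermediate
#' value; intensities beyond the extreme class means are clamped to the
#' nearest class conductivity. The class map assigns each voxel to the class
#' with the nearest reference mean.
#'
#' @param intensity 3-D numeric array of image intensities (or a
#'   `niftiImage` from [RNifti::readNifti()]).
#' @param class_means named numeric vector of reference mean intensities for
#'   (a subset of) `gm`, `wm`, `blood`, `csf`, e.g. estimated from
#'   user-marked samples averaged over three slices.
#' @param voxel_mm voxel size in mm (read from the NIfTI header when the
#'   input is a `niftiImage`).
#' @param table conductivity table, see [conductivity_defaults()].
#' @return a `conductivity_volume` with a `class_map`.
#' @export
classify_intensities <- function(intensity, class_means, voxel_mm = NULL,
                                 table = conductivity_defaults()) {
  affine <- NULL
  if (inherits(intensity, "niftiImage")) {
    pd <- RNifti::pixdim(intensity)
    if (is.null(voxel_mm)) voxel_mm <- pd[1]
    affine <- RNifti::xform(intensity)
    intensity <- array(as.numeric(intensity), dim(intensity))
  }
  if (is.null(voxel_mm)) voxel_mm <- 1
  cls <- names(class_means)
  if (is.null(cls) || !all(cls %in% names(table))) {
    stop("class_means must be named with classes among: ",
         paste(setdiff(names(table), "pes"), collapse = ", "))
  }
  if (anyDuplicated(as.numeric(class_means)) ||
      length(unique(class_means)) < 2) {
    stop("degenerate class reference means (need >= 2 distinct values)")
  }
  ord <- order(class_means)
  means <- as.numeric(class_means)[ord]
  sigmas <- as.numeric(unlist(table[cls]))[ord]
  # piecewise-linear in intensity, clamped outside the extreme means
  sig <- stats::approx(means, sigmas, xout = as.numeric(intensity),
                       rule = 2)$y
  sig <- array(sig, dim(intensity))
  mid <- (means[-1] + means[-length(means)]) / 2
  nearest <- findInterval(as.numeric(intensity), mid) + 1L
  cmap <- array(cls[ord][nearest], dim(intensity))
  mixed <- abs(sig - array(sigmas[nearest], dim(intensity))) > 1e-9
  cmap[mixed] <- "mixed"
  d <- dim(intensity)
  new_conductivity_volume(sig, voxel_mm,
                          origin = -(d - 1) / 2 * voxel_mm,
                          class_map = cmap, affine = affine)
}

#' Overlay a voxelized lead on a conductivity grid
#'
#' Applies the lead occupancy labels to a conductivity array sampled on the
#' same grid: PES cells get the peri-electrode conductivity, contact cells
#' the metal conductivity; insulator cells are excluded from the solve
#' (zero-flux) and marked NA here. Tissue cells are unchanged.
#'
#' @param sigma_grid 3-D conductivity array on the occupancy's grid.
#' @param occ a `lead_occupancy` from [voxelize_lead()].
#' @param table conductivity table (for the PES value).
#' @param sigma_metal conductivity assigned to floating metal contacts.
#' @return list with the modified `sigma` array and the `labels`.
#' @export
apply_lead <- function(sigma_grid, occ, table = conductivity_defaults(),
                       sigma_metal = 1e6) {
  if (!all(dim(sigma_grid) == dim(occ$labels))) {
    stop("sigma grid and lead occupancy have mismatched dimensions")
  }
  sig <- sigma_grid
  sig[occ$labels == LAB_PES] <- table$pes
  sig[occ$labels >= LAB_CONTACT0] <- sigma_metal
  sig[occ$labels == LAB_INSULATOR] <- NA_real_
  list(sigma = sig, labels = occ$labels)
}

# Sample a conductivity volume at lead-local cell centres (world transform
# through the lead frame); nearest-voxel lookup, border-clamped.
sample_sigma <- function(volume, lead, grid) {
  if (isTRUE(volume$homogeneous)) {
    return(array(volume$sigma[1], grid$dim))
  }
  co <- grid_coords(grid)
  n <- prod(grid$dim)
  pl <- cbind(as.numeric(co$x), as.numeric(co$y), as.numeric(co$z))
  pw <- pl %*% t(lead$frame) +
    matrix(lead$tip_position, n, 3, byrow = TRUE)
  d <- dim(volume$sigma)
  idx <- sapply(1:3, function(a) {
    i <- round((pw[, a] - volume$origin[a]) / volume$voxel_mm) + 1
    pmin(pmax(i, 1), d[a])
  })
  array(volume$sigma[cbind(idx[, 1], idx[, 2], idx[, 3])], grid$dim)
}

#' Read an intensity volume from NIfTI-1
#' @param path file path (.nii or .nii.gz).
#' @return a `niftiImage` (pass to [classify_intensities()]).
#' @export
read_intensity_nifti <- function(path) RNifti::readNifti(path)

#' Write a conductivity volume (and optional class map) to NIfTI-1
#'
#' @param volume a `conductivity_volume`.
#' @param path output path for the float32 conductivity image (S/m).
#' @param class_path optional output path for the uint8 class map.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path, class_path = NULL) {
  arr <- volume$sigma
  attr(arr, "pixdim") <- rep(volume$voxel_mm, 3)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"), path)
  if (!is.null(class_path) && !is.null(volume$class_map)) {
    codes <- c(gm = 1L, wm = 2L, blood = 3L, csf = 4L, mixed = 5L)
    cm <- array(codes[volume$class_map], dim(volume$class_map))
    cm[is.na(cm)] <- 0L
    attr(cm, "pixdim") <- rep(volume$voxel_mm, 3)
    RNifti::writeNifti(RNifti::asNifti(cm, datatype = "uint8"), class_path)
  }
  invisible(path)
}
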