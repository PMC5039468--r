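#' Export a field solution
#'
#' Writes the potential and EF-magnitude grids and a JSON metadata sidecar.
#' The native rectilinear (graded) grid is written as legacy-ASCII VTK
#' rectilinear files; in addition the uniform fine region around the lead
#' is resampled and written as NIfTI-1 (useful for overlay on imaging).
#'
#' @param solution a `field_solution`.
#' @param dir output directory (created if needed).
#' @param basename file stem, default from the config label.
#' @param nifti also write resampled NIfTI volumes of the fine region.
#' @return the directory, invisibly.
#' @export
write_solution <- function(solution, dir, basename = NULL, nifti = TRUE) {
  stopifnot(inherits(solution, "field_solution"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- basename %||% solution$config$label
  write_vtk_rect(file.path(dir, paste0(stem, "_potential.vtk")),
                 solution$grid, solution$potential, "potential_V")
  write_vtk_rect(file.path(dir, paste0(stem, "_ef.vtk")),
                 solution$grid, solution$ef, "ef_V_per_mm")
  if (nifti) {
    g <- solution$grid
    h <- g$fine_mm
    hw <- g$fine_halfwidth
    zc <- g$center_z
    ax <- seq(-hw + h / 2, hw - h / 2, by = h)
    pts <- as.matrix(expand.grid(x = ax, y = ax, z = zc + ax))
    for (nm in c("potential", "ef")) {
      v <- solution[[nm]]
      v[is.na(v)] <- 0
      arr <- array(grid_interp(g, v, pts), c(length(ax), length(ax),
                                             length(ax)))
      attr(arr, "pixdim") <- rep(h, 3)
      RNifti::writeNifti(RNifti::asNifti(arr, datatype = "float"),
                         file.path(dir, paste0(stem, "_", nm, ".nii.gz")))
    }
  }
  jsonlite::write_json(
    list(label = solution$config$label, lead = solution$lead$model_name,
         mode = solution$mode, amplitude = solution$amplitude,
         total_current_mA = solution$total_current_mA,
         contact_potential_V = solution$contact_potential_V,
         iterations = solution$solver_stats$iterations,
         relres = solution$solver_stats$relres,
         n_cells = solution$solver_stats$n_cells),
    file.path(dir, paste0(stem, "_meta.json")), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(dir)
}

# legacy-ASCII VTK rectilinear grid with one point-data field
write_vtk_rect <- function(path, grid, values, name) {
  v <- values
  v[is.na(v)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d %d", grid$dim[1], grid$dim[2],
                       grid$dim[3])), con)
  wcoords <- function(tag, x) {
    writeLines(sprintf("%s %d float", tag, length(x)), con)
    writeLines(paste(format(x, trim = TRUE), collapse = " "), con)
  }
  wcoords("X_COORDINATES", grid$x$centers)
  wcoords("Y_COORDINATES", grid$y$centers)
  wcoords("Z_COORDINATES", grid$z$centers)
  writeLines(c(sprintf("POINT_DATA %d", prod(grid$dim)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(paste(format(as.numeric(v), trim = TRUE), collapse = " "), con)
  invisible(path)
}

#' Write an activation table as CSV
#'
#' Long format: lead, tissue_model, mode, direction, diameter_um,
#' amplitude, activation_distance_mm.
#'
#' @param table an `activation_table` from [run_sweep()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activation_csv <- function(table, path) {
  utils::write.csv(activation_long(table), path, row.names = FALSE)
  invisible(path)
}

#' Plot activation-distance curves
#'
#' Distance versus amplitude, one curve per fibre diameter, for a selected
#' lead / tissue model / mode / direction.
#'
#' @param table an `activation_table`.
#' @param lead,tissue_model,mode,direction row filters (defaults: first
#'   value present in the table).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the plotted matrix (amplitudes x diameters).
#' @export
plot_activation_curves <- function(table, lead = NULL, tissue_model = NULL,
                                   mode = NULL, direction = NULL, ...) {
  lead <- lead %||% table$lead[1]
  tissue_model <- tissue_model %||% table$tissue_model[1]
  mode <- mode %||% table$mode[1]
  direction <- direction %||% table$direction[1]
  sub <- table[table$lead == lead & table$tissue_model == tissue_model &
                 table$mode == mode & table$direction == direction, ]
  if (nrow(sub) == 0) stop("no matching rows in the activation table")
  amps <- attr(table, "amplitudes")
  m <- t(as.matrix(sub[, sprintf("dist_%g", amps)]))
  graphics::matplot(amps, m, type = "b", pch = 20, lty = 1,
                    xlab = sprintf("amplitude (%s)",
                                   if (mode == "voltage") "V" else "mA"),
                    ylab = "activation distance (mm)",
                    main = sprintf("%s, %s, %s", lead, tissue_model,
                                   direction), ...)
  graphics::legend("bottomright", legend = sprintf("%.1f um",
                                                   sub$diameter_um),
                   col = seq_len(nrow(sub)), lty = 1, cex = 0.6, ncol = 2)
  invisible(m)
}
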