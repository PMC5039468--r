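#' Solver options
#'
#' Numerical options for the finite-volume field solver. The grid is
#' uniformly fine inside a box around the active contacts and coarsens
#' geometrically towards the grounded boundary. Floating (inactive) contacts
#' are modelled as high-conductivity domains, which enforces the equipotential
#' / zero-net-current condition to well below solver tolerance; the
#' insulating lead body is excluded from the solve (zero-flux faces).
#'
#' @param fine_mm fine cell size (mm); <= 0.25 mm, default 0.1.
#' @param fine_halfwidth_mm half-width (mm) of the refinement box; must
#'   contain the isosurface of interest.
#' @param coarse_mm cap on cell width far from the lead.
#' @param grow geometric growth ratio of cell widths outside the fine box.
#' @param tol relative residual tolerance of the conjugate-gradient solve.
#' @param maxit maximal CG iterations.
#' @param sigma_metal conductivity (S/m) of floating contact metal
#'   (results are insensitive between 1e3 and 1e6; the default keeps the
#'   CG iteration count down).
#' @param table tissue conductivity table (supplies the PES value).
#' @return a `solver_options` list.
#' @export
solver_options <- function(fine_mm = 0.1, fine_halfwidth_mm = 6,
                           coarse_mm = 3, grow = 1.3, tol = 1e-8,
                           maxit = 5000, sigma_metal = 1e3,
                           table = conductivity_defaults()) {
  stopifnot(fine_mm <= 0.25, tol <= 1e-8, fine_halfwidth_mm > 0)
  structure(list(fine_mm = fine_mm, fine_halfwidth_mm = fine_halfwidth_mm,
                 coarse_mm = coarse_mm, grow = grow, tol = tol,
                 maxit = maxit, sigma_metal = sigma_metal, table = table),
            class = "solver_options")
}

# array shift helper: neighbour value along dim, border replicated
shift_arr <- function(a, dim_i, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[dim_i]] + by, 1L), d[dim_i])
  idx[[dim_i]] <- src
  do.call(`[`, c(list(a), idx))
}

# |grad V| by central differences on the rectilinear grid, in V/mm.
# One-sided at borders and next to excluded (NA) cells; NA inside the lead.
ef_magnitude_grid <- function(grid, potential) {
  cent <- list(grid$x$centers, grid$y$centers, grid$z$centers)
  comp <- vector("list", 3)
  for (a in 1:3) {
    vp <- shift_arr(potential, a, +1L)
    vm <- shift_arr(potential, a, -1L)
    n <- grid$dim[a]
    cc <- cent[[a]]
    cp <- cc[pmin(seq_len(n) + 1L, n)]
    cm <- cc[pmax(seq_len(n) - 1L, 1L)]
    per <- c(a, setdiff(1:3, a))
    expand <- function(v) aperm(array(v, grid$dim[per]), order(per))
    xp <- expand(cp); xm <- expand(cm)
    num <- vp - vm
    den <- xp - xm
    # fall back to one-sided differences where a neighbour is excluded
    up_bad <- is.na(vp) & !is.na(vm)
    dn_bad <- is.na(vm) & !is.na(vp)
    x0 <- expand(cc)
    num[up_bad] <- (potential - vm)[up_bad]
    den[up_bad] <- (x0 - xm)[up_bad]
    num[dn_bad] <- (vp - potential)[dn_bad]
    den[dn_bad] <- (xp - x0)[dn_bad]
    g <- num / den
    g[is.na(vp) & is.na(vm)] <- 0
    comp[[a]] <- g
  }
  ef <- sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2)
  ef[is.na(potential)] <- NA_real_
  ef
}

#' Solve a labelled finite-volume problem
#'
#' Low-level entry point: solves the steady-current equation on a grid with
#' explicit cell labels (0 tissue / 1 unit-Dirichlet source / 2 excluded)
#' and a conductivity array. Used internally by [solve_field()] and directly
#' for analytic fixtures such as a spherical electrode.
#'
#' @param grid an `fv_grid`.
#' @param sigma conductivity array (S/m) on the grid.
#' @param labels integer label array.
#' @param amplitude source amplitude in volts (Dirichlet cells are held at
#'   this potential; outer boundary grounded).
#' @param tol,maxit CG tolerance and iteration cap.
#' @return list with `potential` (V), `ef` (V/mm), `total_current_mA`,
#'   `unit_current_A`, `iterations`, `relres`.
#' @export
solve_labelled <- function(grid, sigma, labels, amplitude = 1,
                           tol = 1e-8, maxit = 5000) {
  stopifnot(inherits(grid, "fv_grid"),
            all(dim(sigma) == grid$dim), all(dim(labels) == grid$dim))
  sig <- sigma
  sig[is.na(sig)] <- 1  # excluded cells: value irrelevant
  res <- .fv_solve_cpp(as.integer(grid$dim), grid$x$widths, grid$y$widths,
                       grid$z$widths, as.numeric(sig),
                       as.integer(labels), tol, as.integer(maxit))
  if (!res$converged) {
    stop(sprintf(
      "field solve did not converge: relres %.2e after %d iterations",
      res$relres, res$iterations))
  }
  pot <- res$potential * amplitude
  list(potential = pot, ef = ef_magnitude_grid(grid, pot),
       total_current_mA = res$unit_current_A * amplitude * 1e3,
       unit_current_A = res$unit_current_A,
       iterations = res$iterations, relres = res$relres)
}

#' Solve the electric field around a DBS lead
#'
#' Embeds the lead in the conductivity volume, builds the locally refined
#' grid, voxelizes the lead with its 0.25 mm peri-electrode space, and
#' solves the quasi-static steady-current equation with the active contacts
#' as a common source, floating inactive contacts, insulating shaft and
#' grounded outer boundary. In voltage mode the active contacts are held at
#' the drive amplitude; in current mode the unit-voltage solution is scaled
#' so that the total delivered current equals the requested amplitude
#' (valid by linearity).
#'
#' The 0.25 mm peri-electrode space models the fibrous encapsulation of the
#' chronic stage and belongs to the patient-specific (heterogeneous) tissue
#' models; the homogeneous reference model — the one defining the
#' 3 V / 3.4 mA amplitude equivalence — has no PES. `pes = "auto"`
#' reproduces exactly that convention; `"on"`/`"off"` force either choice.
#'
#' @param volume a `conductivity_volume` (homogeneous or heterogeneous).
#' @param lead a `dbs_lead`.
#' @param config a `stimulus_config`.
#' @param options a [solver_options()].
#' @param pes `"auto"` (PES only for heterogeneous volumes), `"on"` or
#'   `"off"`.
#' @return a `field_solution`: potential (V) and EF magnitude (V/mm) on the
#'   solver grid, total delivered current (mA), contact centre, solver stats.
#' @examples
#' \donttest{
#' vol <- homogeneous_volume(100, 0.5)
#' lead <- build_lead("3389")
#' sol <- solve_field(vol, lead, standard_config(lead, "ring_equivalent"),
#'                    solver_options(fine_mm = 0.2))
#' sol$total_current_mA
#' }
#' @export
solve_field <- function(volume, lead, config, options = solver_options(),
                        pes = c("auto", "on", "off")) {
  stopifnot(inherits(volume, "conductivity_volume"),
            inherits(lead, "dbs_lead"),
            inherits(config, "stimulus_config"))
  pes <- match.arg(pes)
  use_pes <- switch(pes, auto = !isTRUE(volume$homogeneous),
                    on = TRUE, off = FALSE)
  side <- dim(volume$sigma)[1] * volume$voxel_mm
  zc <- active_center_z(lead, config)
  grid <- fv_grid(center_z = zc, domain_mm = side,
                  fine_mm = options$fine_mm,
                  fine_halfwidth_mm = options$fine_halfwidth_mm,
                  grow = options$grow, coarse_mm = options$coarse_mm)
  occ <- voxelize_lead(lead, grid)
  sig <- sample_sigma(volume, lead, grid)
  emb <- apply_lead(sig, occ, table = options$table,
                    sigma_metal = options$sigma_metal)
  if (!use_pes) {
    # PES cells keep the local tissue conductivity
    emb$sigma[occ$labels == LAB_PES] <- sig[occ$labels == LAB_PES]
  }
  labels <- array(LAB_TISSUE, grid$dim)
  labels[occ$labels == LAB_INSULATOR] <- 2L
  for (ci in config$active_contacts) {
    sel <- occ$labels == LAB_CONTACT0 + ci
    if (!any(sel)) {
      stop("active contact ", ci, " has no cells on the grid ",
           "(disconnected or unresolved)")
    }
    labels[sel] <- 1L
  }
  # floating contacts stay label 0 with metal conductivity
  sig_solver <- emb$sigma
  base <- solve_labelled(grid, sig_solver, labels, amplitude = 1,
                         tol = options$tol, maxit = options$maxit)
  if (base$unit_current_A <= 0) {
    stop("degenerate geometry: no current leaves the active contacts")
  }
  if (config$mode == "voltage") {
    scale <- config$amplitude
    total_mA <- base$unit_current_A * scale * 1e3
    contact_V <- config$amplitude
  } else {
    scale <- (config$amplitude / 1e3) / base$unit_current_A
    total_mA <- config$amplitude
    contact_V <- scale
  }
  structure(list(
    grid = grid, potential = base$potential * scale, ef = base$ef * scale,
    labels = occ$labels, lead = lead, config = config,
    mode = config$mode, amplitude = config$amplitude,
    total_current_mA = total_mA, contact_potential_V = contact_V,
    unit_current_A = base$unit_current_A, scale = scale,
    contact_center_local = c(0, 0, zc),
    solver_stats = list(iterations = base$iterations, relres = base$relres,
                        n_cells = prod(grid$dim))
  ), class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf(
    "<field_solution %s> %s mode, %g %s -> total current %.3f mA\n",
    x$lead$model_name, x$mode, x$amplitude,
    if (x$mode == "voltage") "V" else "mA", x$total_current_mA))
  cat(sprintf("  grid %s cells, CG %d iters, relres %.1e\n",
              format(x$solver_stats$n_cells, big.mark = ","),
              x$solver_stats$iterations, x$solver_stats$relres))
  invisible(x)
}

#' Rescale a field solution to another amplitude or mode
#'
#' The problem is linear, so solutions at different amplitudes (or in the
#' other operating mode) are scalar multiples of one solve.
#'
#' @param solution a `field_solution`.
#' @param mode `"voltage"` or `"current"`.
#' @param amplitude new amplitude (V or mA).
#' @return a rescaled `field_solution`.
#' @export
at_amplitude <- function(solution, mode = solution$mode, amplitude) {
  unit_pot <- solution$potential / solution$scale
  unit_ef <- solution$ef / solution$scale
  if (mode == "voltage") {
    scale <- amplitude
    total_mA <- solution$unit_current_A * scale * 1e3
    contact_V <- amplitude
  } else {
    scale <- (amplitude / 1e3) / solution$unit_current_A
    total_mA <- amplitude
    contact_V <- scale
  }
  out <- solution
  out$potential <- unit_pot * scale
  out$ef <- unit_ef * scale
  out$scale <- scale
  out$mode <- mode
  out$amplitude <- amplitude
  out$total_current_mA <- total_mA
  out$contact_potential_V <- contact_V
  out$config$mode <- mode
  out$config$amplitude <- amplitude
  out
}

#' Equivalent current for a voltage-mode configuration
#'
#' The current amplitude that reproduces the voltage-mode field (by
#' linearity this equals the total current delivered by the voltage solve).
#'
#' @param volume,lead,config,options as in [solve_field()]; `config` must be
#'   voltage mode. Alternatively pass an existing voltage-mode
#'   `field_solution` as the first argument.
#' @return equivalent current in mA.
#' @export
equivalent_current <- function(volume, lead = NULL, config = NULL,
                               options = solver_options()) {
  if (inherits(volume, "field_solution")) {
    sol <- volume
    if (sol$mode != "voltage") stop("expected a voltage-mode solution")
    return(sol$total_current_mA)
  }
  if (config$mode != "voltage") stop("expected a voltage-mode config")
  solve_field(volume, lead, config, options)$total_current_mA
}
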