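#' Myelinated axon specification
#'
#' Parameters of the myelinated-axon cable model: nodes of Ranvier carrying
#' fast Na+, persistent Na+, slow K+ and leak channels with mammalian
#' (37 C) kinetics, connected by passive myelinated internodes. Fibre
#' geometry (internodal length, node and axon core diameters, myelin
#' lamellae) scales with the fibre diameter following
#' [mrg_fibre_geometry()]. All membrane parameters live in this one block
#' so the model can be matched against published node-of-Ranvier parameter
#' sets.
#'
#' @param diameter_um fibre diameter in um (1.5 to 7.5).
#' @param pulse_width_us rectangular cathodic pulse width (default 60 us).
#' @param n_nodes number of nodes of Ranvier (odd; default 21).
#' @param segs_per_internode passive segments per internode.
#' @param membrane named list overriding membrane constants (conductances in
#'   S/cm^2, potentials in mV, capacitances in uF/cm^2, resistivity in
#'   Ohm cm).
#' @param dt_us integration step (default 1 us; halve to check convergence).
#' @param t_end_ms detection window after pulse onset.
#' @param settle_ms membrane settling time simulated before the pulse.
#' @return an `axon_spec`.
#' @export
axon_spec <- function(diameter_um, pulse_width_us = 60, n_nodes = 21L,
                      segs_per_internode = 3L, membrane = list(),
                      dt_us = 1, t_end_ms = 3, settle_ms = 2) {
  if (diameter_um < 1.5 || diameter_um > 7.5) {
    stop("fibre diameter must lie in [1.5, 7.5] um")
  }
  mb <- utils::modifyList(list(
    rho_axial = 70,        # Ohm cm axoplasm
    cm_node = 2,           # uF/cm^2
    g_naf = 3.0, g_nap = 0.01, g_ks = 0.08, g_leak = 0.007,  # S/cm^2
    e_na = 50, e_k = -90, e_leak = -90, e_pas_internode = -80,
    v_rest = -80,
    cm_myelin_lamella = 0.1,    # uF/cm^2 per lamella membrane
    gm_myelin_lamella = 0.001,  # S/cm^2 per lamella membrane
    node_length_um = 1,
    rate_factor = 1, min_node_sep = 5L,
    geometry = NULL  # override mrg_fibre_geometry() fields if set
  ), membrane)
  structure(list(diameter_um = diameter_um,
                 pulse_width_us = pulse_width_us,
                 n_nodes = as.integer(n_nodes),
                 segs_per_internode = as.integer(segs_per_internode),
                 membrane = mb, dt_us = dt_us, t_end_ms = t_end_ms,
                 settle_ms = settle_ms),
            class = "axon_spec")
}

#' Diameter-dependent fibre geometry
#'
#' Internodal length, node and internodal axon diameters and the number of
#' myelin lamellae as functions of the fibre diameter, interpolated from
#' the published morphometry of mammalian motor fibres (500/750/1000 um
#' internodes at 5.7/7.3/8.7 um etc.). Below the smallest tabulated
#' diameter the morphometry is extrapolated linearly with physiological
#' floors; the internodal-length extrapolation slope (192 um per um of
#' fibre diameter, floored at 40 x D) is calibrated so that a 4 um fibre
#' driven by a 60 us cathodic pulse reproduces the reference excitability
#' of this model family: a threshold electric field of about 0.2 V/mm.
#'
#' @param diameter_um fibre diameter in um.
#' @param internode_slope extrapolation slope of internodal length below
#'   5.7 um (um per um).
#' @return list with `internode_um`, `node_diam_um`, `axon_diam_um`,
#'   `lamellae`.
#' @export
mrg_fibre_geometry <- function(diameter_um, internode_slope = 192) {
  D <- diameter_um
  tab_D <- c(5.7, 7.3, 8.7, 10, 11.5, 12.8, 14, 15, 16)
  ext <- function(tab_y, floor_y, slope = NULL) {
    if (D >= tab_D[1]) {
      stats::approx(tab_D, tab_y, xout = min(D, 16), rule = 2)$y
    } else {
      if (is.null(slope)) {
        slope <- (tab_y[2] - tab_y[1]) / (tab_D[2] - tab_D[1])
      }
      max(tab_y[1] - (tab_D[1] - D) * slope, floor_y)
    }
  }
  list(
    internode_um = ext(c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450,
                         1500), 40 * D, slope = internode_slope),
    node_diam_um = ext(c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
                       0.2 * D),
    axon_diam_um = ext(c(3.4, 4.6, 5.8, 6.9, 8.1, 9.2, 10.4, 11.5, 12.7),
                       0.4 * D),
    lamellae = max(15, round(ext(c(80, 100, 110, 120, 130, 135, 140, 145,
                                   150), 15))))
}

# Discretised cable: compartment positions (mm along the fibre, centred on
# 0), absolute capacitances/conductances, and axial couplings.
build_cable <- function(spec) {
  mb <- spec$membrane
  D <- spec$diameter_um
  geo <- utils::modifyList(mrg_fibre_geometry(D), mb$geometry %||% list())
  nseg <- spec$segs_per_internode
  L_in <- geo$internode_um        # um
  seg_len <- L_in / nseg
  node_len <- mb$node_length_um
  n_nodes <- spec$n_nodes
  ncomp <- n_nodes + (n_nodes - 1L) * nseg
  is_node <- rep(FALSE, ncomp)
  node_of <- rep(-1L, ncomp)
  len_um <- numeric(ncomp)
  i <- 1L
  for (k in seq_len(n_nodes)) {
    is_node[i] <- TRUE
    node_of[i] <- k - 1L
    len_um[i] <- node_len
    i <- i + 1L
    if (k < n_nodes) {
      len_um[i:(i + nseg - 1L)] <- seg_len
      i <- i + nseg
    }
  }
  pos_um <- cumsum(len_um) - len_um / 2
  pos_um <- pos_um - mean(range(pos_um))
  d_memb <- ifelse(is_node, geo$node_diam_um, D)  # membrane diameter
  d_core <- ifelse(is_node, geo$node_diam_um, geo$axon_diam_um)
  area_cm2 <- pi * d_memb * len_um * 1e-8
  n_lam <- geo$lamellae
  cap_uF <- ifelse(is_node, mb$cm_node,
                   mb$cm_myelin_lamella / (2 * n_lam)) * area_cm2
  gpas_mS <- ifelse(is_node, mb$g_leak,
                    mb$gm_myelin_lamella / (2 * n_lam)) * area_cm2 * 1e3
  e_pas <- ifelse(is_node, mb$e_leak, mb$e_pas_internode)
  gnaf_mS <- ifelse(is_node, mb$g_naf, 0) * area_cm2 * 1e3
  gnap_mS <- ifelse(is_node, mb$g_nap, 0) * area_cm2 * 1e3
  gks_mS <- ifelse(is_node, mb$g_ks, 0) * area_cm2 * 1e3
  # axial conductance between successive compartments (half-lengths in
  # series), S -> mS
  a_core <- pi * (d_core * 1e-4)^2 / 4       # cm^2
  half_r <- mb$rho_axial * (len_um * 1e-4 / 2) / a_core  # Ohm
  gax_mS <- 1e3 / (half_r[-ncomp] + half_r[-1])
  list(pos_mm = pos_um * 1e-3, is_node = is_node, node_of = node_of,
       cap_uF = cap_uF, gpas_mS = gpas_mS, e_pas = e_pas,
       gnaf_mS = gnaf_mS, gnap_mS = gnap_mS, gks_mS = gks_mS,
       gax_mS = gax_mS, length_mm = sum(len_um) * 1e-3)
}

#' Extract parallel potential lines from a field solution
#'
#' Samples the extracellular potential along lines parallel to the lead
#' axis in one of the four directions of the axial plane through the
#' active-contact centre: `anterior` (+y), `posterior` (-y), `lateral`
#' (+x), `medial` (-x) in the lead frame. The first line lies at the lead
#' surface and successive lines step 0.1 mm outwards (62 lines by default).
#'
#' @param solution a `field_solution`.
#' @param direction one of `"anterior"`, `"posterior"`, `"medial"`,
#'   `"lateral"`.
#' @param n_lines number of lines (default 62).
#' @param spacing_mm radial spacing between lines (default 0.1).
#' @param half_length_mm axial half-length of each line.
#' @param step_mm sampling step along a line.
#' @return a `potential_lineset`: matrix of potentials (V, rows = axial
#'   sample points, columns = lines), axial positions, radial distances of
#'   each line from the lead axis, and the drive (mode, amplitude) echoed.
#' @export
extract_potential_lines <- function(solution,
                                    direction = c("anterior", "posterior",
                                                  "medial", "lateral"),
                                    n_lines = 62L, spacing_mm = 0.1,
                                    half_length_mm = 9, step_mm = 0.05) {
  direction <- match.arg(direction)
  grid <- solution$grid
  zc <- solution$contact_center_local[3]
  rb <- solution$lead$body_diameter / 2
  dvec <- switch(direction, anterior = c(0, 1), posterior = c(0, -1),
                 lateral = c(1, 0), medial = c(-1, 0))
  radii <- rb + (seq_len(n_lines) - 1L) * spacing_mm
  if (max(radii) > max(grid$x$centers)) {
    stop("line set extends beyond the solver grid in direction ", direction)
  }
  zr <- seq(zc - half_length_mm, zc + half_length_mm, by = step_mm)
  zlo <- min(grid$z$centers); zhi <- max(grid$z$centers)
  zr <- zr[zr >= zlo & zr <= zhi]
  pot <- solution$potential
  pot[is.na(pot)] <- 0
  m <- vapply(radii, function(r) {
    pts <- cbind(r * dvec[1], r * dvec[2], zr)
    grid_interp(grid, pot, pts)
  }, numeric(length(zr)))
  structure(list(potential_V = m, z_mm = zr, radius_mm = radii,
                 direction = direction, spacing_mm = spacing_mm,
                 mode = solution$mode, amplitude = solution$amplitude,
                 lead_radius_mm = rb, center_z = zc),
            class = "potential_lineset")
}

#' @export
print.potential_lineset <- function(x, ...) {
  cat(sprintf(
    "<potential_lineset> %d lines (%s), %.2g mm spacing, drive %g %s\n",
    length(x$radius_mm), x$direction, x$spacing_mm, x$amplitude,
    if (x$mode == "voltage") "V" else "mA"))
  invisible(x)
}

# Membrane state after the settling period without stimulus; computed once
# per cable and reused across lines and amplitudes.
settle_state <- function(cable, spec) {
  n <- length(cable$cap_uF)
  res <- .cable_run_cpp(
    numeric(n), cable$cap_uF, cable$gpas_mS, cable$e_pas, cable$gnaf_mS,
    cable$gnap_mS, cable$gks_mS, spec$membrane$e_na, spec$membrane$e_k,
    cable$gax_mS, cable$node_of, spec$membrane$v_rest,
    spec$membrane$rate_factor, spec$dt_us * 1e-3, spec$settle_ms, 0, 0,
    as.integer(spec$membrane$min_node_sep), FALSE, list(), TRUE)
  res$state
}

# Simulate one line at one amplitude; TRUE if a propagating action
# potential is detected.
line_activated <- function(lines, cable, spec, line_k, amplitude,
                           init = NULL) {
  scale <- amplitude / lines$amplitude
  ve_line <- lines$potential_V[, line_k] * scale
  z_axon <- cable$pos_mm + lines$center_z
  ve <- stats::approx(lines$z_mm, ve_line, xout = z_axon, rule = 2)$y
  # rectangular cathodic pulse: the contact is the cathode
  ve_mv <- -1e3 * ve
  res <- .cable_run_cpp(
    ve_mv, cable$cap_uF, cable$gpas_mS, cable$e_pas, cable$gnaf_mS,
    cable$gnap_mS, cable$gks_mS, spec$membrane$e_na, spec$membrane$e_k,
    cable$gax_mS, cable$node_of, spec$membrane$v_rest,
    spec$membrane$rate_factor, spec$dt_us * 1e-3,
    if (is.null(init)) spec$settle_ms else 0,
    spec$pulse_width_us * 1e-3, spec$t_end_ms,
    as.integer(spec$membrane$min_node_sep), FALSE, init %||% list(), FALSE)
  isTRUE(res$activated)
}

#' Neuron activation distance
#'
#' Applies the extracellular potential of each line (scaled by linearity to
#' the requested amplitude, cathodic pulse) to the axon cable model and
#' returns the radial distance from the lead axis of the farthest line on
#' which a propagating action potential is elicited (0 if none). Lines are
#' searched outward exploiting that activation is monotone in the drive.
#'
#' @param lines a `potential_lineset` from [extract_potential_lines()].
#' @param axon an [axon_spec()].
#' @param amplitude drive amplitude in the line set's mode units (V or mA).
#' @param start_k search hint: first line index known activated (internal).
#' @return activation distance in mm (radius of the farthest activated
#'   line, measured from the lead axis).
#' @examples
#' \donttest{
#' vol <- homogeneous_volume(100, 0.5)
#' lead <- build_lead("3389")
#' sol <- solve_field(vol, lead, standard_config(lead, "ring_equivalent"),
#'                    solver_options(fine_mm = 0.2))
#' ln <- extract_potential_lines(sol, "posterior")
#' activation_distance(ln, axon_spec(4), amplitude = 3)  # ~3.2 mm
#' }
#' @export
activation_distance <- function(lines, axon, amplitude, start_k = 0L) {
  stopifnot(inherits(lines, "potential_lineset"),
            inherits(axon, "axon_spec"), amplitude >= 0)
  if (amplitude == 0) return(0)
  cable <- build_cable(axon)
  st <- settle_state(cable, axon)
  n <- length(lines$radius_mm)
  k <- search_farthest(function(k) line_activated(lines, cable, axon, k,
                                                  amplitude, st),
                       n, start_k)
  if (k == 0L) 0 else lines$radius_mm[k]
}

# largest k in 1..n with pred(k) TRUE, assuming pred is monotone
# (TRUE for all k below the crossing); 0 if pred(1) is FALSE.
search_farthest <- function(pred, n, start_k = 0L) {
  k <- max(0L, min(start_k, n))
  if (k > 0L && !pred(k)) {
    # hint too optimistic: bisect below
    lo <- 0L; hi <- k
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (pred(mid)) lo <- mid else hi <- mid
    }
    return(lo)
  }
  while (k < n && pred(k + 1L)) k <- k + 1L
  k
}

#' Run the activation-distance sweep
#'
#' Computes activation-distance-versus-amplitude curves for every
#' combination of lead, tissue model, operating mode, direction and fibre
#' diameter; the standard sweep (4 leads x 2 tissue models x 2 modes x 4
#' directions x 13 diameters) yields 832 curves, each over the ten
#' amplitudes 0.5 to 5 in steps of 0.5 (V or mA by mode).
#'
#' @param solutions named list of `field_solution` objects, keyed
#'   `"<lead>|<tissue>|<mode>"` (e.g. `"3389|homogeneous|voltage"`); each
#'   solution's own amplitude is irrelevant (curves use linear rescaling).
#' @param diameters_um fibre diameters (default 1.5-7.5 by 0.5, 13 values).
#' @param amplitudes drive amplitudes (default 0.5-5 by 0.5).
#' @param directions directions to sweep (default all four).
#' @param pulse_width_us pulse width for all rows.
#' @param progress print per-curve progress.
#' @return an `activation_table` data frame: one row per curve with key
#'   columns plus `dist_<amplitude>` columns in mm; amplitudes stored in
#'   `attr(, "amplitudes")`.
#' @export
run_sweep <- function(solutions,
                      diameters_um = seq(1.5, 7.5, by = 0.5),
                      amplitudes = seq(0.5, 5, by = 0.5),
                      directions = c("anterior", "posterior", "medial",
                                     "lateral"),
                      pulse_width_us = 60, progress = FALSE) {
  keys <- strsplit(names(solutions), "|", fixed = TRUE)
  if (any(lengths(keys) != 3)) {
    stop("solution names must be '<lead>|<tissue>|<mode>'")
  }
  rows <- list()
  ri <- 0L
  for (si in seq_along(solutions)) {
    sol <- solutions[[si]]
    key <- keys[[si]]
    if (sol$mode != key[3]) {
      stop("solution '", names(solutions)[si], "' is not in ", key[3],
           " mode")
    }
    for (dir in directions) {
      lines <- extract_potential_lines(sol, dir)
      k_dia <- 0L  # warm start across diameters (distance grows with D)
      for (dia in sort(diameters_um)) {
        spec <- axon_spec(dia, pulse_width_us = pulse_width_us)
        cable <- build_cable(spec)
        st <- settle_state(cable, spec)
        k <- k_dia
        dist <- numeric(length(amplitudes))
        ord <- order(amplitudes)
        for (ai in ord) {
          k <- search_farthest(
            function(kk) line_activated(lines, cable, spec, kk,
                                        amplitudes[ai], st),
            length(lines$radius_mm), k)
          dist[ai] <- if (k == 0L) 0 else lines$radius_mm[k]
          if (ai == ord[1]) k_dia <- k
        }
        ri <- ri + 1L
        rows[[ri]] <- c(list(lead = key[1], tissue_model = key[2],
                             mode = key[3], direction = dir,
                             diameter_um = dia),
                        as.list(stats::setNames(
                          dist, sprintf("dist_%g", amplitudes))))
        if (progress) {
          message(sprintf("curve %d: %s %s %.1f um", ri,
                          names(solutions)[si], dir, dia))
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  attr(out, "amplitudes") <- amplitudes
  class(out) <- c("activation_table", class(out))
  out
}

#' Long-format view of an activation table
#'
#' @param table an `activation_table` from [run_sweep()].
#' @return data frame with one row per (curve, amplitude):
#'   lead, tissue_model, mode, direction, diameter_um, amplitude,
#'   activation_distance_mm.
#' @export
activation_long <- function(table) {
  amps <- attr(table, "amplitudes")
  keys <- table[, c("lead", "tissue_model", "mode", "direction",
                    "diameter_um")]
  out <- do.call(rbind, lapply(seq_along(amps), function(ai) {
    cbind(keys, amplitude = amps[ai],
          activation_distance_mm = table[[sprintf("dist_%g", amps[ai])]])
  }))
  rownames(out) <- NULL
  out
}

#' Calibrate the EF isolevel from activation distances
#'
#' Evaluates the EF magnitude at the activation distance for every
#' (amplitude, direction) entry of a given fibre diameter and returns the
#' median: the EF isolevel that tracks the activation boundary of that
#' fibre population. For 4 um fibres this lands near 0.2 V/mm.
#'
#' @param table an `activation_table`.
#' @param solutions the same named solution list used for the sweep.
#' @param diameter_um fibre diameter to calibrate on (must be in the table).
#' @return median EF magnitude (V/mm) at the activation distance.
#' @export
calibrate_isolevel <- function(table, solutions, diameter_um = 4) {
  amps <- attr(table, "amplitudes")
  sub <- table[table$diameter_um == diameter_um, ]
  if (nrow(sub) == 0) stop("diameter ", diameter_um, " um not in the table")
  dirvec <- list(anterior = c(0, 1), posterior = c(0, -1),
                 lateral = c(1, 0), medial = c(-1, 0))
  efs <- c()
  for (i in seq_len(nrow(sub))) {
    key <- paste(sub$lead[i], sub$tissue_model[i], sub$mode[i], sep = "|")
    sol <- solutions[[key]]
    if (is.null(sol)) stop("missing solution for ", key)
    zc <- sol$contact_center_local[3]
    dv <- dirvec[[sub$direction[i]]]
    ef_unit <- sol$ef / sol$amplitude
    ef_unit[is.na(ef_unit)] <- 0
    for (ai in seq_along(amps)) {
      d <- sub[[sprintf("dist_%g", amps[ai])]][i]
      if (d <= 0) next
      e <- grid_interp(sol$grid, ef_unit,
                       cbind(d * dv[1], d * dv[2], zc)) * amps[ai]
      efs <- c(efs, e)
    }
  }
  if (length(efs) == 0) stop("no activated entries to calibrate on")
  stats::median(efs)
}
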