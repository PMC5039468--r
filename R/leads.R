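.dbsfield_env <- new.env(parent = emptyenv())

#' Lead catalogue
#'
#' Reads the packaged YAML catalogue of lead dimensions (Medtronic 3389,
#' St. Jude 6148 and 6180, SureStim1). A custom catalogue file may be
#' supplied to override dimensions.
#'
#' @param path optional path to an alternative YAML catalogue.
#' @return named list of lead dimension sets plus the peri-electrode-space
#'   thickness.
#' @export
lead_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.dbsfield_env$catalogue)) {
      f <- system.file("extdata", "leads.yaml", package = "dbsfield")
      .dbsfield_env$catalogue <- yaml::read_yaml(f)
    }
    return(.dbsfield_env$catalogue)
  }
  yaml::read_yaml(path)
}

#' Build a parametric DBS lead
#'
#' Constructs the geometry of one of the four supported lead designs:
#' the cylindrical-contact leads 3389 and 6148, the split-ring steering lead
#' 6180, and the 40-contact SureStim1. Contacts are indexed bottom-up from
#' the tip (index 0 = most distal); split segments and SureStim1 contacts
#' are ordered by row then azimuth. Vendor contact labels (C0..C3 for
#' Medtronic, C1.. for St. Jude) are carried alongside the zero-based index.
#'
#' @param model_name one of `"3389"`, `"6148"`, `"6180"`, `"SureStim1"`.
#' @param tip_position numeric length 3, world position (mm) of the lowest
#'   point of the lead body.
#' @param axis unit vector pointing from the tip towards the entry point.
#' @param rotation_deg rotation of the contact azimuths about the lead axis
#'   (used to reorient directional contacts).
#' @param catalogue optional catalogue list from [lead_catalogue()].
#' @return a `dbs_lead` object with a `contacts` data frame (index, label,
#'   shape, axial_center, angular_center, height, arc/axes, area in mm^2).
#' @examples
#' lead <- build_lead("3389")
#' lead$contacts$area  # ~6 mm^2 each
#' @export
build_lead <- function(model_name, tip_position = c(0, 0, 0),
                       axis = c(0, 0, 1), rotation_deg = 0,
                       catalogue = NULL) {
  cat_all <- if (is.null(catalogue)) lead_catalogue() else catalogue
  model_name <- as.character(model_name)
  spec <- cat_all$leads[[model_name]]
  if (is.null(spec)) {
    stop("unknown lead model '", model_name, "'; available: ",
         paste(names(cat_all$leads), collapse = ", "))
  }
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6) {
    stop("`axis` must be a unit vector")
  }
  r <- spec$body_diameter / 2
  contacts <- switch(
    model_name,
    "3389" = , "6148" = ring_lead_contacts(spec, r),
    "6180" = split_ring_contacts(spec, r),
    "SureStim1" = surestim_contacts(spec, r))
  contacts$angular_center <- (contacts$angular_center + rotation_deg) %% 360
  structure(list(
    model_name = model_name,
    body_diameter = spec$body_diameter,
    contacts = contacts,
    insulation_gap = spec$insulation_gap %||% NA_real_,
    tip_position = as.numeric(tip_position),
    axis = axis,
    frame = lead_frame(axis),
    pes_thickness = cat_all$pes_thickness %||% 0.25,
    tip_contact = isTRUE(spec$tip_contact)
  ), class = "dbs_lead")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ring_lead_contacts <- function(spec, r) {
  n <- spec$n_ring_contacts
  h <- spec$contact_height
  gap <- spec$insulation_gap
  lo <- numeric(n); hi <- numeric(n); shape <- character(n)
  area <- numeric(n)
  z <- spec$tip_gap
  for (i in seq_len(n)) {
    if (i == 1 && isTRUE(spec$tip_contact)) {
      lo[i] <- 0; hi[i] <- spec$distal_contact_length
      shape[i] <- "ring_tip"
      # lateral band above the cap plus the hemispherical cap itself
      area[i] <- 2 * pi * r * (hi[i] - r) + 2 * pi * r^2
      z <- hi[i] + gap
    } else {
      lo[i] <- z; hi[i] <- z + h
      shape[i] <- "ring"
      area[i] <- 2 * pi * r * h
      z <- hi[i] + gap
    }
  }
  data.frame(
    index = seq_len(n) - 1L,
    label = paste0("C", spec$label_base + seq_len(n) - 1L),
    shape = shape, axial_lo = lo, axial_hi = hi,
    axial_center = (lo + hi) / 2, angular_center = 0,
    height = hi - lo, arc_deg = 360, ax_azimuthal = NA_real_,
    ax_axial = NA_real_, area = area, stringsAsFactors = FALSE)
}

split_ring_contacts <- function(spec, r) {
  h <- spec$contact_height
  gap <- spec$insulation_gap
  arc_rad <- spec$segment_area / (r * h)
  arc_deg <- arc_rad * 180 / pi
  rows <- list()
  z <- spec$tip_gap
  idx <- 0L
  for (ring in 1:4) {
    lo <- z; hi <- z + h
    if (ring %in% spec$split_rings) {
      for (sgt in 0:2) {
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          index = idx - 1L, label = paste0("C", spec$label_base + idx - 1L),
          shape = "split_segment", axial_lo = lo, axial_hi = hi,
          axial_center = (lo + hi) / 2, angular_center = sgt * 120,
          height = h, arc_deg = arc_deg, ax_azimuthal = NA_real_,
          ax_axial = NA_real_, area = spec$segment_area,
          stringsAsFactors = FALSE)
      }
    } else {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        index = idx - 1L, label = paste0("C", spec$label_base + idx - 1L),
        shape = "ring", axial_lo = lo, axial_hi = hi,
        axial_center = (lo + hi) / 2, angular_center = 0,
        height = h, arc_deg = 360, ax_azimuthal = NA_real_,
        ax_axial = NA_real_, area = 2 * pi * r * h,
        stringsAsFactors = FALSE)
    }
    z <- hi + gap
  }
  do.call(rbind, rows)
}

surestim_contacts <- function(spec, r) {
  a <- spec$ellipse_azimuthal / 2  # semi-axis along the azimuthal arc
  b <- spec$ellipse_axial / 2
  rows <- list()
  idx <- 0L
  for (row in 0:(spec$n_rows - 1L)) {
    zc <- spec$first_row_offset + b + row * spec$row_pitch
    base_ang <- if (row %% 2 == 1) spec$alternate_row_offset else 0
    for (k in 0:(spec$contacts_per_row - 1L)) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        index = idx - 1L,
        label = sprintf("R%dA%d", row + 1L, k + 1L),
        shape = "ellipse", axial_lo = zc - b, axial_hi = zc + b,
        axial_center = zc,
        angular_center = (base_ang + k * spec$row_angle_step) %% 360,
        height = 2 * b, arc_deg = NA_real_, ax_azimuthal = a, ax_axial = b,
        area = pi * a * b, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.dbs_lead <- function(x, ...) {
  cat(sprintf("<dbs_lead %s> diameter %.2f mm, %d contacts, PES %.2f mm\n",
              x$model_name, x$body_diameter, nrow(x$contacts),
              x$pes_thickness))
  cat(sprintf("  tip at (%.1f, %.1f, %.1f) mm, axis (%.2f, %.2f, %.2f)\n",
              x$tip_position[1], x$tip_position[2], x$tip_position[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Standard contact configurations
#'
#' Returns the stimulus configuration used for lead comparisons:
#' `ring_equivalent` activates the third contact (or the contact set
#' equivalent to one ring of a cylindrical lead) and `steering` activates an
#' azimuthally asymmetric subset. For 6180, ring-equivalent means the three
#' segments of the third ring (vendor contacts C5, C6, C7) and steering a
#' single segment (C5); for SureStim1, ring-equivalent is the eight contacts
#' of rows 6-7 and steering a four-contact diamond facing one azimuth.
#'
#' @param lead a `dbs_lead`.
#' @param scheme `"ring_equivalent"` or `"steering"`.
#' @param mode `"voltage"` or `"current"`.
#' @param amplitude drive amplitude; defaults to 3 V (voltage) or 3.4 mA
#'   (current), the study's equivalent pair.
#' @param pulse_width_us pulse width passed through to the axon model.
#' @return a `stimulus_config` with zero-based `active_contacts`.
#' @examples
#' cfg <- standard_config(build_lead("6180"), "ring_equivalent")
#' cfg$active_contacts  # indices 4, 5, 6 (vendor C5, C6, C7)
#' @export
standard_config <- function(lead, scheme = c("ring_equivalent", "steering"),
                            mode = c("voltage", "current"), amplitude = NULL,
                            pulse_width_us = 60) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  stopifnot(inherits(lead, "dbs_lead"))
  active <- switch(
    scheme,
    ring_equivalent = switch(
      lead$model_name,
      "3389" = 2L, "6148" = 2L,
      "6180" = 4:6,
      "SureStim1" = c(20:23, 24:27)),  # rows 6 and 7 (1-based)
    steering = switch(
      lead$model_name,
      "6180" = 4L,  # vendor C5: first segment of the third ring
      # diamond: two adjacent ring-6 contacts flanking azimuth 0 plus one
      # contact each from rings 5 and 7 at azimuth 0
      "SureStim1" = c(16L, 20L, 23L, 24L),
      stop("steering configuration is not applicable to lead ",
           lead$model_name)))
  if (is.null(amplitude)) amplitude <- if (mode == "voltage") 3 else 3.4
  stopifnot(length(active) >= 1, amplitude > 0)
  structure(list(
    active_contacts = as.integer(active),
    active_labels = lead$contacts$label[match(active, lead$contacts$index)],
    mode = mode, amplitude = amplitude, pulse_width_us = pulse_width_us,
    scheme = scheme,
    label = sprintf("%s_%s_%s_%g%s", lead$model_name, scheme, mode,
                    amplitude, if (mode == "voltage") "V" else "mA")
  ), class = "stimulus_config")
}

#' Custom stimulus configuration
#'
#' @param active_contacts zero-based contact indices to drive as one
#'   electrically common source.
#' @inheritParams standard_config
#' @param label optional run label.
#' @export
stimulus_config <- function(active_contacts, mode = c("voltage", "current"),
                            amplitude, pulse_width_us = 60, label = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(active_contacts) >= 1, amplitude > 0)
  structure(list(
    active_contacts = as.integer(active_contacts), active_labels = NULL,
    mode = mode, amplitude = amplitude, pulse_width_us = pulse_width_us,
    scheme = "custom",
    label = label %||% sprintf("custom_%s_%g", mode, amplitude)
  ), class = "stimulus_config")
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat(sprintf("<stimulus_config %s> %s mode, %g %s, contacts {%s}\n",
              x$scheme, x$mode, x$amplitude,
              if (x$mode == "voltage") "V" else "mA",
              paste(x$active_contacts, collapse = ", ")))
  invisible(x)
}

#' Total active contact surface area
#'
#' @param lead a `dbs_lead`.
#' @param config a `stimulus_config`.
#' @return summed geometric area (mm^2) of the active contacts.
#' @export
active_area <- function(lead, config) {
  sum(lead$contacts$area[lead$contacts$index %in% config$active_contacts])
}

# Axial centre (mm from tip) of the active contact set
active_center_z <- function(lead, config) {
  cc <- lead$contacts[lead$contacts$index %in% config$active_contacts, ]
  if (nrow(cc) == 0) stop("no active contacts found on lead")
  (min(cc$axial_lo) + max(cc$axial_hi)) / 2
}
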