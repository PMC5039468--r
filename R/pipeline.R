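#' Built-in simulation campaign specification
#'
#' Enumerates the runs of the standard electric-field campaign (38 runs in
#' five stages) or the neuron-model sweep (832 activation-distance curves).
#' The EF stages: (1) lead 3389 in the homogeneous and both heterogeneous
#' target models, both modes (n = 6); (2) all four leads at both targets,
#' both modes (n = 16); (3) the patient-amplitude scenario at the first
#' target: 1.6 V, its equivalent current, and the standard 3 V / 3.4 mA
#' pair (n = 4); (4) steering configurations of 6180 and SureStim1 at both
#' targets, both modes (n = 8); (5) steering at the reduced amplitudes
#' (1.6 V / 1.3 mA) where the steered profile is visible (n = 4).
#'
#' @param kind `"ef"` (38 field runs) or `"neuron"` (832 sweep curves).
#' @return a `campaign_spec` data frame, one row per run / curve.
#' @export
campaign_spec <- function(kind = c("ef", "neuron")) {
  kind <- match.arg(kind)
  if (kind == "neuron") {
    grid <- expand.grid(
      lead = c("3389", "6148", "6180", "SureStim1"),
      tissue = c("homogeneous", "heterogeneous"),
      mode = c("voltage", "current"),
      direction = c("anterior", "posterior", "medial", "lateral"),
      diameter_um = seq(1.5, 7.5, by = 0.5),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$label <- sprintf("neuron_%s_%s_%s_%s_%.1fum", grid$lead,
                          grid$tissue, grid$mode, grid$direction,
                          grid$diameter_um)
    class(grid) <- c("campaign_spec", class(grid))
    return(grid)
  }
  leads <- c("3389", "6148", "6180", "SureStim1")
  std_amp <- function(mode) ifelse(mode == "voltage", 3, 3.4)
  s1 <- expand.grid(tissue = c("homogeneous", "zi", "vim"),
                    mode = c("voltage", "current"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s1 <- data.frame(stage = 1L, lead = "3389", scheme = "ring_equivalent",
                   s1, amplitude = std_amp(s1$mode))
  s2 <- expand.grid(lead = leads, tissue = c("zi", "vim"),
                    mode = c("voltage", "current"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s2 <- data.frame(stage = 2L, lead = s2$lead, scheme = "ring_equivalent",
                   tissue = s2$tissue, mode = s2$mode,
                   amplitude = std_amp(s2$mode))
  s3 <- data.frame(stage = 3L, lead = "3389", scheme = "ring_equivalent",
                   tissue = "zi",
                   mode = c("voltage", "current", "voltage", "current"),
                   amplitude = c(1.6, NA, 3, 3.4))  # NA: equivalent current
  s4 <- expand.grid(lead = c("6180", "SureStim1"), tissue = c("zi", "vim"),
                    mode = c("voltage", "current"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s4 <- data.frame(stage = 4L, lead = s4$lead, scheme = "steering",
                   tissue = s4$tissue, mode = s4$mode,
                   amplitude = std_amp(s4$mode))
  s5 <- expand.grid(lead = c("6180", "SureStim1"),
                    mode = c("voltage", "current"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s5 <- data.frame(stage = 5L, lead = s5$lead, scheme = "steering",
                   tissue = "zi", mode = s5$mode,
                   amplitude = ifelse(s5$mode == "voltage", 1.6, 1.3))
  spec <- rbind(s1, s2, s3, s4, s5)
  spec$label <- sprintf("ef%02d_%s_%s_%s_%s_%s", seq_len(nrow(spec)),
                        spec$lead, spec$scheme, spec$tissue, spec$mode,
                        ifelse(is.na(spec$amplitude), "eq",
                               sprintf("%g", spec$amplitude)))
  stopifnot(!anyDuplicated(spec$label))
  class(spec) <- c("campaign_spec", class(spec))
  spec
}

#' Tissue models and lead placements for a campaign
#'
#' Builds the homogeneous grey-matter volume and a seeded synthetic
#' heterogeneous volume with two virtual targets 4 mm apart along the
#' trajectory.
#'
#' @param seed integer seed for the synthetic volume.
#' @param synthetic_spec optional [synthetic_brain_spec()] override (its
#'   seed is replaced by `seed`).
#' @return list with `homogeneous` and `heterogeneous` volumes and the
#'   `targets` (tip positions and axis).
#' @export
campaign_volumes <- function(seed = 1L, synthetic_spec = NULL) {
  spec <- synthetic_spec %||% synthetic_brain_spec(seed = seed)
  spec$seed <- seed
  het <- generate_brain(spec)
  tg <- virtual_targets(spec)
  list(homogeneous = homogeneous_volume(spec$side_mm),
       heterogeneous = het, targets = tg, seed = seed)
}

# lead tip placement per campaign tissue label
campaign_lead <- function(model, tissue, volumes) {
  tip <- switch(tissue, homogeneous = c(0, 0, 0),
                zi = volumes$targets$zi, vim = volumes$targets$vim,
                heterogeneous = volumes$targets$zi)
  axis <- if (tissue == "homogeneous") c(0, 0, 1) else volumes$targets$axis
  build_lead(model, tip_position = tip, axis = axis)
}

#' Run an electric-field campaign
#'
#' Executes every run of an EF `campaign_spec`: solves the field, computes
#' the isolevel volume, per-plane maximal extensions and total current, and
#' (optionally) writes per-run artifacts, an aggregate results CSV and a
#' JSON manifest. A failed run is recorded and the campaign continues.
#' One linear solve is shared between the voltage and current run of the
#' same geometry.
#'
#' @param spec an EF `campaign_spec` (see [campaign_spec()]).
#' @param volumes output of [campaign_volumes()] (or a compatible list).
#' @param options [solver_options()] used for all runs.
#' @param isolevel EF isolevel (V/mm) for the metrics.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param progress print per-run progress.
#' @return list with `results` (one metrics row per run), `manifest`
#'   (solver statistics per run) and `n_failed`.
#' @export
run_campaign <- function(spec, volumes, options = solver_options(),
                         isolevel = 0.2, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "campaign_spec"), "stage" %in% names(spec))
  cache <- new.env(parent = emptyenv())
  results <- list()
  manifest <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(spec))) {
    run <- spec[i, ]
    res <- tryCatch({
      vol <- if (run$tissue == "homogeneous") volumes$homogeneous
             else volumes$heterogeneous
      lead <- campaign_lead(run$lead, run$tissue, volumes)
      ckey <- paste(run$lead, run$scheme, run$tissue, sep = "|")
      base <- get0(ckey, envir = cache)
      if (is.null(base)) {
        cfg <- standard_config(lead, run$scheme, mode = "voltage",
                               amplitude = 1)
        base <- solve_field(vol, lead, cfg, options)
        assign(ckey, base, envir = cache)
      }
      amp <- run$amplitude
      if (is.na(amp)) {
        # equivalent current of the stage's programmed voltage (1.6 V)
        amp <- at_amplitude(base, "voltage", 1.6)$total_current_mA
      }
      sol <- at_amplitude(base, run$mode, amp)
      ext <- vapply(c("axial", "sagittal", "coronal"), function(p) {
        max_extension(sol, p, isolevel)
      }, numeric(1))
      list(
        row = data.frame(
          label = run$label, stage = run$stage, lead = run$lead,
          scheme = run$scheme, tissue = run$tissue, mode = run$mode,
          amplitude = amp, total_current_mA = sol$total_current_mA,
          contact_potential_V = sol$contact_potential_V,
          volume_mm3 = isosurface_volume(sol, isolevel),
          ext_axial_mm = ext[["axial"]], ext_sagittal_mm = ext[["sagittal"]],
          ext_coronal_mm = ext[["coronal"]], failed = FALSE),
        stats = c(list(label = run$label), sol$solver_stats))
    }, error = function(e) {
      list(row = data.frame(
             label = run$label, stage = run$stage, lead = run$lead,
             scheme = run$scheme, tissue = run$tissue, mode = run$mode,
             amplitude = run$amplitude, total_current_mA = NA_real_,
             contact_potential_V = NA_real_, volume_mm3 = NA_real_,
             ext_axial_mm = NA_real_, ext_sagittal_mm = NA_real_,
             ext_coronal_mm = NA_real_, failed = TRUE),
           stats = list(label = run$label, error = conditionMessage(e)))
    })
    if (isTRUE(res$row$failed)) n_failed <- n_failed + 1L
    results[[i]] <- res$row
    manifest[[i]] <- res$stats
    if (progress) message("run ", run$label, if (isTRUE(res$row$failed))
      " FAILED" else "")
  }
  results <- do.call(rbind, results)
  out <- list(results = results, manifest = manifest, n_failed = n_failed,
              seed = volumes$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "campaign_results.csv")
    utils::write.csv(results, csv, row.names = FALSE)
    jsonlite::write_json(
      list(seed = volumes$seed, n_runs = nrow(results),
           n_failed = n_failed, runs = manifest,
           checksums = as.list(tools::md5sum(csv))),
      file.path(out_dir, "campaign_manifest.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  }
  out
}

#' Field solutions feeding the neuron sweep
#'
#' Solves the unit-drive field for each lead in the homogeneous and the
#' heterogeneous tissue model (ring-equivalent configuration) and returns
#' the 16 entries keyed `"<lead>|<tissue>|<mode>"` expected by
#' [run_sweep()]; the voltage and current entry of one geometry share a
#' single linear solve.
#'
#' @param volumes output of [campaign_volumes()].
#' @param options [solver_options()].
#' @param leads lead models to include.
#' @return named list of 16 `field_solution` objects.
#' @export
neuron_campaign_solutions <- function(volumes, options = solver_options(),
                                      leads = c("3389", "6148", "6180",
                                                "SureStim1")) {
  out <- list()
  for (lm in leads) {
    for (tissue in c("homogeneous", "heterogeneous")) {
      vol <- volumes[[tissue]]
      lead <- campaign_lead(lm, tissue, volumes)
      cfg <- standard_config(lead, "ring_equivalent", mode = "voltage",
                             amplitude = 1)
      base <- solve_field(vol, lead, cfg, options)
      out[[paste(lm, tissue, "voltage", sep = "|")]] <- base
      out[[paste(lm, tissue, "current", sep = "|")]] <-
        at_amplitude(base, "current", 1)
    }
  }
  out
}

#' Patient-amplitude scenario
#'
#' Reproduces the clinical-setting analysis: solve the field at the
#' programmed voltage, compute the equivalent current, re-express the
#' solution in current mode, and report isolevel volume and per-plane
#' extension for both operating modes.
#'
#' @param volume tissue model (typically heterogeneous).
#' @param lead a `dbs_lead` placed at the implant target.
#' @param voltage programmed amplitude in volts (default 1.6).
#' @param options [solver_options()].
#' @param isolevel EF isolevel (V/mm).
#' @return list with `equivalent_current_mA` and a `report` data frame
#'   (one row per mode: volume and extensions).
#' @export
scenario_patient_amplitude <- function(volume, lead, voltage = 1.6,
                                       options = solver_options(),
                                       isolevel = 0.2) {
  cfg <- standard_config(lead, "ring_equivalent", mode = "voltage",
                         amplitude = voltage)
  sol_v <- solve_field(volume, lead, cfg, options)
  eq_mA <- sol_v$total_current_mA
  sol_i <- at_amplitude(sol_v, "current", eq_mA)
  mk <- function(sol, mode, amp) {
    data.frame(mode = mode, amplitude = amp,
               volume_mm3 = isosurface_volume(sol, isolevel),
               ext_axial_mm = max_extension(sol, "axial", isolevel),
               ext_sagittal_mm = max_extension(sol, "sagittal", isolevel),
               ext_coronal_mm = max_extension(sol, "coronal", isolevel))
  }
  list(equivalent_current_mA = eq_mA,
       report = rbind(mk(sol_v, "voltage", voltage),
                      mk(sol_i, "current", eq_mA)))
}
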