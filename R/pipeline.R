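# Orchestration: one call that runs QC -> standard/master curves ->
# occupancy -> delta-Ct -> performance over either plate CSV inputs or a
# simulation configuration, and writes the report bundle.

#' Load a bundled validation summary table
#'
#' The package ships small CSV transcriptions of the summary tables of an
#' analytical validation study of allele-specific ctDNA qPCR assays
#' (dilution standards, paired delta-Ct means, limiting-dilution occupancy
#' counts, analytical confusion counts, and clinical detection counts), so
#' the whole pipeline can be exercised without laboratory data.
#'
#' @param name One of `"dilution_standards"`, `"delta_ct_panel"`,
#'   `"occupancy_panel"`, `"analytical_performance"`,
#'   `"clinical_specificity"`, `"clinical_detection_lung"`,
#'   `"clinical_detection_latam"`.
#' @return A tibble.
#' @export
validation_fixture <- function(name = c("dilution_standards", "delta_ct_panel",
                                        "occupancy_panel",
                                        "analytical_performance",
                                        "clinical_specificity",
                                        "clinical_detection_lung",
                                        "clinical_detection_latam")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "poisqpcr",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run configuration for a full validation analysis
#'
#' Exactly one input source must be given: paths to plate CSVs, or a
#' simulation configuration.
#'
#' @param plate_paths Character vector of plate CSV paths, or `NULL`.
#' @param sim A [simulation_config()], or `NULL`.
#' @param qc A [qc_config()].
#' @param out_dir Optional output directory for report files.
#' @param format Report format, `"tsv"` or `"json"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(plate_paths = NULL, sim = NULL, qc = qc_config(),
                       out_dir = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(plate_paths) == is.null(sim)) {
    abort("provide exactly one of plate_paths or sim",
          class = "poisqpcr_config_error")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "simulation_config"))
  stopifnot(inherits(qc, "qc_config"))
  structure(list(plate_paths = plate_paths, sim = sim, qc = qc,
                 out_dir = out_dir, format = format),
            class = "run_config")
}

#' Run the full validation pipeline
#'
#' Stages: load or simulate plate data; apply QC; fit per-plate standard
#' curves and a pooled master curve per target; summarize Poisson
#' occupancy per (target, standard); summarize reproducibility under the
#' 1-Ct rule; and, when both background conditions are present, the paired
#' delta-Ct analysis. Deterministic given the inputs (and the simulation
#' seed). When `cfg$out_dir` is set, every table is also written there.
#'
#' @param cfg A [run_config()].
#' @param targets Targets to simulate when in simulation mode.
#' @return Named list of result tables: `wells`, `qc_flagged`,
#'   `curve_table`, `occupancy`, `reproducibility_intra`,
#'   `reproducibility_inter`, `delta_ct` (NULL if single-condition), plus
#'   `summary` (one row per target with master-curve stats).
#' @export
run_validation <- function(cfg, targets = c("BRAF_V600", "EGFR_DEL19")) {
  stopifnot(inherits(cfg, "run_config"))
  wells <- if (!is.null(cfg$plate_paths)) {
    dplyr::bind_rows(lapply(cfg$plate_paths, read_plate_table))
  } else {
    dplyr::bind_rows(lapply(targets, function(t) {
      simulate_curve_plates(cfg$sim, target = t)
    }))
  }
  qc_split <- apply_qc(wells, cfg$qc)
  passing <- qc_split$passing

  amp <- passing[!is.na(passing$ct) & !is.na(passing$truth_copies) &
                   passing$truth_copies > 0, , drop = FALSE]
  curve_tables <- lapply(split(amp, amp$target), function(grp) {
    mc <- build_master_curve(
      tibble::tibble(copies = grp$truth_copies, ct = grp$ct,
                     plate = grp$plate, target = grp$target),
      group_id = "master")
    tbl <- master_curve_table(mc)
    tbl$target <- grp$target[1]
    list(table = tbl, master = mc$master)
  })
  curve_table <- dplyr::bind_rows(lapply(curve_tables, `[[`, "table"))

  occupancy <- occupancy_summary(passing)
  repro_intra <- reproducibility_summary(passing, mode = "intra")
  repro_inter <- reproducibility_summary(passing, mode = "inter",
                                         unit = "instrument")

  delta <- NULL
  has_both <- length(unique(passing$wt_copies > 0)) == 2
  if (has_both) {
    means <- passing |>
      dplyr::filter(!is.na(.data$ct)) |>
      dplyr::group_by(.data$target, .data$standard,
                      condition = ifelse(.data$wt_copies > 0, "with_wt", "no_wt")) |>
      dplyr::summarise(mean_ct = mean(.data$ct), .groups = "drop")
    delta <- delta_ct_table(delta_summary(pair_deltas(means)))
  }

  summary_tbl <- dplyr::bind_rows(lapply(names(curve_tables), function(t) {
    m <- curve_tables[[t]]$master
    tibble::tibble(target = t, master_slope = m$slope,
                   master_intercept = m$intercept,
                   master_r_squared = m$r_squared,
                   master_efficiency = m$efficiency,
                   n_points = m$n_points)
  }))

  out <- list(wells = wells, qc_flagged = qc_split$flagged,
              curve_table = curve_table, occupancy = occupancy,
              reproducibility_intra = repro_intra,
              reproducibility_inter = repro_inter,
              delta_ct = delta, summary = summary_tbl)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    ext <- if (cfg$format == "tsv") ".tsv" else ".json"
    for (nm in setdiff(names(out), "wells")) {
      if (!is.null(out[[nm]]) && nrow(out[[nm]]) > 0) {
        write_report(stats::setNames(list(out[[nm]]), nm),
                     file.path(cfg$out_dir, paste0(nm, ext)),
                     format = cfg$format)
      }
    }
  }
  out
}
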