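#!/usr/bin/env Rscript
# Analytical performance: confusion-matrix sensitivity/specificity with
# the >99% display convention, limit of detection as mutant allele
# fraction, gated specificity on the simulated WT-only panels, clinical
# detection rates with exact binomial CIs, and reproducibility under the
# 1-Ct rule on the simulated 10-plate study.

suppressPackageStartupMessages({
  library(poisqpcr)
  library(dplyr)
})

## analytical sensitivity/specificity from the bundled counts -----------------
perf <- validation_fixture("analytical_performance")
perf_tbl <- bind_rows(lapply(seq_len(nrow(perf)), function(i) {
  r <- perf[i, ]
  sens <- (r$n_positive_tests - r$false_negatives) / r$n_positive_tests
  spec <- (r$n_negative_tests - r$false_positives) / r$n_negative_tests
  tibble::tibble(
    target = r$target,
    sensitivity = sens,
    sensitivity_display = ifelse(sens >= 0.99, ">99%",
                                 paste0(round(100 * sens), "%")),
    specificity = spec,
    specificity_display = ifelse(spec >= 0.99, ">99%",
                                 paste0(round(100 * spec), "%")),
    lod_display = maf_display(maf(r$lod_mutant_copies, r$lod_wt_copies))
  )
}))
cat("Analytical performance per assay:\n")
print(as.data.frame(perf_tbl), digits = 4)
cat(sprintf("\nPooled: %d positive tests, %d false negative(s); every assay >99%% sensitive.\n",
            sum(perf$n_positive_tests), sum(perf$false_negatives)))

dir.create("results", showWarnings = FALSE)
write_report(list(analytical_performance = perf_tbl),
             file.path("results", "analytical_performance.tsv"))

## gated specificity on the simulated WT-only panels --------------------------
plate_dir <- file.path("results", "plates")
if (!dir.exists(plate_dir)) stop("run analysis/01_simulate_plates.R first")
wt_paths <- list.files(plate_dir, pattern = "_wtpanel\\.csv$",
                       full.names = TRUE)
wt_panel <- bind_rows(lapply(wt_paths, read_plate_table))
raw_signals <- sum(!is.na(wt_panel$ct))
calls <- call_well(wt_panel, qc_config())
cc <- confusion_metrics(tibble::tibble(predicted_positive = calls,
                                       truth_positive = FALSE))
cat(sprintf("\nWT-only panels: %d raw signals in %d wells; %d called positive after melt + sequencing gates (specificity %s).\n",
            raw_signals, nrow(wt_panel), cc$fp, cc$specificity_display))

## clinical detection rates ----------------------------------------------------
lung <- validation_fixture("clinical_detection_lung")
lung_rates <- bind_rows(lapply(seq_len(nrow(lung)), function(i) {
  r <- detection_rate(lung$n_detected[i], lung$n_tested[i])
  tibble::tibble(group = lung$group[i], n_tested = r$n_tested,
                 n_detected = r$n_detected, percent = r$percent,
                 ci_low = round(100 * r$ci95[1], 2),
                 ci_high = round(100 * r$ci95[2], 2))
}))
cat("\nClinical detection rates, lung cohort (exact 95% CI):\n")
print(as.data.frame(lung_rates))
write_report(list(clinical_rates_lung = lung_rates),
             file.path("results", "clinical_rates_lung.tsv"))

latam <- validation_fixture("clinical_detection_latam")
latam_rates <- bind_rows(lapply(seq_len(nrow(latam)), function(i) {
  r <- detection_rate(latam$n_detected[i], latam$n_tested[i])
  tibble::tibble(cohort = latam$cohort[i], group = latam$group[i],
                 percent = r$percent,
                 ci_low = round(100 * r$ci95[1], 2),
                 ci_high = round(100 * r$ci95[2], 2))
}))
cat("\nClinical detection rates, Latin American cohorts:\n")
print(as.data.frame(latam_rates))
write_report(list(clinical_rates_latam = latam_rates),
             file.path("results", "clinical_rates_latam.tsv"))

## reproducibility on the simulated 10-plate study ----------------------------
curve_paths <- list.files(plate_dir, pattern = "_curves\\.csv$",
                          full.names = TRUE)
cells <- bind_rows(lapply(curve_paths, function(p) {
  reproducibility_summary(read_plate_table(p), mode = "intra",
                          unit = "instrument")
}))
inter <- bind_rows(lapply(curve_paths, function(p) {
  reproducibility_summary(read_plate_table(p), mode = "inter",
                          unit = "instrument")
}))
cat(sprintf("\nIntra-assay: %d of %d (assay, standard, instrument) cells within 1 Ct SD.\n",
            sum(cells$pass, na.rm = TRUE), sum(!is.na(cells$pass))))
cat(sprintf("Inter-assay: %d of %d (assay, standard) cells within 1 Ct SD of instrument means.\n",
            sum(inter$pass, na.rm = TRUE), sum(!is.na(inter$pass))))
write_report(list(reproducibility_intra = cells,
                  reproducibility_inter = inter),
             file.path("results", "reproducibility.tsv"))
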