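#!/usr/bin/env Rscript
# Generate the synthetic plate data the downstream analyses consume:
# a limiting-dilution series per assay target (standards A-G, Poisson
# per-well copies, dropout at the low end), a 10-plate standard-curve
# study across 5 instruments, and a wild-type-only specificity panel.
# Everything is reproducible from one seed.

suppressPackageStartupMessages(library(poisqpcr))

seed <- 20260922L
out_dir <- file.path("results", "plates")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
targets <- setdiff(ASSAY_TARGETS, "EGFR_WT")

for (t in targets) {
  dil <- simulate_dilution_series(cfg, t)
  write_plate_table(dil, file.path(out_dir, paste0(tolower(t), "_dilution.csv")))

  curves <- simulate_curve_plates(cfg, t, n_plates = 10, n_instruments = 5)
  write_plate_table(curves, file.path(out_dir, paste0(tolower(t), "_curves.csv")))

  wt <- simulate_wt_specificity_panel(simulation_config(seed = seed,
                                                        fp_rate = 0.1),
                                      n_wells = 112, target = t)
  write_plate_table(wt, file.path(out_dir, paste0(tolower(t), "_wtpanel.csv")))

  empties <- sum(is.na(dil$ct))
  cat(sprintf("%-11s dilution series: %3d wells, %2d empty; curve study: %d wells\n",
              t, nrow(dil), empties, nrow(curves)))
}

gt <- ground_truth_table(cfg)
readr::write_csv(gt, file.path("results", "ground_truth.csv"))
cat("\nGround truth (per standard):\n")
print(as.data.frame(gt), digits = 3)
cat(sprintf("\nWrote plate CSVs for %d targets under %s\n",
            length(targets), out_dir))
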