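#!/usr/bin/env Rscript
# Poisson occupancy analysis of the limiting-dilution wells: theoretical
# empty-well expectations, dropout-based lambda estimates with exact CIs,
# censored maximum-likelihood estimates, and the proficiency check of
# observed positives against the Poisson expectation. Runs on both the
# simulated dilution series and the bundled occupancy panel.

suppressPackageStartupMessages({
  library(poisqpcr)
  library(dplyr)
})

cat("Theoretical percent of empty wells by mean copy input:\n")
print(as.data.frame(theoretical_empty_table(1:10)))

plate_dir <- file.path("results", "plates")
if (!dir.exists(plate_dir)) stop("run analysis/01_simulate_plates.R first")

dil_paths <- list.files(plate_dir, pattern = "_dilution\\.csv$",
                        full.names = TRUE)
sim_occ <- bind_rows(lapply(dil_paths, function(p) {
  wells <- read_plate_table(p)
  # per-well copy estimates from that target's own curve, for the MLE
  amp <- wells[!is.na(wells$ct) & wells$standard %in% LETTERS[1:4], ]
  fit <- fit_standard_curve(tibble::tibble(copies = amp$truth_copies,
                                           ct = amp$ct),
                            group_id = wells$target[1])
  wells$copies <- ifelse(is.na(wells$ct), 0, interpolate_copies(wells$ct, fit))
  occupancy_summary(wells)
}))
low <- sim_occ |> filter(standard %in% c("E", "F", "G"))
cat("\nSimulated limiting standards, dropout vs censored MLE:\n")
print(as.data.frame(low), digits = 3)
write_report(list(occupancy_simulated = sim_occ),
             file.path("results", "occupancy_simulated.tsv"))

# proficiency: observed positives vs the Poisson expectation at the
# dropout-estimated content
prof <- low |>
  rowwise() |>
  mutate(n_positive = n_wells - n_empty,
         pass = ifelse(is.finite(lambda_dropout),
                       proficiency_check(n_positive, n_wells,
                                         lambda_dropout)$pass, NA)) |>
  ungroup()
cat(sprintf("\nProficiency: %d of %d limiting cells consistent with Poisson\n",
            sum(prof$pass, na.rm = TRUE), sum(!is.na(prof$pass))))

# the bundled occupancy panel: every numeric printed cell reproduces from
# raw counts through -log(empty fraction)
panel <- validation_fixture("occupancy_panel") |> filter(!is.na(n_wells))
panel_est <- panel |>
  rowwise() |>
  mutate(lambda_dropout = lambda_from_dropout(n_empty, n_wells)$lambda_dropout,
         lambda_rendered = format_lambda(lambda_dropout),
         truncated_mean = ifelse(is.finite(lambda_dropout) & lambda_dropout > 0,
                                 zero_truncated_mean(lambda_dropout), NA)) |>
  ungroup()
cat("\nBundled occupancy panel (lambda from dropout, rendered):\n")
print(as.data.frame(panel_est |>
  select(target, standard, n_empty, n_wells, lambda_rendered,
         printed_poisson_copies)), digits = 3)
write_report(list(occupancy_panel = panel_est |>
                    select(-printed_percent_empty, -printed_poisson_copies)),
             file.path("results", "occupancy_panel.tsv"))
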