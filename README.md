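# poisqpcr

Poisson occupancy statistics and analytical validation for
limiting-dilution qPCR assays.

## What problem this solves

Allele-specific qPCR assays for circulating tumor DNA (ctDNA) are asked
to find one mutant molecule among ~14,000 wild-type (WT) genome copies.
At single-copy inputs, a well with no signal is usually not an assay
failure: loading an average of λ copies per well delivers
Poisson-distributed counts, and a fraction exp(−λ) of wells receive zero
copies — 36.79% at λ = 1. Validating such an assay means separating
sampling zeros from chemistry failures, and this package implements the
statistical machinery that does it:

* **Occupancy model** — theoretical empty-well fractions exp(−λ);
  dropout estimates λ̂ = −log(n₀/n) with exact Clopper–Pearson intervals
  (and the conventional ">10" rendering when no well is empty); a
  censored maximum-likelihood estimator combining the empty-well count
  with per-well copy estimates; the zero-truncated mean λ/(1−e^−λ); and
  an exact binomial proficiency check of observed positives against the
  Poisson expectation.
* **Quantitation** — log-linear standard curves Ct = a + b·log₁₀(copies)
  with efficiency 10^(−1/b) − 1, pooled master curves across
  plates/instruments with auditable per-plate member fits, copy
  interpolation, and reportable-range determination.
* **Interference** — paired ΔCt analysis of the WT background
  (without-WT minus with-WT mean Ct per assay/standard cell).
* **Performance** — confusion-matrix sensitivity/specificity with the
  ">99%" display convention, detection-based limit of detection
  expressed as mutant allele fraction (MAF = m/(m + WT), floored at
  0.01%), Clopper–Pearson detection rates, and the 1-Ct SD
  reproducibility rule.
* **Synthetic plates** — a seeded generator with Poisson per-well
  copies, log-linear Ct response evaluated at the realized copy number,
  empty-well dropout, a systematic WT-background shift, melt
  temperatures for specific vs non-specific products, and rare false
  positives, so the full pipeline is testable with no laboratory data.

Small CSV transcriptions of the validation study's summary tables
(dilution standards, ΔCt panel, occupancy counts, analytical confusion
counts, clinical detection counts) ship in `inst/extdata/` and load via
`validation_fixture()`.

## Worked example

```r
library(poisqpcr)

# How many wells stay empty at one copy per well, in theory?
theoretical_empty_table(c(1, 2, 3))
#> # A tibble: 3 × 2
#>     lam percent_empty
#>   <dbl>         <dbl>
#> 1     1         36.8
#> 2     2         13.5
#> 3     3          4.98

# 26 of 60 replicate wells at the lowest standard gave no signal:
lambda_from_dropout(26, 60)
#> <occupancy_estimate> 26/60 empty (43.3%), lambda = 0.84 [0.57, 1.18]

# so those wells contained ~0.84 mutant copies on average, and the
# occupied ones held lambda/(1 - exp(-lambda)) copies:
zero_truncated_mean(0.84)
#> [1] 1.477833

# a full simulated 10-plate curve study recovers its generating curve:
cfg <- simulation_config(seed = 7)
wells <- simulate_curve_plates(cfg, "BRAF_V600", n_plates = 10)
amp <- wells[!is.na(wells$ct), ]
mc <- build_master_curve(
  tibble::tibble(copies = amp$truth_copies, ct = amp$ct, plate = amp$plate))
mc$master
#> <standard_curve_fit 'master'> Ct = 38.438 -3.505 * log10(copies)  (n = 120)
#>   r^2 = 0.9658, efficiency = 92.9%

# and one mutant copy against 14,000 WT copies is the canonical LoD:
maf_display(maf(1, 14000))
#> [1] "0.01%"
```

The `lambda = 0.84` line says the dropout fraction alone pins the mean
copy input of a nominally ~1-copy standard to below a single copy per
well, with an exact interval that excludes zero — the statistical core
of a single-copy sensitivity claim. The master-curve line shows the
pooled 120-point fit returning the generating slope (−3.45) within
sampling error at r² ≈ 0.97.

## Analysis workflow

Numbered drivers under `analysis/` run the full validation narrative and
write their tables under `results/`:

1. `01_simulate_plates.R` — seeded dilution series, 10-plate curve
   studies, and WT-only specificity panels for all five mutant assays.
2. `02_standard_curves.R` — QC, per-plate and master curves,
   reportable range.
3. `03_occupancy.R` — theoretical table, dropout and censored-MLE λ,
   proficiency checks; also re-derives every numeric occupancy cell of
   the bundled panel.
4. `04_interference.R` — paired ΔCt analysis of the bundled panel plus
   a generator consistency check.
5. `05_performance.R` — sensitivity/specificity/LoD, gated specificity
   on simulated WT panels, clinical detection rates with exact CIs,
   reproducibility under the 1-Ct rule.

```sh
Rscript analysis/01_simulate_plates.R   # then 02..05 in order
```

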