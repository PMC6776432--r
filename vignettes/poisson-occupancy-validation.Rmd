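---
title: "Poisson occupancy statistics and analytical validation of single-copy qPCR assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson occupancy statistics and analytical validation of single-copy qPCR assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poisqpcr)
```

## The problem

Circulating tumor DNA (ctDNA) assays must detect a handful of mutant
molecules in a background of roughly 14,000 wild-type (WT) genome copies
per reaction. At that input level the question "did the assay detect the
mutant?" becomes inseparable from the question "did the well contain a
mutant molecule at all?": pipetting an average of $\lambda$ copies into a
well delivers a Poisson-distributed count, and a fraction $e^{-\lambda}$
of wells receive zero copies no matter how sensitive the chemistry is.
Analytical validation of a single-copy assay therefore has to disentangle
chemistry failures from sampling zeros, and every statistic in this
package exists to serve that separation.

`poisqpcr` implements the statistical layer of such a validation:
occupancy modelling of limiting-dilution wells, standard-curve
quantitation, a paired interference analysis for the WT background,
confusion-matrix performance metrics with a mutant-allele-fraction (MAF)
limit of detection, and a seeded plate simulator so that every estimator
can be exercised, and its calibration checked, without laboratory data.

## The occupancy model

A well loaded with an average of $\lambda$ mutant copies contains $k$
copies with probability $e^{-\lambda}\lambda^k/k!$. Three estimators of
$\lambda$ are provided, in increasing order of information used:

* **Theory** — `expected_empty_fraction(lam)` returns $e^{-\lambda}$, and
  `theoretical_empty_table()` tabulates it as a percentage; at
  $\lambda = 1$, 36.79% of wells are expected empty.
* **Dropout** — `lambda_from_dropout(n_empty, n_wells)` inverts the
  observed empty fraction: $\hat\lambda = -\log(n_0/n)$. The 95% interval
  inverts exact Clopper–Pearson bounds on the empty fraction through
  $-\log$; because the transform is monotone decreasing, the upper
  fraction bound becomes the lower $\lambda$ bound. When no empty wells
  are observed the point estimate is unbounded ($-\log 0$) and reports
  render the conventional `">10"` sentinel instead of a number — the
  estimate is encoded as `Inf`, never as a fabricated value.
* **Censored maximum likelihood** — `lambda_mle(obs)` uses both the
  empty-well count and the per-well copy estimates of amplifying wells
  (interpolated from a standard curve and rounded to integers). Each
  empty well contributes the zero-class probability $e^{-\lambda}$; each
  occupied well contributes its occupancy probability
  $1 - e^{-\lambda}$ times the zero-truncated mass at its count. The
  occupancy factor matters: dropping it (i.e., using the truncated mass
  alone next to the zero class) double-counts the truncation and biases
  $\hat\lambda$ low by a factor $1/(1+e^{-\lambda})$ — about 35% at
  $\lambda = 1$ — which is why the likelihood is written with both
  factors even though they partially cancel algebraically. The estimate
  is maximized numerically on $[0, 50]$ to a tolerance of $10^{-8}$; a
  simpler `rounded_poisson` mode (the sample mean of rounded counts) is
  available for comparison. Positive observations that round to zero are
  clamped to one copy, since an amplifying well held at least one
  template molecule.

`zero_truncated_mean(lam)` returns $\lambda/(1-e^{-\lambda})$, the mean
copy content of occupied wells — the quantity a per-well quantitation
"sees", which exceeds $\lambda$ and tends to 1 as $\lambda \to 0$. It
explains, qualitatively, why MLE-style copy columns in limiting-dilution
panels run higher than dropout columns at sub-copy inputs.

`proficiency_check(n_positive, n_wells, lam)` is an exact two-sided
binomial test of the observed positives against the detection probability
$1-e^{-\lambda}$. The source material states a consistency criterion but
no test; the exact binomial was chosen because the cell sizes (18–60
wells) are too small for normal approximations at detection probabilities
near 1. One consequence is worth knowing: a run can be Poisson-consistent
with its *own estimated* content while failing against its *nominal*
input, because serial dilutions undershoot or overshoot. The check is
therefore most informative when `lam` is the dropout or MLE estimate of
what the wells actually contained.

## Quantitation

Standard curves are ordinary least squares of Ct on $\log_{10}$(copies):
`fit_standard_curve()` reports slope (Ct per decade), intercept (Ct at a
single copy), $r^2$ (squared Pearson correlation of fitted vs observed
Ct), and the amplification efficiency $10^{-1/\text{slope}} - 1$, which
is exactly 1 at the perfect-doubling slope of $-3.3219$.

The **master curve** (`build_master_curve()`) pools all QC-passing points
from many plates into a single OLS fit rather than averaging per-plate
coefficients. Pooling weights each plate by its number of passing points,
which is the behaviour wanted when plates lose points to QC; since the
aggregation convention was genuinely open, the per-plate member fits are
returned alongside the pooled fit so either convention is auditable.
`interpolate_copies(ct, fit)` applies the algebraic inverse
$10^{(ct - \text{intercept})/\text{slope}}$.

`reportable_range()` applies the detection rule for range determination:
a standard level is in range when at least one replicate produced a
QC-passing signal, and the endpoints are the extreme nominal copy inputs
among in-range levels.

## QC and calling

`apply_qc()` applies, in fixed precedence, a minimum-Ct rule (default
flag at Ct ≤ 10, guarding against threshold artifacts), a maximum-Ct rule
(default 45, the configured run length), and a per-target melt-window
rule. The precedence ordering exists only to make the flag reason
deterministic; the partition (passing + flagged = input) does not depend
on it. Two conventions are load-bearing:

* An **absent Ct means an empty well**, which is *information*, not a QC
  failure — empty wells pass QC and feed the occupancy statistics. A
  literal Ct of 0 in an input file is rejected as a parse error, because
  a silent zero would corrupt the dropout fraction.
* A **positive call** (`call_well()`) requires all three orthogonal
  gates: QC-passing Ct, melt temperature inside the target's specific
  window, and sequencing that did not read the product as wild type. A
  late non-specific product or a WT sequence read is a negative call,
  which is how raw spurious qPCR signals at the percent level become a
  final specificity above 99%.

Melt windows are per-assay configuration (default 78–82 °C for every
target). They are example values: amplicon melt behaviour depends on
sequence composition and no measured window is published for these
assays, so real deployments must supply their own.

## Interference analysis

`pair_deltas()` and `delta_summary()` implement the paired
$\Delta\mathrm{Ct}$ analysis of the WT background: for each (target,
standard) cell measured with and without ~14,000 WT copies,
$\Delta = \overline{Ct}_{\text{without}} - \overline{Ct}_{\text{with}}$,
so a positive delta means *earlier* (stronger) amplification with WT
present. Two summaries are reported, labelled, because both are
legitimate "average delta" conventions answering different questions:
the signed mean and sample SD (n−1; the direction and spread of the
effect — on the bundled panel, +0.32 ± 0.52 Ct) and the mean absolute
delta (the typical magnitude, 0.43 Ct). Deltas are recomputed from the
mean-Ct columns rather than taken from any pre-computed difference
column, avoiding double rounding.

## Performance metrics

`confusion_metrics()` computes sensitivity $tp/(tp+fn)$ and specificity
$tn/(tn+fp)$, with display strings following the clinical-validation
convention that any metric at or above 0.99 renders `">99%"` — a perfect
0/120 and a near-perfect 1/135 print identically. `detection_rate()`
pairs a rate with an exact Clopper–Pearson interval (chosen because the
clinical tables cite 95% CIs without naming a method, and the exact
interval is the conservative default at extreme rates such as 0/20).

The limit of detection (`determine_lod()`) is detection-based, not
probit-based: the LoD is the lowest copy level whose positive-well count
is consistent with the Poisson expectation at that level, expressed as a
MAF $m/(m + \text{WT})$. The percent display floors at 0.01%: a single
copy in 14,000 WT copies is a MAF of 0.0071%, which would vanish under
two-decimal rounding, and the floor preserves the conventional "0.01%"
report for sub-floor fractions.

`reproducibility_summary()` applies the 1-Ct rule: a cell passes when the
sample SD of its Cts is at most 1 cycle. Intra-assay mode summarizes raw
replicate Cts per (target, unit, standard) cell; inter-assay mode first
averages per unit (plate, instrument, or operator) and then summarizes
the spread of unit means. Singleton cells are flagged rather than
silently passed.

## What the simulator emulates — and what it does not

`simulation_config()` encodes the study conditions:

| parameter | default | meaning |
|---|---|---|
| standards | A–G: 5120, 640, 80, 10, 5, 2.5, 1.25 copies | 8-fold steps A–D (triplicate), halving E–G (20 replicates), all in 14,000 WT copies |
| `slope`, `intercept` | −3.45, 38.6 | log-linear Ct response; places single-copy wells at Ct ≈ 38–39, consistent with the observed low-standard means |
| `sigma_ct` | 0.3 | replicate Ct noise (cycles) |
| `wt_shift` | mean −0.32, SD 0.52 | WT-background Ct effect (see below) |
| `fp_rate` | 0.04 | spurious-signal probability per WT-only well, before gating |
| `tm_specific`, `tm_nonspecific` | N(80, 0.4), N(73, 1.5) °C | melt peaks of specific vs non-specific products |

Per-well copy counts are Poisson draws, and the Ct response is evaluated
at the **realized** integer copy number, not the nominal mean — so
sampling noise propagates into Ct and the low-copy standards show the
widening spread real plates show. This single choice produces, with no
extra tuning, the observed behaviour that essentially all 1-Ct
reproducibility failures occur at the ~10-copy standard.

The WT-background shift is modelled as a **systematic (target, standard)
effect**: one draw per assay/concentration combination, held fixed across
plates and replicates. The interference panel's ±0.52 spread describes
how the shift varies across such combinations — each combination has one
characteristic delta — not well-to-well noise; drawing it per well would
inflate replicate scatter and corrupt the reproducibility statistics.
Calibration (standard-curve) runs have only the with-WT condition, so
only the mean shift is applied there, as an intercept offset: the
level-specific component of the effect is identified only by the
with/without contrast, and injecting it into a single-condition
calibration would present level-systematic offsets as if they were
curve nonlinearity. No mechanistic model of *why* WT background advances
Ct is attempted; the effect is reproduced descriptively.

Known non-features: the simulator does not model raw fluorescence
curves, pipetting-volume variation, over-dispersion
(Poisson–lognormal), droplet partitioning, or sequencing traces.
Passing tests on simulated plates therefore demonstrate that the
*estimators recover the generating process*, not that real plates follow
that process; the bundled summary tables provide the fixed empirical
anchors.

Simulated tm values for specific products (N(80, 0.4)) sit inside the
default QC window (78–82 °C) and non-specific products (N(73, 1.5))
outside it; these are configuration defaults with no measured
counterpart, chosen to keep the gates exercisable.

## Numerical choices and degenerate inputs

* The censored likelihood is maximized with Brent's method
  (`stats::optimize`) on $[10^{-10}, 50]$, tolerance $10^{-8}$; an
  all-empty observation vector short-circuits to $\hat\lambda = 0$.
* $r^2$ of a two-point or zero-residual curve is defined as exactly 1.
* Dropout CIs at the boundaries: 0 empty wells gives a finite lower
  $\lambda$ bound and an unbounded upper side; all-empty gives
  $\hat\lambda = 0$.
* `proficiency_check` at a degenerate detection probability (0 or 1)
  returns p = 1 when the observation equals the certain outcome and 0
  otherwise, rather than calling the binomial test with an impossible
  null.
* Report writers sort rows by target then standard and render at fixed
  precision, so identical inputs yield byte-identical files.
* Seeds: each simulation operation draws from a stream derived from the
  configuration seed, the target, and the operation, so multi-target
  studies are independent but fully reproducible; the RNG state of the
  calling session is left untouched.

## Problem sizes

The test-suite and analysis scripts run at the study's own scale:
10-plate curve studies (120 wells per target), 72-well dilution series,
112-well specificity panels, 200-replicate recovery loops at 60 wells,
and one 5,000-well draw for the estimator-agreement check. The full
suite completes in well under a minute on a single CPU; distributional
fidelity checks use 2,000–10,000-well batches, the smallest sizes at
which binomial error is comfortably below the tolerances being asserted.

## Limitations

The package validates the statistics of single-copy detection, not the
chemistry: blocker design, amplification mechanism, and sequencing are
outside its scope, entering only as the melt-window and
sequencing-confirmation gates. The LoD rule is detection-based;
laboratories requiring a probit-style LoD95 need a different procedure.
Clinical detection summaries are pure tabulation with exact intervals —
no patient-level modelling, and no concordance analysis against tissue.
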