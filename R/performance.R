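# Analytical performance metrics: confusion counts with the ">99%" display
# convention, limit of detection expressed as mutant allele fraction (MAF),
# exact binomial detection-rate intervals, and the 1-Ct reproducibility rule.

percent_display <- function(x) {
  ifelse(x >= 0.99, ">99%", paste0(round(100 * x), "%"))
}

#' Confusion-matrix metrics for assay calls
#'
#' Tallies predicted vs true positives and computes analytical sensitivity
#' `tp / (tp + fn)` and specificity `tn / (tn + fp)`. Display strings
#' follow the clinical-validation convention of reporting any metric at or
#' above 0.99 as `">99%"` (a perfect 0/120 and a near-perfect 1/135 both
#' render `">99%"`).
#'
#' @param calls Data frame with logical columns `predicted_positive` and
#'   `truth_positive`, one row per test.
#' @return Object of class `confusion_counts`: `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity` (NA when undefined), and the two display
#'   strings.
#' @export
confusion_metrics <- function(calls) {
  calls <- tibble::as_tibble(calls)
  stopifnot(all(c("predicted_positive", "truth_positive") %in% names(calls)))
  if (nrow(calls) < 1) {
    abort("need at least one call", class = "poisqpcr_domain_error")
  }
  p <- calls$predicted_positive
  t <- calls$truth_positive
  tp <- sum(p & t); fn <- sum(!p & t); fp <- sum(p & !t); tn <- sum(!p & !t)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = sens, specificity = spec,
    sensitivity_display = if (is.na(sens)) NA_character_ else percent_display(sens),
    specificity_display = if (is.na(spec)) NA_character_ else percent_display(spec)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d FN %d FP %d TN %d; sens %s spec %s\n",
              x$tp, x$fn, x$fp, x$tn,
              x$sensitivity_display, x$specificity_display))
  invisible(x)
}

#' Call a well positive or negative
#'
#' A well is called positive when all three orthogonal gates pass: a
#' QC-passing Ct is present (within the min/max Ct window), the melt
#' temperature falls in the target's specific-product window, and
#' sequencing did not read the product as wild type (`seq_confirmed` is
#' `NA` — not sequenced — or `TRUE`). A late or non-specific signal, or a
#' product that sequences as WT, is a negative call.
#'
#' @param wells Canonical well tibble.
#' @param qc A [qc_config()].
#' @return Logical vector, one call per well.
#' @export
call_well <- function(wells, qc = qc_config()) {
  stopifnot(inherits(qc, "qc_config"))
  wells <- tibble::as_tibble(wells)
  reason <- rep(NA_character_, nrow(wells))
  has_ct <- !is.na(wells$ct)
  reason[has_ct & wells$ct <= qc$min_ct] <- "min_ct"
  reason[has_ct & wells$ct >= qc$max_ct & is.na(reason)] <- "max_ct"
  lo <- vapply(wells$target, function(t) qc$tm_window[[t]][1], numeric(1))
  hi <- vapply(wells$target, function(t) qc$tm_window[[t]][2], numeric(1))
  tm_ok <- has_ct & !is.na(wells$tm) & wells$tm >= lo & wells$tm <= hi
  seq_ok <- is.na(wells$seq_confirmed) | wells$seq_confirmed
  unname(has_ct & is.na(reason) & tm_ok & seq_ok)
}

#' Mutant allele fraction
#'
#' @param mutant_copies Mutant copies in the reaction.
#' @param wt_copies Wild-type background copies.
#' @return `mutant_copies / (mutant_copies + wt_copies)`.
#' @export
maf <- function(mutant_copies, wt_copies) {
  mutant_copies / (mutant_copies + wt_copies)
}

#' Render a MAF as a percent string with a 0.01% floor
#'
#' Sub-0.01% fractions (a single copy in 14,000 WT copies is 0.0071%)
#' report the conventional floor "0.01%" rather than vanishing to "0.00%"
#' under two-decimal rounding.
#'
#' @param maf_value Fraction in (0, 1).
#' @return Character, e.g. `"0.01%"`.
#' @export
maf_display <- function(maf_value) {
  pct <- pmax(round(100 * maf_value, 2), 0.01)
  sprintf("%.2f%%", pct)
}

#' Determine the limit of detection over a dilution panel
#'
#' Walks the mutant copy levels and selects the lowest level whose
#' detection satisfies the detection rule; by default a level is
#' detectable when its positive-well count is consistent with the Poisson
#' expectation at that copy input ([proficiency_check()]). The LoD is then
#' expressed as a mutant allele fraction against the wild-type background.
#'
#' @param levels Data frame with columns `mutant_copies`, `wt_copies`,
#'   `n_detected`, `n_wells`, sorted by `mutant_copies` descending.
#' @param rule Function `(mutant_copies, wt_copies, n_detected, n_wells)
#'   -> logical`; default Poisson-consistency via [proficiency_check()].
#' @return Object of class `lod_result`: `lod_copies`, `wt_copies`,
#'   `lod_maf`, `lod_maf_display`, and the per-level tibble with a
#'   `detected` flag. All-`NA` fields when no level satisfies the rule.
#' @export
determine_lod <- function(levels, rule = NULL) {
  levels <- tibble::as_tibble(levels)
  stopifnot(all(c("mutant_copies", "wt_copies", "n_detected", "n_wells")
                %in% names(levels)))
  if (nrow(levels) < 1) {
    abort("need at least one level", class = "poisqpcr_domain_error")
  }
  if (is.unsorted(rev(levels$mutant_copies))) {
    abort("levels must be sorted by mutant_copies descending",
          class = "poisqpcr_domain_error")
  }
  if (is.null(rule)) {
    rule <- function(mutant_copies, wt_copies, n_detected, n_wells) {
      proficiency_check(n_detected, n_wells, lam = mutant_copies)$pass
    }
  }
  levels$detected <- mapply(rule, levels$mutant_copies, levels$wt_copies,
                            levels$n_detected, levels$n_wells)
  det <- which(levels$detected)
  if (length(det) == 0) {
    return(structure(list(lod_copies = NA_real_, wt_copies = NA_real_,
                          lod_maf = NA_real_, lod_maf_display = NA_character_,
                          levels = levels), class = "lod_result"))
  }
  i <- det[which.min(levels$mutant_copies[det])]
  m <- levels$mutant_copies[i]; w <- levels$wt_copies[i]
  structure(list(
    lod_copies = m, wt_copies = w,
    lod_maf = maf(m, w), lod_maf_display = maf_display(maf(m, w)),
    levels = levels
  ), class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  if (is.na(x$lod_copies)) {
    cat("<lod_result> undefined (no level met the detection rule)\n")
  } else {
    cat(sprintf("<lod_result> %.3g copies in %g WT copies = %s MAF\n",
                x$lod_copies, x$wt_copies, x$lod_maf_display))
  }
  invisible(x)
}

#' Detection rate with an exact binomial confidence interval
#'
#' @param n_detected Positive tests.
#' @param n_tested Total tests (>= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `n_tested`, `n_detected`, `rate`, `percent`
#'   (rounded to 2 decimals), and `ci95` (Clopper–Pearson bounds on the
#'   rate).
#' @export
detection_rate <- function(n_detected, n_tested, conf_level = 0.95) {
  if (n_tested < 1 || n_detected < 0 || n_detected > n_tested) {
    abort("need 0 <= n_detected <= n_tested with n_tested >= 1",
          class = "poisqpcr_domain_error")
  }
  ci <- binom.test(n_detected, n_tested, conf.level = conf_level)$conf.int
  rate <- n_detected / n_tested
  list(n_tested = n_tested, n_detected = n_detected, rate = rate,
       percent = round(100 * rate, 2), ci95 = as.numeric(ci))
}

#' Inter/intra-assay reproducibility summary under the 1-Ct rule
#'
#' Intra-assay mode summarizes the spread of raw replicate Cts within each
#' (unit, standard) cell; inter-assay mode first averages Cts within each
#' unit (plate, instrument, or operator) and then summarizes the spread of
#' those unit means per standard. A cell passes when its sample SD is at
#' most 1 Ct. Cells with fewer than two values are flagged
#' `insufficient_replicates` (pass = NA) and excluded from pass counts.
#'
#' @param wells Canonical well tibble (amplifying wells only are used;
#'   empty wells carry no Ct).
#' @param mode `"intra"` or `"inter"`.
#' @param unit Grouping unit column: `"plate"` (default), `"instrument"`,
#'   or `"operator"`.
#' @param sd_limit Pass threshold on the Ct SD (default 1.0).
#' @return Tibble with columns `target`, `unit`, `standard`, `n`,
#'   `mean_ct`, `sd_ct`, `cv_percent`, `pass`.
#' @export
reproducibility_summary <- function(wells, mode = c("intra", "inter"),
                                    unit = c("plate", "instrument", "operator"),
                                    sd_limit = 1.0) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  wells <- tibble::as_tibble(wells)
  amp <- wells[!is.na(wells$ct), , drop = FALSE]
  if (mode == "intra") {
    cells <- amp |>
      dplyr::group_by(.data$target, unit = .data[[unit]], .data$standard) |>
      dplyr::summarise(n = dplyr::n(), mean_ct = mean(.data$ct),
                       sd_ct = sd(.data$ct), .groups = "drop")
  } else {
    cells <- amp |>
      dplyr::group_by(.data$target, unit = .data[[unit]], .data$standard) |>
      dplyr::summarise(unit_mean = mean(.data$ct), .groups = "drop") |>
      dplyr::group_by(.data$target, .data$standard) |>
      dplyr::summarise(n = dplyr::n(), mean_ct = mean(.data$unit_mean),
                       sd_ct = sd(.data$unit_mean), .groups = "drop") |>
      dplyr::mutate(unit = "all") |>
      dplyr::relocate("unit", .after = "target")
  }
  cells |>
    dplyr::mutate(
      cv_percent = 100 * .data$sd_ct / .data$mean_ct,
      pass = dplyr::if_else(.data$n < 2, NA, .data$sd_ct <= sd_limit)
    )
}
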