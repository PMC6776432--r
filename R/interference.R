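# Paired delta-Ct analysis: does a large wild-type DNA background degrade
# mutant amplification? Each (target, standard) pair is measured with and
# without ~14,000 background WT copies; delta = mean Ct without WT minus
# mean Ct with WT, so a positive delta means the reaction amplified
# *earlier* (stronger) in the presence of WT DNA.

#' Pair per-condition mean Cts into delta-Ct rows
#'
#' @param mean_table Data frame with columns `target`, `standard`,
#'   `condition` (`"no_wt"` or `"with_wt"`), `mean_ct`. Every
#'   (target, standard) must appear under both conditions exactly once.
#' @return Tibble with columns `target`, `standard`, `mean_ct_no_wt`,
#'   `mean_ct_with_wt`, `delta_ct` (= no_wt - with_wt), in the input's
#'   first-appearance order of pairs.
#' @export
pair_deltas <- function(mean_table) {
  mean_table <- tibble::as_tibble(mean_table)
  stopifnot(all(c("target", "standard", "condition", "mean_ct")
                %in% names(mean_table)))
  bad_cond <- setdiff(unique(mean_table$condition), c("no_wt", "with_wt"))
  if (length(bad_cond) > 0) {
    abort(paste0("unknown condition label(s): ", paste(bad_cond, collapse = ", ")),
          class = "poisqpcr_domain_error")
  }
  wide <- tidyr::pivot_wider(mean_table,
                             id_cols = c("target", "standard"),
                             names_from = "condition",
                             values_from = "mean_ct")
  for (cond in c("no_wt", "with_wt")) {
    if (!cond %in% names(wide) || any(is.na(wide[[cond]]))) {
      missing <- if (!cond %in% names(wide)) wide else wide[is.na(wide[[cond]]), ]
      lab <- paste(missing$target, missing$standard, sep = "/", collapse = ", ")
      abort(paste0("unmatched condition '", cond, "' for: ", lab),
            class = "poisqpcr_pairing_error")
    }
  }
  tibble::tibble(
    target = wide$target,
    standard = wide$standard,
    mean_ct_no_wt = wide$no_wt,
    mean_ct_with_wt = wide$with_wt,
    delta_ct = wide$no_wt - wide$with_wt
  )
}

#' Summarize a set of delta-Ct pairs
#'
#' Reports both the signed summary (mean and sample SD of the deltas, the
#' interference effect and its spread) and the mean absolute delta (the
#' typical magnitude of the shift irrespective of direction). Both are
#' legitimate "average delta Ct" conventions; they answer different
#' questions, so both are returned, labelled.
#'
#' @param pairs Tibble from [pair_deltas()] (>= 2 pairs for an SD).
#' @return Object of class `delta_ct_summary`: list with `pairs`,
#'   `n_pairs`, `mean_signed`, `sd_signed` (n-1 denominator), `mean_abs`.
#' @export
delta_summary <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot("delta_ct" %in% names(pairs))
  if (nrow(pairs) < 2) {
    abort("need >= 2 pairs to estimate a standard deviation",
          class = "poisqpcr_insufficient_data_error")
  }
  d <- pairs$delta_ct
  structure(list(
    pairs = pairs,
    n_pairs = length(d),
    mean_signed = mean(d),
    sd_signed = sd(d),
    mean_abs = mean(abs(d))
  ), class = "delta_ct_summary")
}

#' @export
print.delta_ct_summary <- function(x, ...) {
  cat(sprintf(
    "<delta_ct_summary> %d pairs: mean delta Ct %+.2f (SD %.2f), mean |delta| %.2f\n",
    x$n_pairs, x$mean_signed, x$sd_signed, x$mean_abs))
  invisible(x)
}

#' Delta-Ct report table (pairs plus a summary block)
#'
#' @param summary A `delta_ct_summary`.
#' @return Tibble of the pairs with three appended summary rows labelled
#'   `mean_signed`, `sd_signed`, `mean_abs` in the `standard` column.
#' @export
delta_ct_table <- function(summary) {
  stopifnot(inherits(summary, "delta_ct_summary"))
  dplyr::bind_rows(
    summary$pairs,
    tibble::tibble(
      target = "ALL",
      standard = c("mean_signed", "sd_signed", "mean_abs"),
      mean_ct_no_wt = NA_real_, mean_ct_with_wt = NA_real_,
      delta_ct = c(summary$mean_signed, summary$sd_signed, summary$mean_abs)
    )
  )
}
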