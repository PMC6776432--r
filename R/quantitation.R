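# Log-linear standard curves: ct = intercept + slope * log10(copies).
# Amplification efficiency follows from the slope as 10^(-1/slope) - 1,
# so a perfect doubling per cycle gives slope -3.3219 and efficiency 1.

#' Fit a log-linear qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(copies). The intercept is the
#' expected Ct at a single copy; the slope (Ct per decade of input) maps to
#' amplification efficiency as `10^(-1/slope) - 1`.
#'
#' @param points Data frame with numeric columns `copies` (> 0) and `ct`.
#' @param group_id Label for the fit (plate, instrument, or `"master"`).
#'
#' @return An object of class `standard_curve_fit`: a list with `slope`,
#'   `intercept`, `r_squared` (squared Pearson correlation of fitted vs
#'   observed Ct), `efficiency`, `n_points`, `group_id`.
#' @export
fit_standard_curve <- function(points, group_id = "curve") {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("copies", "ct") %in% names(points)))
  if (any(!is.finite(points$copies) | points$copies <= 0)) {
    abort("all copies must be positive and finite",
          class = "poisqpcr_domain_error")
  }
  if (any(!is.finite(points$ct))) {
    abort("all ct values must be finite", class = "poisqpcr_domain_error")
  }
  x <- log10(points$copies)
  if (length(unique(x)) < 2) {
    abort("standard curve needs >= 2 distinct copy levels",
          class = "poisqpcr_degenerate_fit_error")
  }
  fit <- lm(ct ~ x, data = tibble::tibble(ct = points$ct, x = x))
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  fitted_ct <- unname(fit$fitted.values)
  r2 <- if (sd(points$ct) == 0 || sd(fitted_ct) == 0) {
    1.0  # all residual variation is zero on a flat or exact line
  } else {
    cor(fitted_ct, points$ct)^2
  }
  structure(list(
    slope = slope,
    intercept = intercept,
    r_squared = r2,
    efficiency = 10^(-1 / slope) - 1,
    n_points = nrow(points),
    group_id = group_id
  ), class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<standard_curve_fit '%s'> Ct = %.3f %+.3f * log10(copies)  (n = %d)\n",
    x$group_id, x$intercept, x$slope, x$n_points))
  cat(sprintf("  r^2 = %.4f, efficiency = %.1f%%\n",
              x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Predict the expected Ct for a copy-number input
#'
#' @param copies Positive copy numbers.
#' @param fit A `standard_curve_fit`.
#' @return Numeric Ct values.
#' @export
predict_ct <- function(copies, fit) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (any(copies <= 0)) {
    abort("copies must be positive", class = "poisqpcr_domain_error")
  }
  fit$intercept + fit$slope * log10(copies)
}

#' Interpolate copy number from an observed Ct
#'
#' Algebraic inverse of the standard curve: `copies = 10^((ct - intercept)
#' / slope)`. Strictly decreasing in Ct for the usual negative slope.
#'
#' @param ct Observed Ct values (numeric).
#' @param fit A `standard_curve_fit` with non-zero slope.
#' @return Positive copy estimates.
#' @export
interpolate_copies <- function(ct, fit) {
  stopifnot(inherits(fit, "standard_curve_fit"))
  if (fit$slope == 0) {
    abort("cannot interpolate from a zero-slope curve",
          class = "poisqpcr_degenerate_fit_error")
  }
  10^((ct - fit$intercept) / fit$slope)
}

#' Build a master curve by pooling QC-passing points across plates
#'
#' Aggregates standard-curve points from several plates/instruments of one
#' assay target into a single OLS fit. Pooling (rather than averaging
#' per-plate coefficients) weights each plate by its number of passing
#' points; the per-plate member fits are returned alongside so either
#' convention can be audited.
#'
#' @param points Data frame with columns `copies`, `ct`, and a grouping
#'   column (default `plate`) identifying the member curves; an optional
#'   `target` column must be single-valued.
#' @param group_id Label for the pooled fit (default `"master"`).
#' @param member_col Name of the member grouping column.
#'
#' @return A list of class `master_curve`: `master` (the pooled
#'   `standard_curve_fit`) and `members` (tibble of per-member slope,
#'   intercept, efficiency, r_squared, n_points).
#' @export
build_master_curve <- function(points, group_id = "master",
                               member_col = "plate") {
  points <- tibble::as_tibble(points)
  if ("target" %in% names(points) && length(unique(points$target)) > 1) {
    abort("master curve points must come from a single assay target",
          class = "poisqpcr_domain_error")
  }
  if (!member_col %in% names(points)) {
    points[[member_col]] <- "pooled"
  }
  master <- fit_standard_curve(points, group_id = group_id)
  members <- points |>
    dplyr::group_by(.data[[member_col]]) |>
    dplyr::group_map(function(grp, key) {
      f <- fit_standard_curve(grp, group_id = as.character(key[[1]]))
      tibble::tibble(group_id = f$group_id, y_intercept = f$intercept,
                     slope = f$slope, efficiency = f$efficiency,
                     r_squared = f$r_squared, n_points = f$n_points)
    }) |>
    dplyr::bind_rows()
  structure(list(master = master, members = members), class = "master_curve")
}

#' Tabulate a master curve and its member fits
#'
#' One row per member fit plus a final row for the pooled master curve,
#' with the columns conventionally reported for qPCR regression summaries.
#'
#' @param mc A `master_curve` from [build_master_curve()].
#' @return Tibble with columns `group_id`, `y_intercept`, `slope`,
#'   `efficiency`, `r_squared`, `n_points`.
#' @export
master_curve_table <- function(mc) {
  stopifnot(inherits(mc, "master_curve"))
  m <- mc$master
  dplyr::bind_rows(
    mc$members,
    tibble::tibble(group_id = m$group_id, y_intercept = m$intercept,
                   slope = m$slope, efficiency = m$efficiency,
                   r_squared = m$r_squared, n_points = m$n_points)
  )
}

#' Determine the reportable range from per-standard detection results
#'
#' A standard level is within the reportable range when at least one of
#' its replicate wells produced a QC-passing amplification signal. The
#' range endpoints are the smallest and largest nominal copy inputs among
#' in-range levels.
#'
#' @param levels Data frame with columns `standard`, `nominal_copies`,
#'   `n_detected` (QC-passing positive wells), `n_wells`.
#' @return List with `min_copies`, `max_copies` (both `NA` when nothing was
#'   detected) and `levels`, the input tibble with an added logical
#'   `in_range` column.
#' @export
reportable_range <- function(levels) {
  levels <- tibble::as_tibble(levels)
  stopifnot(all(c("standard", "nominal_copies", "n_detected", "n_wells")
                %in% names(levels)))
  if (nrow(levels) < 1) {
    abort("need at least one standard level", class = "poisqpcr_domain_error")
  }
  levels$in_range <- levels$n_detected >= 1
  inr <- levels$nominal_copies[levels$in_range]
  list(
    min_copies = if (length(inr)) min(inr) else NA_real_,
    max_copies = if (length(inr)) max(inr) else NA_real_,
    levels = levels
  )
}
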