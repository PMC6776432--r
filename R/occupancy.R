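# Poisson occupancy model for limiting-dilution wells.
# With a mean of lambda copies per well, the chance a well receives zero
# copies is exp(-lambda); observed empty-well fractions therefore estimate
# lambda as -log(empty fraction) ("dropout" estimate), and the full
# censored likelihood uses both the empty count and the per-well copy
# estimates of occupied wells.

#' Theoretical fraction of empty wells under Poisson occupancy
#'
#' @param lam Non-negative mean copies per well.
#' @return `exp(-lam)`, the Poisson zero-class probability.
#' @export
expected_empty_fraction <- function(lam) {
  if (any(lam < 0)) {
    abort("mean copies per well must be non-negative",
          class = "poisqpcr_domain_error")
  }
  exp(-lam)
}

#' Theoretical empty-well percentage table
#'
#' Tabulates `100 * exp(-lambda)` (rounded to 2 decimals) over a set of
#' mean copy inputs — the expected percentage of replicates with zero
#' copies at each input level.
#'
#' @param lams Numeric vector of non-negative mean copies per well.
#' @return Tibble with columns `lam` and `percent_empty`.
#' @export
theoretical_empty_table <- function(lams) {
  tibble::tibble(
    lam = as.numeric(lams),
    percent_empty = round(100 * expected_empty_fraction(as.numeric(lams)), 2)
  )
}

#' Estimate mean copies per well from the empty-well (dropout) fraction
#'
#' Inverts the Poisson zero-class probability: with `n_empty` of `n_wells`
#' empty, `lambda = -log(n_empty / n_wells)`. When no empty wells are
#' observed the point estimate is unbounded and the conventional `">10"`
#' sentinel is reported (encoded as `Inf`). The 95% CI inverts exact
#' Clopper–Pearson bounds on the empty fraction through `-log`.
#'
#' @param n_empty Number of wells with no amplification signal.
#' @param n_wells Total replicate wells (>= 1).
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return An object of class `occupancy_estimate`: list with `n_wells`,
#'   `n_empty`, `empty_fraction`, `lambda_dropout` (`Inf` when
#'   `n_empty = 0`), and `ci95 = c(low, high)` for lambda.
#' @export
lambda_from_dropout <- function(n_empty, n_wells, conf_level = 0.95) {
  if (n_wells < 1 || n_empty < 0 || n_empty > n_wells) {
    abort("need 0 <= n_empty <= n_wells with n_wells >= 1",
          class = "poisqpcr_domain_error")
  }
  frac <- n_empty / n_wells
  lambda <- if (n_empty == 0) Inf else -log(frac)
  alpha <- 1 - conf_level
  # Clopper-Pearson bounds on the empty fraction p; lambda = -log(p) is
  # decreasing in p, so the p upper bound gives the lambda lower bound.
  p_low <- if (n_empty == 0) 0 else qbeta(alpha / 2, n_empty, n_wells - n_empty + 1)
  p_high <- if (n_empty == n_wells) 1 else
    qbeta(1 - alpha / 2, n_empty + 1, n_wells - n_empty)
  ci <- c(-log(p_high), if (p_low == 0) Inf else -log(p_low))
  structure(list(
    n_wells = as.integer(n_wells),
    n_empty = as.integer(n_empty),
    empty_fraction = frac,
    lambda_dropout = lambda,
    ci95 = ci
  ), class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("<occupancy_estimate> %d/%d empty (%.1f%%), lambda = %s [%s, %s]\n",
              x$n_empty, x$n_wells, 100 * x$empty_fraction,
              format_lambda(x$lambda_dropout),
              format_lambda(x$ci95[1]), format_lambda(x$ci95[2])))
  invisible(x)
}

# Censored Poisson log-likelihood. Each empty well contributes the zero
# class exp(-lambda); each occupied well contributes the probability of
# being occupied, 1 - exp(-lambda), times the zero-truncated mass at its
# rounded copy count. Dropping the occupancy factor would double-count the
# truncation and bias lambda low by a factor 1/(1 + exp(-lambda)).
censored_loglik <- function(lambda, n_empty, pos_counts) {
  if (lambda <= 0) {
    return(if (n_empty > 0 && length(pos_counts) == 0) 0 else -Inf)
  }
  ll <- -n_empty * lambda
  if (length(pos_counts) > 0) {
    # occupancy factor log(1 - exp(-lambda)) and the truncated-mass
    # denominator cancel, leaving the untruncated Poisson mass
    ll <- ll + sum(dpois(pos_counts, lambda, log = TRUE))
  }
  ll
}

#' Maximum-likelihood estimate of mean copies per well
#'
#' Two likelihood conventions for well-level copy observations (0 for
#' empty wells, interpolated copy estimates for amplifying wells):
#'
#' * `"censored_positive"` (default): empty wells contribute the Poisson
#'   zero-class probability; occupied wells contribute their occupancy
#'   probability times the zero-truncated Poisson mass at their rounded
#'   count — the full censored-data likelihood, combining the dropout
#'   information with the per-well quantitation. Maximized numerically on
#'   `[0, 50]`.
#' * `"rounded_poisson"`: every observation is rounded to the nearest
#'   non-negative integer and the plain Poisson MLE (the sample mean of
#'   the rounded counts) is returned.
#'
#' Positive observations that round to zero are clamped to one copy: an
#' amplifying well contained at least one template molecule.
#'
#' @param obs Numeric vector of non-negative per-well copy observations.
#' @param mode `"censored_positive"` or `"rounded_poisson"`.
#' @param tol Convergence tolerance for the numerical maximization.
#' @return The estimate `lambda_hat` (non-negative scalar).
#' @export
lambda_mle <- function(obs, mode = c("censored_positive", "rounded_poisson"),
                       tol = 1e-8) {
  mode <- match.arg(mode)
  if (length(obs) == 0) {
    abort("need at least one observation", class = "poisqpcr_domain_error")
  }
  if (any(!is.finite(obs) | obs < 0)) {
    abort("observations must be finite and non-negative",
          class = "poisqpcr_domain_error")
  }
  if (mode == "rounded_poisson") {
    return(mean(round(obs)))
  }
  n_empty <- sum(obs == 0)
  pos <- obs[obs > 0]
  pos_counts <- pmax(1, round(pos))
  if (length(pos_counts) == 0) {
    return(0)
  }
  opt <- optimize(censored_loglik, interval = c(1e-10, 50), maximum = TRUE,
                  tol = tol, n_empty = n_empty, pos_counts = pos_counts)
  if (!is.finite(opt$objective)) {
    abort("censored likelihood maximization failed to converge",
          class = "poisqpcr_numeric_error")
  }
  opt$maximum
}

#' Mean copies among occupied wells (zero-truncated Poisson mean)
#'
#' Conditioning a Poisson(`lam`) count on being at least one gives mean
#' `lam / (1 - exp(-lam))` — the average copy content of wells that show a
#' signal, which exceeds `lam` and tends to 1 as `lam` tends to 0 (a
#' barely-occupied plate holds single copies).
#'
#' @param lam Positive mean copies per well.
#' @return The zero-truncated mean.
#' @export
zero_truncated_mean <- function(lam) {
  if (any(lam <= 0)) {
    abort("lam must be positive", class = "poisqpcr_domain_error")
  }
  lam / (1 - exp(-lam))
}

#' Proficiency check of observed positives against Poisson expectation
#'
#' Exact two-sided binomial test of the observed number of amplifying
#' wells against the Poisson detection probability `1 - exp(-lam)`. The
#' run is proficient at level `alpha` when the observed positives are
#' consistent with the expectation (p-value >= alpha).
#'
#' @param n_positive Observed amplifying wells.
#' @param n_wells Total wells.
#' @param lam Non-negative mean copies per well under the hypothesis.
#' @param alpha Significance level (default 0.05).
#' @return List with `pass` (logical), `p_value`, and
#'   `expected_positive` (`n_wells * (1 - exp(-lam))`).
#' @export
proficiency_check <- function(n_positive, n_wells, lam, alpha = 0.05) {
  if (lam < 0) {
    abort("lam must be non-negative", class = "poisqpcr_domain_error")
  }
  if (n_positive < 0 || n_positive > n_wells) {
    abort("need 0 <= n_positive <= n_wells", class = "poisqpcr_domain_error")
  }
  p_detect <- 1 - exp(-lam)
  if (p_detect %in% c(0, 1)) {
    # degenerate hypothesis: only the certain outcome is consistent
    p_value <- if (n_positive == round(n_wells * p_detect)) 1 else 0
  } else {
    p_value <- binom.test(n_positive, n_wells, p = p_detect)$p.value
  }
  list(pass = p_value >= alpha, p_value = p_value,
       expected_positive = n_wells * p_detect)
}

#' Occupancy summary table for a limiting-dilution panel
#'
#' Per (target, standard) cell: counts of empty wells, the observed empty
#' percentage, and the dropout lambda estimate, mirroring the columns of a
#' single-copy sensitivity panel.
#'
#' @param wells Canonical well tibble (QC-passing; empty wells have
#'   `ct = NA`).
#' @return Tibble with columns `target`, `standard`, `n_wells`, `n_empty`,
#'   `percent_empty`, `lambda_dropout`, `lambda_ci_low`, `lambda_ci_high`,
#'   `lambda_mle` (censored MLE from rounded interpolated truth-free
#'   occupancy alone is impossible, so this column is `NA` unless a
#'   `copies` column with per-well estimates is present).
#' @export
occupancy_summary <- function(wells) {
  wells <- tibble::as_tibble(wells)
  stopifnot(all(c("target", "standard", "ct") %in% names(wells)))
  wells |>
    dplyr::group_by(.data$target, .data$standard) |>
    dplyr::group_map(function(grp, key) {
      n <- nrow(grp)
      n_empty <- sum(is.na(grp$ct))
      est <- lambda_from_dropout(n_empty, n)
      mle <- if ("copies" %in% names(grp)) {
        obs <- ifelse(is.na(grp$ct), 0, grp$copies)
        lambda_mle(obs, mode = "censored_positive")
      } else {
        NA_real_
      }
      tibble::tibble(
        target = key$target, standard = key$standard,
        n_wells = n, n_empty = n_empty,
        percent_empty = round(100 * est$empty_fraction, 1),
        lambda_dropout = est$lambda_dropout,
        lambda_ci_low = est$ci95[1], lambda_ci_high = est$ci95[2],
        lambda_mle = mle
      )
    }) |>
    dplyr::bind_rows()
}
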