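# Independent oracles used across tests.

# Brute-force grid maximization of the censored Poisson log-likelihood
# (zero class for empties; occupancy probability times zero-truncated mass
# for occupied wells), independent of the package's optimizer path.
grid_censored_mle <- function(obs, lo = 1e-4, hi = 20, step = 1e-4) {
  n_empty <- sum(obs == 0)
  pos <- pmax(1, round(obs[obs > 0]))
  if (length(pos) == 0) return(0)
  grid <- seq(lo, hi, by = step)
  ll <- -n_empty * grid +
    length(pos) * log(1 - exp(-grid)) +
    vapply(grid, function(l) {
      sum(dpois(pos, l, log = TRUE)) - length(pos) * log(1 - exp(-l))
    }, numeric(1))
  grid[which.max(ll)]
}

# Small deterministic plate table used by the IO/QC tests.
toy_wells <- function() {
  tibble::tibble(
    target = rep("BRAF_V600", 6),
    standard = rep(c("C", "G"), each = 3),
    plate = "P1", instrument = "I1", operator = "O1",
    replicate = rep(1:3, 2),
    ct = c(33.1, 32.8, 33.4, 38.5, NA, 39.1),
    tm = c(80.1, 79.9, 80.4, 80.0, NA, 79.7),
    wt_copies = 14000, truth_copies = rep(c(80, 1.25), each = 3),
    seq_confirmed = c(TRUE, TRUE, TRUE, TRUE, NA, TRUE)
  )
}

fixture_delta_means <- function() {
  d <- validation_fixture("delta_ct_panel")
  dplyr::bind_rows(
    tibble::tibble(target = d$target, standard = d$standard,
                   condition = "no_wt", mean_ct = d$mean_ct),
    tibble::tibble(target = d$target, standard = d$standard,
                   condition = "with_wt", mean_ct = d$mean_ct_wt)
  )
}
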