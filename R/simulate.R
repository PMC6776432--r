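# Seeded generator of plate data with the statistical structure the
# analysis assumes: Poisson-distributed per-well copy counts, a log-linear
# Ct response with Gaussian noise evaluated at the *realized* integer copy
# number (so sampling noise widens the Ct spread at low input, as real
# low-copy wells do), dropout of zero-copy wells, a small additive Ct
# shift when wild-type background DNA is present, melt temperatures for
# specific vs non-specific products, and rare false-positive signals in
# wild-type-only wells.

#' Default limiting-dilution standard definitions
#'
#' Seven standards: A–D span ~5120 down to ~10 copies per reaction in
#' 8-fold steps (run in triplicate); E–G halve standard D down to ~1.25
#' copies and are run with 20 replicates because stochastic sampling
#' dominates at those levels. Every standard carries a ~14,000-copy
#' wild-type background.
#'
#' @param wt_copies Wild-type background copies per well (default 14000).
#' @return Tibble with columns `name`, `nominal_mean_copies`,
#'   `ddpcr_reference_copies`, `wt_copies`, `n_replicates`.
#' @export
default_standards <- function(wt_copies = 14000) {
  tibble::tibble(
    name = LETTERS[1:7],
    nominal_mean_copies = c(5120, 640, 80, 10, 5, 2.5, 1.25),
    ddpcr_reference_copies = NA_real_,
    wt_copies = wt_copies,
    n_replicates = c(3L, 3L, 3L, 3L, 20L, 20L, 20L)
  )
}

#' Simulation configuration for synthetic plate data
#'
#' Defaults encode the study conditions the statistics are validated
#' under: a log-linear Ct response with slope -3.45 and single-copy
#' intercept 38.6 (placing one-copy wells at Ct ~38-39), replicate Ct
#' noise of 0.3 cycles, and an additive Ct shift of mean -0.32 / SD 0.52
#' cycles when wild-type background is present (the with-WT condition
#' amplifies slightly earlier on average). Melt temperatures and the
#' false-positive rate are configuration-only plumbing values with no
#' measured counterpart.
#'
#' @param seed Integer seed; every simulation is reproducible from it.
#' @param slope,intercept,sigma_ct Ct-response parameters (Ct per decade,
#'   Ct at one copy, replicate noise SD in cycles).
#' @param standards Tibble as from [default_standards()].
#' @param wt_shift `c(mean, sd)` of the additive Ct shift seen when
#'   `wt_copies > 0`. One shift is drawn per (target, standard)
#'   combination and held fixed across plates and replicates: the shift is
#'   a systematic property of each assay/concentration cell, and the SD
#'   describes how the shift varies across cells, not well-to-well noise.
#' @param fp_rate Probability a wild-type-only well emits a spurious
#'   signal, before melt/sequencing gating.
#' @param fp_seq_wt_rate Fraction of spurious signals that sequencing
#'   reads as wild type (`seq_confirmed = FALSE`).
#' @param tm_specific,tm_nonspecific `c(mean, sd)` melt-peak temperature
#'   (degrees C) of specific and non-specific products.
#' @param max_cycles Ct values are clipped below this run length.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              slope = -3.45,
                              intercept = 38.6,
                              sigma_ct = 0.3,
                              standards = default_standards(),
                              wt_shift = c(mean = -0.32, sd = 0.52),
                              fp_rate = 0.04,
                              fp_seq_wt_rate = 0.95,
                              tm_specific = c(mean = 80, sd = 0.4),
                              tm_nonspecific = c(mean = 73, sd = 1.5),
                              max_cycles = 45) {
  problems <- character(0)
  if (!is.numeric(seed) || length(seed) != 1) problems <- c(problems, "seed")
  if (!is.numeric(sigma_ct) || sigma_ct <= 0) problems <- c(problems, "sigma_ct")
  if (!is.numeric(fp_rate) || fp_rate < 0 || fp_rate >= 1) {
    problems <- c(problems, "fp_rate")
  }
  if (!is.numeric(fp_seq_wt_rate) || fp_seq_wt_rate < 0 || fp_seq_wt_rate > 1) {
    problems <- c(problems, "fp_seq_wt_rate")
  }
  if (!is.data.frame(standards) ||
      !all(c("name", "nominal_mean_copies", "wt_copies", "n_replicates")
           %in% names(standards)) ||
      any(standards$nominal_mean_copies < 0)) {
    problems <- c(problems, "standards")
  }
  if (length(wt_shift) != 2 || wt_shift[2] < 0) problems <- c(problems, "wt_shift")
  if (length(tm_specific) != 2 || tm_specific[2] <= 0) {
    problems <- c(problems, "tm_specific")
  }
  if (length(tm_nonspecific) != 2 || tm_nonspecific[2] <= 0) {
    problems <- c(problems, "tm_nonspecific")
  }
  if (!is.numeric(max_cycles) || max_cycles <= 0) {
    problems <- c(problems, "max_cycles")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid simulation config field(s): ",
                 paste(problems, collapse = ", ")),
          class = "poisqpcr_config_error")
  }
  structure(list(seed = as.integer(seed), slope = slope, intercept = intercept,
                 sigma_ct = sigma_ct, standards = tibble::as_tibble(standards),
                 wt_shift = unname(wt_shift), fp_rate = fp_rate,
                 fp_seq_wt_rate = fp_seq_wt_rate,
                 tm_specific = unname(tm_specific),
                 tm_nonspecific = unname(tm_nonspecific),
                 max_cycles = max_cycles),
            class = "simulation_config")
}

# Stable per-(purpose, target) stream offset so simulating several targets
# from one seed yields independent draws while staying reproducible.
sim_seed <- function(cfg, target, purpose) {
  idx <- match(target, c(ASSAY_TARGETS, "ANY"))
  if (is.na(idx)) idx <- length(ASSAY_TARGETS) + 2L
  off <- switch(purpose, dilution = 1000L, specificity = 2000L,
                plates = 3000L, shift = 5000L, 4000L)
  (abs(cfg$seed) %% 1000000L) * 100L + off + idx
}

# The wild-type background shift is a systematic (target, standard)-level
# effect: each assay/concentration combination has one characteristic
# delta, reproducible across plates, and the configured mean/SD describe
# the spread of those deltas across combinations — not per-well noise.
# Drawn from a dedicated seeded stream so it is stable for a given config.
wt_shift_for <- function(cfg, target) {
  shifts <- withr::with_seed(sim_seed(cfg, target, "shift"), {
    rnorm(nrow(cfg$standards), cfg$wt_shift[1], cfg$wt_shift[2])
  })
  stats::setNames(shifts, cfg$standards$name)
}

# Ct response at the realized copy numbers; `shift` is the (constant)
# cell-level WT-background effect, applied only when WT DNA is present.
sim_ct <- function(cfg, k, wt_copies, shift = 0) {
  ct <- cfg$intercept + cfg$slope * log10(k) + rnorm(length(k), 0, cfg$sigma_ct)
  ct[wt_copies > 0] <- ct[wt_copies > 0] + shift
  pmin(pmax(ct, 0.01), cfg$max_cycles - 0.01)
}

#' Simulate a limiting-dilution series for one assay target
#'
#' For every standard level and replicate, the realized copy number is
#' drawn as `k ~ Poisson(nominal_mean_copies)`. Zero-copy wells are empty
#' (absent Ct and Tm); occupied wells get
#' `ct = intercept + slope * log10(k) + N(0, sigma_ct)`, plus the WT
#' background shift when `wt_copies > 0`, clipped into `(0, max_cycles)`,
#' and a specific-product melt temperature.
#'
#' @param cfg A [simulation_config()].
#' @param target Assay target label.
#' @param plate,instrument,operator Identifiers stamped on the wells.
#' @return Canonical well tibble (one row per well).
#' @export
simulate_dilution_series <- function(cfg, target = "BRAF_V600",
                                     plate = "P1", instrument = "I1",
                                     operator = "O1") {
  stopifnot(inherits(cfg, "simulation_config"))
  shifts <- wt_shift_for(cfg, target)
  withr::local_seed(sim_seed(cfg, target, "dilution") +
                      1000000L * (match(plate, paste0("P", 1:100), nomatch = 0L)))
  rows <- lapply(seq_len(nrow(cfg$standards)), function(i) {
    std <- cfg$standards[i, ]
    n <- std$n_replicates
    k <- rpois(n, std$nominal_mean_copies)
    ct <- rep(NA_real_, n)
    tm <- rep(NA_real_, n)
    occ <- k >= 1
    if (any(occ)) {
      ct[occ] <- sim_ct(cfg, k[occ], rep(std$wt_copies, sum(occ)),
                        shift = shifts[[std$name]])
      tm[occ] <- rnorm(sum(occ), cfg$tm_specific[1], cfg$tm_specific[2])
    }
    tibble::tibble(
      target = target, standard = std$name, plate = plate,
      instrument = instrument, operator = operator,
      replicate = seq_len(n), ct = ct, tm = tm,
      wt_copies = std$wt_copies,
      truth_copies = std$nominal_mean_copies,
      seq_confirmed = ifelse(occ, TRUE, NA)
    )
  })
  validate_wells(dplyr::bind_rows(rows), max_cycles = cfg$max_cycles)
}

#' Simulate a wild-type-only analytical specificity panel
#'
#' Wells contain only background WT DNA. Each emits a spurious signal
#' with probability `fp_rate`; spurious signals appear in the late Ct
#' range with a non-specific melt temperature, and a fraction
#' `fp_seq_wt_rate` of them sequence as wild type — so the melt-window
#' and sequencing gates of [call_well()] can remove them.
#'
#' @param cfg A [simulation_config()].
#' @param n_wells Number of WT-only wells.
#' @param target Assay target label.
#' @param plate Plate identifier.
#' @return Canonical well tibble.
#' @export
simulate_wt_specificity_panel <- function(cfg, n_wells, target = "BRAF_V600",
                                          plate = "P1") {
  stopifnot(inherits(cfg, "simulation_config"), n_wells >= 1)
  withr::local_seed(sim_seed(cfg, target, "specificity"))
  signal <- runif(n_wells) < cfg$fp_rate
  ct <- rep(NA_real_, n_wells)
  tm <- rep(NA_real_, n_wells)
  seq_conf <- rep(NA, n_wells)
  n_fp <- sum(signal)
  if (n_fp > 0) {
    ct[signal] <- pmin(rnorm(n_fp, cfg$max_cycles - 5, 1.5),
                       cfg$max_cycles - 0.01)
    tm[signal] <- rnorm(n_fp, cfg$tm_nonspecific[1], cfg$tm_nonspecific[2])
    seq_conf[signal] <- runif(n_fp) >= cfg$fp_seq_wt_rate
  }
  validate_wells(tibble::tibble(
    target = target, standard = "WT_ONLY", plate = plate,
    instrument = "I1", operator = "O1", replicate = seq_len(n_wells),
    ct = ct, tm = tm, wt_copies = 14000, truth_copies = 0,
    seq_confirmed = seq_conf
  ), max_cycles = cfg$max_cycles)
}

#' Simulate a multi-plate standard-curve study
#'
#' Runs the four quantitative standards (A–D) in triplicate on each of
#' `n_plates` plates spread across `n_instruments` instruments and
#' `n_operators` operators — the design used for master curves and
#' reproducibility assessment.
#'
#' @param cfg A [simulation_config()].
#' @param target Assay target label.
#' @param n_plates Number of plates (default 10).
#' @param n_instruments Instruments, assigned round-robin (default 5).
#' @param n_operators Operators, assigned round-robin (default 3).
#' @param standards Standard names to include (default A–D).
#' @param n_replicates Replicates per standard per plate (default 3).
#' @return Canonical well tibble across all plates.
#' @export
simulate_curve_plates <- function(cfg, target = "BRAF_V600", n_plates = 10,
                                  n_instruments = 5, n_operators = 3,
                                  standards = LETTERS[1:4], n_replicates = 3) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::local_seed(sim_seed(cfg, target, "plates"))
  std <- cfg$standards[cfg$standards$name %in% standards, ]
  rows <- lapply(seq_len(n_plates), function(p) {
    inst <- paste0("I", ((p - 1) %% n_instruments) + 1)
    oper <- paste0("O", ((p - 1) %% n_operators) + 1)
    plate_rows <- lapply(seq_len(nrow(std)), function(i) {
      s <- std[i, ]
      k <- rpois(n_replicates, s$nominal_mean_copies)
      ct <- rep(NA_real_, n_replicates)
      tm <- rep(NA_real_, n_replicates)
      occ <- k >= 1
      if (any(occ)) {
        # a calibration study has only the with-WT condition, so the
        # common component of the WT effect is absorbed by the curve and
        # only the mean shift is applied; the level-specific spread is a
        # property of the with/without contrast (simulate_dilution_series)
        ct[occ] <- sim_ct(cfg, k[occ], rep(s$wt_copies, sum(occ)),
                          shift = cfg$wt_shift[1])
        tm[occ] <- rnorm(sum(occ), cfg$tm_specific[1], cfg$tm_specific[2])
      }
      tibble::tibble(
        target = target, standard = s$name, plate = paste0("P", p),
        instrument = inst, operator = oper, replicate = seq_len(n_replicates),
        ct = ct, tm = tm, wt_copies = s$wt_copies,
        truth_copies = s$nominal_mean_copies,
        seq_confirmed = ifelse(occ, TRUE, NA)
      )
    })
    dplyr::bind_rows(plate_rows)
  })
  validate_wells(dplyr::bind_rows(rows), max_cycles = cfg$max_cycles)
}

#' Ground-truth table for a simulation configuration
#'
#' The recovery oracle used by tests: for every standard, the nominal mean
#' copies and the Poisson-expected empty fraction `exp(-mean)`.
#'
#' @param cfg A [simulation_config()].
#' @return Tibble with columns `standard`, `nominal_mean_copies`,
#'   `expected_empty_fraction`.
#' @export
ground_truth_table <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  tibble::tibble(
    standard = cfg$standards$name,
    nominal_mean_copies = cfg$standards$nominal_mean_copies,
    expected_empty_fraction =
      expected_empty_fraction(cfg$standards$nominal_mean_copies)
  )
}
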