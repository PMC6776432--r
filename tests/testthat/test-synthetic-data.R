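test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 5)
  a <- simulate_dilution_series(cfg, "KRAS_EX2")
  b <- simulate_dilution_series(cfg, "KRAS_EX2")
  expect_identical(a, b)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(a, p1); write_plate_table(b, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed actually changes the draws
  c2 <- simulate_dilution_series(simulation_config(seed = 6), "KRAS_EX2")
  expect_false(identical(a$ct, c2$ct))
})

test_that("empty-well fractions match the Poisson zero class", {
  std <- tibble::tibble(name = "G", nominal_mean_copies = 1.0,
                        ddpcr_reference_copies = NA_real_,
                        wt_copies = 0, n_replicates = 10000L)
  cfg <- simulation_config(seed = 31, standards = std)
  wells <- simulate_dilution_series(cfg, "BRAF_V600")
  frac <- mean(is.na(wells$ct))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 10000)
  expect_lt(abs(frac - exp(-1)), 3 * se)

  # zero nominal copies: every well is empty
  std0 <- dplyr::mutate(std, nominal_mean_copies = 0, n_replicates = 50L)
  w0 <- simulate_dilution_series(simulation_config(seed = 1, standards = std0),
                                 "BRAF_V600")
  expect_true(all(is.na(w0$ct)))
})

test_that("per-standard empty fractions are distributionally faithful", {
  # chi-square goodness of fit of empty counts against exp(-lambda)
  std <- tibble::tibble(name = c("E", "F", "G"),
                        nominal_mean_copies = c(5, 2.5, 1.25),
                        ddpcr_reference_copies = NA_real_,
                        wt_copies = 14000, n_replicates = 2000L)
  pvals <- vapply(1:5, function(s) {
    cfg <- simulation_config(seed = 100 + s, standards = std)
    wells <- simulate_dilution_series(cfg, "EGFR_T790M")
    counts <- tapply(is.na(wells$ct), wells$standard, sum)
    expected_p <- exp(-std$nominal_mean_copies)
    stat <- sum((counts - 2000 * expected_p)^2 /
                  (2000 * expected_p * (1 - expected_p)))
    pchisq(stat, df = 3, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(pvals >= 0.01))
})

test_that("Ct response tracks the realized copy number, with WT shift", {
  std <- tibble::tibble(name = c("A", "B"),
                        nominal_mean_copies = c(5120, 640),
                        ddpcr_reference_copies = NA_real_,
                        wt_copies = c(0L, 0L), n_replicates = 500L)
  cfg <- simulation_config(seed = 77, standards = std, sigma_ct = 0.05)
  wells <- simulate_dilution_series(cfg, "EGFR_DEL19")
  mean_a <- mean(wells$ct[wells$standard == "A"])
  mean_b <- mean(wells$ct[wells$standard == "B"])
  # 8-fold dilution = log10(8) decades on the curve
  expect_equal(mean_b - mean_a, -cfg$slope * log10(8), tolerance = 0.05)
})

test_that("WT background shift is a systematic (target, standard) effect", {
  # one shift per assay/concentration cell, constant across plates, with
  # the configured mean and spread across cells
  cfg <- simulation_config(seed = 88, sigma_ct = 0.05)
  shifts <- unlist(lapply(ASSAY_TARGETS, function(t) {
    poisqpcr:::wt_shift_for(cfg, t)
  }))
  expect_equal(length(shifts), 6 * 7)
  expect_equal(mean(shifts), cfg$wt_shift[1],
               tolerance = 3 * cfg$wt_shift[2] / sqrt(length(shifts)) / 0.32)
  expect_gt(sd(shifts), 0.35)
  expect_lt(sd(shifts), 0.7)

  # the shift moves condition-cell means coherently: across plates of one
  # target, the same standard lands at the same shifted mean
  w1 <- simulate_dilution_series(cfg, "EGFR_T790M", plate = "P1")
  w2 <- simulate_dilution_series(cfg, "EGFR_T790M", plate = "P2")
  pred <- cfg$intercept + cfg$slope * log10(5120)
  off1 <- mean(w1$ct[w1$standard == "A"]) - pred
  off2 <- mean(w2$ct[w2$standard == "A"]) - pred
  expect_equal(off1, off2, tolerance = 0.15)
  expect_equal(off1, poisqpcr:::wt_shift_for(cfg, "EGFR_T790M")[["A"]],
               tolerance = 0.1)

  # calibration plates see only the mean shift: an intercept offset that
  # leaves the fitted slope at the generating value
  wells <- simulate_curve_plates(cfg, "EGFR_T790M", n_plates = 20,
                                 standards = "A", n_replicates = 3)
  cell_means <- tapply(wells$ct, wells$plate, mean, na.rm = TRUE)
  expect_lt(sd(cell_means), 0.1)
  expect_equal(mean(cell_means) - pred, cfg$wt_shift[1], tolerance = 0.05)
  # within-cell replicate SD stays at the sigma_ct scale
  expect_lt(median(tapply(wells$ct, wells$plate, sd)), 0.2)
})

test_that("specificity panel respects the false-positive machinery", {
  cfg <- simulation_config(seed = 13, fp_rate = 0)
  clean <- simulate_wt_specificity_panel(cfg, 200)
  expect_true(all(is.na(clean$ct)))

  cfg2 <- simulation_config(seed = 13, fp_rate = 0.1)
  noisy <- simulate_wt_specificity_panel(cfg2, 400)
  raw_signals <- sum(!is.na(noisy$ct))
  expect_gt(raw_signals, 0)
  called <- sum(call_well(noisy, qc_config()))
  expect_lte(called, raw_signals)  # gates only remove
})

test_that("gated specificity at plate-scale FP rates exceeds 99%", {
  # raw spurious-signal rate of order 5/50 per plate; after melt and
  # sequencing gates the called-positive rate must stay under 1%
  cfg <- simulation_config(seed = 29, fp_rate = 0.1)
  panel <- dplyr::bind_rows(lapply(ASSAY_TARGETS[1:5], function(t) {
    simulate_wt_specificity_panel(cfg, 112, target = t)
  }))
  calls <- call_well(panel, qc_config())
  cc <- confusion_metrics(tibble::tibble(predicted_positive = calls,
                                         truth_positive = FALSE))
  expect_gte(cc$specificity, 0.99)
  expect_equal(cc$specificity_display, ">99%")
})

test_that("ground truth table is the exp(-lambda) oracle", {
  cfg <- simulation_config(seed = 1)
  gt <- ground_truth_table(cfg)
  expect_equal(gt$expected_empty_fraction,
               exp(-cfg$standards$nominal_mean_copies), tolerance = 1e-12)
  g <- gt[gt$standard == "G", ]
  expect_equal(g$expected_empty_fraction, exp(-1.25), tolerance = 1e-12)
  empty_cfg <- simulation_config(seed = 1, standards = default_standards()[0, ])
  expect_equal(nrow(ground_truth_table(empty_cfg)), 0)
})

test_that("invalid configurations list the offending fields", {
  expect_error(simulation_config(sigma_ct = -1), "sigma_ct",
               class = "poisqpcr_config_error")
  expect_error(simulation_config(fp_rate = 1.5), "fp_rate",
               class = "poisqpcr_config_error")
  err <- tryCatch(simulation_config(sigma_ct = 0, fp_rate = 2),
                  error = identity)
  expect_match(conditionMessage(err), "sigma_ct")
  expect_match(conditionMessage(err), "fp_rate")
})

test_that("pipeline closure: simulated data recovers curve and lambda", {
  cfg <- simulation_config(seed = 55)
  wells <- simulate_dilution_series(cfg, "EGFR_L858R")
  # curve from the quantitative standards (A-D)
  amp <- wells[!is.na(wells$ct) & wells$standard %in% LETTERS[1:4], ]
  fit <- fit_standard_curve(tibble::tibble(copies = amp$truth_copies,
                                           ct = amp$ct))
  expect_lt(abs(fit$slope - cfg$slope), 0.6)  # 12 points, stochastic copies
  # occupancy at the limiting standards recovers lambda within the CI
  for (sname in c("F", "G")) {
    sub <- wells[wells$standard == sname, ]
    est <- lambda_from_dropout(sum(is.na(sub$ct)), nrow(sub))
    lam <- cfg$standards$nominal_mean_copies[cfg$standards$name == sname]
    expect_true(est$ci95[1] <= lam && lam <= est$ci95[2])
  }
})
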