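test_that("confusion counts partition calls and follow the >99% display", {
  perf <- validation_fixture("analytical_performance")
  for (i in seq_len(nrow(perf))) {
    row <- perf[i, ]
    calls <- dplyr::bind_rows(
      tibble::tibble(predicted_positive = rep(TRUE, row$n_positive_tests -
                                                row$false_negatives),
                     truth_positive = TRUE),
      tibble::tibble(predicted_positive = rep(FALSE, row$false_negatives),
                     truth_positive = TRUE),
      tibble::tibble(predicted_positive = rep(TRUE, row$false_positives),
                     truth_positive = FALSE),
      tibble::tibble(predicted_positive = rep(FALSE, row$n_negative_tests -
                                                row$false_positives),
                     truth_positive = FALSE)
    )
    cc <- confusion_metrics(calls)
    expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, nrow(calls))
    expect_equal(cc$fn, row$false_negatives)
    expect_gte(cc$sensitivity, 0.99)
    expect_equal(cc$sensitivity_display, ">99%")
    expect_equal(cc$specificity_display, ">99%")
  }
  # an 80% metric renders as a rounded percent, not the sentinel
  weak <- confusion_metrics(tibble::tibble(
    predicted_positive = c(rep(TRUE, 8), rep(FALSE, 2)),
    truth_positive = rep(TRUE, 10)))
  expect_equal(weak$sensitivity_display, "80%")
})

test_that("well calling gates on Ct QC, melt window, and sequencing", {
  qc <- qc_config()
  wells <- dplyr::bind_rows(
    well_table("BRAF_V600", "E", ct = 36, tm = 80, seq_confirmed = TRUE),
    well_table("BRAF_V600", "E", ct = 36, tm = 80),            # unsequenced
    well_table("BRAF_V600", "WT_ONLY", ct = 40, tm = 73),      # non-specific
    well_table("BRAF_V600", "WT_ONLY", ct = 40, tm = 80,
               seq_confirmed = FALSE),                         # sequences WT
    well_table("BRAF_V600", "E", ct = 8, tm = 80),             # early artifact
    well_table("BRAF_V600", "G")                               # empty
  )
  expect_equal(call_well(wells, qc),
               c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("MAF and its display floor behave at assay scale", {
  expect_equal(maf(1, 14000), 1 / 14001, tolerance = 1e-12)
  expect_equal(maf_display(maf(1, 14000)), "0.01%")   # 0.0071% floors up
  expect_equal(maf_display(maf(2.8, 14000)), "0.02%")
  expect_equal(maf_display(maf(14, 14000)), "0.10%")
})

test_that("LoD picks the lowest Poisson-consistent level", {
  # every level detected in proportion to its Poisson expectation
  levels <- tibble::tibble(
    mutant_copies = c(10, 5, 2.5, 1.25),
    wt_copies = 14000,
    n_wells = c(18, 20, 20, 20),
    n_detected = round(c(18, 20, 20, 20) * (1 - exp(-c(10, 5, 2.5, 1.25))))
  )
  lod <- determine_lod(levels)
  expect_equal(lod$lod_copies, 1.25)
  expect_equal(lod$lod_maf_display, "0.01%")

  # adding a detected lower level can only lower (never raise) the LoD MAF
  with_lower <- dplyr::bind_rows(levels, tibble::tibble(
    mutant_copies = 0.625, wt_copies = 14000, n_wells = 40,
    n_detected = round(40 * (1 - exp(-0.625)))))
  lod2 <- determine_lod(with_lower)
  expect_lte(lod2$lod_maf, lod$lod_maf)

  # nothing detected: undefined LoD, not an error
  none <- determine_lod(dplyr::mutate(levels, n_detected = 0))
  expect_true(is.na(none$lod_copies))

  expect_error(determine_lod(levels[c(2, 1), ]),
               class = "poisqpcr_domain_error")  # unsorted
})

test_that("detection rates reproduce clinical percentages with exact CIs", {
  lung <- validation_fixture("clinical_detection_lung")
  for (i in seq_len(nrow(lung))) {
    r <- detection_rate(lung$n_detected[i], lung$n_tested[i])
    expect_equal(r$percent, lung$printed_percent[i])
    expect_true(r$ci95[1] <= r$rate && r$rate <= r$ci95[2])
  }
  # 0 of 20 (clinical specificity panel): exact upper bound 1-0.025^(1/20)
  r0 <- detection_rate(0, 20)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci95[2], 1 - 0.025^(1 / 20), tolerance = 1e-9)
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(2024)
  p <- 0.2; n <- 50
  hits <- replicate(500, {
    x <- rbinom(1, n, p)
    ci <- detection_rate(x, n)$ci95
    ci[1] <= p && p <= ci[2]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("reproducibility cells pass or fail the 1-Ct SD rule", {
  wells <- dplyr::bind_rows(
    well_table("BRAF_V600", "A", plate = "P1", replicate = 1:3,
               ct = c(30.0, 30.2, 30.4), tm = 80),
    well_table("BRAF_V600", "B", plate = "P1", replicate = 1:3,
               ct = c(30, 31.5, 33), tm = 80),
    well_table("BRAF_V600", "C", plate = "P1", replicate = 1,
               ct = 33, tm = 80)  # singleton: insufficient replicates
  )
  tab <- reproducibility_summary(wells, mode = "intra", unit = "plate")
  a <- tab[tab$standard == "A", ]; b <- tab[tab$standard == "B", ]
  expect_equal(a$sd_ct, 0.2, tolerance = 1e-9)
  expect_true(a$pass)
  expect_equal(b$sd_ct, 1.5, tolerance = 1e-9)
  expect_false(b$pass)
  expect_true(is.na(tab$pass[tab$standard == "C"]))
  expect_equal(a$cv_percent, 100 * 0.2 / 30.2, tolerance = 1e-9)
})

test_that("inter-assay mode summarizes spread of unit means", {
  wells <- dplyr::bind_rows(lapply(1:4, function(p) {
    well_table("BRAF_V600", "A", plate = paste0("P", p), replicate = 1:3,
               ct = c(30, 30.2, 30.4) + (p - 1) * 0.1, tm = 80)
  }))
  tab <- reproducibility_summary(wells, mode = "inter", unit = "plate")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n, 4L)                       # four plate means
  expect_equal(tab$sd_ct, sd(30.2 + 0:3 * 0.1), tolerance = 1e-9)
  expect_true(tab$pass)
})
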