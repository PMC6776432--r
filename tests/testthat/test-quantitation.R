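test_that("exact log-linear points are fit exactly", {
  pts <- tibble::tibble(copies = c(1, 10, 100), ct = c(38.0, 34.678, 31.356))
  fit <- fit_standard_curve(pts, "exact")
  expect_equal(fit$slope, -3.322, tolerance = 1e-6)
  expect_equal(fit$intercept, 38.0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  # slope -3.322 is within rounding of the perfect-doubling slope
  expect_equal(fit$efficiency, 1.0, tolerance = 1e-2)
})

test_that("any two distinct points define a perfect line", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- tibble::tibble(copies = sort(10^runif(2, 0, 4)),
                          ct = rnorm(2, 30, 5))
    fit <- fit_standard_curve(pts)
    expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  }
})

test_that("efficiency and slope are exact algebraic partners", {
  for (slope in c(-3.1, -3.322, -3.45, -3.9)) {
    pts <- tibble::tibble(copies = c(1, 10, 100),
                          ct = 38 + slope * c(0, 1, 2))
    fit <- fit_standard_curve(pts)
    expect_equal(-1 / log10(1 + fit$efficiency), fit$slope, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid curve inputs error", {
  expect_error(fit_standard_curve(tibble::tibble(copies = c(10, 10, 10),
                                                 ct = c(30, 30.5, 31))),
               class = "poisqpcr_degenerate_fit_error")
  expect_error(fit_standard_curve(tibble::tibble(copies = c(0, 10),
                                                 ct = c(40, 30))),
               class = "poisqpcr_domain_error")
})

test_that("interpolation inverts prediction and is monotone decreasing", {
  fit <- fit_standard_curve(tibble::tibble(copies = c(1, 10, 100),
                                           ct = c(38.6, 35.15, 31.7)))
  expect_equal(interpolate_copies(fit$intercept, fit), 1.0, tolerance = 1e-9)
  expect_equal(interpolate_copies(fit$intercept + fit$slope, fit), 10.0,
               tolerance = 1e-9)
  for (c0 in c(0.5, 1, 7, 123, 5120)) {
    expect_equal(interpolate_copies(predict_ct(c0, fit), fit), c0,
                 tolerance = 1e-9)
  }
  cts <- seq(25, 40, by = 0.5)
  expect_true(all(diff(interpolate_copies(cts, fit)) < 0))
})

test_that("simulated curves recover the generating slope", {
  # a single 12-point triplicate curve estimates the slope with an SE near
  # 0.1, so the recovery property is asserted on the median over plates
  cfg <- simulation_config(seed = 11, sigma_ct = 0.3)
  wells <- simulate_curve_plates(cfg, "EGFR_L858R", n_plates = 15,
                                 standards = LETTERS[1:4], n_replicates = 3)
  errs <- vapply(split(wells, wells$plate), function(pl) {
    amp <- pl[!is.na(pl$ct), ]
    fit <- fit_standard_curve(tibble::tibble(copies = amp$truth_copies,
                                             ct = amp$ct))
    abs(fit$slope - cfg$slope)
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("slope error shrinks as Ct noise vanishes", {
  errs <- vapply(c(0.5, 0.05, 0.005), function(sig) {
    cfg <- simulation_config(seed = 3, sigma_ct = sig)
    med <- vapply(1:20, function(i) {
      set.seed(1000 + i)
      copies <- rep(c(5120, 640, 80, 10), each = 3)
      ct <- cfg$intercept + cfg$slope * log10(copies) +
        rnorm(length(copies), 0, sig)
      fit <- fit_standard_curve(tibble::tibble(copies = copies, ct = ct))
      abs(fit$slope - cfg$slope)
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("master curve pooling matches single fits on shared designs", {
  pts <- tibble::tibble(copies = rep(c(1, 10, 100, 1000), 2),
                        ct = rep(c(38, 34.5, 31, 27.5), 2),
                        plate = rep(c("P1", "P2"), each = 4))
  mc <- build_master_curve(pts)
  single <- fit_standard_curve(pts[pts$plate == "P1", c("copies", "ct")])
  expect_equal(mc$master$slope, single$slope, tolerance = 1e-9)
  expect_equal(mc$master$intercept, single$intercept, tolerance = 1e-9)
  expect_equal(nrow(mc$members), 2)
  # one plate only: identical to the plain fit
  mc1 <- build_master_curve(pts[pts$plate == "P1", ])
  expect_equal(mc1$master$slope, single$slope, tolerance = 1e-12)
  # mixed targets refuse to pool
  pts$target <- rep(c("BRAF_V600", "KRAS_EX2"), each = 4)
  expect_error(build_master_curve(pts), class = "poisqpcr_domain_error")
})

test_that("the 10-plate master curve is tight and linear", {
  cfg <- simulation_config(seed = 19)
  wells <- simulate_curve_plates(cfg, "BRAF_V600", n_plates = 10,
                                 n_instruments = 5)
  amp <- wells[!is.na(wells$ct), ]
  mc <- build_master_curve(tibble::tibble(copies = amp$truth_copies,
                                          ct = amp$ct, plate = amp$plate))
  expect_gte(mc$master$r_squared, 0.94)
  expect_lt(abs(mc$master$slope - cfg$slope), 0.15)
  tbl <- master_curve_table(mc)
  expect_equal(nrow(tbl), 11)  # 10 member fits + the pooled row
  expect_equal(tbl$group_id[11], "master")
})

test_that("reportable range requires one signal per level", {
  levels <- tibble::tibble(
    standard = LETTERS[1:7],
    nominal_copies = c(5120, 640, 80, 10, 5, 2.5, 1.25),
    n_detected = c(3, 3, 3, 3, 18, 0, 9),
    n_wells = c(3, 3, 3, 3, 20, 20, 20)
  )
  rr <- reportable_range(levels)
  expect_false(rr$levels$in_range[rr$levels$standard == "F"])
  expect_equal(rr$min_copies, 1.25)
  expect_equal(rr$max_copies, 5120)
  # all-A-D detected means all four quantitative levels are in range
  expect_true(all(rr$levels$in_range[rr$levels$standard %in% LETTERS[1:4]]))
  # single detected level collapses the range
  one <- reportable_range(levels[3, ])
  expect_equal(one$min_copies, one$max_copies)
  # nothing detected is an empty range, not an error
  none <- reportable_range(dplyr::mutate(levels, n_detected = 0))
  expect_true(is.na(none$min_copies))
})
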