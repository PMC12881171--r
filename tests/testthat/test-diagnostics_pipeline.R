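test_that("acceleration window follows the second-difference rule", {
  # accelerating then decelerating incidence on a uniform grid:
  # slopes 1,2,4,7,5,2 -> second differences 1,2,3,-2,-3
  s <- incidence_series("R1", seq(20, 50, 5), seq(25, 55, 5),
                        c(1, 2, 4, 8, 15, 20, 22))
  w <- acceleration_window(s)
  expect_equal(w$included, 1:5)
  expect_equal(w$upper_age_bound, 45)   # upper edge of the 5th bin
  # divided differences: raw second differences over the 5-year spacing
  expect_equal(w$rule_trace$second_difference, c(1, 2, 3, -2, -3) / 5)
  expect_equal(w$rule_trace$pass[1:4], c(TRUE, TRUE, TRUE, FALSE))
  expect_false(w$degenerate)
})

test_that("noiseless exponential accelerates everywhere; linear incidence degenerates", {
  w <- acceleration_window(noiseless_series("exponential"))
  expect_equal(w$included, 1:7)
  expect_equal(w$upper_age_bound, 60)
  lin <- incidence_series("R1", seq(20, 50, 5), seq(25, 55, 5),
                          seq(2, 14, 2))
  expect_warning(wl <- acceleration_window(lin), "minimal leading window")
  expect_true(wl$degenerate)
  expect_equal(wl$included, 1:2)
})

test_that("acceleration window is invariant to incidence rescaling", {
  s <- incidence_series("R1", seq(20, 50, 5), seq(25, 55, 5),
                        c(1, 2, 4, 8, 15, 20, 22))
  s2 <- incidence_series("R1", seq(20, 50, 5), seq(25, 55, 5),
                         1000 * c(1, 2, 4, 8, 15, 20, 22))
  expect_equal(acceleration_window(s2)$included,
               acceleration_window(s)$included)
})

test_that("age-window restriction keeps only fully contained bins", {
  s <- noiseless_series("exponential")
  win <- apply_window(s, 30, 55)
  expect_equal(nrow(win), 5L)
  expect_true(all(win$age_lower >= 30 & win$age_upper <= 55))
})

test_that("sensitivity scan tracks the generating model in every window", {
  ex <- noiseless_series("exponential")
  scan_f <- sensitivity_scan(ex, "vary_final_age")
  expect_true(all(scan_f$delta_r2 > 0))
  # admissible bounds: windows of >= 4 of the 7 bins
  expect_equal(scan_f$bound, seq(45, 60, 5))
  expect_equal(scan_f$n, 4:7)
  scan_i <- sensitivity_scan(ex, "vary_initial_age")
  expect_true(all(scan_i$delta_r2 > 0))
  expect_equal(nrow(scan_i), 4L)
  pl <- noiseless_series("power_law")
  expect_true(all(sensitivity_scan(pl, "vary_final_age")$delta_r2 < 0))
  expect_warning(out <- sensitivity_scan(ex[1:3, ], "vary_final_age"),
                 "no admissible window")
  expect_equal(nrow(out), 0L)
})

test_that("widening past the acceleration bound erodes the exponential advantage", {
  # peak-shaped incidence: exponential up to 60, then deceleration
  bins <- age_bins(seq(25, 80, 5))
  inc <- 0.034 * exp(0.117 * pmin(bins$mid, 57.5)) *
    exp(-0.05 * pmax(bins$mid - 57.5, 0))
  s <- incidence_series("R1", bins$lower, bins$upper, inc)
  scan <- sensitivity_scan(s, "vary_final_age")
  last3 <- tail(scan$delta_r2, 3)
  expect_true(all(diff(last3) < 0))
})

test_that("config validation reports every problem at once", {
  err <- tryCatch(run_full_analysis(list(
    input = "/nonexistent/file.csv",
    truth = list(family = "weibull"),
    window = "everything",
    prior_scales = c(-1, 0.354))), error = function(e) conditionMessage(e))
  expect_match(err, "mutually exclusive")
  expect_match(err, "not found")
  expect_match(err, "family")
  expect_match(err, "window")
  expect_match(err, "prior_scales")
})

test_that("full analysis on exponential truth favours the exponential at every stage", {
  cfg <- list(truth = list(family = "exponential", a_e = 0.034, b = 0.117,
                           heterogeneity = list(intercept_sd = 0.05,
                                                slope_sd = 0.001)),
              seed = 101,
              fracpoly_grid = seq(-1, 2, 0.5))
  rep1 <- run_full_analysis(cfg)
  expect_gt(rep1$jzs$bf10, 1)
  expect_gt(rep1$ml_ratio$bf10, 1)
  expect_gt(rep1$hierarchical$bf$bf10, 1)
  expect_gt(rep1$delta_r2, 0)
  expect_equal(rep1$fits$loglog_linear$n, 7L)
  expect_equal(rep1$provenance$window$convention, "bin upper edges")
  # determinism: byte-identical JSON for the same config and seed
  rep2 <- run_full_analysis(cfg)
  expect_identical(report_json(rep1), report_json(rep2))
  # JSON parses and carries the headline numbers
  parsed <- jsonlite::fromJSON(report_json(rep1))
  expect_equal(parsed$delta_r2, rep1$delta_r2, tolerance = 1e-10)
  expect_equal(parsed$jzs$bf10, rep1$jzs$bf10, tolerance = 1e-6)
})

test_that("explicit windows and CSV input run end to end", {
  s <- simulate_registries(calibrated_truth("exponential"), ref_bins(),
                           2e6, 2, seed = 55)
  path <- file.path(withr::local_tempdir(), "in.csv")
  write_incidence_csv(s, path)
  rep <- run_full_analysis(list(input = path, window = c(25, 60),
                                hierarchical = FALSE,
                                fracpoly_grid = seq(0, 1, 0.5)))
  expect_equal(rep$provenance$window$policy, "explicit")
  expect_equal(rep$fits$semilog_linear$n, 7L)  # pooled across 2 registries
  expect_true(rep$provenance$pooled)
  expect_null(rep$hierarchical)
})

test_that("evidence directions agree across methods on noiseless fixtures", {
  for (curve in c("exponential", "power_law")) {
    truth <- calibrated_truth(curve)
    s <- near_noiseless_registries(truth, seed = 9)
    pooled <- pool_registries(s)
    dr2 <- r2_difference(pooled)
    ml <- ml_ratio_bf(fit_linear(pooled, "semilog"),
                      fit_linear(pooled, "loglog"))
    jz <- compare_exp_vs_power(pooled)
    hb <- hier_bf(fit_hier(s, "semilog"), fit_hier(s, "loglog"))
    expected_sign <- if (curve == "exponential") 1 else -1
    expect_equal(sign(dr2), expected_sign)
    expect_equal(sign(ml$log_bf10), expected_sign)
    expect_equal(sign(jz$log_bf10), expected_sign)
    expect_equal(sign(hb$log_bf10), expected_sign)
  }
})
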