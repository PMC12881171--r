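test_that("JZS Bayes factor behaves like a Bayes factor", {
  # no signal: response orthogonal to the predictor by construction
  t <- c(30, 40, 50, 60, 70, 80)
  y_orth <- residuals(lm(z ~ t, data.frame(z = c(1, -1, 1, -1, 1, -1), t)))
  s <- incidence_series("R1", t - 5, t + 5, exp(y_orth + 5))
  expect_lt(jzs_bf_vs_null(s, "t")$bf, 1)
  # monotone in R^2 at fixed n (checked through the internal formula by
  # constructing data with increasing correlation)
  bfs <- sapply(c(0.2, 0.5, 0.8, 0.95, 0.999), function(rho) {
    y <- rho * scale(t)[, 1] + sqrt(1 - rho^2) * scale(y_orth)[, 1]
    jzs_bf_vs_null(incidence_series("R1", t - 5, t + 5, exp(y + 5)),
                   "t")$bf
  })
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bf_vs_null(s[1:3, ], "t"), "at least 4")
})

test_that("quadrature matches the Monte-Carlo mixing oracle", {
  set.seed(77)
  for (rep in 1:6) {
    n <- sample(7:15, 1)
    t <- sort(runif(n, 25, 70))
    y <- 0.05 * t + rnorm(n, sd = 0.5)
    s <- incidence_series("R1", t - 1, t + 1, exp(y))
    r <- sample(c(0.354, 1), 1)
    q <- jzs_bf_vs_null(s, "t", prior_scale = r)
    mc <- mc_jzs_bf(q$n, 1, q$r_squared, r, ndraw = 2e6)
    expect_equal(q$bf, mc, tolerance = 0.02)
  }
})

test_that("JZS BF is invariant to response and predictor rescaling", {
  set.seed(5)
  t <- seq(27.5, 57.5, 5)
  inc <- exp(rnorm(7, 0.1 * t, 0.2))
  s <- incidence_series("R1", t - 2.5, t + 2.5, inc)
  base <- compare_exp_vs_power(s)$log_bf10
  # affine rescaling of the response = unit change of incidence
  s_scaled <- incidence_series("R1", t - 2.5, t + 2.5, inc * 1e3)
  expect_equal(compare_exp_vs_power(s_scaled)$log_bf10, base,
               tolerance = 1e-6)
  # positive rescaling of the age predictor (years -> decades)
  s_dec <- incidence_series("R1", (t - 2.5) / 10, (t + 2.5) / 10, inc)
  expect_equal(jzs_bf_vs_null(s_dec, "t")$bf, jzs_bf_vs_null(s, "t")$bf,
               tolerance = 1e-6)
})

test_that("the encompassing comparison points toward the generating model", {
  expect_gt(compare_exp_vs_power(noiseless_series("exponential"))$bf10, 1)
  expect_lt(compare_exp_vs_power(noiseless_series("power_law"))$bf10, 1)
})

test_that("ML-ratio BF matches its closed form and is antisymmetric", {
  # frozen closed form: ((1 - 0.979) / (1 - 0.993))^(7/2) = 3^3.5
  expect_equal(((1 - 0.979) / (1 - 0.993))^(7 / 2), 3^3.5,
               tolerance = 1e-12)
  s <- simulate_registry(calibrated_truth("exponential"), ref_bins(), 2e6,
                         seed = 21)
  fs <- fit_linear(s, "semilog")
  fl <- fit_linear(s, "loglog")
  b <- ml_ratio_bf(fs, fl)
  expect_equal(b$bf10,
               ((1 - fl$r_squared) / (1 - fs$r_squared))^(b$n / 2),
               tolerance = 1e-8)
  expect_equal(b$bf10, exp(fs$loglik - fl$loglik), tolerance = 1e-8)
  expect_equal(b$bf01, 1 / b$bf10, tolerance = 1e-12)
  # equal residuals: even evidence
  f2 <- fl; f2$scale <- "semilog"
  expect_equal(ml_ratio_bf(f2, fl)$bf10, 1)
  # exact semi-log fit: flagged overflow
  ov <- ml_ratio_bf(fit_linear(noiseless_series("exponential"), "semilog"),
                    fit_linear(noiseless_series("exponential"), "loglog"))
  expect_true(ov$overflow)
  expect_identical(ov$bf10, Inf)
})

test_that("prior robustness table scans scales and converges to the ML ratio", {
  s <- simulate_registry(calibrated_truth("exponential"), ref_bins(), 2e6,
                         seed = 31)
  tab <- prior_robustness(s)
  expect_equal(nrow(tab), 7L)  # 6 scales + ML-ratio reference
  expect_equal(tab$scale, c(0.01, 0.354, 1, 10, 1000, 1e5, Inf))
  ml <- tab$log_bf10[tab$method == "ml_ratio"]
  # widest prior closest to the flat-prior limit
  expect_lt(abs(tab$log_bf10[tab$scale == 1e5] - ml),
            abs(tab$log_bf10[tab$scale == 0.354] - ml))
  # monotone approach along the scale grid
  gaps <- abs(tab$log_bf10[tab$method == "jzs"] - ml)
  expect_true(all(diff(gaps) <= 1e-8))
  # sign consistency on a no-signal instance across all scales
  t <- c(30, 40, 50, 60, 70, 80)
  y_orth <- residuals(lm(z ~ t, data.frame(z = c(1, -1, 1, -1, 1, -1), t)))
  s0 <- incidence_series("R1", t - 5, t + 5, exp(y_orth + 5))
  tab0 <- prior_robustness(s0)
  expect_true(all(sign(tab0$log_bf10) == sign(tab0$log_bf10[1])))
})

test_that("evidence grading follows the standard thresholds", {
  expect_equal(as.character(grade_evidence(8.7)), "moderate")
  expect_equal(as.character(grade_evidence(2.3e4)), "extreme")
  expect_equal(as.character(grade_evidence(1)), "none")
  expect_equal(as.character(grade_evidence(2)), "anecdotal")
  # boundaries take the lower category
  expect_equal(as.character(grade_evidence(3)), "anecdotal")
  expect_equal(as.character(grade_evidence(10)), "moderate")
  expect_equal(as.character(grade_evidence(30)), "strong")
  expect_equal(as.character(grade_evidence(100)), "very strong")
  # reciprocal grading with direction
  g <- grade_evidence(1 / 50)
  expect_equal(as.character(g), "very strong")
  expect_equal(attr(g, "direction"), "H0")
  expect_equal(attr(grade_evidence(7), "direction"), "H1")
  expect_error(grade_evidence(0), "positive")
  expect_error(grade_evidence(-2), "positive")
})

test_that("slope credible interval brackets the estimate and tracks the data", {
  s <- pool_registries(simulate_registries(calibrated_truth("exponential"),
                                           ref_bins(), 2e6, 5, seed = 3))
  ci <- slope_credible_interval(s, "semilog")
  ols <- coef(lm(log(incidence) ~ age_mid, s))[2]
  expect_lt(ci["lower"], ci["estimate"])
  expect_lt(ci["estimate"], ci["upper"])
  expect_equal(unname(ci["estimate"]), unname(ols), tolerance = 0.02)
  # a 99% interval contains the 95% one
  ci99 <- slope_credible_interval(s, "semilog", level = 0.99)
  expect_lt(ci99["lower"], ci["lower"])
  expect_gt(ci99["upper"], ci["upper"])
})
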