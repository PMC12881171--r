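test_that("noiseless curves are fitted exactly on their own scale", {
  ex <- noiseless_series("exponential", a = 0.034, b = 0.117)
  f_semi <- fit_linear(ex, "semilog")
  expect_equal(f_semi$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(f_semi$coefficients["slope"]), 0.117,
               tolerance = 1e-10)
  expect_equal(unname(f_semi$coefficients["intercept"]), log(0.034),
               tolerance = 1e-10)
  f_log <- fit_linear(ex, "loglog")
  expect_equal(f_log$r_squared, 0.988785, tolerance = 1e-4)
  expect_equal(r2_difference(ex), 0.011215, tolerance = 1e-4)

  pl <- noiseless_series("power_law", k = 5)
  f_pl <- fit_linear(pl, "loglog")
  expect_equal(f_pl$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(f_pl$coefficients["slope"]), 4, tolerance = 1e-10)
  expect_lt(r2_difference(pl), 0)
})

test_that("least squares agrees with brute-force normal equations", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    degree <- sample(1:2, 1)
    t <- sort(runif(n, 20, 80))
    inc <- exp(rnorm(n, 1 + 0.05 * t, 0.3))
    s <- incidence_series("R1", t - 1, t + 1, inc)
    scale <- sample(c("loglog", "semilog"), 1)
    f <- fit_linear(s, scale, degree)
    x <- if (scale == "loglog") log(t) else t
    X <- if (degree == 1) cbind(1, x) else cbind(1, x, x^2)
    beta <- solve(t(X) %*% X, t(X) %*% log(inc))
    expect_equal(unname(f$coefficients), as.numeric(beta),
                 tolerance = 1e-10)
    expect_equal(f$rss, sum((log(inc) - X %*% beta)^2), tolerance = 1e-8)
    expect_equal(f$loglik, -(n / 2) * (log(2 * pi * f$rss / n) + 1))
  }
})

test_that("quadratic never fits worse and R2 is scale-invariant", {
  set.seed(42)
  t <- seq(27.5, 57.5, 5)
  inc <- exp(rnorm(7, 0.1 * t, 0.1))
  s <- incidence_series("R1", t - 2.5, t + 2.5, inc)
  for (sc in c("loglog", "semilog")) {
    expect_lte(fit_linear(s, sc, 2)$rss, fit_linear(s, sc, 1)$rss)
    # rescaling incidence units (affine shift of the log response)
    s2 <- incidence_series("R1", t - 2.5, t + 2.5, inc * 1000)
    expect_equal(fit_linear(s2, sc)$r_squared, fit_linear(s, sc)$r_squared,
                 tolerance = 1e-12)
  }
  # degenerate response: R2 defined as 0 on both scales
  flat <- incidence_series("R1", t - 2.5, t + 2.5, rep(3.3, 7))
  expect_equal(fit_linear(flat, "loglog")$r_squared, 0)
  expect_equal(r2_difference(flat), 0)
})

test_that("fit preconditions are enforced", {
  s <- noiseless_series("exponential")
  withzero <- incidence_series("R1", c(30, 35, 40), c(35, 40, 45),
                               c(1, 0, 2))
  expect_error(fit_linear(withzero, "loglog"), "filter_records")
  expect_error(fit_linear(s[1:2, ], "semilog"), "underdetermined")
  expect_error(fit_linear(s[1:3, ], "loglog", degree = 2),
               "underdetermined")
})

test_that("curvature classification distinguishes the two laws", {
  ex <- noiseless_series("exponential")
  pl <- noiseless_series("power_law")
  expect_equal(supralinearity_check(ex, "loglog"), "supralinear")
  expect_equal(supralinearity_check(ex, "semilog"), "linear")
  expect_equal(supralinearity_check(pl, "semilog"), "sublinear")
  expect_equal(supralinearity_check(pl, "loglog"), "linear")
})

test_that("fractional polynomials recover the generating exponent", {
  expect_equal(fracpoly_scan(noiseless_series("exponential"))$x_opt, 1.0)
  expect_equal(fracpoly_scan(noiseless_series("power_law"))$x_opt, 0.0)
})

test_that("fracpoly profile is consistent with the linear fits", {
  s <- simulate_registry(calibrated_truth("exponential"), ref_bins(), 2e6,
                         seed = 9)
  fp <- fracpoly_scan(s)
  expect_false(anyNA(fp$loglik))
  expect_equal(fp$loglik[fp$x_grid == 0], fit_linear(s, "loglog")$loglik,
               tolerance = 1e-10)
  expect_equal(fp$loglik[fp$x_grid == 1], fit_linear(s, "semilog")$loglik,
               tolerance = 1e-10)
  expect_length(fp$loglik, 41L)
})

test_that("leave-one-out R2 matches brute-force sub-fits", {
  # exact 3-point toy in semi-log scale: sub-fits computed by hand give
  # squared errors 1, 0.25, 1 and SST = 42/9
  toy <- incidence_series("R1", c(0.5, 1.5, 2.5), c(1.5, 2.5, 3.5),
                          exp(c(1, 2, 4)))
  expect_equal(loo_r2(toy, "semilog"), 1 - 2.25 / (42 / 9),
               tolerance = 1e-12)
  # independent brute force with stats::lm on a noisy fixture
  s <- simulate_registry(calibrated_truth("exponential"), ref_bins(), 2e6,
                         seed = 13)
  d <- data.frame(y = log(s$incidence), x = s$age_mid)
  pred <- sapply(seq_len(nrow(d)), function(i)
    predict(lm(y ~ x, d[-i, ]), d[i, ]))
  expect_equal(loo_r2(s, "semilog"),
               1 - sum((d$y - pred)^2) / sum((d$y - mean(d$y))^2),
               tolerance = 1e-10)
})

test_that("collinear data give loo R2 of 1; noise lowers loo below in-sample R2", {
  expect_equal(loo_r2(noiseless_series("exponential"), "semilog"), 1,
               tolerance = 1e-10)
  for (seed in 1:5) {
    s <- simulate_registry(calibrated_truth("exponential"), ref_bins(),
                           2e5, seed = seed)
    s <- filter_records(s)
    expect_lte(loo_r2(s, "semilog"), fit_linear(s, "semilog")$r_squared)
    expect_lte(loo_r2(s, "loglog"), fit_linear(s, "loglog")$r_squared)
  }
})
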