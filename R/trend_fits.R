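# Stack a series into the fitted point set: abscissa t = bin midpoint,
# response y = ln(incidence).  Multi-registry input is stacked unweighted;
# registry structure is handled only by the hierarchical module.
series_points <- function(series) {
  if (inherits(series, "incidence_series")) {
    t <- series$age_mid
    inc <- series$incidence
    reg <- series$registry
  } else if (is.list(series) && !is.null(series$t)) {
    t <- series$t
    inc <- if (!is.null(series$incidence)) series$incidence else exp(series$y)
    reg <- if (!is.null(series$registry)) series$registry
           else rep("R1", length(t))
  } else stop("expected an incidence_series or a list with components t, y")
  if (any(is.na(t))) stop("open-ended bins present; filter before fitting")
  if (any(t <= 0)) stop("bin midpoints must be positive")
  if (any(inc <= 0))
    stop("zero or negative incidence; apply filter_records() before fitting")
  list(t = as.numeric(t), y = log(as.numeric(inc)), registry = reg)
}

ml_loglik <- function(rss, n) {
  if (rss <= 0) return(Inf)
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

#' Least-squares fit of log incidence on transformed age
#'
#' Fits `ln(incidence)` by ordinary least squares on `ln(t)` (log-log
#' scale: a power law, slope `k - 1`) or on `t` (semi-log scale: an
#' exponential, slope `b`), optionally with a quadratic term.  The
#' log-likelihood is the Gaussian maximum, using the ML variance estimate
#' `rss / n`, so likelihood-ratio Bayes factors have the closed form used
#' in [ml_ratio_bf()].  A zero-variance response yields `r_squared = 0` by
#' convention.
#'
#' @param series An [incidence_series] (all registries stacked), after
#'   [filter_records()].
#' @param scale `"loglog"` or `"semilog"`.
#' @param degree 1 (linear) or 2 (quadratic).
#' @return An object of class `"fit_result"`: list with `scale`, `degree`,
#'   `coefficients` (intercept, slope, and `quad` when `degree = 2`),
#'   `r_squared`, `rss`, `n`, `loglik`, plus the fitted point set.
#' @examples
#' s <- simulate_registry(exponential_truth(0.034, 0.117),
#'                        age_bins(seq(25, 60, 5)), 2e6, seed = 1)
#' fit_linear(s, "semilog")$coefficients
#' @export
fit_linear <- function(series, scale = c("loglog", "semilog"), degree = 1) {
  scale <- match.arg(scale)
  stopifnot(degree %in% c(1, 2))
  p <- series_points(series)
  n <- length(p$t)
  if (n < degree + 2)
    stop(sprintf("underdetermined fit: %d points for degree %d", n, degree))
  x <- if (scale == "loglog") log(p$t) else p$t
  X <- if (degree == 1) cbind(intercept = 1, slope = x)
       else cbind(intercept = 1, slope = x, quad = x^2)
  fit <- stats::lm.fit(X, p$y)
  rss <- sum(fit$residuals^2)
  sst <- sum((p$y - mean(p$y))^2)
  r2 <- if (sst <= 0) 0 else max(0, min(1, 1 - rss / sst))
  structure(list(scale = scale, degree = degree,
                 coefficients = stats::coef(fit),
                 r_squared = r2, rss = rss, n = n,
                 loglik = ml_loglik(rss, n),
                 fitted = as.numeric(X %*% stats::coef(fit)),
                 x = x, y = p$y),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s degree %d: R^2 = %.4f, n = %d, loglik = %.3f\n",
              x$scale, x$degree, x$r_squared, x$n, x$loglik))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Difference in linear fit performance between scales
#'
#' Computes `R^2(semilog) - R^2(loglog)` for degree-1 fits: positive
#' values favour the exponential function, negative values the power law.
#'
#' @param series An [incidence_series].
#' @return Signed numeric difference.
#' @export
r2_difference <- function(series) {
  fit_linear(series, "semilog", 1)$r_squared -
    fit_linear(series, "loglog", 1)$r_squared
}

#' Classify curvature of log incidence in a given scale
#'
#' Fits a quadratic and classifies the curve as supralinear (positive
#' quadratic coefficient), sublinear (negative), or linear when the
#' quadratic term is negligible -- its magnitude below `tol` or its
#' removal changing `R^2` by less than `1e-4`.  A truly exponential curve
#' is supralinear in log-log scale and linear in semi-log scale; a power
#' law is linear in log-log and sublinear in semi-log.
#'
#' @param series An [incidence_series].
#' @param scale `"loglog"` or `"semilog"`.
#' @param tol Absolute tolerance on the quadratic coefficient.
#' @return `"supralinear"`, `"sublinear"`, or `"linear"`.
#' @export
supralinearity_check <- function(series, scale = c("loglog", "semilog"),
                                 tol = 1e-8) {
  scale <- match.arg(scale)
  f2 <- fit_linear(series, scale, 2)
  f1 <- fit_linear(series, scale, 1)
  q <- unname(f2$coefficients["quad"])
  if (abs(q) < tol || abs(f2$r_squared - f1$r_squared) < 1e-4)
    return("linear")
  if (q > 0) "supralinear" else "sublinear"
}

#' Fractional-polynomial scan over age transforms
#'
#' Fits `ln(incidence) = b1 * t^(x) + b2` over a grid of exponents, with
#' the convention `t^(0) = ln(t)`, and reports the exponent maximising the
#' Gaussian log-likelihood.  The expected optimum is `x = 0` for a power
#' law and `x = 1` for an exponential curve.  Likelihood ties are broken
#' toward the smaller `|x|` with a warning.
#'
#' @param series An [incidence_series] with at least 4 points.
#' @param x_grid Exponent grid; default -2 to 2 in steps of 0.1.
#' @return An object of class `"fracpoly_result"`: list with `x_grid`,
#'   `loglik`, `x_opt`, and the coefficients at the optimum.
#' @export
fracpoly_scan <- function(series, x_grid = seq(-2, 2, by = 0.1)) {
  p <- series_points(series)
  n <- length(p$t)
  if (n < 4) stop("fractional-polynomial scan needs at least 4 points")
  x_grid <- round(x_grid, 10)
  ll <- vapply(x_grid, function(x) {
    tx <- if (x == 0) log(p$t) else p$t^x
    fit <- stats::lm.fit(cbind(1, tx), p$y)
    ml_loglik(sum(fit$residuals^2), n)
  }, numeric(1))
  top <- which(ll >= max(ll) - 1e-12 * max(1, abs(max(ll))))
  if (length(top) > 1L) {
    warning("likelihood tie in fractional-polynomial scan; ",
            "choosing the exponent with smallest |x|")
    top <- top[order(abs(x_grid[top]))]
  }
  x_opt <- x_grid[top[1L]]
  tx <- if (x_opt == 0) log(p$t) else p$t^x_opt
  cf <- stats::coef(stats::lm.fit(cbind(intercept = 1, beta1 = tx), p$y))
  structure(list(x_grid = x_grid, loglik = ll, x_opt = x_opt,
                 coefficients = cf, n = n),
            class = "fracpoly_result")
}

#' @export
print.fracpoly_result <- function(x, ...) {
  cat(sprintf("<fracpoly_result> x_opt = %.1f (n = %d)\n", x$x_opt, x$n))
  invisible(x)
}

#' Leave-one-out cross-validated R-squared
#'
#' Each point's contribution comes from a model fitted without it:
#' `1 - sum((y_i - pred_(-i))^2) / sum((y_i - mean(y))^2)` on the
#' log-incidence scale.  Always at or below 1; typically below the
#' in-sample `R^2` on noisy data.
#'
#' @param series An [incidence_series] with at least `degree + 3` points.
#' @param scale `"loglog"` or `"semilog"`.
#' @param degree 1 or 2.
#' @return Cross-validated R-squared (can be negative for a model worse
#'   than the mean).
#' @export
loo_r2 <- function(series, scale = c("loglog", "semilog"), degree = 1) {
  scale <- match.arg(scale)
  p <- series_points(series)
  n <- length(p$t)
  # each leave-one-out sub-fit must stay determined: n - 1 >= degree + 1
  if (n < degree + 2) stop("too few points for leave-one-out validation")
  x <- if (scale == "loglog") log(p$t) else p$t
  X <- if (degree == 1) cbind(1, x) else cbind(1, x, x^2)
  pred <- vapply(seq_len(n), function(i) {
    cf <- stats::coef(stats::lm.fit(X[-i, , drop = FALSE], p$y[-i]))
    sum(X[i, ] * cf)
  }, numeric(1))
  sst <- sum((p$y - mean(p$y))^2)
  if (sst <= 0) return(if (all(abs(pred - p$y) < 1e-12)) 1 else 0)
  1 - sum((p$y - pred)^2) / sst
}
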