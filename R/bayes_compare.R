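# Log Bayes factor of a p-predictor linear sub-model against the
# intercept-only null under the Jeffreys-Zellner-Siow prior: the g-prior
# marginal-likelihood ratio
#     (1 + g)^{(n-1-p)/2} * (1 + g (1 - R^2))^{-(n-1)/2}
# mixed over g with the Zellner-Siow density implied by a Cauchy(scale r)
# on standardized coefficients, i.e. inverse-gamma(1/2, n r^2 / 2).
# Integration is adaptive quadrature on z = ln(g), with the integrand
# exponentiated around its mode for stability at extreme Bayes factors.
jzs_log_bf <- function(n, p, r2, prior_scale, rel_tol = 1e-8) {
  stopifnot(n >= p + 3, r2 >= 0, prior_scale > 0)
  if (r2 >= 1) return(Inf)
  a <- (n - 1 - p) / 2
  cc <- (n - 1) / 2
  ls <- log1p(-r2)             # log(1 - R^2)
  bb <- n * prior_scale^2 / 2  # inverse-gamma rate
  logf <- function(z) {
    # log1p(exp(u)) computed stably for large |u|
    l1p <- function(u) ifelse(u > 0, u + log1p(exp(-u)), log1p(exp(u)))
    a * l1p(z) - cc * l1p(z + ls) +
      0.5 * log(bb) - lgamma(0.5) - 0.5 * z - bb * exp(-z)
  }
  m <- stats::optimize(logf, c(-400, 400), maximum = TRUE)
  val <- stats::integrate(function(z) exp(logf(z) - m$objective),
                          -Inf, Inf, rel.tol = rel_tol)
  if (val$message != "OK" || !is.finite(val$value) || val$value <= 0)
    stop("JZS quadrature failed: ", val$message)
  m$objective + log(val$value)
}

#' JZS Bayes factor of a one-predictor model against the intercept-only null
#'
#' Computes the Bayes factor for the regression of `ln(incidence)` on a
#' single predictor -- age `t` (exponential model) or `ln(t)` (power-law
#' model) -- against the intercept-only null, under the default
#' Jeffreys-Zellner-Siow prior: a Cauchy distribution (default scale
#' 0.354) on the standardized coefficient and the Jeffreys prior on the
#' residual variance.  The Bayes factor depends on the data only through
#' `n` and the sub-model's `R^2`, which makes it invariant to affine
#' rescaling of the response and positive rescaling of the predictor.
#'
#' @param series An [incidence_series] (or point list).
#' @param predictor `"t"` (semi-log/exponential) or `"ln_t"`
#'   (log-log/power-law).
#' @param prior_scale Cauchy scale of the JZS prior; default 0.354.
#' @return List of class `"jzs_bf"` with `bf`, `log_bf`, `r_squared`, `n`,
#'   `predictor`, `prior_scale`.
#' @export
jzs_bf_vs_null <- function(series, predictor = c("t", "ln_t"),
                           prior_scale = 0.354) {
  predictor <- match.arg(predictor)
  p <- series_points(series)
  n <- length(p$t)
  if (n < 4) stop("JZS Bayes factor needs at least 4 points")
  x <- if (predictor == "t") p$t else log(p$t)
  if (stats::sd(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm.fit(cbind(1, x), p$y)
  sst <- sum((p$y - mean(p$y))^2)
  r2 <- if (sst <= 0) 0 else 1 - sum(fit$residuals^2) / sst
  r2 <- min(max(r2, 0), 1)
  lbf <- jzs_log_bf(n, 1L, r2, prior_scale)
  structure(list(bf = exp(lbf), log_bf = lbf, r_squared = r2, n = n,
                 predictor = predictor, prior_scale = prior_scale),
            class = "jzs_bf")
}

new_bayes_comparison <- function(log_bf10, method, prior_scale, n,
                                 overflow = FALSE, degenerate = FALSE) {
  bf10 <- exp(log_bf10)
  structure(list(bf10 = bf10, bf01 = exp(-log_bf10), log_bf10 = log_bf10,
                 method = method, prior_scale = prior_scale, n = n,
                 grade = grade_evidence(if (is.finite(bf10) && bf10 > 0)
                   bf10 else exp(sign(log_bf10) * 700)),
                 overflow = overflow, degenerate = degenerate),
            class = "bayes_comparison")
}

#' @export
print.bayes_comparison <- function(x, ...) {
  fmt <- function(b) if (is.finite(b) && b < 100) sprintf("%.3g", b)
                     else sprintf("%.2e", b)
  dir <- if (x$log_bf10 > 0) "favours exponential (H1)"
         else if (x$log_bf10 < 0) "favours power law (H0)" else "equivocal"
  cat(sprintf("<bayes_comparison> BF10 = %s, BF01 = %s [%s%s, n = %d]\n",
              fmt(x$bf10), fmt(x$bf01), x$method,
              if (!is.na(x$prior_scale))
                sprintf(", scale %.3g", x$prior_scale) else "", x$n))
  cat(sprintf("  %s evidence, %s\n", x$grade, dir))
  invisible(x)
}

#' Bayesian comparison of the exponential versus the power-law model
#'
#' Implements the encompassing regression
#' `ln(I) = b1 * t + b2 * ln(t) + b3 + e`: the exponential hypothesis H1
#' is the sub-model with `b2 = 0`, the power-law hypothesis H0 the
#' sub-model with `b1 = 0`.  With equal prior model probabilities (the
#' beta-binomial(1, 1) prior over single-predictor models reduces to
#' equal odds, so no adjustment is applied), the Bayes factor is the ratio
#' of the two sub-models' JZS Bayes factors against the common null:
#' `BF10 = BF(t) / BF(ln t)`.
#'
#' @param series An [incidence_series].
#' @param prior_scale Cauchy scale of the JZS prior; default 0.354.
#' @return A `"bayes_comparison"`: `bf10 > 1` favours the exponential,
#'   `bf10 < 1` the power law; includes `bf01`, the evidence grade and
#'   the prior scale.
#' @export
compare_exp_vs_power <- function(series, prior_scale = 0.354) {
  p <- series_points(series)
  if (length(p$t) >= 2 &&
      isTRUE(all.equal(stats::cor(p$t, log(p$t)), 1, tolerance = 1e-12)))
    stop("collinear predictors: t and ln(t) are numerically identical")
  b1 <- jzs_bf_vs_null(series, "t", prior_scale)
  b0 <- jzs_bf_vs_null(series, "ln_t", prior_scale)
  new_bayes_comparison(b1$log_bf - b0$log_bf, method = "jzs",
                       prior_scale = prior_scale, n = b1$n)
}

#' Maximum-likelihood-ratio approximation to the Bayes factor
#'
#' Approximates `BF10` as the ratio of maximized likelihoods of the
#' semi-log (exponential, H1) and log-log (power-law, H0) fits, which is
#' the large-sample / flat-prior limit of the JZS Bayes factor.  With ML
#' variance estimates this equals
#' `((1 - R^2_loglog) / (1 - R^2_semilog))^(n/2)`; both expressions are
#' computed and must agree to 1e-8 relative.  It tends to overestimate
#' the evidence at small n.
#'
#' @param fit_semilog,fit_loglog Degree-1 [fit_linear()] results on the
#'   same data.
#' @return A `"bayes_comparison"` with method `"ml_ratio"`.  An exact
#'   semi-log fit (`R^2 = 1`) returns an infinite Bayes factor flagged
#'   with `overflow = TRUE`.
#' @export
ml_ratio_bf <- function(fit_semilog, fit_loglog) {
  stopifnot(inherits(fit_semilog, "fit_result"),
            inherits(fit_loglog, "fit_result"),
            fit_semilog$scale == "semilog", fit_loglog$scale == "loglog")
  if (fit_semilog$n != fit_loglog$n ||
      !isTRUE(all.equal(fit_semilog$y, fit_loglog$y)))
    stop("the two fits must share the same response vector")
  n <- fit_semilog$n
  sst <- sum((fit_semilog$y - mean(fit_semilog$y))^2)
  if (fit_semilog$rss <= 1e-12 * max(sst, .Machine$double.xmin))
    return(new_bayes_comparison(Inf, "ml_ratio", NA_real_, n,
                                overflow = TRUE))
  log_bf <- fit_semilog$loglik - fit_loglog$loglik
  log_bf_r2 <- (n / 2) * (log1p(-fit_loglog$r_squared) -
                            log1p(-fit_semilog$r_squared))
  if (abs(log_bf - log_bf_r2) > 1e-8 * max(1, abs(log_bf)))
    stop("internal inconsistency between likelihood and R^2 forms")
  new_bayes_comparison(log_bf, "ml_ratio", NA_real_, n)
}

#' Robustness of the Bayes factor to the JZS prior scale
#'
#' Recomputes the exponential-versus-power-law comparison across prior
#' scales from extremely narrow to extremely wide, and appends the
#' maximum-likelihood-ratio value as the infinite-scale reference (the
#' JZS prior tends to the uniform prior as the scale grows, where the
#' Bayes factor approaches the likelihood ratio).
#'
#' @param series An [incidence_series].
#' @param scales Prior scales to scan.
#' @return A data frame with one row per scale (plus the `Inf` row):
#'   `scale`, `method`, `bf10`, `bf01`, `log_bf10`, `grade`.
#' @export
prior_robustness <- function(series,
                             scales = c(0.01, 0.354, 1, 10, 1000, 1e5)) {
  rows <- lapply(scales, function(s) {
    b <- compare_exp_vs_power(series, prior_scale = s)
    data.frame(scale = s, method = "jzs", bf10 = b$bf10, bf01 = b$bf01,
               log_bf10 = b$log_bf10, grade = b$grade)
  })
  fs <- fit_linear(series, "semilog", 1)
  fl <- fit_linear(series, "loglog", 1)
  ml <- ml_ratio_bf(fs, fl)
  rows <- c(rows, list(data.frame(scale = Inf, method = "ml_ratio",
                                  bf10 = ml$bf10, bf01 = ml$bf01,
                                  log_bf10 = ml$log_bf10, grade = ml$grade)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior credible interval for the regression slope
#'
#' Equal-tailed credible interval for the slope of `ln(incidence)` on `t`
#' (semi-log scale: the exponential rate `b`) or on `ln(t)` (log-log
#' scale: the power-law slope `k - 1`), under the same
#' Jeffreys-Zellner-Siow setup as [jzs_bf_vs_null()]: a Zellner g-prior
#' on the slope mixed over g with the Zellner-Siow density, and the
#' Jeffreys prior on intercept and residual variance.  Conditional on g
#' the marginal posterior of the slope is a shrunk, scaled Student-t with
#' `n - 1` degrees of freedom; the mixture over the posterior of g is
#' evaluated by quadrature on `ln(g)` and the interval endpoints by
#' root-finding on the mixture CDF.
#'
#' @param series An [incidence_series].
#' @param scale `"semilog"` (slope is `b`) or `"loglog"` (slope is
#'   `k - 1`).
#' @param prior_scale Cauchy scale of the JZS prior; default 0.354.
#' @param level Credibility level, default 0.95.
#' @return Named numeric vector `c(lower, estimate, upper)` where
#'   `estimate` is the posterior median.
#' @export
slope_credible_interval <- function(series, scale = c("semilog", "loglog"),
                                    prior_scale = 0.354, level = 0.95) {
  scale <- match.arg(scale)
  p <- series_points(series)
  n <- length(p$t)
  if (n < 4) stop("credible interval needs at least 4 points")
  x <- if (scale == "semilog") p$t else log(p$t)
  y <- p$y
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  bhat <- sum(xc * (y - mean(y))) / ssx
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("degenerate response: zero variance of ln(incidence)")
  r2 <- max(0, min(1, bhat^2 * ssx / sst))
  bb <- n * prior_scale^2 / 2
  l1p <- function(u) ifelse(u > 0, u + log1p(exp(-u)), log1p(exp(u)))
  logf <- function(z)
    ((n - 2) / 2) * l1p(z) - ((n - 1) / 2) * l1p(z + log1p(-r2)) +
    0.5 * log(bb) - lgamma(0.5) - 0.5 * z - bb * exp(-z)
  m <- stats::optimize(logf, c(-400, 400), maximum = TRUE)
  zg <- seq(m$maximum - 40, m$maximum + 40, length.out = 801L)
  w <- exp(logf(zg) - m$objective)
  w <- w / sum(w)
  shr <- exp(zg) / (1 + exp(zg))  # shrinkage factor g / (1 + g)
  mu <- shr * bhat
  sc <- sqrt(shr * sst * (1 - shr * r2) / (n - 1) / ssx)
  cdf <- function(b) sum(w * stats::pt((b - mu) / sc, df = n - 1))
  span <- 60 * max(sc) + abs(bhat) + 1
  q <- function(prob) stats::uniroot(function(b) cdf(b) - prob,
                                     c(bhat - span, bhat + span),
                                     tol = 1e-10)$root
  c(lower = q((1 - level) / 2), estimate = q(0.5),
    upper = q((1 + level) / 2))
}

#' Grade the strength of Bayesian evidence
#'
#' Standard descriptive levels: anecdotal (1 < BF < 3), moderate (> 3),
#' strong (> 10), very strong (> 30) and extreme (> 100); boundary values
#' take the lower category and `BF = 1` grades as `"none"`.  Values below
#' 1 are graded on the reciprocal (the `BF01` convention), with the
#' direction recorded in the `"direction"` attribute (`"H1"`, `"H0"`, or
#' `"none"`).
#'
#' @param bf A positive Bayes factor.
#' @return Character label with attribute `direction`.
#' @examples
#' grade_evidence(8.7)    # moderate
#' grade_evidence(2.3e4)  # extreme
#' @export
grade_evidence <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 1L || is.na(bf) || bf <= 0)
    stop("'bf' must be a single positive number")
  direction <- if (bf > 1) "H1" else if (bf < 1) "H0" else "none"
  m <- max(bf, 1 / bf)
  label <- if (m == 1) "none"
    else if (m <= 3) "anecdotal"
    else if (m <= 10) "moderate"
    else if (m <= 30) "strong"
    else if (m <= 100) "very strong"
    else "extreme"
  structure(label, direction = direction)
}
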