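# Assemble the modelling frame for mixed-effects fits: response
# y = ln(incidence), abscissa x per scale (or a fractional exponent), and
# the registry grouping factor.
hier_frame <- function(series, scale, x_exp = NULL) {
  p <- series_points(series)
  x <- if (!is.null(x_exp)) {
    if (x_exp == 0) log(p$t) else p$t^x_exp
  } else if (scale == "loglog") log(p$t) else p$t
  data.frame(y = p$y, x = x, registry = factor(p$registry))
}

#' Hierarchical mixed-effects fit of log incidence
#'
#' Fits `ln(incidence) = b0 + b1 * x + (u_registry + v_registry * x) + e`
#' with `x = ln(t)` (log-log scale, power law) or `x = t` (semi-log scale,
#' exponential), registry-level random intercepts and slopes with an
#' unstructured 2x2 covariance, by maximum likelihood (not REML, so
#' log-likelihoods are comparable across transforms of the abscissa).
#' Data are never pooled: the registry structure is carried by the random
#' effects.  The reported `r_squared` is conditional: the squared
#' correlation between observed and fitted log incidence including the
#' predicted random effects.
#'
#' When the stacked data are an exact fixed-effects fit (zero residual
#' variance), the mixed-model likelihood is unbounded; the fit degenerates
#' to the OLS solution with zero random-effect variances, infinite
#' log-likelihood and `degenerate = TRUE`.  A singular random-effects
#' covariance is flagged the same way, with the estimates retained.
#'
#' @param series A multi-registry [incidence_series] (at least 2
#'   registries, each with at least 3 points).
#' @param scale `"loglog"` or `"semilog"`.
#' @param x_exp Optional fractional exponent overriding `scale` (used by
#'   [hier_fracpoly()]; `0` means `ln(t)`).
#' @return An object of class `"hier_fit"`: `fixed` (b0, b1), `ranef_var`
#'   (variances and covariance of the registry effects), `loglik`,
#'   `r_squared`, `n_points`, `n_registries`, `degenerate`, `scale`, and
#'   the underlying `model` when non-degenerate.
#' @export
fit_hier <- function(series, scale = c("loglog", "semilog"), x_exp = NULL) {
  scale <- match.arg(scale)
  d <- hier_frame(series, scale, x_exp)
  if (nlevels(d$registry) < 2L)
    stop("hierarchical fit needs at least 2 registries")
  if (any(table(d$registry) < 3L))
    stop("each registry needs at least 3 points")
  ols <- stats::lm.fit(cbind(1, d$x), d$y)
  if (sum(ols$residuals^2) < 1e-10 * max(1, sum(d$y^2))) {
    cf <- stats::coef(ols)
    return(structure(list(scale = if (is.null(x_exp)) scale
                          else sprintf("fracpoly x = %.1f", x_exp),
                          fixed = c(b0 = unname(cf[1]), b1 = unname(cf[2])),
                          ranef_var = c(var_intercept = 0, var_slope = 0,
                                        cov = 0),
                          loglik = Inf, r_squared = 1,
                          n_points = nrow(d),
                          n_registries = nlevels(d$registry),
                          degenerate = TRUE, model = NULL),
                     class = "hier_fit"))
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ x + (1 + x | registry), data = d, REML = FALSE,
               control = lme4::lmerControl(
                 optimizer = "bobyqa", calc.derivs = FALSE,
                 check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(cond) { i <- which(cond); if (length(i)) vc$vcov[i[1L]] else 0 }
  reg <- vc$grp == "registry"
  var_u <- pick(reg & vc$var1 == "(Intercept)" & is.na(vc$var2))
  var_v <- pick(reg & vc$var1 == "x" & is.na(vc$var2))
  cov_uv <- pick(reg & vc$var1 == "(Intercept)" & !is.na(vc$var2) &
                   vc$var2 == "x")
  fe <- lme4::fixef(fit)
  structure(list(scale = if (is.null(x_exp)) scale
                 else sprintf("fracpoly x = %.1f", x_exp),
                 fixed = c(b0 = unname(fe[1]), b1 = unname(fe[2])),
                 ranef_var = c(var_intercept = var_u, var_slope = var_v,
                               cov = cov_uv),
                 loglik = as.numeric(stats::logLik(fit)),
                 r_squared = stats::cor(d$y, stats::fitted(fit))^2,
                 n_points = nrow(d),
                 n_registries = nlevels(d$registry),
                 degenerate = lme4::isSingular(fit), model = fit),
            class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf(
    "<hier_fit> %s: b1 = %.4f, R^2 = %.4f, loglik = %.3f (%d points, %d registries)%s\n",
    x$scale, x$fixed["b1"], x$r_squared, x$loglik, x$n_points,
    x$n_registries, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Likelihood-ratio Bayes factor between hierarchical models
#'
#' `BF10 = exp(loglik_semilog - loglik_loglog)`: evidence for the
#' hierarchical exponential model (H1) against the hierarchical power-law
#' model (H0), both fitted by maximum likelihood on the same non-pooled
#' data.  Swapping the arguments returns the exact reciprocal.  If either
#' fit is degenerate the result carries the flag.
#'
#' @param fit_semilog,fit_loglog [fit_hier()] results on the same data.
#' @return A `"bayes_comparison"` with method `"ml_ratio"`.
#' @export
hier_bf <- function(fit_semilog, fit_loglog) {
  stopifnot(inherits(fit_semilog, "hier_fit"),
            inherits(fit_loglog, "hier_fit"))
  if (fit_semilog$n_points != fit_loglog$n_points)
    stop("the two hierarchical fits must use the same data")
  lb <- fit_semilog$loglik - fit_loglog$loglik
  if (is.nan(lb)) lb <- 0  # both degenerate: equal (infinite) likelihoods
  new_bayes_comparison(lb, "ml_ratio", NA_real_, fit_semilog$n_points,
                       overflow = !is.finite(lb),
                       degenerate = fit_semilog$degenerate ||
                         fit_loglog$degenerate)
}

#' Hierarchical fractional-polynomial scan
#'
#' Repeats the fractional-polynomial fit with the mixed-effects model at
#' each exponent of the grid (`t^(x)`, with `t^(0) = ln(t)`), on
#' non-pooled data, and returns the profile and its maximiser.  Exponents
#' whose fit fails are recorded as `NA` and excluded from the argmax with
#' a warning; ties go to the smaller `|x|`.
#'
#' @param series A multi-registry [incidence_series].
#' @param x_grid Exponent grid; default -2 to 2 in steps of 0.1.
#' @return A `"fracpoly_result"` whose `loglik` profile comes from
#'   [fit_hier()].
#' @export
hier_fracpoly <- function(series, x_grid = seq(-2, 2, by = 0.1)) {
  x_grid <- round(x_grid, 10)
  ll <- vapply(x_grid, function(x) {
    tryCatch(fit_hier(series, "loglog", x_exp = x)$loglik,
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(ll))
    warning(sum(is.na(ll)), " exponent(s) failed to converge; ",
            "excluded from the argmax")
  ok <- which(!is.na(ll))
  top <- ok[ll[ok] >= max(ll[ok]) - 1e-12 * max(1, abs(max(ll[ok])))]
  if (length(top) > 1L) top <- top[order(abs(x_grid[top]))]
  structure(list(x_grid = x_grid, loglik = ll, x_opt = x_grid[top[1L]],
                 coefficients = fit_hier(series, "loglog",
                                         x_exp = x_grid[top[1L]])$fixed,
                 n = nrow(series)),
            class = "fracpoly_result")
}

#' Leave-one-out cross-validation of the hierarchical fit
#'
#' Each point is predicted from a mixed-effects model fitted without it;
#' the left-out point's registry random effects are re-estimated from
#' that registry's remaining points.  If a registry falls below 2 points
#' the prediction uses fixed effects only (flagged via a warning).
#' Returns `1 - SSE / SST` on the log-incidence scale, as in [loo_r2()].
#'
#' @param series A multi-registry [incidence_series].
#' @param scale `"loglog"` or `"semilog"`.
#' @return Cross-validated R-squared.
#' @export
hier_loo <- function(series, scale = c("loglog", "semilog")) {
  scale <- match.arg(scale)
  d <- hier_frame(series, scale)
  n <- nrow(d)
  fixed_only <- 0L
  pred <- vapply(seq_len(n), function(i) {
    di <- d[-i, , drop = FALSE]
    sub <- fit_hier_frame(di)
    if (is.null(sub$model)) {  # degenerate: exact OLS
      return(sub$fixed[1] + sub$fixed[2] * d$x[i])
    }
    reg_left <- sum(di$registry == d$registry[i])
    if (reg_left < 2L) {
      fixed_only <<- fixed_only + 1L
      fe <- lme4::fixef(sub$model)
      return(unname(fe[1] + fe[2] * d$x[i]))
    }
    unname(stats::predict(sub$model, newdata = d[i, , drop = FALSE],
                          allow.new.levels = FALSE))
  }, numeric(1))
  if (fixed_only > 0L)
    warning(fixed_only, " point(s) predicted from fixed effects only ",
            "(registry reduced below 2 points)")
  sst <- sum((d$y - mean(d$y))^2)
  if (sst <= 0) return(if (all(abs(pred - d$y) < 1e-6)) 1 else 0)
  1 - sum((d$y - pred)^2) / sst
}

# fit_hier on a prebuilt frame (internal; used by hier_loo refits).
fit_hier_frame <- function(d) {
  ols <- stats::lm.fit(cbind(1, d$x), d$y)
  if (sum(ols$residuals^2) < 1e-10 * max(1, sum(d$y^2))) {
    cf <- stats::coef(ols)
    return(list(fixed = c(unname(cf[1]), unname(cf[2])), model = NULL))
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ x + (1 + x | registry), data = d, REML = FALSE,
               control = lme4::lmerControl(
                 optimizer = "bobyqa", calc.derivs = FALSE,
                 check.conv.singular = "ignore"))))
  list(fixed = unname(lme4::fixef(fit)), model = fit)
}
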