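#' Select the age window where incidence accelerates
#'
#' Both candidate curves (power law with `k > 2`, exponential with
#' `b > 0`) have positive first and second derivatives, so their fitting
#' performance can be compared fairly only over ages where the observed
#' incidence accelerates.  Starting from the youngest bin, the window is
#' extended while the second divided difference of incidence (on the
#' linear scale) versus bin midpoint stays strictly positive; the first
#' violation (including an exactly-zero second difference) terminates it.
#' The reported upper bound is the upper edge of the last included bin.
#'
#' @param series A single-registry (typically pooled) [incidence_series]
#'   with at least 4 bounded bins.
#' @param smooth Apply a 3-point running-median smoother to incidence
#'   before differencing (for noisy single registries); off by default.
#' @return An object of class `"acceleration_window"`: `included` (row
#'   indices of the retained bins), `upper_age_bound`, `rule_trace` (per
#'   interior midpoint: second difference and pass/fail), `degenerate`
#'   (`TRUE` when no strictly positive second difference was found, in
#'   which case only the minimal leading window of 2 bins is returned,
#'   with a warning).
#' @export
acceleration_window <- function(series, smooth = FALSE) {
  stopifnot(inherits(series, "incidence_series"))
  if (n_registries(series) != 1L)
    stop("acceleration window is defined on a single (or pooled) registry")
  if (any(is.na(series$age_mid)))
    stop("open-ended bins present; filter before windowing")
  n <- nrow(series)
  if (n < 4L) stop("need at least 4 bins to assess acceleration")
  t <- series$age_mid
  y <- series$incidence
  if (smooth) y <- stats::runmed(y, 3)
  slope <- diff(y) / diff(t)
  d2 <- diff(slope)  # divided second differences (sign only matters)
  included <- 2L     # bins 1..2 always form the trivial leading window
  trace <- data.frame(midpoint = t[2:(n - 1L)], second_difference = d2,
                      pass = NA)
  for (i in seq_along(d2)) {
    ok <- d2[i] > 0
    trace$pass[i] <- ok
    if (!ok) break
    included <- i + 2L
  }
  degenerate <- included == 2L
  if (degenerate)
    warning("no strictly positive second difference at the youngest bins; ",
            "returning the minimal leading window")
  structure(list(included = seq_len(included),
                 upper_age_bound = series$age_upper[included],
                 rule_trace = trace, degenerate = degenerate),
            class = "acceleration_window")
}

#' @export
print.acceleration_window <- function(x, ...) {
  cat(sprintf("<acceleration_window> %d bin(s) included, upper bound %g y%s\n",
              length(x$included), x$upper_age_bound,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Restrict a series to an age window
#'
#' Keeps records whose bins lie inside `[lower, upper]` (bin lower edge at
#' or above `lower`, bin upper edge at or below `upper`).
#'
#' @param series An [incidence_series].
#' @param lower,upper Window bounds in years; `upper` may come from
#'   [acceleration_window()]'s `upper_age_bound`.
#' @return The windowed [incidence_series].
#' @export
apply_window <- function(series, lower = -Inf, upper = Inf) {
  stopifnot(inherits(series, "incidence_series"))
  keep <- series$age_lower >= lower & !is.na(series$age_upper) &
    series$age_upper <= upper
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(series, "provenance"),
            class = class(series))
}

#' Sensitivity of the scale comparison to the age range
#'
#' Recomputes the R-squared difference (semi-log minus log-log) while
#' progressively decreasing the final age included (respecting the
#' acceleration assumption) or increasing the initial age.  Positive
#' values favour the exponential function.  Windows with fewer than
#' `min_points` records are excluded.
#'
#' @param series An [incidence_series].
#' @param mode `"vary_final_age"` or `"vary_initial_age"`.
#' @param min_points Minimum records per window (default 4).
#' @return A data frame of class `"sensitivity_curve"`: `bound` (the
#'   varied age bound), `delta_r2`, `n`; ordered by `bound`.  Empty, with
#'   a warning, when no admissible window exists.
#' @export
sensitivity_scan <- function(series,
                             mode = c("vary_final_age", "vary_initial_age"),
                             min_points = 4) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "incidence_series"))
  bounds <- if (mode == "vary_final_age")
    sort(unique(series$age_upper[!is.na(series$age_upper)]))
  else sort(unique(series$age_lower))
  rows <- lapply(bounds, function(bnd) {
    win <- if (mode == "vary_final_age")
      apply_window(series, upper = bnd)
    else apply_window(series, lower = bnd)
    if (nrow(win) < min_points) return(NULL)
    data.frame(bound = bnd, delta_r2 = r2_difference(win), n = nrow(win))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    warning("no admissible window with at least ", min_points, " points")
    out <- data.frame(bound = numeric(0), delta_r2 = numeric(0),
                      n = integer(0))
  }
  rownames(out) <- NULL
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (is.null(config$input) && is.null(config$truth))
    add("config must name either 'input' (CSV path) or a 'truth' block")
  if (!is.null(config$input) && !is.null(config$truth))
    add("'input' and 'truth' are mutually exclusive")
  if (!is.null(config$input) && !file.exists(config$input))
    add(sprintf("input file not found: %s", config$input))
  if (!is.null(config$truth)) {
    tr <- config$truth
    if (is.null(tr$family) ||
        !tr$family %in% c("exponential", "power_law", "multistep"))
      add("truth$family must be exponential, power_law or multistep")
    if (is.null(config$seed)) add("a seed is required for synthetic input")
  }
  if (!is.null(config$window) && !identical(config$window, "auto") &&
      !(is.numeric(config$window) && length(config$window) == 2L))
    add("window must be \"auto\" or a numeric c(lower, upper)")
  if (!is.null(config$prior_scales) &&
      (!is.numeric(config$prior_scales) || any(config$prior_scales <= 0)))
    add("prior_scales must be positive numbers")
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed)))
    add("seed must be an integer")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

config_truth <- function(tr) {
  switch(tr$family,
         exponential = exponential_truth(tr$a_e, tr$b),
         power_law = power_law_truth(tr$a_m, tr$k),
         multistep = multistep_truth(tr$step_rates))
}

#' Run the full curve-comparison analysis
#'
#' Orchestrates the whole pipeline on observed or synthetic data:
#' filtering, optional pooling, acceleration-window selection, linear and
#' quadratic fits on both scales, the R-squared difference, the JZS
#' Bayesian comparison with its prior-robustness table, the
#' maximum-likelihood-ratio Bayes factor, the fractional-polynomial scan,
#' hierarchical mixed-effects fits with their Bayes factor (when at least
#' two registries are present), leave-one-out cross-validation, and
#' age-range sensitivity scans.  All Bayes factors are graded.  The
#' report is a nested list, rendered to machine-readable JSON by
#' [report_json()]; with a fixed seed the pipeline is fully deterministic.
#'
#' @param config A named list (or path to a YAML file) with fields:
#'   `input` (CSV path) or `truth` (list with `family` and its parameters:
#'   `a_e`/`b`, `a_m`/`k`, or `step_rates`; plus optional `bin_edges`,
#'   `person_years`, `n_registries`, `heterogeneity`); `pool` (logical,
#'   default `TRUE` when counts allow); `window` (`"auto"` or
#'   `c(lower, upper)`); `prior_scales`; `fracpoly_grid`; `hierarchical`
#'   (logical, default auto); `seed` (required for synthetic input);
#'   filter flags `adult_only`, `drop_zero`, `drop_unbounded`.
#'   Configuration problems are listed exhaustively before any
#'   computation.
#' @return A nested list of class `"incidence_report"`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_config(config)
  grab <- function(name, default) if (is.null(config[[name]])) default
                                  else config[[name]]
  # --- data ---------------------------------------------------------------
  if (!is.null(config$input)) {
    raw <- read_incidence_csv(config$input)
    data_src <- config$input
  } else {
    tr <- config$truth
    design <- reference_design()
    bins <- if (!is.null(tr$bin_edges)) age_bins(tr$bin_edges)
            else design$bins
    py <- grab_field(tr, "person_years", design$person_years)
    nreg <- grab_field(tr, "n_registries", design$n_registries)
    het <- if (!is.null(tr$heterogeneity))
      do.call(heterogeneity_spec, tr$heterogeneity)
    truth <- config_truth(tr)
    raw <- if (tr$family == "multistep" && isTRUE(tr$cohort))
      simulate_multistep_cohort(tr$step_rates,
                                grab_field(tr, "n_subjects", 1e6),
                                bins, seed = config$seed)
    else simulate_registries(truth, bins, py, nreg, het, seed = config$seed)
    data_src <- sprintf("synthetic (%s)", tr$family)
  }
  filtered <- filter_records(raw,
                             adult_only = grab("adult_only", TRUE),
                             drop_zero = grab("drop_zero", TRUE),
                             drop_unbounded = grab("drop_unbounded", TRUE))
  multi <- n_registries(filtered) > 1L
  can_pool <- multi && all(!is.na(filtered$cases)) &&
    all(!is.na(filtered$person_years))
  pool <- grab("pool", can_pool)
  pooled <- if (multi && pool) pool_registries(filtered) else filtered
  # --- acceleration window ------------------------------------------------
  window_cfg <- grab("window", "auto")
  window_series <- if (n_registries(pooled) == 1L) pooled
    else pool_registries(filtered, fallback = "mean")
  if (identical(window_cfg, "auto")) {
    win <- acceleration_window(window_series)
    bounds <- c(-Inf, win$upper_age_bound)
  } else {
    win <- NULL
    bounds <- window_cfg
  }
  analysed <- apply_window(pooled, bounds[1L], bounds[2L])
  # --- fits ---------------------------------------------------------------
  fits <- list(
    loglog_linear = fit_linear(analysed, "loglog", 1),
    loglog_quadratic = fit_linear(analysed, "loglog", 2),
    semilog_linear = fit_linear(analysed, "semilog", 1),
    semilog_quadratic = fit_linear(analysed, "semilog", 2))
  delta_r2 <- fits$semilog_linear$r_squared - fits$loglog_linear$r_squared
  shape <- list(loglog = supralinearity_check(analysed, "loglog"),
                semilog = supralinearity_check(analysed, "semilog"))
  jzs <- compare_exp_vs_power(analysed,
                              prior_scale = grab("prior_scale", 0.354))
  robustness <- prior_robustness(analysed,
                                 scales = grab("prior_scales",
                                               c(0.01, 0.354, 1, 10,
                                                 1000, 1e5)))
  mlbf <- ml_ratio_bf(fits$semilog_linear, fits$loglog_linear)
  fp <- fracpoly_scan(analysed, x_grid = grab("fracpoly_grid",
                                              seq(-2, 2, by = 0.1)))
  loo <- list(loglog = loo_r2(analysed, "loglog"),
              semilog = loo_r2(analysed, "semilog"))
  # --- hierarchical (never pooled) ----------------------------------------
  hier <- NULL
  hier_data <- apply_window(filtered, bounds[1L], bounds[2L])
  if (isTRUE(grab("hierarchical", multi)) && n_registries(hier_data) > 1L &&
      all(table(hier_data$registry) >= 3L)) {
    hs <- fit_hier(hier_data, "semilog")
    hl <- fit_hier(hier_data, "loglog")
    hier <- list(semilog = hs, loglog = hl, bf = hier_bf(hs, hl),
                 fracpoly = hier_fracpoly(hier_data,
                                          grab("fracpoly_grid",
                                               seq(-2, 2, by = 0.1))),
                 loo = list(loglog = hier_loo(hier_data, "loglog"),
                            semilog = hier_loo(hier_data, "semilog")))
  }
  sens <- list(
    vary_final_age = sensitivity_scan(pooled, "vary_final_age"),
    vary_initial_age = sensitivity_scan(pooled, "vary_initial_age"))
  structure(list(
    schema_version = "1.0",
    provenance = list(data = data_src,
                      seed = config$seed,
                      n_raw = nrow(raw), n_filtered = nrow(filtered),
                      pooled = multi && pool,
                      window = list(policy = if (is.null(win)) "explicit"
                                    else "auto",
                                    bounds = bounds,
                                    convention = "bin upper edges",
                                    degenerate = if (!is.null(win))
                                      win$degenerate else NA),
                      n_analysed = nrow(analysed)),
    window = win, fits = fits, delta_r2 = delta_r2, shape = shape,
    jzs = jzs, robustness = robustness, ml_ratio = mlbf,
    fracpoly = fp, loo = loo, hierarchical = hier,
    sensitivity = sens),
    class = "incidence_report")
}

grab_field <- function(lst, name, default)
  if (is.null(lst[[name]])) default else lst[[name]]

#' Render an analysis report as JSON
#'
#' Serialises an [run_full_analysis()] report to JSON with 12 significant
#' digits; model objects are dropped, so the output is stable text: the
#' same configuration and seed yield byte-identical JSON.
#'
#' @param report An `"incidence_report"`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  strip <- function(x) {
    if (inherits(x, "fit_result"))
      return(lapply(unclass(x)[c("scale", "degree", "coefficients",
                                 "r_squared", "rss", "n", "loglik")],
                    strip))
    if (inherits(x, "hier_fit"))
      return(lapply(unclass(x)[c("scale", "fixed", "ranef_var", "loglik",
                                 "r_squared", "n_points", "n_registries",
                                 "degenerate")], strip))
    if (inherits(x, "jzs_bf") || inherits(x, "bayes_comparison") ||
        inherits(x, "fracpoly_result") || inherits(x, "acceleration_window"))
      return(lapply(unclass(x), strip))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, strip))
    if (is.numeric(x)) {
      x[!is.finite(x) & !is.na(x)] <-
        sign(x[!is.finite(x) & !is.na(x)]) * .Machine$double.xmax
      if (!is.null(names(x)) && length(x) > 1) return(as.list(x))
    }
    x
  }
  js <- jsonlite::toJSON(strip(unclass(report)), auto_unbox = TRUE,
                         digits = I(12), na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
print.incidence_report <- function(x, ...) {
  cat("<incidence_report>\n")
  cat(sprintf("  data: %s (%d points analysed, pooled: %s)\n",
              x$provenance$data, x$provenance$n_analysed,
              x$provenance$pooled))
  cat(sprintf("  window: [%g, %g] (%s)\n", x$provenance$window$bounds[1],
              x$provenance$window$bounds[2], x$provenance$window$policy))
  cat(sprintf("  R^2 loglog = %.4f, semilog = %.4f (delta = %+.4f)\n",
              x$fits$loglog_linear$r_squared,
              x$fits$semilog_linear$r_squared, x$delta_r2))
  cat(sprintf("  JZS BF10 = %.4g (%s); ML-ratio BF10 = %.4g (%s)\n",
              x$jzs$bf10, x$jzs$grade, x$ml_ratio$bf10, x$ml_ratio$grade))
  cat(sprintf("  fracpoly x_opt = %.1f\n", x$fracpoly$x_opt))
  if (!is.null(x$hierarchical))
    cat(sprintf("  hierarchical BF10 = %.4g (%s), x_opt = %.1f\n",
                x$hierarchical$bf$bf10, x$hierarchical$bf$grade,
                x$hierarchical$fracpoly$x_opt))
  invisible(x)
}
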