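#' Generating truths for synthetic age-incidence data
#'
#' A `synthetic_truth` declares the mechanism behind simulated incidence:
#' an exponential curve `I(t) = a_e * exp(b * t)`, a power law
#' `I(t) = a_m * t^(k-1)` (the Armitage-Doll signature with `k` steps), or
#' a mechanistic multistep process whose onset age is the sum of `k`
#' independent exponential waiting times, one per step, giving the exact
#' hypoexponential hazard (Erlang when the step rates are equal).
#'
#' @param a_e,a_m Positive multiplicative constants, in incidence units
#'   (per 100,000 person-years).
#' @param b Exponential acceleration rate per year of age (`b > 0` for an
#'   accelerating curve; `b = 0` degenerates to a constant).
#' @param k Integer number of steps, `k >= 2`; the log-log slope is `k - 1`.
#' @param step_rates Vector of `k` positive per-year rates, one per step.
#' @return An object of class `"synthetic_truth"`.
#' @examples
#' exponential_truth(a_e = 0.034, b = 0.117)
#' power_law_truth(a_m = 2e-6, k = 5)
#' multistep_truth(rep(0.011, 6))
#' @name synthetic_truth
NULL

#' @rdname synthetic_truth
#' @export
exponential_truth <- function(a_e, b) {
  stopifnot(is.numeric(a_e), length(a_e) == 1L, a_e > 0,
            is.numeric(b), length(b) == 1L, b >= 0)
  structure(list(family = "exponential", a_e = a_e, b = b),
            class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @export
power_law_truth <- function(a_m, k) {
  stopifnot(is.numeric(a_m), length(a_m) == 1L, a_m > 0,
            is.numeric(k), length(k) == 1L, k >= 2, k == round(k))
  structure(list(family = "power_law", a_m = a_m, k = as.integer(k)),
            class = "synthetic_truth")
}

#' @rdname synthetic_truth
#' @export
multistep_truth <- function(step_rates) {
  stopifnot(is.numeric(step_rates), length(step_rates) >= 2L,
            all(step_rates > 0))
  structure(list(family = "multistep", step_rates = as.numeric(step_rates)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>", x$family, "\n")
  str(unclass(x)[-1], give.attr = FALSE)
  invisible(x)
}

#' Registry-level heterogeneity specification
#'
#' Registry random effects act on the intercept of `ln(incidence)` and on
#' the slope of the truth family's linear scale: `b` for exponential truth
#' and `k - 1` for power-law truth (multistep truth takes the intercept
#' offset only).  Setting both standard deviations to zero makes all
#' registries share the same expected curve.
#'
#' @param intercept_sd Standard deviation of registry log-incidence offsets.
#' @param slope_sd Standard deviation of registry slope offsets.
#' @param correlation Correlation between the two offsets, in `[-1, 1]`.
#' @return An object of class `"heterogeneity_spec"`.
#' @export
heterogeneity_spec <- function(intercept_sd = 0, slope_sd = 0,
                               correlation = 0) {
  stopifnot(intercept_sd >= 0, slope_sd >= 0,
            correlation >= -1, correlation <= 1)
  structure(list(intercept_sd = intercept_sd, slope_sd = slope_sd,
                 correlation = correlation),
            class = "heterogeneity_spec")
}

# Exact hypoexponential hazard (per year).  Equal rates use the Erlang
# closed form through pgamma/dgamma on the log scale; all-distinct rates
# use the partial-fraction expansion; repeated-but-not-all-equal rates fall
# back to the phase-type matrix exponential.
hypoexp_hazard <- function(t, rates) {
  k <- length(rates)
  if (length(unique(rates)) == 1L) {
    lam <- rates[1L]
    lf <- stats::dgamma(t, shape = k, rate = lam, log = TRUE)
    lS <- stats::pgamma(t, shape = k, rate = lam, lower.tail = FALSE,
                        log.p = TRUE)
    return(exp(lf - lS))
  }
  if (length(unique(rates)) == k) {
    w <- vapply(seq_len(k), function(i)
      prod(rates[-i] / (rates[-i] - rates[i])), numeric(1))
    S <- vapply(t, function(tt) sum(w * exp(-rates * tt)), numeric(1))
    f <- vapply(t, function(tt) sum(w * rates * exp(-rates * tt)), numeric(1))
    return(f / S)
  }
  # general phase-type: bidiagonal generator, absorption density over survival
  Tm <- diag(-rates, k)
  if (k > 1L) Tm[cbind(seq_len(k - 1L), seq_len(k - 1L) + 1L)] <-
      rates[-k]
  alpha <- c(1, rep(0, k - 1L))
  vapply(t, function(tt) {
    row1 <- (alpha %*% as.matrix(Matrix::expm(Tm * tt)))[1L, ]
    surv <- sum(row1)
    dens <- row1[k] * rates[k]  # exit rate from the final transient state
    dens / surv
  }, numeric(1))
}

#' Expected incidence under a generating truth
#'
#' Evaluates the noiseless incidence curve, per 100,000 person-years, at
#' ages `t`: `a_e * exp(b t)` for exponential truth, `a_m * t^(k-1)` for
#' power-law truth, and the exact hypoexponential hazard times 100,000 for
#' multistep truth (the hazard of the sum of the step waiting times; under
#' equal rates this is the Erlang hazard).
#'
#' @param truth A [synthetic_truth].
#' @param t Ages in years, all positive.
#' @return Numeric vector of incidence rates per 100,000 person-years.
#' @export
expected_incidence <- function(truth, t) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (any(!is.finite(t) | t <= 0)) stop("ages 't' must be positive")
  switch(truth$family,
         exponential = truth$a_e * exp(truth$b * t),
         power_law = truth$a_m * t^(truth$k - 1L),
         multistep = 1e5 * hypoexp_hazard(t, truth$step_rates))
}

# Draw one (intercept, slope) offset pair from a heterogeneity spec.  A
# zero-sd spec draws nothing, so it is stream-identical to no spec at all.
draw_offsets <- function(h) {
  if (is.null(h) || (h$intercept_sd == 0 && h$slope_sd == 0))
    return(c(0, 0))
  z <- stats::rnorm(2L)
  u <- h$intercept_sd * z[1L]
  v <- h$slope_sd * (h$correlation * z[1L] +
                       sqrt(1 - h$correlation^2) * z[2L])
  c(u, v)
}

# Expected incidence with registry offsets (u on ln scale, v on the slope
# of the truth family's linear scale).
offset_incidence <- function(truth, t, u, v) {
  switch(truth$family,
         exponential = exp(u) * truth$a_e * exp((truth$b + v) * t),
         power_law = exp(u) * truth$a_m * t^(truth$k - 1L + v),
         multistep = exp(u) * 1e5 * hypoexp_hazard(t, truth$step_rates))
}

#' Simulate one registry of age-binned incidence
#'
#' Draws Poisson case counts per bin around the truth's expected curve at
#' the bin midpoint (the rare-disease approximation: prevalence does not
#' deplete the population at risk), after applying registry-level random
#' offsets, and recomputes the incidence rate from the sampled counts.
#'
#' @param truth A [synthetic_truth].
#' @param bins Bounded age bins from [age_bins()].
#' @param person_years Person-years at risk per bin; recycled to the
#'   number of bins.
#' @param heterogeneity Optional [heterogeneity_spec]; `NULL` for none.
#' @param seed Integer seed; the only source of randomness, applied
#'   locally (the caller's random state is untouched).
#' @param registry_id Registry label.
#' @return An [incidence_series] with one row per bin.
#' @export
simulate_registry <- function(truth, bins, person_years,
                              heterogeneity = NULL, seed,
                              registry_id = "R1") {
  stopifnot(inherits(truth, "synthetic_truth"), all(!is.na(bins$upper)),
            all(person_years > 0))
  py <- rep_len(as.numeric(person_years), nrow(bins))
  withr::with_seed(seed, {
    off <- draw_offsets(heterogeneity)
    mu <- offset_incidence(truth, bins$mid, off[1L], off[2L]) / 1e5 * py
    cases <- stats::rpois(nrow(bins), mu)
  })
  incidence_series(registry = registry_id,
                   age_lower = bins$lower, age_upper = bins$upper,
                   incidence = cases / py * 1e5,
                   cases = cases, person_years = py,
                   provenance = sprintf("simulate_registry(%s, seed = %d)",
                                        truth$family, as.integer(seed)))
}

#' Simulate a multi-registry incidence dataset
#'
#' Convenience wrapper around [simulate_registry()]: one registry per
#' label, each with its own random offsets (drawn inside a single seeded
#' stream, so the whole dataset is reproducible from one seed).
#'
#' @inheritParams simulate_registry
#' @param n_registries Number of registries to simulate.
#' @return A multi-registry [incidence_series].
#' @export
simulate_registries <- function(truth, bins, person_years, n_registries,
                                heterogeneity = NULL, seed) {
  stopifnot(n_registries >= 1L)
  py <- rep_len(as.numeric(person_years), nrow(bins))
  out <- withr::with_seed(seed, {
    lapply(seq_len(n_registries), function(i) {
      off <- draw_offsets(heterogeneity)
      mu <- offset_incidence(truth, bins$mid, off[1L], off[2L]) / 1e5 * py
      cases <- stats::rpois(nrow(bins), mu)
      data.frame(registry = sprintf("R%d", i),
                 age_lower = bins$lower, age_upper = bins$upper,
                 incidence = cases / py * 1e5,
                 cases = cases, person_years = py)
    })
  })
  stack <- do.call(rbind, out)
  incidence_series(stack$registry, stack$age_lower, stack$age_upper,
                   stack$incidence, stack$cases, stack$person_years,
                   provenance = sprintf(
                     "simulate_registries(%s, n = %d, seed = %d)",
                     truth$family, n_registries, as.integer(seed)))
}

#' Simulate a multistep cohort mechanistically
#'
#' Generates onset ages as sums of `k` independent exponential waiting
#' times (one per pathogenic step) for a closed cohort followed from
#' birth, and converts them to age-binned incidence: cases are onsets
#' falling in each bin and person-years are the exact time at risk spent
#' in the bin, with subjects leaving the risk set at onset.  Unlike
#' [simulate_registry()], this simulator depletes the at-risk pool, making
#' it the mechanistic check on the rare-disease approximation.
#'
#' @param step_rates Vector of `k >= 1` positive per-year rates.
#' @param n_subjects Cohort size.
#' @param bins Bounded age bins from [age_bins()].
#' @param seed Integer seed (local; caller's random state untouched).
#' @param registry_id Registry label for the output series.
#' @param chunk_size Subjects simulated per block, to bound memory.
#' @return An [incidence_series]; bins in which no person-time was accrued
#'   (everyone already affected) are dropped.
#' @export
simulate_multistep_cohort <- function(step_rates, n_subjects, bins, seed,
                                      registry_id = "cohort",
                                      chunk_size = 1e6) {
  stopifnot(all(step_rates > 0), n_subjects >= 1, all(!is.na(bins$upper)))
  k <- length(step_rates)
  nb <- nrow(bins)
  cases <- numeric(nb)
  py <- numeric(nb)
  withr::with_seed(seed, {
    done <- 0
    while (done < n_subjects) {
      m <- min(chunk_size, n_subjects - done)
      onset <- numeric(m)
      for (j in seq_len(k))
        onset <- onset + stats::rexp(m, rate = step_rates[j])
      for (i in seq_len(nb)) {
        lo <- bins$lower[i]; hi <- bins$upper[i]
        cases[i] <- cases[i] + sum(onset >= lo & onset < hi)
        py[i] <- py[i] + sum(pmax(0, pmin(onset, hi) - lo))
      }
      done <- done + m
    }
  })
  keep <- py > 0  # bins with no person-time at risk carry no information
  incidence_series(registry = registry_id,
                   age_lower = bins$lower[keep], age_upper = bins$upper[keep],
                   incidence = (cases / py * 1e5)[keep],
                   cases = cases[keep], person_years = py[keep],
                   provenance = sprintf(
                     "simulate_multistep_cohort(k = %d, n = %g, seed = %d)",
                     k, n_subjects, as.integer(seed)))
}

#' Canonical multi-registry study design
#'
#' The package's reference design for simulation studies: seven 5-year
#' adult age bins spanning 25-60 years (midpoints 27.5-57.5), five
#' registries, and 2e6 person-years per registry-bin.  With the default
#' exponential truth (`b = 0.117`) the amplitude is calibrated so that the
#' expected total case count is about 6,000 across the five registries,
#' matching the scale of a large multi-registry rare-disease dataset.
#'
#' @param total_cases Expected total case count used to calibrate
#'   amplitudes in [calibrated_truth()].
#' @return A list with `bins`, `person_years`, `n_registries`,
#'   `total_cases`.
#' @export
reference_design <- function(total_cases = 6274) {
  list(bins = age_bins(seq(25, 60, by = 5)),
       person_years = 2e6,
       n_registries = 5L,
       total_cases = total_cases)
}

#' Calibrate a truth's amplitude to a target case count
#'
#' Returns an exponential or power-law truth whose amplitude makes the
#' expected total number of cases under `design` equal `design$total_cases`.
#' Slope parameters (`b`, `k`) are left as given; only the multiplicative
#' constant is solved for, so calibration never changes the curve's shape.
#'
#' @param family `"exponential"` or `"power_law"`.
#' @param b Exponential rate per year (exponential family).
#' @param k Integer number of steps (power-law family).
#' @param design A design list from [reference_design()].
#' @return A [synthetic_truth] with calibrated amplitude.
#' @export
calibrated_truth <- function(family = c("exponential", "power_law"),
                             b = 0.117, k = 5L,
                             design = reference_design()) {
  family <- match.arg(family)
  t <- design$bins$mid
  py <- rep_len(design$person_years, length(t))
  shape <- switch(family, exponential = exp(b * t), power_law = t^(k - 1))
  expected_per_unit <- design$n_registries * sum(shape / 1e5 * py)
  a <- design$total_cases / expected_per_unit
  switch(family,
         exponential = exponential_truth(a_e = a, b = b),
         power_law = power_law_truth(a_m = a, k = k))
}

#' Reference step rates for the multistep simulator
#'
#' Equal per-step rates for a `k`-step process, defaulting to 0.011 per
#' year per step: with `k = 6` this puts the lifetime risk by age 100 at
#' about 1/350 (the Erlang(6) cumulative probability), the scale of a
#' rare adult-onset neurodegenerative disease.  Small per-step rates are
#' what make the power-law approximation of the multistep hazard hold at
#' adult ages; see the package vignette for how quickly it degrades as
#' the rates grow.
#'
#' @param k Number of steps.
#' @param rate Per-step rate per year.
#' @return Numeric vector of length `k`.
#' @export
reference_step_rates <- function(k = 6L, rate = 0.011) rep(rate, k)

#' Write a generator configuration as YAML
#'
#' Records the truth, heterogeneity, design and seed of a simulation in a
#' plain-text YAML file, echoed into output provenance for reproducibility.
#'
#' @param truth A [synthetic_truth].
#' @param design A design list from [reference_design()].
#' @param heterogeneity Optional [heterogeneity_spec].
#' @param seed Integer seed.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(truth, design, heterogeneity = NULL,
                                   seed, path) {
  cfg <- list(truth = unclass(truth),
              design = list(bin_edges = c(design$bins$lower[1],
                                          design$bins$upper),
                            person_years = design$person_years,
                            n_registries = design$n_registries),
              heterogeneity = if (!is.null(heterogeneity))
                unclass(heterogeneity),
              seed = as.integer(seed))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
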