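# Shared fixtures: all built in code, no files.

# Canonical 5-year adult bins, midpoints 27.5 ... 57.5.
ref_bins <- function() age_bins(seq(25, 60, by = 5))

# Noiseless series following an exact curve at the reference midpoints.
noiseless_series <- function(curve = c("exponential", "power_law"),
                             a = 0.034, b = 0.117, k = 5,
                             bins = ref_bins(), registry = "R1") {
  curve <- match.arg(curve)
  inc <- switch(curve,
                exponential = a * exp(b * bins$mid),
                power_law = a * bins$mid^(k - 1))
  incidence_series(registry = registry, age_lower = bins$lower,
                   age_upper = bins$upper, incidence = inc)
}

# Near-noiseless multi-registry fixture: enormous person-years shrink the
# Poisson noise to ~1e-3 relative, keeping mixed models well-defined.
near_noiseless_registries <- function(truth, n_registries = 5, seed = 1,
                                      person_years = 1e10,
                                      bins = ref_bins()) {
  simulate_registries(truth, bins, person_years, n_registries, seed = seed)
}

# Independent Monte-Carlo oracle for the JZS Bayes factor: draw g from its
# inverse-gamma Zellner-Siow mixing density and average the g-prior
# marginal-likelihood ratio directly.  Shares no code with the quadrature.
mc_jzs_bf <- function(n, p, r2, prior_scale, ndraw) {
  g <- 1 / stats::rgamma(ndraw, shape = 0.5, rate = n * prior_scale^2 / 2)
  mean(exp(((n - 1 - p) / 2) * log1p(g) -
             ((n - 1) / 2) * log1p(g * (1 - r2))))
}

# Write a small incidence CSV and return its path.
write_fixture_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "incidence.csv")
  writeLines(lines, path)
  path
}
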