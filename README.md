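# incidencelaw

Does an age-specific incidence curve rise like a **power law** or like an
**exponential**? The question carries mechanistic weight: the Armitage–Doll
multistep model of pathogenesis — disease onset as the completion of *k*
rare, irreversible, sequential stochastic steps, each with an exponential
waiting time — predicts, at ages where cumulative risk is still small,

```
I(t) = a_m * t^(k-1)          ln I = ln a_m + (k-1) ln t     (linear in log-log)
```

while a process of continuous damage accumulation (Gompertz-like, as in
all-cause mortality) gives

```
I(t) = a_e * exp(b t)         ln I = ln a_e + b t            (linear in semi-log)
```

The exponential is, by construction, incompatible with the multistep
model, so deciding between the two functions — which look nearly identical
on a linear plot and both fit real data with R² above 0.9 — is a way to
*falsify* a multistep interpretation of an age-incidence curve.
`incidencelaw` implements that decision as a reusable, tested pipeline
for multi-registry age-binned incidence data (rates per 100,000
person-years), for epidemiologists and modellers who want to run it on
their own registry tables or stress-test it on simulated ones.

## What the package does

- **Data model and rules** — CSV in/out for registry × age-bin records;
  filtering (adults only, non-zero rates, bounded bins); pooling across
  registries by summed cases and person-years.
- **Trend fits** — OLS of ln *I* on ln *t* or *t*, linear and quadratic;
  supra/sub-linearity classification; fractional polynomials
  `ln I = β1 t^(x) + β2` over x ∈ [−2, 2] (x = 0 meaning ln *t*), whose
  optimum discriminates power law (x ≈ 0) from exponential (x ≈ 1);
  leave-one-out cross-validated R².
- **Bayesian comparison** — the encompassing regression
  `ln I = β1 t + β2 ln t + β3 + ε`, comparing the two single-predictor
  sub-models by Jeffreys–Zellner–Siow Bayes factors (Cauchy scale 0.354
  on standardized coefficients, Jeffreys prior on σ²), computed by
  adaptive quadrature over the Zellner–Siow g-mixture; prior-scale
  robustness scans; the maximum-likelihood-ratio approximation
  `((1 − R²_loglog)/(1 − R²_semilog))^(n/2)`; evidence grading
  (anecdotal/moderate/strong/very strong/extreme); posterior credible
  intervals for the slope.
- **Hierarchical models** — mixed-effects fits with registry-level random
  intercepts and slopes (ML, via lme4) on never-pooled data, their
  likelihood-ratio Bayes factor, hierarchical fractional polynomials and
  hierarchical leave-one-out.
- **Diagnostics** — the acceleration window (second-difference rule
  selecting ages where incidence accelerates, the only region where the
  comparison is fair) and age-range sensitivity scans.
- **Synthetic data** — seeded generators for all of the above: Poisson
  registry sampling around exponential/power-law/multistep truths,
  registry heterogeneity, and a mechanistic multistep cohort simulator
  (onset age = sum of exponential waiting times; exact hypoexponential
  hazard available in closed form).

## Worked example

Simulate five registries under an exponential truth with b = 0.117/year,
calibrated to ≈ 6,274 expected cases over seven 5-year adult bins
(25–60 years, 2×10⁶ person-years per registry-bin), then pool and compare:

```r
library(incidencelaw)
truth  <- calibrated_truth("exponential", b = 0.117)
series <- simulate_registries(truth, age_bins(seq(25, 60, 5)), 2e6, 5, seed = 42)
pooled <- pool_registries(series)

fit_linear(pooled, "semilog")
#> <fit_result> semilog degree 1: R^2 = 0.9990, n = 7, loglik = 12.875
#> intercept     slope
#> -3.456855  0.118689

fit_linear(pooled, "loglog")
#> <fit_result> loglog degree 1: R^2 = 0.9852, n = 7, loglik = 3.608
#>  intercept      slope
#> -16.323618   4.814311

compare_exp_vs_power(pooled)
#> <bayes_comparison> BF10 = 1.94e+02, BF01 = 0.00516 [jzs, scale 0.354, n = 7]
#>   extreme evidence, favours exponential (H1)

round(slope_credible_interval(pooled, "semilog"), 4)
#>    lower estimate    upper
#>   0.1131   0.1186   0.1238
```

Both scales fit "well" (R² 0.985 vs 0.999), yet the small gap translates
into a Bayes factor of ~194 for the exponential — the generating model —
and the credible interval for b covers the true 0.117. Note the log-log
fit happily reports a pseudo-slope of 4.8 ("k ≈ 6") even though no
multistep process generated these data. The whole pipeline in one call:

```r
report <- run_full_analysis(list(truth = list(family = "exponential",
                                              a_e = truth$a_e, b = 0.117),
                                 seed = 42))
report
#> <incidence_report>
#>   data: synthetic (exponential) (7 points analysed, pooled: TRUE)
#>   window: [-Inf, 60] (auto)
#>   R^2 loglog = 0.9852, semilog = 0.9990 (delta = +0.0138)
#>   JZS BF10 = 193.7 (extreme); ML-ratio BF10 = 1.057e+04 (extreme)
#>   fracpoly x_opt = 1.1
#>   hierarchical BF10 = 4.84e+05 (extreme), x_opt = 1.1
report_json(report, "report.json")   # machine-readable, deterministic
```

See `vignettes/comparing-age-incidence-laws.Rmd` for the methods, the
modelling assumptions, and the numerical choices.

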