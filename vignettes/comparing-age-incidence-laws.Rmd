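---
title: "Comparing power-law and exponential age-incidence curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing power-law and exponential age-incidence curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incidencelaw)
```

## The inference problem

Many adult-onset diseases show incidence rising steeply with age. Two
families of curves compete to describe that rise, and they carry very
different mechanistic implications.

The **power law** $I(t) = a_m t^{k-1}$ is the signature of the
Armitage–Doll multistep model: pathogenesis as $k$ rare, irreversible,
ordered stochastic changes, each with an exponentially distributed
waiting time. When every per-step rate $\lambda_i$ is small enough that
the cumulative risk at age $t$ is negligible, the hazard of the sum of
waiting times is approximately
$\left(\prod_i \lambda_i\right) t^{k-1}/(k-1)!$, i.e. a straight line of
slope $k-1$ in log-log coordinates.

The **exponential** $I(t) = a_e e^{bt}$ is the Gompertz-like form used
for two centuries to describe age-specific all-cause mortality, and is
generally associated with *continuous* accumulation of damage. It is
incompatible with the multistep model by construction: no choice of
$k$ and step rates produces it.

The two curves are almost indistinguishable on a linear plot and both
achieve high $R^2$ on real data; the discriminating information lives in
*small differences* of fit between the log-log and semi-log scales. A
noiseless exponential evaluated at this package's reference midpoints
(27.5–57.5 years, see below) has log-log $R^2 = 0.989$ — excellent, yet
exactly $0.011$ short of the semi-log fit's $1.000$. The package's job
is to measure such gaps honestly and quantify them as evidence.

Because observing a good power-law fit cannot *prove* a multistep
mechanism (many processes produce power laws), the package's comparison
is framed as potential *falsification*: if an alternative of equal
complexity fits better, the multistep reading loses its only
epidemiological support.

## The comparison pipeline

1. **Filtering.** Only adult bins (lower bound ≥ 18 years), only
   non-zero rates (zeros from finite sampling become $-\infty$ on the
   log scale), only bounded bins (open-ended bins have no midpoint).
   The regression abscissa is the bin midpoint; there is no within-bin
   integration.
2. **Acceleration window.** Both candidate curves have positive first
   and second derivatives ($k > 2$, $b > 0$), so they can be compared
   fairly only where observed incidence accelerates. Starting at the
   youngest adult bin, the window extends while the second divided
   difference of incidence (linear scale) versus midpoint is strictly
   positive; an exactly-zero difference terminates it (the conservative
   choice — it avoids inflating the exponential's advantage, since
   violations of the assumption bias the comparison *toward* the power
   law). The reported bound is the upper edge of the last included bin;
   whether a published bound refers to edges or midpoints is often
   ambiguous, so the convention is recorded in every report.
3. **Fits.** OLS of $\ln I$ on $\ln t$ and on $t$, degree 1 and 2. The
   quadratic coefficient classifies curvature: an exponential is
   supralinear in log-log and linear in semi-log; a power law is linear
   in log-log and sublinear in semi-log.
4. **Bayes factors.** The encompassing regression
   $\ln I = \beta_1 t + \beta_2 \ln t + \beta_3 + \varepsilon$ defines
   H1 ($\beta_2 = 0$, exponential) and H0 ($\beta_1 = 0$, power law).
   Each sub-model is compared to the intercept-only null under the JZS
   prior, and $\mathrm{BF}_{10}$ is the ratio of those two Bayes
   factors (equal prior model odds: the beta-binomial(1,1) model prior
   over two single-predictor models reduces to a no-op).
5. **Ancillary checks.** Prior-scale robustness (0.01 to $10^5$, plus
   the ML-ratio as the flat-prior limit), fractional polynomials,
   hierarchical mixed-effects models on never-pooled data, leave-one-out
   cross-validation, and age-range sensitivity scans.

## The JZS Bayes factor

For a sub-model with $p$ predictors and in-sample $R^2$ on $n$ points,
the Zellner g-prior gives the marginal-likelihood ratio against the
intercept-only null in closed form, and the Zellner–Siow (Cauchy, scale
$r$, default $0.354$) prior on standardized coefficients corresponds to
mixing $g$ over an inverse-gamma$(1/2,\ n r^2/2)$ density:

$$\mathrm{BF} = \int_0^\infty (1+g)^{(n-1-p)/2}
  \bigl(1 + g(1-R^2)\bigr)^{-(n-1)/2} \pi(g)\, dg .$$

The package integrates on $z = \ln g$ with adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-8}$), exponentiating the
log-integrand around its mode so that Bayes factors of order $10^4$ and
beyond remain accurate. Because the integrand depends on the data only
through $n$ and $R^2$, the Bayes factor is invariant to affine
rescaling of the response and positive rescaling of the predictor;
standardization before integration is therefore unnecessary and not
performed. The test suite validates the quadrature against an
independent Monte-Carlo oracle that draws $g$ directly from its mixing
density ($10^7$ draws, 1% tolerance). Exact sub-model fits
($R^2 = 1$) yield an infinite Bayes factor, returned with an overflow
flag rather than an error.

The **ML-ratio approximation**
$\mathrm{BF}_{10} \approx \exp(\ell_{semi} - \ell_{log}) =
\bigl((1-R^2_{log})/(1-R^2_{semi})\bigr)^{n/2}$
is the $r \to \infty$ limit; it overestimates evidence at small $n$ and
is used where a full JZS integral per fit would be wasteful (the
hierarchical comparison). The equality of its two forms holds only
because the Gaussian log-likelihood uses the ML variance estimate
$\mathrm{RSS}/n$ (not $n-p$); both forms are computed and must agree to
$10^{-8}$ relative. Evidence is graded on the standard ladder:
anecdotal ($1<\mathrm{BF}<3$), moderate ($>3$), strong ($>10$), very
strong ($>30$), extreme ($>100$); boundaries take the lower category,
and values below 1 are graded on the reciprocal with the direction
noted.

The **credible interval** for the slope (`slope_credible_interval`)
uses the same prior setup: conditional on $g$ the marginal posterior of
the slope is a shrunk, scaled Student-$t$ with $n-1$ degrees of
freedom; the $g$-mixture is evaluated on an 801-node quadrature grid
spanning ±40 log-units around the posterior mode of $\ln g$, and
quantiles come from root-finding on the mixture CDF. This is the
package's interval for "the data recover $b$": it propagates both
residual-variance and prior-scale-shrinkage uncertainty, which matters
at $n = 7$ where a plain OLS interval is anti-conservative under
heteroskedastic Poisson noise.

## Hierarchical models

With several registries the package fits
$\ln I = \beta_0 + \beta_1 x + (u_{reg} + v_{reg}\, x) + \varepsilon$,
$x = \ln t$ or $t$, with an unstructured 2×2 random-effects covariance
(the model equations impose no independence between intercept and slope
offsets), by **maximum likelihood** — not REML — so that log-likelihoods
are comparable across the two transforms of the abscissa and their
ratio is a meaningful Bayes factor. Estimation is delegated to
`lme4::lmer` (bobyqa optimizer); a singular covariance is reported with
a degeneracy flag rather than an error. When the stacked data admit an
exact fixed-effects fit the mixed likelihood is unbounded; the fit then
degenerates explicitly to the OLS solution with zero variances and
infinite log-likelihood, flagged as such. The hierarchical $R^2$ is a
declared choice: the squared correlation between observed and fitted
log incidence *including* predicted random effects (a conditional,
fit-performance reading). Hierarchical leave-one-out re-estimates the
left-out point's registry effects from that registry's remaining
points, falling back to fixed effects (with a warning) if fewer than
two remain.

## What the generator emulates — and what it does not

`simulate_registries` draws, per registry and bin, Poisson case counts
around the truth's expected curve at the bin midpoint, then recomputes
rates — the rare-disease approximation, in which prevalence does not
deplete the population at risk. Registry heterogeneity acts on the
$\ln I$ intercept and on the slope of the truth's own linear scale
($b$ or $k-1$), with an optional correlation; zero standard deviations
reproduce the homogeneous stream exactly. `simulate_multistep_cohort`
is the mechanistic counterpart: onset ages are sums of $k$ exponential
waiting times, subjects leave the risk set at onset, and bins with no
person-time are dropped. Every simulation takes a single integer seed
and leaves the caller's random state untouched.

The reference design (`reference_design()`) fixes the study
conditions: seven 5-year bins spanning 25–60 years, five registries,
$2 \times 10^6$ person-years per registry-bin, and amplitudes
calibrated (`calibrated_truth()`) so that the expected total is 6,274
cases — the scale of a large pooled multi-registry rare-disease
dataset. The bin grid itself is pinned by an analytic identity: the
log-log $R^2$ of a noiseless exponential depends only on the midpoint
grid (it equals $\mathrm{cor}(t, \ln t)^2$), and midpoints
27.5–57.5 give $0.98878$ and a scale difference of $0.01122$ — the
$0.989/0.011$ calibration the package's acceptance checks assert. The
upper edge of 60 years is also where a typical adult acceleration
window ends.

Not emulated: competing-risk mortality, cohort/period effects,
age-varying person-year pyramids beyond user-supplied per-bin values,
registry quality differences, and the deceleration/peak of incidence at
high ages. Passing tests on these fixtures therefore show that the
*inferential machinery* is correct and well-calibrated under clean
Poisson sampling — not that real registry data, with extraction error
and unmodelled heterogeneity, will produce equally large Bayes factors.

## The multistep simulator's power-law regime, quantified

The default step rates (`reference_step_rates()`: $k = 6$ equal rates
of $0.011$/year) are calibrated so the Erlang(6) lifetime risk by age
100 is about 1/350, a realistic rare-disease figure. This choice makes
the regime question concrete. The Erlang log-hazard at small cumulative
risk is $\mathrm{const} + (k-1)\ln t - \lambda t + \ln S(t)^{-1}$;
projecting the $-\lambda t$ term onto $\ln t$ over midpoints 27–57
shows the fitted log-log slope is approximately
$k - 1 - \lambda\,\mathrm{Cov}(t,\ln t)/\mathrm{Var}(\ln t)
\approx 5 - 41\lambda$. So the textbook slope $k-1$ is reached only as
$\lambda \to 0$ — but the expected number of onsets scales as
$(\lambda t)^k$, so small rates also mean almost no cases. At the
default rate a $10^7$-subject cohort yields ~600 onsets in the adult
window: the noiseless slope is ≈ 4.56, and the estimate from one cohort
is noise-dominated (spread of roughly ±0.3–0.5, with the
fractional-polynomial optimum wandering correspondingly). There is no
equal-rate setting that gives both a slope within a couple of tenths of
$k-1$ and enough cases for a stable fit at this cohort size; the
acceptance run reports whatever the seeded cohort actually produces.
The noiseless hazard itself (via `expected_incidence`) does approach
slope $k-1$ as rates shrink — the approximation, and its breakdown, are
both visible in code.

## Numerical choices and edge cases

- Natural logarithms internally everywhere; base-10 is a display
  concern only and does not affect $R^2$.
- Degenerate (zero-variance) log response: $R^2 := 0$, curvature
  classification skipped.
- Fractional-polynomial grid exponents are rounded to 10 decimals so
  $x = 0$ and $x = 1$ match exactly; likelihood ties break toward the
  smaller $|x|$ with a warning; hierarchical scan exponents that fail
  to converge are recorded as missing and excluded from the argmax.
- Quadratic-term "linearity" threshold: coefficient magnitude below
  $10^{-8}$ or $R^2$ change below $10^{-4}$.
- Pooling requires an identical bin grid and true counts; without
  counts, the person-years-weighted mean (or, behind an explicit
  override, the plain mean) is available and flagged as approximate in
  the provenance.
- Leave-one-out needs each sub-fit determined ($n \ge$ degree + 2);
  with OLS hat values $h_{ii} < 1$ this guarantees
  $\mathrm{LOO}\ R^2 \le$ in-sample $R^2$.
- Reports serialize floats at 12 significant digits and contain no
  timestamps, so identical configurations and seeds give byte-identical
  JSON.

## Problem sizes used in the checks

The packaged checks run at the sizes a laptop handles in about a
minute: the Monte-Carlo JZS oracle uses $10^7$ draws on 20 instances;
coverage of $b$ uses 100 replicates of the reference design;
model-selection direction uses 200 replicates per truth; the multistep
cohort uses $10^7$ subjects; the Erlang onset-distribution check uses a
$10^5$-subject Kolmogorov–Smirnov comparison at $\alpha = 0.01$.

## Known limitations

- The comparison is between two two-parameter curves on log incidence
  with Gaussian error; there is no Poisson-likelihood GLM on counts and
  no weighting by case counts (a deliberate scope choice — the point-
  per-bin regression is the procedure under study).
- Incidence declining at high ages is out of scope; the acceleration
  window excludes, rather than models, that region (beta or
  susceptibility models would be the natural extension).
- The acceleration rule is a hard threshold on noisy second
  differences; for unpooled noisy registries an optional 3-point median
  smoother is available but off by default, and pooling is the
  recommended route to smooth derivatives.
- Bayes factors compare exactly these two models; neither is thereby
  shown to be the true generating process.
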