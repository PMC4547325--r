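---
title: "Estimating rural and urban trends in child growth from survey summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rural and urban trends in child growth from survey summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthrotrend)
```

## The estimation problem

Height-for-age (HAZ) and weight-for-age (WAZ) Z scores express a child's
height or weight relative to a well-nourished reference population of the
same age and sex.  Population means of these scores, and the prevalences of
stunting (HAZ < -2) and underweight (WAZ < -2), are the standard summary
measures of child undernutrition.  National surveys report these quantities
irregularly: a typical country contributes only a handful of surveys over a
quarter century, some cover only part of the country or part of the 0-59
month age range, some report rural and urban children together, and older
surveys were scored against the 1977 NCHS reference rather than the 2006
WHO growth standards.

`anthrotrend` estimates, from such sparse and heterogeneous summary data,
the full time series of the rural and urban Z-score population
distributions for every country in an analysis set — including
country-years with no data at all — together with coherent uncertainty.
Everything downstream (prevalences, credible intervals, posterior
probabilities of direction, regional aggregates, undernourished child
counts, and the decomposition of change into rural, urban, and urbanisation
components) is computed from the posterior draws of those distributions.

## Model

For one metric (HAZ or WAZ; the two are fitted separately), the rural mean
of country $c$ in region $r(c)$ at year $t$ is

$$\mu_{c,t}^{R} = a_0 + a_{r(c)} + a_c + (b_0 + b_{r(c)} + b_c)\,(t - t_0)
  + u_{c,t} + \beta^\top x_{c,t},$$

with $t_0 = 1998$ (the window midpoint), $u_{c,\cdot}$ a per-country
second-order random-walk (RW2) smooth non-linear deviation constrained to
be orthogonal to the constant and linear terms, and $x_{c,t}$ four
standardized covariates (maternal education, log per-person GDP, urban
proportion, and a health-care access index).  The urban mean adds a
country-year offset with its own hierarchy,

$$\mu_{c,t}^{U} = \mu_{c,t}^{R} + (d_0 + d_c) + (g_0 + g_c)(t - t_0),$$

so the urban-rural differential varies by country and drifts linearly over
time.  Intercepts and slopes are nested (global, region, country) normal
random effects; all hierarchical SDs carry half-normal priors and fixed
effects carry vague normal(0, $10^2$) priors.  Whether the urban offset
should also carry its own smooth non-linear term is genuinely open; we
chose intercept-plus-slope because the offset is identified from far fewer
observations than the level.

Each country-year-stratum *population* is a five-component normal mixture
whose shape (weights, mean-offset pattern, SD pattern) is shared globally —
one shape per stratum, each with a free scale parameter — and whose
location is anchored so the mixture mean equals $\mu$ exactly.  The default
shape has total SD 1.13 and skewness $-0.42$, giving the mild left skew
typical of HAZ distributions; scaling offsets and SDs together preserves
the shape while letting the data set the spread.

### Observation model

An observed survey mean $y_i$ contributes a normal likelihood term with
variance
$$v_i = \mathrm{se}_i^2 + \tau_{\mathrm{nat}}^2
  + \mathbb{1}[\text{subnational}]\ \tau_{\mathrm{sub}}^2
  + \mathbb{1}[\text{partial age}]\ \tau_{\mathrm{age}}^2
  + v_i^{\mathrm{conv}},$$
the sum of sampling error, a non-sampling error floor applied to every
source, extra variance for subnational and partial-age-range sources, and
any reference-conversion variance.  The defaults
($\tau_{\mathrm{nat}} = 0.05$, $\tau_{\mathrm{sub}} = 0.10$,
$\tau_{\mathrm{age}} = 0.05$ Z) are on the scale of non-sampling errors
reported in multi-country anthropometry work; they are configuration
constants, not estimated parameters.  A combined-stratum source observes
$(1-p)\mu^{R} + p\mu^{U}$ with $p$ the country-year urban fraction.  An
observed prevalence below $-2$ enters on the probit scale, compared with
the probit of the model's mixture tail mass, with a delta-method binomial
variance plus the non-sampling terms rescaled by the population variance.
Prevalence-only information therefore constrains the mixture scales, while
means constrain locations.

### Reference conversion

Summaries scored against the NCHS 1977 reference are converted to WHO 2006
by deterministic quantile mapping: the stratum population is assumed normal
in NCHS Z space, each quantile is pushed through the measurement scale (cm
or kg) via the NCHS LMS inverse and re-scored with the WHO LMS parameters,
averaging over the source's age range and both sexes equally.  The exact
regression used in earlier published conversions is not public, so the
mapping is our own reproducible stand-in; its added uncertainty is
quantified as the squared discrepancy between mapped moments under the
normal assumption and under a mildly left-skewed two-component mixture with
the same first two moments, and carried into $v_i^{\mathrm{conv}}$.  For
height the LMS transform is affine ($L = 1$), so the conversion variance is
essentially zero; for weight it is positive.  A 400-point quantile grid is
used with shift/ratio calibration against the unmapped grid, which makes
conversion with identical tables exactly the identity.

The packaged reference tables are **synthetic**: smooth LMS curves through
anchor knots calibrated so medians and one-Z measurement equivalents match
the WHO standards' published magnitudes (about 3.2 cm and 4.7 cm of height
and 1.4 kg and 2.6 kg of weight per Z score at ages 2 and 5 years,
sex-averaged).  Real WHO/NCHS tables in the same CSV schema are drop-in
replacements via `read_reference_table()`.

### Sampling

Given the variance components and mixture scales, the latent field (fixed
effects, covariate coefficients, region/country effects, RW2 coefficients)
is jointly Gaussian given the mean-type observations.  The sampler exploits
this: the field is proposed from its exact Gaussian full conditional,
augmented with a local linearization of each prevalence term (solving for
the population mean at which the model tail equals the observed
prevalence), and a Metropolis-Hastings step with the exact mixture-tail
likelihood corrects the linearization error, so the chain targets the exact
posterior.  Hierarchical SDs and the two log mixture scales are updated by
adaptive random-walk Metropolis (adaptation only during burn-in).  The
default control retains 2500 posterior draws after thinning across chains;
convergence is monitored by split-chain scale reduction (threshold 1.05)
and effective sample size, with failures surfaced as warnings and recorded
in the diagnostics, never silently.

### Summaries and decomposition

Credible intervals are percentiles 2.5-97.5 of the retained draws, with
the linear-interpolation percentile convention.  The posterior probability
of direction is the fraction of draws agreeing in sign with the point
estimate (0.5 = direction indeterminate).  Regional and global quantities
are population-weighted averages of country draws, weighted by the
stratum-specific under-5 population — the country urban fraction applied to
the under-5 population, since no child-specific urban fraction is available
in the inputs.  Undernourished counts multiply prevalence draws by stratum
populations draw-wise.

The change in a population mean between a start and end year decomposes
additively into rural change weighted by the start-year rural share, urban
change weighted by the start-year urban share, and urbanisation — the
change in urban proportion times the end-year urban-rural differential.
This weight assignment is the unique one for which the three components sum
to the total exactly, as an algebraic identity.  The decomposition is
applied per posterior draw and shares are averaged across draws (not
computed from averaged inputs): the ratio is non-linear, and per-draw
averaging propagates uncertainty coherently.  Draws whose total change is
numerically negligible (|total| below a tolerance) are excluded from share
averaging and counted in a diagnostic, because share ratios are
ill-conditioned near a zero denominator.

## What the synthetic generator emulates — and what it does not

The generator draws ground truth from exactly the hierarchy the model
assumes, then emits survey records with the study-like composition: a
Poisson number of sources per country (mean 4.8), 84% nationally
representative, a mix of rural/urban/combined reporting, 15%
NCHS-referenced sources (emitted in NCHS Z space via the inverse quantile
mapping), 80% full age coverage, and observation noise matching the
modelled variance.  Countries with zero sources arise naturally and
exercise hierarchical shrinkage.

Because generator and model share the mean structure, recovery tests
validate the *implementation* (likelihood, sampler, shrinkage, coverage
calibration) — they cannot detect misspecification against real data, where
trends need not be RW2-smooth, non-sampling errors need not be normal, and
the mixture shape need not be shared across countries.  The magnitudes of
the non-sampling SDs are likewise chosen for testing power, since no public
values exist.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  simulation = simulation_config(n_regions = 2, countries_per_region = 4),
  mcmc = mcmc_control(chains = 2, iter = 4000, burnin = 1000, draws = 2500),
  out_dir = "run1", seed = 1)
res <- run_pipeline(cfg)
head(res$estimates)
subset(res$decomposition, level == "global")
```

The run directory contains the simulated inputs, `estimates.csv`
(country/region/global means and prevalences with credible intervals),
`decomposition.csv`, `diagnostics.json`, and `manifest.json` (seed and
configuration hash); re-running with the same configuration reproduces the
CSVs byte for byte.

## Numerical choices and limitations

* Problem sizes in the shipped tests are desk-scale (2 regions x 4
  countries x 27 years, a few hundred retained draws per replicate fit,
  20 replicate fits for coverage); the model itself has no scale-specific
  constants.
* Year centering at 1998 and covariate standardization are conditioning
  choices; results are invariant to them up to reparameterization.
* Multi-year surveys must be dated to a midpoint year upstream; the data
  model takes a single integer year per source.
* The RW2 basis absorbs the constant and linear null space, so smooth
  deviations are identified separately from intercepts and slopes.
* Ties at exactly zero in the posterior probability of direction are split
  equally between the two directions.
* Weight-for-height, BMI-for-age, severe (< -3) and overweight (> +2)
  thresholds, and sub-country geography are out of scope.
* Separating urbanisation into migration versus differential natural
  growth is not attempted; the decomposition treats urbanisation as a
  single compositional term.
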