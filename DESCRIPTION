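Package: anthrotrend
Title: Rural and Urban Trends in Child Height-for-Age and Weight-for-Age Z Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of national, regional, and global trends in children's
    height-for-age and weight-for-age Z scores by rural and urban place of
    residence from sparse, heterogeneous survey summary statistics. Implements
    the LMS growth-reference transform (WHO 2006 and NCHS 1977 dialects) with
    conversion of summary statistics between references, a Bayesian
    hierarchical model in which each country-year-stratum Z-score population
    is a five-component normal mixture and trends are a linear term plus a
    smooth non-linear deviation informed by covariates, MCMC fitting with
    convergence diagnostics, posterior summaries (credible intervals,
    stunting/underweight prevalence, posterior probabilities of direction,
    population-weighted regional aggregates, undernourished child counts), an
    additive decomposition of change in mean Z into rural, urban, and
    urbanisation components, and a synthetic multi-country survey generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
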