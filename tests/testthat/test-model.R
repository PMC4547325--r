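# Model module: mean structure, mixtures, observation variances, and the
# data log-likelihood against a brute-force oracle.

test_that("mean_z evaluates the hierarchical mean structure", {
  meta <- make_test_meta()
  st <- make_zero_state()
  spec <- model_spec()
  # all effects zero
  expect_equal(mean_z("AAA", "rural", 2000, st, meta, spec), 0)
  expect_equal(mean_z("AAA", "urban", 1985, st, meta, spec), 0)
  # global slope only: 0.01/yr at center + 10
  st2 <- make_zero_state(b0 = 0.01)
  expect_equal(mean_z("BBB", "rural", 2008, st2, meta, spec), 0.1)
  # rural vs urban difference is exactly the country-year urban offset
  st3 <- make_zero_state(d0 = 0.3, g0 = 0.01,
                         d_country = c(AAA = 0.05, BBB = -0.1))
  for (yy in c(1985, 1998, 2011)) {
    off <- 0.3 + 0.05 + 0.01 * (yy - 1998)
    expect_equal(mean_z("AAA", "urban", yy, st3, meta, spec) -
                   mean_z("AAA", "rural", yy, st3, meta, spec), off)
    # combined = rural + p * offset with p = 0.4
    expect_equal(mean_z("AAA", "combined", yy, st3, meta, spec) -
                   mean_z("AAA", "rural", yy, st3, meta, spec), 0.4 * off)
  }
  expect_error(mean_z("ZZZ", "rural", 2000, st, meta, spec), "unknown country")
  expect_error(mean_z("AAA", "rural", 1950, st, meta, spec), "window")
})

test_that("population mixtures are anchored and match their moments", {
  spec <- model_spec()
  # K = 1: a single normal at mu
  spec1 <- model_spec(K = 1, shape = list(weights = 1, offsets = 0, sds = 1.1))
  mix1 <- population_mixture(-0.7, spec1)
  expect_equal(mix1$means, -0.7)
  # anchoring for arbitrary (unanchored) shapes
  sh <- list(weights = c(0.3, 0.5, 0.2, 0, 0),
             offsets = c(-1, 0.2, 2, 0, 0), sds = c(1, 1, 1, 1, 1))
  mix <- population_mixture(-1.3, spec, sh)
  expect_equal(sum(mix$weights * mix$means), -1.3, tolerance = 1e-12)
  # moments of the default shape match a large sampling oracle
  mix_d <- population_mixture(0, spec)
  mom <- mixture_moments(mix_d)
  set.seed(42)
  comp <- sample(5, 1e6, replace = TRUE, prob = mix_d$weights)
  draws <- rnorm(1e6, mix_d$means[comp], mix_d$sds[comp])
  emp_skew <- mean((draws - mean(draws))^3) / sd(draws)^3
  expect_lt(abs(mom[["skewness"]] - emp_skew), 0.01)
  expect_lt(abs(mom[["sd"]] - sd(draws)), 0.01)
  # invalid weights
  expect_error(population_mixture(0, spec, list(weights = c(0.5, 0.2, 0.1, 0.1, 0.2),
                                                offsets = rep(0, 5),
                                                sds = rep(1, 5))), "sum to 1")
})

test_that("combined-stratum mixture interpolates between the strata", {
  spec <- model_spec()
  r <- population_mixture(-1, spec)
  u <- population_mixture(-0.5, spec)
  expect_equal(combined_stratum_mixture(r, u, 0), r)
  expect_equal(combined_stratum_mixture(r, u, 1), u)
  m <- combined_stratum_mixture(r, u, 0.4)
  expect_length(m$weights, 10)
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  expect_equal(sum(m$weights * m$means), 0.6 * -1 + 0.4 * -0.5,
               tolerance = 1e-12)
})

test_that("observation variance composes additively over inflation terms", {
  spec <- model_spec(tau_national = 0.05, tau_subnational_extra = 0.1,
                     tau_partial_age_extra = 0.04)
  base <- list(se_mean = 0.03, coverage = "national", age_coverage = "full")
  expect_equal(observation_variance(base, spec), 0.03^2 + 0.05^2)
  spec0 <- model_spec(tau_national = 0, tau_subnational_extra = 0,
                      tau_partial_age_extra = 0)
  expect_equal(observation_variance(base, spec0), 0.03^2)
  sub <- base; sub$coverage <- "subnational"
  expect_equal(observation_variance(sub, spec) - observation_variance(base, spec),
               0.1^2)
  part <- base; part$age_coverage <- "partial"
  expect_equal(observation_variance(part, spec) - observation_variance(base, spec),
               0.04^2)
  expect_equal(observation_variance(base, spec, conversion_variance = 0.02) -
                 observation_variance(base, spec), 0.02)
  # monotone: subnational never less than national at equal se
  expect_gte(observation_variance(sub, spec), observation_variance(base, spec))
})

test_that("log-likelihood matches a brute-force recomputation and is additive", {
  meta <- make_test_meta(urban_fraction = 0.35)
  spec <- model_spec()
  st <- make_zero_state(a0 = -1.4, b0 = 0.02, d0 = 0.4,
                        log_scale = c(rural = 0.1, urban = -0.05))
  sources <- as_sources(rbind(
    make_source_row("AAA", 1995, "rural", mean_z = -1.3, prev_below = 0.31),
    make_source_row("BBB", 2005, "urban", coverage = "subnational",
                    age_coverage = "partial", mean_z = -0.8),
    make_source_row("AAA", 2010, "combined", mean_z = -1.0, prev_below = 0.22,
                    n = 1200)))
  sources$conversion_variance <- c(0, 0.003, 0)

  expect_equal(log_likelihood(st, sources[0, ], meta, spec), 0)

  # brute force, written directly from the documented observation model
  brute <- 0
  for (i in 1:3) {
    s <- sources[i, ]
    t <- s$year - 1998
    mu_r <- -1.4 + 0.02 * t
    mu_u <- mu_r + 0.4
    mu <- c(rural = mu_r, urban = mu_u,
            combined = 0.65 * mu_r + 0.35 * mu_u)[[s$stratum]]
    v <- s$se_mean^2 + spec$tau_national^2 + s$conversion_variance +
      (s$coverage == "subnational") * spec$tau_subnational_extra^2 +
      (s$age_coverage == "partial") * spec$tau_partial_age_extra^2
    brute <- brute + dnorm(s$mean_z, mu, sqrt(v), log = TRUE)
    if (!is.na(s$prev_below)) {
      lam <- exp(c(rural = 0.1, urban = -0.05))
      tail_at <- function(m, l)
        sum(spec$shape$weights *
              pnorm((-2 - (m + l * spec$shape$offsets)) / (l * spec$shape$sds)))
      pi_mod <- switch(s$stratum,
                       rural = tail_at(mu_r, lam[["rural"]]),
                       urban = tail_at(mu_u, lam[["urban"]]),
                       combined = 0.65 * tail_at(mu_r, lam[["rural"]]) +
                         0.35 * tail_at(mu_u, lam[["urban"]]))
      p_obs <- min(max(s$prev_below, 1 / (2 * s$n)), 1 - 1 / (2 * s$n))
      Bv <- sum(spec$shape$weights * (spec$shape$sds^2 + spec$shape$offsets^2))
      smv <- switch(s$stratum,
                    rural = lam[["rural"]]^2 * Bv,
                    urban = lam[["urban"]]^2 * Bv,
                    combined = (0.65 * lam[["rural"]]^2 +
                                  0.35 * lam[["urban"]]^2) * Bv)
      tauv <- v - s$se_mean^2
      vz <- p_obs * (1 - p_obs) / (s$n * dnorm(qnorm(p_obs))^2) + tauv / smv
      brute <- brute + dnorm(qnorm(p_obs), qnorm(pi_mod), sqrt(vz), log = TRUE)
    }
  }
  expect_equal(log_likelihood(st, sources, meta, spec), brute,
               tolerance = 1e-10)

  # additive decomposition over sources
  ll_all <- log_likelihood(st, sources, meta, spec)
  ll_12 <- log_likelihood(st, sources[1:2, ], meta, spec)
  ll_3 <- log_likelihood(st, sources[3, ], meta, spec)
  expect_equal(ll_all, ll_12 + ll_3, tolerance = 1e-12)
})

test_that("posterior draws keep mixtures anchored and weights normalized", {
  sf <- shared_small_fit()
  fit <- sf$fit
  spec <- fit$spec
  for (d in c(1, 50, 150)) {
    st <- state_from_draw(fit, d)
    mu <- mean_z("C01", "rural", 1999, st, fit$meta, spec)
    mix <- population_mixture(mu, spec,
                              anthrotrend:::scaled_shape(spec, st$log_scale[["rural"]]))
    expect_equal(sum(mix$weights), 1, tolerance = 1e-12)
    expect_equal(sum(mix$weights * mix$means), mu, tolerance = 1e-12)
    expect_equal(mu, fit$mu[d, "C01", "1999", "rural"], tolerance = 1e-10)
  }
})
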