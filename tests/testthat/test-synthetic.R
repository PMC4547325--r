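# Synthetic-data generator: determinism, degenerate configurations, source
# composition, and the observation-error model.

test_that("truth generation is deterministic and respects degenerate configs", {
  cfg <- simulation_config()
  t1 <- generate_truth(cfg, seed = 3)
  t2 <- generate_truth(cfg, seed = 3)
  expect_identical(t1$table, t2$table)
  expect_identical(t1$meta, t2$meta)

  # all random effects and covariate effects off: the global line exactly
  cfg0 <- simulation_config(region_int_sd = 0, region_slope_sd = 0,
                            country_int_sd = 0, country_slope_sd = 0,
                            smooth_sd = 0, urban_offset_sd = 0,
                            urban_offset_slope_sd = 0,
                            covariate_coefs = c(educ_years = 0, log_gdp = 0,
                                                urban_prop = 0,
                                                health_access = 0))
  tr <- generate_truth(cfg0, seed = 4)
  rural <- tr$table[tr$table$stratum == "rural", ]
  expect_equal(rural$true_mean,
               cfg0$global_intercept +
                 cfg0$global_slope * (rural$year - cfg0$center_year),
               tolerance = 1e-12)

  # urban offset mean 0.5 with zero SDs: urban - rural = 0.5 everywhere
  cfg5 <- simulation_config(urban_offset_mean = 0.5, urban_offset_sd = 0,
                            urban_offset_slope_sd = 0)
  tr5 <- generate_truth(cfg5, seed = 5)
  wide <- merge(tr5$table[tr5$table$stratum == "rural", c("country", "year", "true_mean")],
                tr5$table[tr5$table$stratum == "urban", c("country", "year", "true_mean")],
                by = c("country", "year"), suffixes = c("_r", "_u"))
  expect_equal(wide$true_mean_u - wide$true_mean_r,
               rep(0.5, nrow(wide)), tolerance = 1e-12)

  # truth mixtures are anchored at the true means
  spec <- tr5$spec
  i <- 40
  mix <- population_mixture(tr5$table$true_mean[i], spec)
  expect_equal(sum(mix$weights * mix$means), tr5$table$true_mean[i],
               tolerance = 1e-12)
})

test_that("survey generation is deterministic and matches the configured composition", {
  cfg <- simulation_config(n_regions = 2, countries_per_region = 5)
  truth <- generate_truth(cfg, seed = 6)
  s1 <- generate_surveys(truth, cfg, seed = 7)
  s2 <- generate_surveys(truth, cfg, seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s2))

  # source count over 10 countries at density 4.8: within Poisson 99% bounds
  expect_gte(nrow(s1), qpois(0.005, 10 * 4.8))
  expect_lte(nrow(s1), qpois(0.995, 10 * 4.8))

  # composition over a large generated pool
  cfg_big <- simulation_config(n_regions = 2, countries_per_region = 5,
                               source_density = 1000, frac_nchs = 0)
  truth_big <- generate_truth(cfg_big, seed = 8)
  big <- generate_surveys(truth_big, cfg_big, seed = 9)
  expect_gt(nrow(big), 9000)
  expect_gt(mean(big$coverage == "national"), 0.82)
  expect_lt(mean(big$coverage == "national"), 0.86)
  expect_equal(mean(big$stratum == "combined"), cfg_big$frac_combined,
               tolerance = 0.02)
})

test_that("observed means have the modelled error variance and no-noise limit is exact", {
  # zero-noise limit: observed means equal true means
  cfg0 <- simulation_config(tau_national = 0, tau_subnational_extra = 0,
                            tau_partial_age_extra = 0, n_median = 1e12,
                            frac_nchs = 0, frac_with_prev = 0)
  truth0 <- generate_truth(cfg0, seed = 10)
  s0 <- generate_surveys(truth0, cfg0, seed = 11)
  for (i in seq_len(nrow(s0))) {
    true_m <- anthrotrend:::truth_mean(truth0, s0$country[i], s0$year[i],
                                       s0$stratum[i])
    expect_equal(s0$mean_z[i], true_m, tolerance = 1e-4)
  }

  # standardized residuals have unit SD (pooled over ~1e4 sources)
  cfg <- simulation_config(n_regions = 2, countries_per_region = 5,
                           source_density = 1000, frac_nchs = 0,
                           frac_with_prev = 0)
  truth <- generate_truth(cfg, seed = 12)
  src <- generate_surveys(truth, cfg, seed = 13)
  spec <- truth$spec
  zres <- vapply(seq_len(nrow(src)), function(i) {
    true_m <- anthrotrend:::truth_mean(truth, src$country[i], src$year[i],
                                       src$stratum[i])
    v <- observation_variance(src[i, ], spec, 0)
    (src$mean_z[i] - true_m) / sqrt(v)
  }, numeric(1))
  expect_equal(sd(zres), 1, tolerance = 0.05)
  expect_equal(mean(zres), 0, tolerance = 0.05)

  # combined-stratum sources equal the urban-fraction weighted average of
  # the stratum means in the zero-noise limit
  comb <- which(s0$stratum == "combined")
  for (i in head(comb, 5)) {
    p <- truth0$meta$urban_fraction[truth0$meta$country == s0$country[i] &
                                      truth0$meta$year == s0$year[i]]
    mr <- anthrotrend:::truth_mean(truth0, s0$country[i], s0$year[i], "rural")
    mu <- anthrotrend:::truth_mean(truth0, s0$country[i], s0$year[i], "urban")
    expect_equal(s0$mean_z[i], (1 - p) * mr + p * mu, tolerance = 1e-4)
  }
})

test_that("NCHS-flagged sources survive the round trip through reference conversion", {
  cfg <- simulation_config(frac_nchs = 1, tau_national = 0,
                           tau_subnational_extra = 0,
                           tau_partial_age_extra = 0, n_median = 1e12,
                           frac_with_prev = 0,
                           n_regions = 1, countries_per_region = 3)
  truth <- generate_truth(cfg, seed = 20)
  src <- generate_surveys(truth, cfg, seed = 21)
  expect_true(all(src$reference == "NCHS1977"))
  prepared <- prepare_sources(src)
  expect_true(all(prepared$reference == "WHO2006"))
  for (i in seq_len(nrow(prepared))) {
    true_m <- anthrotrend:::truth_mean(truth, prepared$country[i],
                                       prepared$year[i], prepared$stratum[i])
    # WHO -> NCHS emission then NCHS -> WHO preparation recovers the truth
    # up to quantile-grid error
    expect_equal(prepared$mean_z[i], true_m, tolerance = 0.01)
  }
})

test_that("simulation files are written and reloadable", {
  cfg <- simulation_config(n_regions = 1, countries_per_region = 2)
  truth <- generate_truth(cfg, seed = 30)
  src <- generate_surveys(truth, cfg, seed = 31)
  dir <- withr::local_tempdir()
  paths <- write_simulation(truth, src, dir)
  expect_true(all(file.exists(paths)))
  back <- read_sources(paths[["sources"]])
  expect_equal(nrow(back), nrow(src))
  meta_back <- read_country_meta(paths[["meta"]])
  expect_equal(unique(meta_back$country), unique(truth$meta$country))
})
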