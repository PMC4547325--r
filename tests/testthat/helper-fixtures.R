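# Shared in-code fixtures for the test suite.

test_years <- 1985:2011

# country metadata with constant covariates and configurable urban fractions
make_test_meta <- function(countries = c("AAA", "BBB"),
                           regions = c("SSA", "SSA"),
                           years = test_years,
                           urban_fraction = 0.4,
                           pop_under5 = 1e6) {
  rows <- do.call(rbind, lapply(seq_along(countries), function(i) {
    data.frame(country = countries[i], region = regions[i], year = years,
               pop_under5 = pop_under5, urban_fraction = urban_fraction,
               educ_years = 4 + 0.05 * (years - min(years)),
               log_gdp = 7.5 + 0.01 * (years - min(years)),
               urban_prop = urban_fraction,
               health_access = 0.5, stringsAsFactors = FALSE)
  }))
  as_country_meta(rows, years = years)
}

# model state with every effect zero (optionally overridden)
make_zero_state <- function(countries = c("AAA", "BBB"),
                            regions = c("SSA", "SSA"),
                            years = test_years, ...) {
  region_of <- setNames(regions, countries)
  regs <- unique(regions)
  st <- model_state(
    a0 = 0, b0 = 0, d0 = 0, g0 = 0,
    beta = setNames(numeric(4), c("educ_years", "log_gdp", "urban_prop",
                                  "health_access")),
    a_region = setNames(numeric(length(regs)), regs),
    b_region = setNames(numeric(length(regs)), regs),
    a_country = setNames(numeric(length(countries)), countries),
    b_country = setNames(numeric(length(countries)), countries),
    d_country = setNames(numeric(length(countries)), countries),
    g_country = setNames(numeric(length(countries)), countries),
    u = matrix(0, length(countries), length(years),
               dimnames = list(countries, years)),
    region_of = region_of, center_year = 1998)
  over <- list(...)
  for (nm in names(over)) st[[nm]] <- over[[nm]]
  st
}

make_source_row <- function(country = "AAA", year = 2000, stratum = "rural",
                            coverage = "national", age_coverage = "full",
                            metric = "haz", mean_z = -1.2, sd_z = 1.1,
                            n = 2500, se_mean = sd_z / sqrt(n),
                            prev_below = NA_real_, reference = "WHO2006") {
  data.frame(country = country, year = year, stratum = stratum,
             coverage = coverage, age_coverage = age_coverage,
             metric = metric, mean_z = mean_z, sd_z = sd_z, n = n,
             se_mean = se_mean, prev_below = prev_below,
             reference = reference, stringsAsFactors = FALSE)
}

# one small fit shared across test files (built on first use)
.fit_cache <- new.env(parent = emptyenv())
shared_small_fit <- function() {
  if (!is.null(.fit_cache$fit)) return(.fit_cache)
  cfg <- simulation_config(n_regions = 2, countries_per_region = 2)
  truth <- generate_truth(cfg, seed = 11)
  sources <- generate_surveys(truth, cfg, seed = 12)
  fit <- suppressWarnings(
    fit_hiermix(sources, truth$meta, truth$spec,
                mcmc_control(chains = 2, iter = 700, burnin = 300,
                             draws = 200, seed = 5)))
  .fit_cache$cfg <- cfg
  .fit_cache$truth <- truth
  .fit_cache$sources <- sources
  .fit_cache$fit <- fit
  .fit_cache
}
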