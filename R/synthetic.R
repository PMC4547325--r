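# Synthetic multi-country survey database generator.  Emulates the structure
# of the compiled survey database the estimation pipeline was designed for:
# sparse heterogeneous sources (about 4.8 per country on average, 84%
# national), mixed rural/urban/combined reporting, a fraction of sources
# scored against the older NCHS reference, sampling plus non-sampling error,
# and skewed mixture population distributions.

#' Simulation configuration
#'
#' Defines the ground-truth data-generating process: hierarchy sizes, true
#' hyperparameters of the mean structure, mixture shape and scales,
#' observation-error parameters, and survey-source composition.  The
#' defaults encode the study conditions the generator emulates: 4.8 sources
#' per country on average, 84% nationally representative, years 1985-2011,
#' mildly left-skewed populations, and a positive urban height/weight
#' advantage.
#'
#' @param n_regions number of regions.
#' @param countries_per_region countries per region.
#' @param years analysis window.
#' @param metric \code{"haz"} or \code{"waz"}.
#' @param global_intercept,global_slope global mean-Z level at the centering
#'   year and linear trend per year.
#' @param region_int_sd,region_slope_sd,country_int_sd,country_slope_sd SDs
#'   of region/country random intercepts and slopes.
#' @param smooth_sd SD of the second-order random-walk increments of the
#'   smooth non-linear trend (per year).
#' @param covariate_coefs named true coefficients on standardized covariates.
#' @param urban_offset_mean,urban_offset_sd mean and SD of country urban
#'   offsets (urban minus rural mean Z at the centering year).
#' @param urban_offset_slope_sd SD of country urban-offset linear slopes.
#' @param shape mixture shape pattern (\code{\link{default_mixture_shape}}).
#' @param mixture_scale named \code{c(rural=, urban=)} multipliers of the
#'   shape's spread.
#' @param tau_national,tau_subnational_extra,tau_partial_age_extra
#'   non-sampling error SDs (match \code{\link{model_spec}}).
#' @param source_density mean number of sources per country (Poisson).
#' @param frac_national probability a source is nationally representative.
#' @param frac_combined probability a source reports rural and urban children
#'   together; the remainder splits equally into rural and urban records.
#' @param frac_nchs probability a source is reported against the NCHS 1977
#'   reference.
#' @param frac_full_age probability a source covers the full 0-59 months.
#' @param frac_with_prev probability a source also reports the prevalence
#'   below -2.
#' @param n_median median survey sample size (log-normal).
#' @param center_year trend centering year.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_regions = 2, countries_per_region = 4,
                              years = 1985:2011, metric = "haz",
                              global_intercept = -1.6, global_slope = 0.02,
                              region_int_sd = 0.3, region_slope_sd = 0.008,
                              country_int_sd = 0.35, country_slope_sd = 0.008,
                              smooth_sd = 0.015,
                              covariate_coefs = c(educ_years = 0.05,
                                                  log_gdp = 0.05,
                                                  urban_prop = 0.02,
                                                  health_access = 0.03),
                              urban_offset_mean = 0.4, urban_offset_sd = 0.15,
                              urban_offset_slope_sd = 0.004,
                              shape = default_mixture_shape(),
                              mixture_scale = c(rural = 1, urban = 1),
                              tau_national = 0.05,
                              tau_subnational_extra = 0.10,
                              tau_partial_age_extra = 0.05,
                              source_density = 4.8, frac_national = 0.84,
                              frac_combined = 0.25, frac_nchs = 0.15,
                              frac_full_age = 0.8, frac_with_prev = 0.6,
                              n_median = 3000, center_year = 1998) {
  metric <- match.arg(metric, METRICS)
  sds <- c(region_int_sd, region_slope_sd, country_int_sd, country_slope_sd,
           smooth_sd, urban_offset_sd, urban_offset_slope_sd,
           tau_national, tau_subnational_extra, tau_partial_age_extra)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  fr <- c(frac_national, frac_combined, frac_nchs, frac_full_age,
          frac_with_prev)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(shape$weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1", call. = FALSE)
  structure(as.list(environment()), class = "simulation_config")
}

# region codes R1, R2, ... and country codes C01, C02, ... (ISO3-like slots)
sim_region_codes <- function(n) sprintf("R%d", seq_len(n))
sim_country_codes <- function(n) sprintf("C%02d", seq_len(n))

#' Generate ground truth
#'
#' Draws the true model state (all hierarchical effects, per-country
#' second-order random-walk smooth trends, covariate series, urban offsets)
#' and tabulates the true mean Z and prevalence below -2 for every
#' country-year and stratum.  Deterministic given \code{seed}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param seed integer seed.
#' @return list of class \code{synthetic_truth} with elements \code{state}
#'   (a \code{\link{model_state}}), \code{meta} (an \code{anthro_meta}),
#'   \code{table} (data frame country, year, stratum, true_mean, true_prev),
#'   \code{spec} (the matching \code{\link{model_spec}}), and \code{config}.
#' @export
generate_truth <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  R <- config$n_regions
  C <- R * config$countries_per_region
  if (R > 7)
    stop("at most 7 regions supported by the default region codes", call. = FALSE)
  regions <- default_regions()[seq_len(R)]
  countries <- sim_country_codes(C)
  region_of <- setNames(rep(regions, each = config$countries_per_region),
                        countries)
  years <- config$years
  T <- length(years)
  tc <- years - config$center_year

  # covariate and population series: smooth trends with country-level noise
  meta_rows <- list()
  for (cc in countries) {
    educ0 <- runif(1, 2, 8); educ_sl <- runif(1, 0.02, 0.12)
    gdp0 <- runif(1, 6.5, 9); gdp_sl <- runif(1, 0, 0.04)
    hac0 <- runif(1, 0.3, 0.7); hac_sl <- runif(1, 0, 0.01)
    q0 <- rnorm(1, 0, 0.7); q_sl <- rnorm(1, 0.03, 0.01)
    p_urb <- stats::plogis(q0 + q_sl * tc)
    pop0 <- rlnorm(1, log(2e6), 1)
    pop <- pop0 * exp(0.01 * (tc - min(tc)))
    meta_rows[[cc]] <- data.frame(
      country = cc, region = region_of[[cc]], year = years,
      pop_under5 = pop, urban_fraction = p_urb,
      educ_years = educ0 + educ_sl * (tc - min(tc)),
      log_gdp = gdp0 + gdp_sl * (tc - min(tc)),
      urban_prop = p_urb,
      health_access = pmin(1, hac0 + hac_sl * (tc - min(tc))),
      stringsAsFactors = FALSE)
  }
  meta <- as_country_meta(do.call(rbind, meta_rows),
                          regions = default_regions(), years = years)

  spec <- model_spec(metric = config$metric, shape = config$shape,
                     tau_national = config$tau_national,
                     tau_subnational_extra = config$tau_subnational_extra,
                     tau_partial_age_extra = config$tau_partial_age_extra,
                     center_year = config$center_year)

  # standardization constants from the generated covariates
  xc <- as.matrix(meta[, spec$covariates])
  covar_mean <- colMeans(xc)
  covar_sd <- apply(xc, 2, sd)
  covar_sd[covar_sd == 0] <- 1

  # hierarchical effects
  rw2 <- rw2_basis(T)
  u <- matrix(0, C, T, dimnames = list(countries, years))
  if (config$smooth_sd > 0)
    for (i in seq_len(C))
      u[i, ] <- as.vector(rw2$Z %*% rnorm(T - 2, 0,
                                          config$smooth_sd / sqrt(rw2$lambda)))
  beta <- config$covariate_coefs[spec$covariates]
  beta[is.na(beta)] <- 0
  names(beta) <- spec$covariates
  state <- model_state(
    a0 = config$global_intercept, b0 = config$global_slope,
    d0 = config$urban_offset_mean, g0 = 0,
    beta = beta,
    a_region = setNames(rnorm(R, 0, config$region_int_sd), regions),
    b_region = setNames(rnorm(R, 0, config$region_slope_sd), regions),
    a_country = setNames(rnorm(C, 0, config$country_int_sd), countries),
    b_country = setNames(rnorm(C, 0, config$country_slope_sd), countries),
    d_country = setNames(rnorm(C, 0, config$urban_offset_sd), countries),
    g_country = setNames(rnorm(C, 0, config$urban_offset_slope_sd), countries),
    u = u,
    log_scale = c(rural = log(config$mixture_scale[["rural"]]),
                  urban = log(config$mixture_scale[["urban"]])),
    region_of = region_of, center_year = config$center_year,
    covar_mean = covar_mean, covar_sd = covar_sd)

  tab <- expand.grid(country = countries, year = years,
                     stratum = c("rural", "urban"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$true_mean <- mapply(function(cc, yy, ss)
    mean_z(cc, ss, yy, state, meta, spec),
    tab$country, tab$year, tab$stratum)
  tab$true_prev <- mapply(function(m, ss) {
    mix <- population_mixture(m, spec,
                              scaled_shape(spec, state$log_scale[[ss]]))
    prevalence_below(mix)
  }, tab$true_mean, tab$stratum)

  structure(list(state = state, meta = meta, table = tab, spec = spec,
                 config = config, seed = seed),
            class = "synthetic_truth")
}

truth_mean <- function(truth, country, year, stratum) {
  if (stratum == "combined") {
    p <- truth$meta$urban_fraction[truth$meta$country == country &
                                     truth$meta$year == year]
    r <- truth_mean(truth, country, year, "rural")
    u <- truth_mean(truth, country, year, "urban")
    return((1 - p) * r + p * u)
  }
  tb <- truth$table
  tb$true_mean[tb$country == country & tb$year == year & tb$stratum == stratum]
}

#' Generate a synthetic survey database
#'
#' Draws survey summary records from the ground truth: per country a
#' Poisson(\code{source_density}) number of sources with random year,
#' stratum, coverage, and age-coverage attributes; the observed mean is the
#' true stratum mean (urban-fraction weighted for combined sources) plus
#' normal noise with variance \code{se^2} plus the applicable non-sampling
#' terms; observed prevalence (when reported) is binomial around the true
#' mixture tail probability.  NCHS-flagged sources are emitted in NCHS Z
#' space by quantile-mapping the WHO-space summary through the measurement
#' scale.  Deterministic given \code{seed}.
#'
#' @param truth a \code{\link{generate_truth}} result.
#' @param config the matching \code{\link{simulation_config}}.
#' @param seed integer seed.
#' @param who,nchs reference tables for NCHS-space emission.
#' @return an \code{anthro_sources} data frame.
#' @export
generate_surveys <- function(truth, config = truth$config, seed = 1,
                             who = synthetic_reference_table("WHO2006"),
                             nchs = synthetic_reference_table("NCHS1977")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(seed)
  spec <- truth$spec
  years <- config$years
  base_sd <- sqrt(shape_base_var(spec))
  rows <- list()
  k <- 0L
  for (cc in unique(truth$meta$country)) {
    n_src <- rpois(1, config$source_density)
    if (n_src == 0) next
    for (s in seq_len(n_src)) {
      yy <- sample(years, 1)
      stratum <- if (runif(1) < config$frac_combined) "combined"
        else if (runif(1) < 0.5) "rural" else "urban"
      coverage <- if (runif(1) < config$frac_national) "national" else "subnational"
      age_cov <- if (runif(1) < config$frac_full_age) "full" else "partial"
      n <- max(100, round(rlnorm(1, log(config$n_median), 0.5)))
      p_urb <- truth$meta$urban_fraction[truth$meta$country == cc &
                                           truth$meta$year == yy]
      mu_true <- truth_mean(truth, cc, yy, stratum)
      sd_pop <- switch(stratum,
        rural = exp(truth$state$log_scale[["rural"]]) * base_sd,
        urban = exp(truth$state$log_scale[["urban"]]) * base_sd,
        combined = sqrt(source_mix_var("combined", p_urb, spec,
                                       truth$state$log_scale) +
                          p_urb * (1 - p_urb) *
                          (truth_mean(truth, cc, yy, "urban") -
                             truth_mean(truth, cc, yy, "rural"))^2))
      sd_obs <- sd_pop * exp(rnorm(1, 0, 0.02))
      se <- sd_obs / sqrt(n)
      src_stub <- list(se_mean = se, coverage = coverage,
                       age_coverage = age_cov)
      v <- observation_variance(src_stub, spec, 0)
      y <- mu_true + rnorm(1, 0, sqrt(v))
      prev <- NA_real_
      if (runif(1) < config$frac_with_prev) {
        mu_r <- truth_mean(truth, cc, yy, "rural")
        mu_u <- truth_mean(truth, cc, yy, "urban")
        prev_true <- model_prevalence(stratum, mu_r, mu_u, p_urb, spec,
                                      truth$state$log_scale)
        prev <- rbinom(1, n, prev_true) / n
      }
      reference <- "WHO2006"
      if (runif(1) < config$frac_nchs) {
        rng <- if (age_cov == "full") c(0, 59) else c(6, 35)
        mapped <- map_summary(y, sd_obs, config$metric, rng, who, nchs)
        y <- mapped$mean
        sd_obs <- mapped$sd
        se <- sd_obs / sqrt(n)
        if (!is.na(prev)) prev <- mapped$prev
        reference <- "NCHS1977"
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        country = cc, year = yy, stratum = stratum, coverage = coverage,
        age_coverage = age_cov, metric = config$metric,
        mean_z = y, sd_z = sd_obs, n = n, se_mean = se,
        prev_below = prev, reference = reference, stringsAsFactors = FALSE)
    }
  }
  if (!k)
    return(as_sources(data.frame(country = character(), year = integer(),
                                 stratum = character(), coverage = character(),
                                 age_coverage = character(), metric = character(),
                                 mean_z = numeric(), sd_z = numeric(),
                                 n = numeric(), se_mean = numeric(),
                                 prev_below = numeric(), reference = character()),
                      years = years))
  as_sources(do.call(rbind, rows), years = years)
}

#' Write a simulated dataset to CSV
#'
#' Writes the sources, country metadata, and truth tables of a simulation to
#' an output directory.
#'
#' @param truth a \code{\link{generate_truth}} result.
#' @param sources a \code{\link{generate_surveys}} result.
#' @param dir output directory (created if needed).
#' @return named vector of the three file paths, invisibly.
#' @export
write_simulation <- function(truth, sources, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sources = file.path(dir, "sources.csv"),
             meta = file.path(dir, "country_meta.csv"),
             truth = file.path(dir, "truth.csv"))
  write.csv(as.data.frame(sources), paths[["sources"]], row.names = FALSE)
  write.csv(as.data.frame(truth$meta), paths[["meta"]], row.names = FALSE)
  write.csv(truth$table, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
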