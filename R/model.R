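# Hierarchical mixture model for country-year-stratum Z-score distributions.
#
# Mean structure (single metric, HAZ or WAZ, fitted separately):
#   mu[c,t,rural] = a0 + a_region + a_country
#                   + (b0 + b_region + b_country) * (t - center)
#                   + u[c,t]                       (RW2 smooth, per country)
#                   + beta' x[c,t]                 (standardized covariates)
#   mu[c,t,urban] = mu[c,t,rural] + d[c,t]
#   d[c,t]        = (d0 + d_country) + (g0 + g_country) * (t - center)
#   combined      = (1-p) mu_rural + p mu_urban,  p = urban fraction
#
# Each country-year-stratum population is a K-component normal mixture with a
# globally shared shape (weights, offset pattern, SD pattern), one free scale
# per stratum, anchored so the mixture mean equals mu.

#' Default five-component mixture shape
#'
#' Component weights, mean offsets (anchored to weighted mean zero), and SDs
#' of the mixture representing one population's Z-score distribution around
#' its mean.  The default produces a mildly left-skewed distribution
#' (skewness about -0.4, total SD about 1.13), typical of height-for-age
#' Z-score populations.
#'
#' @return list with numeric vectors \code{weights}, \code{offsets},
#'   \code{sds}, each of length 5.
#' @export
default_mixture_shape <- function() {
  w <- c(0.10, 0.20, 0.30, 0.25, 0.15)
  o <- c(-1.6, -0.7, 0.0, 0.45, 0.9)
  o <- o - sum(w * o)
  list(weights = w, offsets = o, sds = c(1.05, 0.95, 0.85, 0.80, 0.75))
}

#' Model specification
#'
#' Collects every structural and prior constant of the hierarchical model:
#' mixture size and shape pattern, known observation-variance parameters
#' (non-sampling error SDs, on the Z-score scale), prior scales of the
#' hierarchical variance components (half-normal), the fixed-effect prior SD,
#' the trend centering year, and the covariate list.
#'
#' @param metric \code{"haz"} or \code{"waz"}; sources are filtered to this
#'   metric when fitting.
#' @param K number of mixture components (default 5).
#' @param shape mixture shape pattern (see \code{\link{default_mixture_shape}}).
#' @param tau_national non-sampling error SD applied to every source (Z).
#' @param tau_subnational_extra additional error SD for subnational sources.
#' @param tau_partial_age_extra additional error SD for sources not covering
#'   the full 0-59 month age range.
#' @param prior_scales named list of half-normal prior scales for the
#'   hierarchical SDs: \code{region_int, region_slope, country_int,
#'   country_slope, smooth, urban_int, urban_slope}.
#' @param fixed_effect_sd prior SD of global fixed effects and covariate
#'   coefficients.
#' @param log_scale_prior_sd prior SD of the log mixture-scale parameters.
#' @param center_year year at which the linear trend is centered.
#' @param covariates covariate column names in the country metadata.
#' @param rhat_threshold split-chain scale-reduction value above which a
#'   convergence warning is recorded.
#' @return list of class \code{model_spec}.
#' @export
model_spec <- function(metric = "haz", K = 5, shape = default_mixture_shape(),
                       tau_national = 0.05,
                       tau_subnational_extra = 0.10,
                       tau_partial_age_extra = 0.05,
                       prior_scales = list(region_int = 0.5,
                                           region_slope = 0.02,
                                           country_int = 0.5,
                                           country_slope = 0.02,
                                           smooth = 0.05,
                                           urban_int = 0.3,
                                           urban_slope = 0.01),
                       fixed_effect_sd = 10,
                       log_scale_prior_sd = 0.5,
                       center_year = 1998,
                       covariates = c("educ_years", "log_gdp",
                                      "urban_prop", "health_access"),
                       rhat_threshold = 1.05) {
  metric <- match.arg(metric, METRICS)
  stopifnot(K >= 1, length(shape$weights) == K,
            length(shape$offsets) == K, length(shape$sds) == K,
            abs(sum(shape$weights) - 1) < 1e-8, all(shape$sds > 0),
            tau_national >= 0, tau_subnational_extra >= 0,
            tau_partial_age_extra >= 0)
  ps <- unlist(prior_scales)
  if (any(ps <= 0)) stop("prior scales must be positive", call. = FALSE)
  shape$offsets <- shape$offsets - sum(shape$weights * shape$offsets)
  structure(list(metric = metric, K = K, shape = shape,
                 tau_national = tau_national,
                 tau_subnational_extra = tau_subnational_extra,
                 tau_partial_age_extra = tau_partial_age_extra,
                 prior_scales = prior_scales,
                 fixed_effect_sd = fixed_effect_sd,
                 log_scale_prior_sd = log_scale_prior_sd,
                 center_year = center_year, covariates = covariates,
                 rhat_threshold = rhat_threshold),
            class = "model_spec")
}

#' Normal-mixture distribution
#'
#' @param weights component probabilities, summing to 1.
#' @param means component means (Z scores).
#' @param sds component SDs, positive.
#' @return list of class \code{mixture_distribution}.
#' @export
mixture_distribution <- function(weights, means, sds) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1", call. = FALSE)
  if (any(weights < 0)) stop("mixture weights must be nonnegative", call. = FALSE)
  if (any(sds <= 0)) stop("mixture SDs must be positive", call. = FALSE)
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  structure(list(weights = weights, means = means, sds = sds),
            class = "mixture_distribution")
}

#' Moments of a normal mixture
#'
#' Analytic mean, SD, and skewness.
#'
#' @param mix a \code{\link{mixture_distribution}}.
#' @return named numeric vector \code{mean, sd, skewness}.
#' @export
mixture_moments <- function(mix) {
  m <- sum(mix$weights * mix$means)
  ctr <- mix$means - m
  v <- sum(mix$weights * (mix$sds^2 + ctr^2))
  m3 <- sum(mix$weights * (ctr^3 + 3 * ctr * mix$sds^2))
  c(mean = m, sd = sqrt(v), skewness = m3 / v^1.5)
}

#' Population mixture at a given mean
#'
#' Builds the K-component mixture representing one country-year-stratum
#' Z-score population: the shared shape pattern located so that the mixture
#' mean equals \code{mu} exactly (the offsets are re-anchored to weighted
#' mean zero).
#'
#' @param mu the stratum mean Z score.
#' @param spec a \code{\link{model_spec}} (supplies K).
#' @param shape shape parameters: list with \code{weights}, \code{offsets},
#'   \code{sds} of length \code{spec$K}.
#' @return a \code{\link{mixture_distribution}} with mean exactly \code{mu}.
#' @export
population_mixture <- function(mu, spec, shape = spec$shape) {
  if (length(shape$weights) != spec$K)
    stop("shape has ", length(shape$weights), " components, spec$K = ",
         spec$K, call. = FALSE)
  if (abs(sum(shape$weights) - 1) > 1e-8)
    stop("mixture weights must sum to 1", call. = FALSE)
  off <- shape$offsets - sum(shape$weights * shape$offsets)
  mixture_distribution(shape$weights, mu + off, shape$sds)
}

#' Combined-stratum mixture
#'
#' The Z-score population of all children when rural and urban children are
#' reported together: a 2K-component mixture with the rural components
#' weighted by \code{1 - p_urban} and the urban components by \code{p_urban}.
#'
#' @param rural,urban \code{\link{mixture_distribution}}s.
#' @param p_urban urban fraction in [0, 1].
#' @return a \code{\link{mixture_distribution}}.
#' @export
combined_stratum_mixture <- function(rural, urban, p_urban) {
  stopifnot(p_urban >= 0, p_urban <= 1)
  if (p_urban == 0) return(rural)
  if (p_urban == 1) return(urban)
  mixture_distribution(c((1 - p_urban) * rural$weights, p_urban * urban$weights),
                       c(rural$means, urban$means),
                       c(rural$sds, urban$sds))
}

# stratum mixture shape at scale exp(eta): offsets and SDs both scale,
# preserving shape (skewness) while scaling the spread
scaled_shape <- function(spec, eta) {
  list(weights = spec$shape$weights,
       offsets = spec$shape$offsets * exp(eta),
       sds = spec$shape$sds * exp(eta))
}

# total variance of the unit-scale shape
shape_base_var <- function(spec) {
  sum(spec$shape$weights * (spec$shape$sds^2 + spec$shape$offsets^2))
}

#' Observation variance of a survey summary mean
#'
#' Total variance attached to an observed stratum mean Z score:
#' \code{se_mean^2 + tau_national^2}, plus \code{tau_subnational_extra^2} for
#' subnational sources, plus \code{tau_partial_age_extra^2} for sources not
#' covering the full age range, plus any NCHS-to-WHO
#' \code{conversion_variance}.
#'
#' @param source one source record (list or one-row data frame with
#'   \code{se_mean}, \code{coverage}, \code{age_coverage}).
#' @param spec a \code{\link{model_spec}}.
#' @param conversion_variance added variance from reference conversion
#'   (0 for WHO-referenced sources).
#' @return variance on the squared Z-score scale.
#' @export
observation_variance <- function(source, spec, conversion_variance = 0) {
  v <- source$se_mean^2 + spec$tau_national^2 + conversion_variance
  v <- v + ifelse(source$coverage == "subnational",
                  spec$tau_subnational_extra^2, 0)
  v + ifelse(source$age_coverage == "partial",
             spec$tau_partial_age_extra^2, 0)
}

# ---- model state -----------------------------------------------------------

#' Construct a model state
#'
#' A complete set of latent quantities: global fixed effects, region and
#' country random effects, per-country smooth trend values, covariate
#' coefficients (on standardized covariates), urban-offset effects, log
#' mixture scales per stratum, and the covariate standardization constants.
#' Used both for posterior draws and for synthetic ground truth.
#'
#' @param a0,b0 global intercept and slope (per year).
#' @param d0,g0 global urban-offset intercept and slope.
#' @param beta named covariate coefficients (standardized scale).
#' @param a_region,b_region named vectors over regions.
#' @param a_country,b_country,d_country,g_country named vectors over countries.
#' @param u matrix of smooth-trend values, countries x years (dimnames set).
#' @param log_scale named vector \code{c(rural=, urban=)} of log mixture
#'   scales.
#' @param region_of named vector mapping country to region.
#' @param center_year trend centering year.
#' @param covar_mean,covar_sd standardization constants for the covariates.
#' @return list of class \code{model_state}.
#' @export
model_state <- function(a0 = 0, b0 = 0, d0 = 0, g0 = 0, beta = numeric(0),
                        a_region, b_region, a_country, b_country,
                        d_country, g_country, u, log_scale = c(rural = 0, urban = 0),
                        region_of, center_year = 1998,
                        covar_mean = NULL, covar_sd = NULL) {
  structure(list(a0 = a0, b0 = b0, d0 = d0, g0 = g0, beta = beta,
                 a_region = a_region, b_region = b_region,
                 a_country = a_country, b_country = b_country,
                 d_country = d_country, g_country = g_country,
                 u = u, log_scale = log_scale, region_of = region_of,
                 center_year = center_year,
                 covar_mean = covar_mean, covar_sd = covar_sd),
            class = "model_state")
}

covariate_values <- function(meta, country, year, spec, state) {
  row <- meta[meta$country == country & meta$year == year, , drop = FALSE]
  if (!nrow(row)) stop("no metadata for ", country, " ", year, call. = FALSE)
  x <- as.numeric(row[1, spec$covariates])
  if (!is.null(state$covar_mean))
    x <- (x - state$covar_mean) / state$covar_sd
  x
}

#' Model mean Z score for a country-year-stratum
#'
#' Evaluates the hierarchical mean structure at one country, stratum, and
#' year: summed intercepts, summed slopes times centered year, the smooth
#' non-linear deviation, the covariate inner product, and (for urban) the
#' country-year urban offset; \code{"combined"} returns the urban-fraction
#' weighted average of the rural and urban means.
#'
#' @param country country code (must exist in \code{state$region_of}).
#' @param stratum \code{"rural"}, \code{"urban"}, or \code{"combined"}.
#' @param year calendar year (must be a column of \code{state$u}).
#' @param state a \code{\link{model_state}}.
#' @param meta an \code{anthro_meta} table (covariates, urban fraction).
#' @param spec a \code{\link{model_spec}} (covariate list).
#' @return mean Z score (numeric scalar).
#' @export
mean_z <- function(country, stratum, year, state, meta, spec = model_spec()) {
  if (!country %in% names(state$region_of))
    stop("unknown country: ", country, call. = FALSE)
  stratum <- match.arg(stratum, STRATA)
  yr <- as.character(year)
  if (!yr %in% colnames(state$u))
    stop("year ", year, " outside the fitted window", call. = FALSE)
  reg <- state$region_of[[country]]
  t <- year - state$center_year
  covar <- if (length(state$beta))
    sum(state$beta * covariate_values(meta, country, year, spec, state)) else 0
  mu_r <- state$a0 + state$a_region[[reg]] + state$a_country[[country]] +
    (state$b0 + state$b_region[[reg]] + state$b_country[[country]]) * t +
    state$u[country, yr] + covar
  d <- state$d0 + state$d_country[[country]] +
    (state$g0 + state$g_country[[country]]) * t
  switch(stratum,
         rural = mu_r,
         urban = mu_r + d,
         combined = {
           p <- meta$urban_fraction[meta$country == country & meta$year == year]
           if (!length(p)) stop("no metadata for ", country, " ", year, call. = FALSE)
           mu_r + p[1] * d
         })
}

# ---- likelihood ------------------------------------------------------------

clamp_prev <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))

# model prevalence below `thr` for a source, given stratum means and etas
model_prevalence <- function(stratum, mu_r, mu_u, p_urb, spec, log_scale,
                             thr = -2) {
  pr <- function(mu, eta) {
    sh <- scaled_shape(spec, eta)
    sum(sh$weights * pnorm((thr - (mu + sh$offsets)) / sh$sds))
  }
  switch(stratum,
         rural = pr(mu_r, log_scale[["rural"]]),
         urban = pr(mu_u, log_scale[["urban"]]),
         combined = (1 - p_urb) * pr(mu_r, log_scale[["rural"]]) +
           p_urb * pr(mu_u, log_scale[["urban"]]))
}

# probit-scale variance of an observed prevalence: binomial sampling part by
# the delta method, plus non-sampling and conversion variance rescaled from
# the Z-mean scale by the population variance
prev_probit_variance <- function(p_obs, n, tau_var, mix_var) {
  p_obs * (1 - p_obs) / (n * dnorm(qnorm(p_obs))^2) + tau_var / mix_var
}

prev_tau_var <- function(source, spec, conversion_variance = 0) {
  observation_variance(source, spec, conversion_variance) - source$se_mean^2
}

source_mix_var <- function(stratum, p_urb, spec, log_scale) {
  B <- shape_base_var(spec)
  switch(stratum,
         rural = exp(2 * log_scale[["rural"]]) * B,
         urban = exp(2 * log_scale[["urban"]]) * B,
         combined = ((1 - p_urb) * exp(2 * log_scale[["rural"]]) +
                       p_urb * exp(2 * log_scale[["urban"]])) * B)
}

#' Data log-likelihood of a model state
#'
#' Sum over sources of (i) a normal log-density term for the observed mean,
#' with variance \code{\link{observation_variance}}, and (ii) if the source
#' reports a prevalence below -2, a normal log-density term on the probit
#' scale comparing \code{qnorm(observed prevalence)} with
#' \code{qnorm(model mixture tail probability)}, with delta-method variance
#' \code{p(1-p) / (n dnorm(qnorm(p))^2)} plus the source's non-sampling and
#' conversion variance divided by the population variance.  Sources must be
#' WHO-referenced (convert NCHS sources first, see
#' \code{\link{prepare_sources}}); a \code{conversion_variance} column, if
#' present, is carried into both terms.  Priors are not included; an empty
#' source set gives 0.
#'
#' @param state a \code{\link{model_state}}.
#' @param sources an \code{anthro_sources} data frame (single metric,
#'   WHO2006-referenced).
#' @param meta an \code{anthro_meta} table.
#' @param spec a \code{\link{model_spec}}.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, sources, meta, spec) {
  if (!nrow(sources)) return(0)
  if (any(sources$reference != "WHO2006"))
    stop("sources must be converted to WHO2006 first (prepare_sources)",
         call. = FALSE)
  cv <- if ("conversion_variance" %in% names(sources))
    sources$conversion_variance else rep(0, nrow(sources))
  ll <- 0
  for (i in seq_len(nrow(sources))) {
    src <- sources[i, ]
    mu_r <- mean_z(src$country, "rural", src$year, state, meta, spec)
    mu_u <- mean_z(src$country, "urban", src$year, state, meta, spec)
    p_urb <- meta$urban_fraction[meta$country == src$country &
                                   meta$year == src$year][1]
    mu <- switch(src$stratum, rural = mu_r, urban = mu_u,
                 combined = (1 - p_urb) * mu_r + p_urb * mu_u)
    if (!is.finite(mu)) stop("non-finite model mean", call. = FALSE)
    v <- observation_variance(src, spec, cv[i])
    ll <- ll + dnorm(src$mean_z, mu, sqrt(v), log = TRUE)
    if (!is.na(src$prev_below)) {
      p_obs <- clamp_prev(src$prev_below, src$n)
      pi_mod <- model_prevalence(src$stratum, mu_r, mu_u, p_urb, spec,
                                 state$log_scale)
      vz <- prev_probit_variance(p_obs, src$n, prev_tau_var(src, spec, cv[i]),
                                 source_mix_var(src$stratum, p_urb, spec,
                                                state$log_scale))
      ll <- ll + dnorm(qnorm(p_obs), qnorm(pi_mod), sqrt(vz), log = TRUE)
    }
  }
  ll
}

#' Convert NCHS-referenced sources to the WHO 2006 standards
#'
#' Applies \code{\link{convert_summary_nchs_to_who}} to every NCHS-referenced
#' row, using the age range implied by the source's age coverage (0-59 months
#' for \code{"full"}, 6-35 months for \code{"partial"}), and records the
#' conversion variance in a \code{conversion_variance} column (0 for sources
#' already WHO-referenced).
#'
#' @param sources an \code{anthro_sources} data frame.
#' @param who,nchs \code{reference_table}s; default to the packaged synthetic
#'   tables.
#' @return the sources with reference \code{"WHO2006"} everywhere and a
#'   \code{conversion_variance} column.
#' @export
prepare_sources <- function(sources,
                            who = synthetic_reference_table("WHO2006"),
                            nchs = synthetic_reference_table("NCHS1977")) {
  if (!"conversion_variance" %in% names(sources))
    sources$conversion_variance <- 0
  idx <- which(sources$reference == "NCHS1977")
  for (i in idx) {
    src <- sources[i, ]
    rng <- if (src$age_coverage == "full") c(0, 59) else c(6, 35)
    s <- summary_statistic(src$mean_z, src$sd_z, src$prev_below, "NCHS1977")
    conv <- convert_summary_nchs_to_who(s, src$metric, rng, who, nchs)
    sources$mean_z[i] <- conv$summary$mean_z
    sources$sd_z[i] <- conv$summary$sd_z
    sources$prev_below[i] <- conv$summary$prev_below
    sources$reference[i] <- "WHO2006"
    sources$conversion_variance[i] <- conv$conversion_variance
  }
  sources
}
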