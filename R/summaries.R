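# Posterior summarization: credible intervals, mixture tail prevalences,
# posterior probabilities of direction, population-weighted aggregation,
# and undernourished child counts.

#' Summarize a vector of posterior draws
#'
#' Posterior mean with a 2.5-97.5 percentile credible interval, using the
#' linear-interpolation percentile convention (\code{quantile type 7}).
#'
#' @param draws numeric vector of posterior draws (length >= 2, finite).
#' @return named numeric vector \code{mean, lo, hi}.
#' @export
summarize_draws <- function(draws) {
  if (length(draws) < 2) stop("need at least 2 draws", call. = FALSE)
  if (any(!is.finite(draws))) stop("draws must be finite", call. = FALSE)
  ci <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  c(mean = mean(draws), lo = ci[1], hi = ci[2])
}

#' Mixture tail prevalence
#'
#' Probability mass of a normal mixture below a threshold:
#' \code{sum(w_k * pnorm((thr - m_k) / s_k))}.  With the default threshold -2
#' this is the stunting (HAZ) or underweight (WAZ) prevalence.
#'
#' @param mix a \code{\link{mixture_distribution}}.
#' @param threshold Z-score threshold (default -2).
#' @return probability in [0, 1].
#' @export
prevalence_below <- function(mix, threshold = -2) {
  sum(mix$weights * pnorm((threshold - mix$means) / mix$sds))
}

#' Posterior probability of direction
#'
#' The posterior probability that an estimated change is in the direction of
#' its point estimate: \code{max(f, 1 - f)} where \code{f} is the fraction
#' of draws above zero (draws exactly at zero split equally).  0.5 means an
#' increase is statistically indistinguishable from a decrease.
#'
#' @param change_draws numeric vector of posterior draws of a change.
#' @return list of class \code{posterior_probability} with elements
#'   \code{pp} (in [0.5, 1]) and \code{direction} (+1/-1, sign of the
#'   posterior mean).
#' @export
pp_direction <- function(change_draws) {
  if (length(change_draws) < 2) stop("need at least 2 draws", call. = FALSE)
  f <- mean(change_draws > 0) + 0.5 * mean(change_draws == 0)
  structure(list(pp = max(f, 1 - f),
                 direction = if (mean(change_draws) >= 0) 1 else -1),
            class = "posterior_probability")
}

#' Population-weighted aggregation of draw vectors
#'
#' Draw-wise weighted average of member quantities (e.g. country mean-Z or
#' prevalence draws aggregated to a region), with weights normalized to sum
#' to one.
#'
#' @param member_draws list of equal-length numeric draw vectors, or a matrix
#'   with one column per member.
#' @param weights nonnegative weights (e.g. under-5 populations), not all
#'   zero.
#' @return numeric vector of aggregated draws.
#' @export
aggregate_population_weighted <- function(member_draws, weights) {
  if (is.list(member_draws)) {
    len <- vapply(member_draws, length, 0L)
    if (length(unique(len)) != 1)
      stop("member draw vectors must have equal length", call. = FALSE)
    member_draws <- do.call(cbind, member_draws)
  }
  if (ncol(member_draws) != length(weights))
    stop("one weight per member required", call. = FALSE)
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  as.vector(member_draws %*% (weights / sum(weights)))
}

#' Undernourished child counts by stratum
#'
#' Draw-wise counts of children below the -2 threshold: rural count =
#' rural prevalence x rural under-5 population, urban likewise with the
#' urban fraction, total = rural + urban (exactly, per draw).
#'
#' @param prev_rural,prev_urban prevalence draw vectors in [0, 1].
#' @param pop_under5 under-5 population (persons).
#' @param urban_fraction urban share of the under-5 population, in [0, 1].
#' @return data frame with draw-wise columns \code{rural, urban, total}.
#' @export
count_undernourished <- function(prev_rural, prev_urban, pop_under5,
                                 urban_fraction) {
  stopifnot(length(prev_rural) == length(prev_urban),
            all(prev_rural >= 0 & prev_rural <= 1),
            all(prev_urban >= 0 & prev_urban <= 1),
            pop_under5 >= 0, urban_fraction >= 0, urban_fraction <= 1)
  rural <- prev_rural * (1 - urban_fraction) * pop_under5
  urban <- prev_urban * urban_fraction * pop_under5
  data.frame(rural = rural, urban = urban, total = rural + urban)
}

# prevalence draws for one country-year-stratum of a fit:
# vectorized over draws via the K mixture components
prev_draws_for <- function(fit, country, year, stratum) {
  sh <- fit$spec$shape
  yr <- as.character(year)
  lam <- exp(fit$eta[, stratum])
  mu <- fit$mu[, country, yr, stratum]
  out <- 0
  for (k in seq_along(sh$weights))
    out <- out + sh$weights[k] *
      pnorm((-2 - (mu + lam * sh$offsets[k])) / (lam * sh$sds[k]))
  out
}

#' Summarize a fit into an estimates table
#'
#' Produces the estimates CSV rows (see \code{\link{write_estimates}}) at
#' country, region, or global level: posterior mean and 2.5-97.5 percentile
#' intervals of the mean Z score and of the prevalence below -2, by year and
#' stratum.  Regional and global quantities are population-weighted averages
#' of the country draws, weighted by the stratum-specific under-5 population
#' (the country urban fraction applied to the under-5 population).
#'
#' @param fit a \code{hiermix_fit}.
#' @param meta an \code{anthro_meta} table (defaults to the one used to fit).
#' @param level \code{"country"}, \code{"region"}, or \code{"global"}.
#' @param years subset of years to report (default all fitted years).
#' @return data frame with the estimates schema.
#' @export
summarize_fit <- function(fit, meta = fit$meta,
                          level = c("country", "region", "global"),
                          years = fit$years) {
  level <- match.arg(level)
  rows <- list()
  k <- 0L
  for (yr in years) {
    pops <- meta[meta$year == yr, ]
    pops <- pops[match(fit$countries, pops$country), ]
    w_strat <- list(rural = pops$pop_under5 * (1 - pops$urban_fraction),
                    urban = pops$pop_under5 * pops$urban_fraction)
    for (stratum in c("rural", "urban")) {
      mu_mat <- fit$mu[, , as.character(yr), stratum, drop = TRUE]
      if (is.null(dim(mu_mat)))
        mu_mat <- matrix(mu_mat, ncol = length(fit$countries))
      prev_mat <- vapply(fit$countries, function(cc)
        prev_draws_for(fit, cc, yr, stratum), numeric(dim(fit$mu)[1]))
      groups <- switch(level,
        country = setNames(as.list(fit$countries), fit$countries),
        region = split(fit$countries, fit$regions_of[fit$countries]),
        global = list(ALL = fit$countries))
      for (gid in names(groups)) {
        members <- groups[[gid]]
        mi <- match(members, fit$countries)
        w <- w_strat[[stratum]][mi]
        if (length(members) == 1) {
          mu_d <- mu_mat[, mi]
          prev_d <- prev_mat[, mi]
        } else {
          mu_d <- aggregate_population_weighted(mu_mat[, mi, drop = FALSE], w)
          prev_d <- aggregate_population_weighted(prev_mat[, mi, drop = FALSE], w)
        }
        sm <- summarize_draws(mu_d)
        sp <- summarize_draws(prev_d)
        k <- k + 1L
        rows[[k]] <- data.frame(
          level = level, id = gid, year = yr, stratum = stratum,
          metric = fit$spec$metric,
          mean = sm[["mean"]], mean_lo = sm[["lo"]], mean_hi = sm[["hi"]],
          prev = sp[["mean"]], prev_lo = sp[["lo"]], prev_hi = sp[["hi"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' @export
print.posterior_probability <- function(x, ...) {
  cat("PP = ", formatC(x$pp, digits = 2, format = "f"),
      " (direction ", if (x$direction > 0) "increase" else "decrease", ")\n",
      sep = "")
  invisible(x)
}
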