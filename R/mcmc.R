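# MCMC fitting of the hierarchical mixture model.
#
# The latent Gaussian field (fixed effects, covariate coefficients, region
# and country effects, RW2 smooth coefficients) is updated jointly from its
# Gaussian full conditional given the mean-type observations, augmented with
# a linearized (probit) pseudo-observation for each prevalence record; the
# linearization error is corrected by a Metropolis-Hastings step using the
# exact mixture-tail prevalence likelihood, so the sampler targets the exact
# posterior.  Hierarchical SDs and the log mixture scales are updated by
# adaptive random-walk Metropolis.

# second-order random-walk basis: columns of Z span the complement of
# {constant, linear}; coefficient k has prior variance sd^2 / lambda_k, which
# reproduces the RW2 increment density exp(-sum(diff(u,2)^2) / (2 sd^2))
rw2_basis <- function(T) {
  D <- diff(diag(T), differences = 2)
  K <- crossprod(D)
  e <- eigen(K, symmetric = TRUE)
  keep <- seq_len(T - 2)
  list(Z = e$vectors[, keep, drop = FALSE], lambda = e$values[keep])
}

theta_layout <- function(countries, regions, T, n_cov = 4L) {
  C <- length(countries); R <- length(regions)
  idx <- list()
  pos <- 0L
  take <- function(n) { out <- pos + seq_len(n); pos <<- pos + n; out }
  idx$a0 <- take(1); idx$b0 <- take(1); idx$d0 <- take(1); idx$g0 <- take(1)
  idx$beta <- take(n_cov)
  idx$a_region <- setNames(take(R), regions)
  idx$b_region <- setNames(take(R), regions)
  idx$a_country <- setNames(take(C), countries)
  idx$b_country <- setNames(take(C), countries)
  idx$d_country <- setNames(take(C), countries)
  idx$g_country <- setNames(take(C), countries)
  idx$v <- matrix(take(C * (T - 2)), nrow = C, byrow = TRUE,
                  dimnames = list(countries, NULL))
  idx$dim <- pos
  idx
}

# design row for the rural mean and for the urban-offset part; the full row
# for a stratum is rural + w_urban * offset, w_urban in {0, 1, p}
design_rows <- function(country, year, layout, regions_of, years, center_year,
                        Z, xstd) {
  dim <- layout$dim
  t <- year - center_year
  ti <- match(year, years)
  reg <- regions_of[[country]]
  r <- numeric(dim)
  r[layout$a0] <- 1
  r[layout$b0] <- t
  r[layout$beta] <- xstd
  r[layout$a_region[[reg]]] <- 1
  r[layout$b_region[[reg]]] <- t
  r[layout$a_country[[country]]] <- 1
  r[layout$b_country[[country]]] <- t
  r[layout$v[country, ]] <- Z[ti, ]
  off <- numeric(dim)
  off[layout$d0] <- 1
  off[layout$g0] <- t
  off[layout$d_country[[country]]] <- 1
  off[layout$g_country[[country]]] <- t
  list(rural = r, offset = off)
}

# prior variance vector of theta given hierarchical SDs
theta_prior_var <- function(layout, sig, spec, lambda, C) {
  pv <- numeric(layout$dim)
  pv[c(layout$a0, layout$b0, layout$d0, layout$g0, layout$beta)] <-
    spec$fixed_effect_sd^2
  pv[layout$a_region] <- sig[["region_int"]]^2
  pv[layout$b_region] <- sig[["region_slope"]]^2
  pv[layout$a_country] <- sig[["country_int"]]^2
  pv[layout$b_country] <- sig[["country_slope"]]^2
  pv[layout$d_country] <- sig[["urban_int"]]^2
  pv[layout$g_country] <- sig[["urban_slope"]]^2
  pv[as.vector(layout$v)] <- rep(sig[["smooth"]]^2 / lambda, each = C)
  pv
}

#' MCMC settings
#'
#' @param chains number of chains.
#' @param iter iterations per chain (including burn-in).
#' @param burnin burn-in iterations per chain (also the adaptation window).
#' @param draws total posterior draws retained after thinning, across chains
#'   (default 2500).
#' @param seed integer seed; the fit is deterministic given the seed and
#'   settings.
#' @return list of class \code{mcmc_control}.
#' @export
mcmc_control <- function(chains = 2, iter = 4000, burnin = 1000,
                         draws = 2500, seed = 1) {
  per_chain <- draws %/% chains
  thin <- (iter - burnin) %/% per_chain
  if (thin < 1)
    stop("iter - burnin must be at least draws/chains", call. = FALSE)
  structure(list(chains = chains, iter = iter, burnin = burnin,
                 draws = per_chain * chains, per_chain = per_chain,
                 thin = thin, seed = seed),
            class = "mcmc_control")
}

half_normal_lp <- function(s, scale) dnorm(s, 0, scale, log = TRUE)

# log prior density of theta blocks governed by sigma (for sigma updates)
block_lp <- function(theta, layout, sig_name, sig_val, lambda, C) {
  switch(sig_name,
    region_int = sum(dnorm(theta[layout$a_region], 0, sig_val, log = TRUE)),
    region_slope = sum(dnorm(theta[layout$b_region], 0, sig_val, log = TRUE)),
    country_int = sum(dnorm(theta[layout$a_country], 0, sig_val, log = TRUE)),
    country_slope = sum(dnorm(theta[layout$b_country], 0, sig_val, log = TRUE)),
    urban_int = sum(dnorm(theta[layout$d_country], 0, sig_val, log = TRUE)),
    urban_slope = sum(dnorm(theta[layout$g_country], 0, sig_val, log = TRUE)),
    smooth = {
      sds <- rep(sig_val / sqrt(lambda), each = C)
      sum(dnorm(theta[as.vector(layout$v)], 0, sds, log = TRUE))
    })
}

#' Fit the hierarchical mixture model by MCMC
#'
#' Estimates posterior distributions of every country-year-stratum mean Z
#' score (and, through the mixture scales, the full population
#' distributions) from survey summary sources.  NCHS-referenced sources are
#' converted to the WHO 2006 standards first (adding conversion variance).
#' Countries with no data receive estimates through hierarchical shrinkage
#' towards their region and the global trend.
#'
#' @param sources an \code{anthro_sources} data frame; filtered to
#'   \code{spec$metric}.
#' @param meta an \code{anthro_meta} table covering every country to
#'   estimate.
#' @param spec a \code{\link{model_spec}}.
#' @param mcmc an \code{\link{mcmc_control}}.
#' @param who,nchs reference tables used to convert NCHS sources (defaults:
#'   packaged synthetic tables).
#' @param verbose print progress.
#' @return an object of class \code{hiermix_fit} with elements \code{mu}
#'   (array draws x country x year x stratum of posterior mean-Z draws),
#'   \code{theta}, \code{sigma}, \code{eta} (draw matrices), \code{chain}
#'   (chain index per draw), \code{diagnostics} (split-chain scale reduction
#'   and effective sample sizes of monitored quantities, plus any
#'   convergence warnings), and the spec/meta/layout needed by downstream
#'   summaries.
#' @export
fit_hiermix <- function(sources, meta, spec = model_spec(),
                        mcmc = mcmc_control(),
                        who = synthetic_reference_table("WHO2006"),
                        nchs = synthetic_reference_table("NCHS1977"),
                        verbose = FALSE) {
  sources <- sources[sources$metric == spec$metric, , drop = FALSE]
  if (!nrow(sources)) stop("no sources for metric ", spec$metric, call. = FALSE)
  sources <- prepare_sources(sources, who, nchs)
  unknown <- setdiff(sources$country, meta$country)
  if (length(unknown))
    stop("sources reference countries missing from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  years <- attr(meta, "years")
  if (is.null(years)) years <- sort(unique(meta$year))
  T <- length(years)
  countries <- sort(unique(meta$country))
  regions_of <- setNames(meta$region[match(countries, meta$country)], countries)
  regions <- sort(unique(regions_of))
  C <- length(countries); R <- length(regions)

  layout <- theta_layout(countries, regions, T,
                         n_cov = length(spec$covariates))
  rw2 <- rw2_basis(T)

  # covariate standardization over country-years
  xc <- as.matrix(meta[, spec$covariates])
  covar_mean <- colMeans(xc)
  covar_sd <- apply(xc, 2, sd)
  covar_sd[covar_sd == 0] <- 1
  xs_lookup <- scale(xc, covar_mean, covar_sd)
  meta_key <- paste(meta$country, meta$year)

  xstd_at <- function(country, year)
    xs_lookup[match(paste(country, year), meta_key), ]
  p_at <- function(country, year)
    meta$urban_fraction[match(paste(country, year), meta_key)]

  n <- nrow(sources)
  X <- matrix(0, n, layout$dim)
  y <- sources$mean_z
  v_obs <- numeric(n)
  # prevalence records
  has_prev <- !is.na(sources$prev_below)
  Pr <- Pu <- matrix(0, sum(has_prev), layout$dim)
  prev_meta <- vector("list", sum(has_prev))
  jp <- 0L
  for (i in seq_len(n)) {
    src <- sources[i, ]
    dr <- design_rows(src$country, src$year, layout, regions_of, years,
                      spec$center_year, rw2$Z, xstd_at(src$country, src$year))
    p_urb <- p_at(src$country, src$year)
    w_u <- switch(src$stratum, rural = 0, urban = 1, combined = p_urb)
    X[i, ] <- dr$rural + w_u * dr$offset
    v_obs[i] <- observation_variance(src, spec, src$conversion_variance)
    if (has_prev[i]) {
      jp <- jp + 1L
      Pr[jp, ] <- dr$rural
      Pu[jp, ] <- dr$rural + dr$offset
      p_obs <- clamp_prev(src$prev_below, src$n)
      prev_meta[[jp]] <- list(
        stratum = src$stratum, p_urb = p_urb, n = src$n, p_obs = p_obs,
        z_obs = qnorm(p_obs),
        tau_var = prev_tau_var(src, spec, src$conversion_variance))
    }
  }
  n_prev <- jp

  # exact prevalence log-likelihood for all prevalence records (vectorized
  # over sources; tail weights wr/wu are 1/0, 0/1, or (1-p)/p for combined)
  pv <- if (n_prev) {
    data.frame(
      wr = vapply(prev_meta, function(pm)
        switch(pm$stratum, rural = 1, urban = 0, combined = 1 - pm$p_urb), 0),
      wu = vapply(prev_meta, function(pm)
        switch(pm$stratum, rural = 0, urban = 1, combined = pm$p_urb), 0),
      z_obs = vapply(prev_meta, `[[`, 0, "z_obs"),
      p_obs = vapply(prev_meta, `[[`, 0, "p_obs"),
      n = vapply(prev_meta, `[[`, 0, "n"),
      tau_var = vapply(prev_meta, `[[`, 0, "tau_var"))
  } else NULL
  B <- shape_base_var(spec)
  sh <- spec$shape
  mix_tail <- function(mu, lam) {
    out <- 0
    for (k in seq_along(sh$weights))
      out <- out + sh$weights[k] *
        pnorm((-2 - (mu + lam * sh$offsets[k])) / (lam * sh$sds[k]))
    out
  }
  prev_ll <- function(theta, eta) {
    if (!n_prev) return(0)
    mu_r <- as.vector(Pr %*% theta)
    mu_u <- as.vector(Pu %*% theta)
    lr <- exp(eta[["rural"]]); lu <- exp(eta[["urban"]])
    pi_mod <- pv$wr * mix_tail(mu_r, lr) + pv$wu * mix_tail(mu_u, lu)
    pi_mod <- pmin(pmax(pi_mod, 1e-12), 1 - 1e-12)
    smv <- (pv$wr * lr^2 + pv$wu * lu^2) * B
    vz <- pv$p_obs * (1 - pv$p_obs) / (pv$n * dnorm(pv$z_obs)^2) +
      pv$tau_var / smv
    sum(dnorm(pv$z_obs, qnorm(pi_mod), sqrt(vz), log = TRUE))
  }

  # linearized pseudo-observations for the Gaussian proposal: solve for the
  # population mean m0 at which the model's probit tail equals the observed
  # probit prevalence, and use the local slope for the pseudo-variance; the
  # exact mixture-tail likelihood corrects the (small) linearization error
  pseudo_obs <- function(eta) {
    if (!n_prev) return(list(y = numeric(0), v = numeric(0),
                             X = matrix(0, 0, layout$dim)))
    lr <- exp(eta[["rural"]]); lu <- exp(eta[["urban"]])
    gvec <- function(m) {
      pi_m <- pv$wr * mix_tail(m, lr) + pv$wu * mix_tail(m, lu)
      qnorm(pmin(pmax(pi_m, 1e-12), 1 - 1e-12))
    }
    smv <- (pv$wr * lr^2 + pv$wu * lu^2) * B
    # Newton solve g(m0) = z_obs for all records at once (g is close to
    # affine in m, so a few damped steps suffice)
    m0 <- -2 - pv$z_obs * sqrt(smv)
    slope <- rep(-1, n_prev)
    for (step in 1:30) {
      gm <- gvec(m0)
      slope <- pmin((gvec(m0 + 1e-4) - gm) / 1e-4, -1e-3)  # g is decreasing
      resid <- gm - pv$z_obs
      if (max(abs(resid)) < 1e-8) break
      m0 <- m0 - pmax(pmin(resid / slope, 1), -1)
    }
    vz <- pv$p_obs * (1 - pv$p_obs) / (pv$n * dnorm(pv$z_obs)^2) +
      pv$tau_var / smv
    ylin <- m0
    vlin <- vz / slope^2
    Xlin <- pv$wr * Pr + pv$wu * Pu
    list(y = ylin, v = vlin, X = Xlin,
         Q = crossprod(Xlin / sqrt(vlin)),
         b = as.vector(crossprod(Xlin, ylin / vlin)))
  }

  pseudo_ll <- function(theta, po) {
    if (!n_prev) return(0)
    sum(dnorm(po$y, as.vector(po$X %*% theta), sqrt(po$v), log = TRUE))
  }

  # constant (mean-observation) part of the normal equations
  Q_mean <- crossprod(X / sqrt(v_obs))
  b_mean <- as.vector(crossprod(X, y / v_obs))

  # Gaussian full conditional of theta given mean obs + pseudo obs
  draw_theta <- function(sig, po) {
    Q <- Q_mean
    b <- b_mean
    if (n_prev) {
      Q <- Q + po$Q
      b <- b + po$b
    }
    diag(Q) <- diag(Q) + 1 / theta_prior_var(layout, sig, spec, rw2$lambda, C)
    Rch <- chol(Q)
    m <- backsolve(Rch, forwardsolve(t(Rch), b))
    list(theta = m + backsolve(Rch, rnorm(layout$dim)), mean = m)
  }

  sig_names <- names(spec$prior_scales)
  sig_scales <- unlist(spec$prior_scales)
  monitored <- c(paste0("sigma_", sig_names), "eta_rural", "eta_urban",
                 "a0", "b0", "d0", "g0")

  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, mcmc$chains)

  keep_theta <- matrix(NA_real_, mcmc$draws, layout$dim)
  keep_sigma <- matrix(NA_real_, mcmc$draws, length(sig_names),
                       dimnames = list(NULL, sig_names))
  keep_eta <- matrix(NA_real_, mcmc$draws, 2,
                     dimnames = list(NULL, c("rural", "urban")))
  keep_chain <- integer(mcmc$draws)
  mon_draws <- matrix(NA_real_, mcmc$draws, length(monitored),
                      dimnames = list(NULL, monitored))
  accept <- c(theta = 0, theta_n = 0)

  row0 <- 0L
  for (ch in seq_len(mcmc$chains)) {
    set.seed(chain_seeds[ch])
    sig <- setNames(sig_scales * runif(length(sig_scales), 0.4, 1.2), sig_names)
    eta <- c(rural = rnorm(1, 0, 0.1), urban = rnorm(1, 0, 0.1))
    po <- pseudo_obs(eta)
    theta <- draw_theta(sig, po)$theta
    pll <- prev_ll(theta, eta)
    sll <- pseudo_ll(theta, po)
    step_sig <- setNames(rep(0.3, length(sig_names)), sig_names)
    step_eta <- c(rural = 0.2, urban = 0.2)
    acc_sig <- acc_eta <- step_sig * 0
    acc_eta <- c(rural = 0, urban = 0)
    keep_at <- mcmc$burnin + seq_len(mcmc$per_chain) * mcmc$thin
    ki <- 0L
    for (it in seq_len(mcmc$iter)) {
      # theta block: Gaussian proposal + MH correction for the exact
      # prevalence likelihood vs its linearization
      prop <- draw_theta(sig, po)$theta
      pll_p <- prev_ll(prop, eta)
      sll_p <- pseudo_ll(prop, po)
      accept[["theta_n"]] <- accept[["theta_n"]] + 1
      if (log(runif(1)) < (pll_p - sll_p) - (pll - sll)) {
        theta <- prop; pll <- pll_p; sll <- sll_p
        accept[["theta"]] <- accept[["theta"]] + 1
      }
      # hierarchical SDs
      for (sn in sig_names) {
        cur <- sig[[sn]]
        lp_cur <- block_lp(theta, layout, sn, cur, rw2$lambda, C) +
          half_normal_lp(cur, spec$prior_scales[[sn]]) + log(cur)
        prop_s <- cur * exp(rnorm(1, 0, step_sig[[sn]]))
        lp_prop <- block_lp(theta, layout, sn, prop_s, rw2$lambda, C) +
          half_normal_lp(prop_s, spec$prior_scales[[sn]]) + log(prop_s)
        if (log(runif(1)) < lp_prop - lp_cur) {
          sig[[sn]] <- prop_s
          acc_sig[[sn]] <- acc_sig[[sn]] + 1
        }
      }
      # mixture log-scales
      for (st in c("rural", "urban")) {
        prop_eta <- eta
        prop_eta[[st]] <- eta[[st]] + rnorm(1, 0, step_eta[[st]])
        lp_cur <- pll + dnorm(eta[[st]], 0, spec$log_scale_prior_sd, log = TRUE)
        pll_p <- prev_ll(theta, prop_eta)
        lp_prop <- pll_p + dnorm(prop_eta[[st]], 0, spec$log_scale_prior_sd,
                                 log = TRUE)
        if (log(runif(1)) < lp_prop - lp_cur) {
          eta <- prop_eta
          pll <- pll_p
          acc_eta[[st]] <- acc_eta[[st]] + 1
          po <- pseudo_obs(eta)
          sll <- pseudo_ll(theta, po)
        }
      }
      # adapt RW steps during burn-in
      if (it <= mcmc$burnin && it %% 50 == 0) {
        rate_s <- acc_sig / 50
        step_sig <- pmin(pmax(step_sig * exp(rate_s - 0.44), 0.01), 2)
        acc_sig[] <- 0
        rate_e <- acc_eta / 50
        step_eta <- pmin(pmax(step_eta * exp(rate_e - 0.44), 0.01), 2)
        acc_eta[] <- 0
      }
      if (ki < mcmc$per_chain && it == keep_at[ki + 1L]) {
        ki <- ki + 1L
        row <- row0 + ki
        keep_theta[row, ] <- theta
        keep_sigma[row, ] <- sig
        keep_eta[row, ] <- eta
        keep_chain[row] <- ch
        mon_draws[row, ] <- c(sig, eta,
                              theta[c(layout$a0, layout$b0,
                                      layout$d0, layout$g0)])
      }
    }
    row0 <- row0 + mcmc$per_chain
    if (verbose) message("chain ", ch, " done")
  }

  # posterior mean-Z draws for every country-year-stratum
  Xr_pred <- matrix(0, C * T, layout$dim)
  Xu_pred <- matrix(0, C * T, layout$dim)
  k <- 0L
  # column order must be country-fastest to match the [draw, country, year]
  # array layout
  for (yr in years) for (cc in countries) {
    k <- k + 1L
    dr <- design_rows(cc, yr, layout, regions_of, years, spec$center_year,
                      rw2$Z, xstd_at(cc, yr))
    Xr_pred[k, ] <- dr$rural
    Xu_pred[k, ] <- dr$rural + dr$offset
  }
  mu <- array(NA_real_, c(mcmc$draws, C, T, 2),
              dimnames = list(NULL, countries, years, c("rural", "urban")))
  mu[, , , "rural"] <- keep_theta %*% t(Xr_pred)
  mu[, , , "urban"] <- keep_theta %*% t(Xu_pred)

  diag <- mcmc_diagnostics(mon_draws, keep_chain, spec$rhat_threshold)
  if (length(diag$warnings)) warning(paste(diag$warnings, collapse = "; "),
                                     call. = FALSE)
  diag$accept_theta <- unname(accept[["theta"]] / max(1, accept[["theta_n"]]))

  structure(list(mu = mu, theta = keep_theta, sigma = keep_sigma,
                 eta = keep_eta, chain = keep_chain, diagnostics = diag,
                 spec = spec, meta = meta, countries = countries,
                 regions = regions, regions_of = regions_of, years = years,
                 layout = layout, rw2 = rw2, mcmc = mcmc,
                 covar_mean = covar_mean, covar_sd = covar_sd,
                 sources = sources),
            class = "hiermix_fit")
}

# split-chain potential scale reduction and a crude effective sample size
split_rhat <- function(x, chain) {
  parts <- list()
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    h <- length(xs) %/% 2
    if (h < 2) return(NA_real_)
    parts <- c(parts, list(xs[1:h], xs[(h + 1):(2 * h)]))
  }
  m <- length(parts); nn <- length(parts[[1]])
  means <- vapply(parts, mean, 0)
  vars <- vapply(parts, var, 0)
  B <- nn * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(x, chain) {
  total <- 0
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    nn <- length(xs)
    if (var(xs) == 0) { total <- total + nn; next }
    rho <- stats::acf(xs, lag.max = min(100, nn - 1), plot = FALSE)$acf[-1]
    pos <- which(rho < 0.05)
    cut <- if (length(pos)) pos[1] - 1 else length(rho)
    tau <- 1 + 2 * sum(rho[seq_len(cut)])
    total <- total + nn / max(tau, 1)
  }
  total
}

mcmc_diagnostics <- function(mon, chain, threshold) {
  rhat <- apply(mon, 2, split_rhat, chain = chain)
  ess <- apply(mon, 2, ess_basic, chain = chain)
  warnings <- character(0)
  bad <- names(rhat)[!is.na(rhat) & rhat > threshold]
  if (length(bad))
    warnings <- paste0("split-chain scale reduction above ", threshold,
                       " for: ", paste(bad, collapse = ", "))
  list(rhat = rhat, ess = ess, warnings = warnings)
}

# reconstruct a model_state from one retained draw (for mean_z,
# log_likelihood cross-checks, and downstream use)
#' Extract one posterior draw as a model state
#'
#' @param fit a \code{hiermix_fit}.
#' @param draw draw index (1..number of retained draws).
#' @return a \code{\link{model_state}}.
#' @export
state_from_draw <- function(fit, draw) {
  th <- fit$theta[draw, ]
  lay <- fit$layout
  C <- length(fit$countries); T <- length(fit$years)
  u <- matrix(0, C, T, dimnames = list(fit$countries, fit$years))
  for (i in seq_len(C))
    u[i, ] <- as.vector(fit$rw2$Z %*% th[lay$v[i, ]])
  model_state(
    a0 = th[lay$a0], b0 = th[lay$b0], d0 = th[lay$d0], g0 = th[lay$g0],
    beta = setNames(th[lay$beta], fit$spec$covariates),
    a_region = setNames(th[lay$a_region], fit$regions),
    b_region = setNames(th[lay$b_region], fit$regions),
    a_country = setNames(th[lay$a_country], fit$countries),
    b_country = setNames(th[lay$b_country], fit$countries),
    d_country = setNames(th[lay$d_country], fit$countries),
    g_country = setNames(th[lay$g_country], fit$countries),
    u = u, log_scale = c(rural = unname(fit$eta[draw, "rural"]),
                         urban = unname(fit$eta[draw, "urban"])),
    region_of = fit$regions_of, center_year = fit$spec$center_year,
    covar_mean = fit$covar_mean, covar_sd = fit$covar_sd)
}

#' @export
print.hiermix_fit <- function(x, ...) {
  cat("Hierarchical mixture model fit (", x$spec$metric, "): ",
      dim(x$mu)[1], " posterior draws, ", length(x$countries),
      " countries x ", length(x$years), " years\n", sep = "")
  cat("max split-chain Rhat: ",
      round(max(x$diagnostics$rhat, na.rm = TRUE), 3), "\n", sep = "")
  if (length(x$diagnostics$warnings))
    cat("warnings:", x$diagnostics$warnings, "\n")
  invisible(x)
}
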