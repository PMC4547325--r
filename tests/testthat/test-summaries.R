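# Posterior summaries: credible intervals, tail prevalence, posterior
# probability of direction, aggregation, and child counts.

test_that("summarize_draws uses the 2.5-97.5 linear-interpolation percentiles", {
  expect_equal(summarize_draws(rep(3.7, 10)),
               c(mean = 3.7, lo = 3.7, hi = 3.7))
  s <- summarize_draws(1:1000)
  expect_equal(s[["lo"]], 25.975)
  expect_equal(s[["hi"]], 975.025)
  set.seed(7)
  s2 <- summarize_draws(rnorm(2500))
  expect_equal(s2[["lo"]], -1.96, tolerance = 0.08)
  expect_equal(s2[["hi"]], 1.96, tolerance = 0.08)
  expect_error(summarize_draws(1), "at least 2")
  expect_error(summarize_draws(c(1, NA)), "finite")
})

test_that("prevalence_below matches closed forms and Monte Carlo", {
  spec <- model_spec()
  single <- mixture_distribution(1, 0, 1)
  expect_equal(prevalence_below(single), pnorm(-2))
  # symmetric mixture centered at the threshold has tail mass 1/2
  sym <- mixture_distribution(c(0.5, 0.5), c(-2.4, -1.6), c(0.8, 0.8))
  expect_equal(prevalence_below(sym), 0.5, tolerance = 1e-12)
  # default shape at mu = -1.5 vs a large sampling oracle
  mix <- population_mixture(-1.5, spec)
  set.seed(8)
  comp <- sample(5, 1e6, replace = TRUE, prob = mix$weights)
  draws <- rnorm(1e6, mix$means[comp], mix$sds[comp])
  expect_lt(abs(prevalence_below(mix) - mean(draws < -2)), 0.002)
  # monotone decreasing in the location
  locs <- seq(-3, 1, by = 0.25)
  prevs <- vapply(locs, function(m) prevalence_below(population_mixture(m, spec)),
                  numeric(1))
  expect_true(all(diff(prevs) < 0))
})

test_that("pp_direction reflects the draw sign distribution", {
  expect_equal(pp_direction(rep(0.2, 100))$pp, 1.0)
  expect_equal(pp_direction(c(rep(1, 2000), rep(-1, 500)))$pp, 0.8)
  x <- rnorm(1250)
  sym <- c(x, -x)
  expect_equal(pp_direction(sym)$pp, 0.5)
  # invariant under sign flip, always in [0.5, 1]
  set.seed(9)
  for (i in 1:20) {
    d <- rnorm(500, runif(1, -1, 1))
    p1 <- pp_direction(d)$pp
    expect_equal(p1, pp_direction(-d)$pp)
    expect_gte(p1, 0.5); expect_lte(p1, 1)
  }
})

test_that("population-weighted aggregation behaves as a weighted mean", {
  a <- c(0, 0, 0); b <- c(1, 1, 1)
  expect_equal(aggregate_population_weighted(list(a), 5), a)
  expect_equal(aggregate_population_weighted(list(a, b), c(1, 1)),
               c(0.5, 0.5, 0.5))
  expect_equal(aggregate_population_weighted(list(a, b), c(2, 0)), a)
  expect_error(aggregate_population_weighted(list(a, c(1, 2)), c(1, 1)),
               "equal length")
  expect_error(aggregate_population_weighted(list(a, b), c(0, 0)),
               "not all zero")
  # aggregation commutes with the posterior mean
  set.seed(10)
  m1 <- rnorm(300); m2 <- rnorm(300, 1)
  w <- c(3, 7)
  agg <- aggregate_population_weighted(list(m1, m2), w)
  expect_equal(mean(agg), 0.3 * mean(m1) + 0.7 * mean(m2), tolerance = 1e-12)
})

test_that("undernourished counts are exact draw-wise arithmetic", {
  z <- rep(0, 4)
  expect_equal(count_undernourished(z, z, 1e6, 0.3)$total, z)
  out <- count_undernourished(c(0.4, 0.4), c(0.2, 0.2), 1000, 0.25)
  expect_equal(out$rural, c(300, 300))
  expect_equal(out$urban, c(50, 50))
  expect_equal(out$total, c(350, 350))
  # p = 0: everything rural
  out0 <- count_undernourished(c(0.4), c(0.2), 1000, 0)
  expect_equal(out0$urban, 0)
  expect_equal(out0$total, 400)
  # total = rural + urban exactly, nonnegative
  set.seed(11)
  pr <- runif(100); pu <- runif(100)
  cc <- count_undernourished(pr, pu, 5e5, 0.37)
  expect_true(all(cc$total == cc$rural + cc$urban))
  expect_true(all(cc$rural >= 0 & cc$urban >= 0))
})

test_that("summarize_fit produces valid estimate tables at all levels", {
  sf <- shared_small_fit()
  fit <- sf$fit
  est_c <- summarize_fit(fit, level = "country", years = c(1985, 1998, 2011))
  expect_equal(nrow(est_c), 4 * 3 * 2)   # countries x years x strata
  expect_true(all(est_c$mean_lo <= est_c$mean & est_c$mean <= est_c$mean_hi))
  expect_true(all(est_c$prev >= 0 & est_c$prev <= 1))
  est_g <- summarize_fit(fit, level = "global", years = 2011)
  expect_equal(nrow(est_g), 2)
  # global mean draws are population-weighted combinations of country draws
  yr <- "2011"
  w <- fit$meta$pop_under5[fit$meta$year == 2011] *
    (1 - fit$meta$urban_fraction[fit$meta$year == 2011])
  manual <- as.vector(fit$mu[, , yr, "rural"] %*% (w / sum(w)))
  expect_equal(est_g$mean[est_g$stratum == "rural"], mean(manual),
               tolerance = 1e-10)
  # writable
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimates(path, rbind(est_c, est_g))
  expect_equal(nrow(read_estimates(path)), nrow(est_c) + 2)
})
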