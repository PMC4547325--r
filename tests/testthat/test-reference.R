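# Growth-reference module: LMS transform, lookups, unit equivalents,
# NCHS -> WHO conversion.

test_that("LMS transform matches its closed form and is monotone", {
  # median maps to zero for any parameters
  for (L in c(-0.5, 0, 1)) {
    expect_equal(lms_zscore(12.9, list(L = L, M = 12.9, S = 0.11)), 0)
    expect_equal(lms_inverse(0, list(L = L, M = 12.9, S = 0.11)), 12.9)
  }
  # L = 1 reduces to (x - M) / (M * S)
  expect_equal(lms_zscore(105, list(L = 1, M = 100, S = 0.05)), 1.0)
  expect_equal(lms_inverse(-2, list(L = 1, M = 100, S = 0.05)), 90)
  # independently derived value of the Box-Cox form
  expect_equal(lms_zscore(15, list(L = -0.3, M = 12.9, S = 0.11)),
               1.340560, tolerance = 1e-6)
  # strict monotonicity in x
  x <- seq(8, 20, length.out = 200)
  z <- lms_zscore(x, list(L = -0.3, M = 12.9, S = 0.11))
  expect_true(all(diff(z) > 0))
})

test_that("lms_inverse is the exact inverse on random rows", {
  set.seed(1)
  for (i in 1:100) {
    lms <- list(L = runif(1, -1, 1.5), M = runif(1, 3, 120),
                S = runif(1, 0.02, 0.2))
    z <- runif(1, -3.5, 3.5)
    if (1 + lms$L * lms$S * z <= 0) next
    expect_equal(lms_zscore(lms_inverse(z, lms), lms), z, tolerance = 1e-10)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(lms_zscore(-1, list(L = 1, M = 100, S = 0.05)), "positive")
  expect_error(lms_zscore(10, list(L = 1, M = -1, S = 0.05)), "M > 0")
  expect_error(lms_inverse(-25, list(L = 1, M = 100, S = 0.05)),
               "invertible")
  who <- synthetic_reference_table("WHO2006")
  expect_error(lookup_lms(who, 80, "male", "height"), "outside")
  expect_error(zscore_unit_equivalent(24.5, "height", who), "grid")
})

test_that("reference table I/O validates schema and interpolates", {
  path <- system.file("extdata", "who2006_synthetic_lms.csv",
                      package = "anthrotrend")
  who <- read_reference_table(path)
  expect_s3_class(who, "reference_table")
  expect_identical(attr(who, "kind"), "WHO2006")
  # interpolation is linear in L, M, S between grid points
  a <- lookup_lms(who, 24, "male", "height")
  b <- lookup_lms(who, 25, "male", "height")
  mid <- lookup_lms(who, 24.5, "male", "height")
  expect_equal(mid$M, (a$M + b$M) / 2)
  expect_equal(mid$S, (a$S + b$S) / 2)
  # broken tables are rejected
  df <- as.data.frame(who)
  expect_error(as_reference_table(df[-5, ]), "contiguous")
  df2 <- df; df2$S[3] <- -1
  expect_error(as_reference_table(df2), "S > 0")
  df3 <- rbind(df, df[1, ])
  expect_error(as_reference_table(df3), "duplicate")
})

test_that("one-Z measurement equivalents are positive, sex-averaged, and grow with age", {
  who <- synthetic_reference_table("WHO2006")
  for (age in c(0, 12, 24, 36, 48, 60))
    for (m in c("height", "weight"))
      expect_gt(zscore_unit_equivalent(age, m, who), 0)
  expect_gt(zscore_unit_equivalent(60, "height", who),
            zscore_unit_equivalent(24, "height", who))
  # closed form under L = 1: equals the mean of M * S over sexes
  df <- data.frame(kind = "WHO2006",
                   metric = "height",
                   sex = rep(c("male", "female"), each = 2),
                   age_months = c(10, 11, 10, 11),
                   L = 1, M = c(70, 71, 69, 70), S = 0.04)
  tb <- as_reference_table(df)
  expect_equal(zscore_unit_equivalent(10, "height", tb),
               mean(c(70, 69) * 0.04))
})

test_that("NCHS->WHO conversion with identical tables is the identity with zero variance", {
  who <- synthetic_reference_table("WHO2006")
  twin <- as.data.frame(who)
  twin$kind <- "NCHS1977"
  twin <- as_reference_table(twin)
  s <- summary_statistic(-1.2, 1.1, 0.25, "NCHS1977")
  conv <- convert_summary_nchs_to_who(s, "haz", c(0, 59), who, twin)
  expect_equal(conv$summary$mean_z, -1.2, tolerance = 1e-10)
  expect_equal(conv$summary$sd_z, 1.1, tolerance = 1e-10)
  expect_equal(conv$conversion_variance, 0, tolerance = 1e-12)
  expect_identical(conv$summary$reference, "WHO2006")
})

test_that("NCHS->WHO conversion matches a Monte-Carlo quantile-mapping oracle", {
  who <- synthetic_reference_table("WHO2006")
  nchs <- synthetic_reference_table("NCHS1977")
  for (case in list(list(m = -1.2, s = 1.1, metric = "haz"),
                    list(m = -0.6, s = 1.2, metric = "waz"))) {
    s <- summary_statistic(case$m, case$s, 0.3, "NCHS1977")
    conv <- convert_summary_nchs_to_who(s, case$metric, c(0, 59), who, nchs)
    # oracle: sample the assumed-normal NCHS-space population, push each
    # child through the measurement scale at a random age and sex
    set.seed(99)
    N <- 1e6
    z <- rnorm(N, case$m, case$s)
    ages <- sample(0:59, N, replace = TRUE)
    sexes <- sample(c("male", "female"), N, replace = TRUE)
    lmsm <- if (case$metric == "haz") "height" else "weight"
    mapped <- numeric(N)
    for (a in 0:59) for (sx in c("male", "female")) {
      i <- which(ages == a & sexes == sx)
      lf <- lookup_lms(nchs, a, sx, lmsm)
      lt <- lookup_lms(who, a, sx, lmsm)
      mapped[i] <- lms_zscore(lms_inverse(z[i], lf), lt)
    }
    expect_lt(abs(conv$summary$mean_z - mean(mapped)), 0.005)
    expect_lt(abs(conv$summary$sd_z - sd(mapped)), 0.005)
    expect_lt(abs(conv$summary$prev_below - mean(mapped < -2)), 0.005)
  }
})

test_that("conversion refuses mismatched references", {
  who <- synthetic_reference_table("WHO2006")
  nchs <- synthetic_reference_table("NCHS1977")
  s_who <- summary_statistic(-1, 1, NA_real_, "WHO2006")
  expect_error(convert_summary_nchs_to_who(s_who, "haz", c(0, 59), who, nchs),
               "not NCHS1977")
  s <- summary_statistic(-1, 1, NA_real_, "NCHS1977")
  expect_error(convert_summary_nchs_to_who(s, "haz", c(0, 59), nchs, who),
               "kind")
})
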