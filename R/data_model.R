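ANALYSIS_YEARS <- 1985:2011
STRATA <- c("rural", "urban", "combined")
COVERAGE <- c("national", "subnational")
AGE_COVERAGE <- c("full", "partial")
METRICS <- c("haz", "waz")

#' Default region codes
#'
#' Seven geographical region codes used when no region configuration is
#' supplied: sub-Saharan Africa (SSA); central Asia, Middle East, and north
#' Africa (CAMENA); south Asia (SAS); east and southeast Asia (ESEA);
#' southern and tropical Latin America (STLA); Andean and central Latin
#' America and Caribbean (ACLAC); Oceania (OCE).
#'
#' @return character vector of 7 region codes.
#' @export
default_regions <- function() {
  c("SSA", "CAMENA", "SAS", "ESEA", "STLA", "ACLAC", "OCE")
}

stop_rows <- function(msg, rows) {
  stop(msg, " (row", if (length(rows) > 1) "s", " ",
       paste(rows, collapse = ", "), ")", call. = FALSE)
}

#' Read survey summary sources
#'
#' Reads and validates a CSV of survey summary records, one per
#' country-year-stratum-metric.  Columns:
#' \code{country,year,stratum,coverage,age_coverage,metric,mean_z,sd_z,n,se_mean,prev_below,reference}.
#' Categorical tokens are case-insensitive.  Validation failures are reported
#' with the offending data row numbers.
#'
#' @param path path to the sources CSV.
#' @param years permitted analysis window (integer vector).
#' @return a data frame of class \code{anthro_sources}.
#' @export
read_sources <- function(path, years = ANALYSIS_YEARS) {
  if (!file.exists(path)) stop("sources file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_sources(df, years = years)
}

#' @rdname read_sources
#' @param df data frame with the sources schema.
#' @export
as_sources <- function(df, years = ANALYSIS_YEARS) {
  need <- c("country", "year", "stratum", "coverage", "age_coverage", "metric",
            "mean_z", "sd_z", "n", "se_mean", "prev_below", "reference")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sources missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  for (col in c("stratum", "coverage", "age_coverage", "metric"))
    df[[col]] <- tolower(trimws(df[[col]]))
  df$reference <- toupper(trimws(df$reference))
  df$country <- toupper(trimws(df$country))

  bad <- which(!df$stratum %in% STRATA)
  if (length(bad)) stop_rows("unknown stratum token", bad)
  bad <- which(!df$coverage %in% COVERAGE)
  if (length(bad)) stop_rows("unknown coverage token", bad)
  bad <- which(!df$age_coverage %in% AGE_COVERAGE)
  if (length(bad)) stop_rows("unknown age_coverage token", bad)
  bad <- which(!df$metric %in% METRICS)
  if (length(bad)) stop_rows("unknown metric token", bad)
  bad <- which(!df$reference %in% REFERENCE_KINDS)
  if (length(bad)) stop_rows("unknown reference token", bad)
  bad <- which(!(df$year %in% years))
  if (length(bad)) stop_rows("year outside analysis window", bad)
  bad <- which(!is.finite(df$se_mean) | df$se_mean <= 0)
  if (length(bad)) stop_rows("se_mean must be positive", bad)
  bad <- which(!is.finite(df$n) | df$n < 1)
  if (length(bad)) stop_rows("sample size n must be >= 1", bad)
  bad <- which(!is.finite(df$mean_z))
  if (length(bad)) stop_rows("mean_z must be finite", bad)
  bad <- which(!is.finite(df$sd_z) | df$sd_z <= 0)
  if (length(bad)) stop_rows("sd_z must be positive", bad)
  bad <- which(!is.na(df$prev_below) & (df$prev_below < 0 | df$prev_below > 1))
  if (length(bad)) stop_rows("prev_below must lie in [0, 1]", bad)

  structure(df, years = years, class = c("anthro_sources", "data.frame"))
}

#' Read country metadata and covariate series
#'
#' Reads a CSV with one row per country-year, columns
#' \code{country,region,year,pop_under5,urban_fraction,educ_years,log_gdp,urban_prop,health_access},
#' and validates complete coverage of the analysis window for every country,
#' region membership against a configured region list, and ranges
#' (\code{urban_fraction} in [0, 1], \code{pop_under5 >= 0}).
#'
#' @param path path to the country-meta CSV.
#' @param regions permitted region codes (default \code{\link{default_regions}}).
#' @param years required year coverage per country.
#' @return a data frame of class \code{anthro_meta}, sorted by country, year.
#' @export
read_country_meta <- function(path, regions = default_regions(),
                              years = ANALYSIS_YEARS) {
  if (!file.exists(path)) stop("country-meta file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_country_meta(df, regions = regions, years = years)
}

#' @rdname read_country_meta
#' @param df data frame with the country-meta schema.
#' @export
as_country_meta <- function(df, regions = default_regions(),
                            years = ANALYSIS_YEARS) {
  need <- c("country", "region", "year", "pop_under5", "urban_fraction",
            "educ_years", "log_gdp", "urban_prop", "health_access")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("country-meta missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  df$country <- toupper(trimws(df$country))
  df$region <- toupper(trimws(df$region))

  bad <- which(!df$region %in% regions)
  if (length(bad)) stop_rows("unknown region code", bad)
  bad <- which(df$urban_fraction < 0 | df$urban_fraction > 1)
  if (length(bad)) stop_rows("urban_fraction must lie in [0, 1]", bad)
  bad <- which(df$pop_under5 < 0)
  if (length(bad)) stop_rows("pop_under5 must be >= 0", bad)

  for (cc in unique(df$country)) {
    have <- df$year[df$country == cc]
    if (anyDuplicated(have))
      stop("duplicate years for country ", cc, call. = FALSE)
    gaps <- setdiff(years, have)
    if (length(gaps))
      stop("country ", cc, " missing year", if (length(gaps) > 1) "s", " ",
           paste(gaps, collapse = ", "), call. = FALSE)
    reg <- unique(df$region[df$country == cc])
    if (length(reg) != 1)
      stop("country ", cc, " assigned to multiple regions", call. = FALSE)
  }
  df <- df[order(df$country, df$year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, years = years, regions = regions,
            class = c("anthro_meta", "data.frame"))
}

#' Write and read estimate tables
#'
#' Estimates CSV schema:
#' \code{level,id,year,stratum,metric,mean,mean_lo,mean_hi,prev,prev_lo,prev_hi}
#' where \code{level} is country/region/global, intervals are 2.5-97.5
#' percentiles of the posterior draws, and prevalences lie in [0, 1].
#' Numeric fields are written with 17 significant digits so a read-back
#' reproduces the written values exactly.
#'
#' @param path output CSV path.
#' @param rows a data frame with the estimates schema.
#' @return \code{path}, invisibly.
#' @export
write_estimates <- function(path, rows) {
  need <- c("level", "id", "year", "stratum", "metric",
            "mean", "mean_lo", "mean_hi", "prev", "prev_lo", "prev_hi")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("estimates missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- as.data.frame(rows)[, need, drop = FALSE]
  if (nrow(rows)) {
    bad <- which(!(rows$mean_lo <= rows$mean & rows$mean <= rows$mean_hi))
    if (length(bad)) stop_rows("mean credible interval must bracket the mean", bad)
    ok_prev <- is.na(rows$prev) |
      (rows$prev_lo <= rows$prev & rows$prev <= rows$prev_hi &
         rows$prev_lo >= 0 & rows$prev_hi <= 1)
    if (any(!ok_prev)) stop_rows("invalid prevalence interval", which(!ok_prev))
  }
  out <- rows
  for (col in c("mean", "mean_lo", "mean_hi", "prev", "prev_lo", "prev_hi"))
    out[[col]] <- ifelse(is.na(rows[[col]]), "",
                         formatC(rows[[col]], digits = 17, format = "g"))
  con <- file(path, open = "wb")   # binary: byte-identical across platforms
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("estimates file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(level = "character", id = "character"))
  df
}

#' @export
print.anthro_sources <- function(x, ...) {
  cat("Survey summary sources: ", nrow(x), " records, ",
      length(unique(x$country)), " countries, years ",
      min(x$year), "-", max(x$year), "\n", sep = "")
  invisible(x)
}

#' @export
print.anthro_meta <- function(x, ...) {
  cat("Country metadata: ", length(unique(x$country)), " countries x ",
      length(attr(x, "years")), " years, regions: ",
      paste(sort(unique(x$region)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
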