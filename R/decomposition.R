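# Additive decomposition of a change in population mean Z into rural,
# urban, and urbanisation components.

#' Decompose a change in population mean Z score
#'
#' The change in a population's mean Z between a start and an end period is
#' decomposed additively into: the change among rural children weighted by
#' the start-period rural share, the change among urban children weighted by
#' the start-period urban share, and an urbanisation component equal to the
#' change in urban proportion times the end-period urban-rural differential:
#' \deqn{total = [p_1 z_{u1} + (1-p_1) z_{r1}] - [p_0 z_{u0} + (1-p_0) z_{r0}]}
#' \deqn{rural = (1-p_0)(z_{r1}-z_{r0}),\quad urban = p_0 (z_{u1}-z_{u0}),}
#' \deqn{urbanisation = (p_1-p_0)(z_{u1}-z_{r1}).}
#' The three components sum to the total exactly (an algebraic identity),
#' and the normalized shares sum to 1 whenever the total change is nonzero;
#' individual components and shares may be negative or exceed 1.  All
#' arguments are vectorized (e.g. over posterior draws).
#'
#' @param z_r_start,z_u_start rural and urban mean Z at the start.
#' @param z_r_end,z_u_end rural and urban mean Z at the end.
#' @param p_start,p_end urban fraction at start and end, in [0, 1].
#' @param share_tol total changes with absolute value below this are flagged
#'   as having undefined shares (shares set to NA).
#' @return list of class \code{decomposition_result} with vectors
#'   \code{total_change}, \code{rural_component}, \code{urban_component},
#'   \code{urbanisation_component}, \code{shares} (3-column matrix rural /
#'   urban / urbanisation), and \code{n_zero_total} (count of inputs with
#'   undefined shares).
#' @export
decompose_change <- function(z_r_start, z_u_start, z_r_end, z_u_end,
                             p_start, p_end, share_tol = 1e-12) {
  if (any(p_start < 0 | p_start > 1 | p_end < 0 | p_end > 1))
    stop("urban fractions must lie in [0, 1]", call. = FALSE)
  rural <- (1 - p_start) * (z_r_end - z_r_start)
  urban <- p_start * (z_u_end - z_u_start)
  urbanisation <- (p_end - p_start) * (z_u_end - z_r_end)
  total <- (p_end * z_u_end + (1 - p_end) * z_r_end) -
    (p_start * z_u_start + (1 - p_start) * z_r_start)
  ok <- abs(total) > share_tol
  shares <- cbind(rural = ifelse(ok, rural / total, NA_real_),
                  urban = ifelse(ok, urban / total, NA_real_),
                  urbanisation = ifelse(ok, urbanisation / total, NA_real_))
  structure(list(total_change = total, rural_component = rural,
                 urban_component = urban,
                 urbanisation_component = urbanisation,
                 shares = shares, n_zero_total = sum(!ok)),
            class = "decomposition_result")
}

#' Decompose a fitted trend draw-wise
#'
#' Applies \code{\link{decompose_change}} to every posterior draw of the
#' start- and end-year rural and urban mean Z at country, region, or global
#' level, and summarizes the component shares as means of the per-draw
#' shares with 2.5-97.5 percentile intervals.  Draws with (numerically) zero
#' total change are excluded from share averaging and counted in the output.
#' Regional stratum means are population-weighted averages of the country
#' draws; the regional urban fraction is the under-5 population share living
#' in urban areas.
#'
#' @param fit a \code{hiermix_fit}.
#' @param meta an \code{anthro_meta} (defaults to the fit's).
#' @param start_year,end_year decomposition period (default: first and last
#'   fitted year).
#' @param level \code{"country"}, \code{"region"}, or \code{"global"}.
#' @return data frame with columns \code{level,id,metric,component,
#'   share_mean,share_lo,share_hi,n_zero_total}.
#' @export
decompose_fit <- function(fit, meta = fit$meta,
                          start_year = min(fit$years),
                          end_year = max(fit$years),
                          level = c("country", "region", "global")) {
  level <- match.arg(level)
  groups <- switch(level,
    country = setNames(as.list(fit$countries), fit$countries),
    region = split(fit$countries, fit$regions_of[fit$countries]),
    global = list(ALL = fit$countries))
  grab <- function(yr, stratum, members) {
    m <- fit$mu[, members, as.character(yr), stratum, drop = FALSE]
    matrix(m, nrow = dim(fit$mu)[1])
  }
  pop_at <- function(yr, members) {
    rows <- meta[meta$year == yr & meta$country %in% members, ]
    rows <- rows[match(members, rows$country), ]
    list(pop = rows$pop_under5, p = rows$urban_fraction)
  }
  out <- list()
  k <- 0L
  for (gid in names(groups)) {
    members <- groups[[gid]]
    s0 <- pop_at(start_year, members); s1 <- pop_at(end_year, members)
    agg <- function(yr, stratum, w) {
      mm <- grab(yr, stratum, members)
      if (length(members) == 1) as.vector(mm)
      else aggregate_population_weighted(mm, w)
    }
    zr0 <- agg(start_year, "rural", s0$pop * (1 - s0$p))
    zu0 <- agg(start_year, "urban", s0$pop * s0$p)
    zr1 <- agg(end_year, "rural", s1$pop * (1 - s1$p))
    zu1 <- agg(end_year, "urban", s1$pop * s1$p)
    p0 <- sum(s0$pop * s0$p) / sum(s0$pop)
    p1 <- sum(s1$pop * s1$p) / sum(s1$pop)
    dec <- decompose_change(zr0, zu0, zr1, zu1, p0, p1)
    for (comp in colnames(dec$shares)) {
      sh <- dec$shares[, comp]
      sh <- sh[!is.na(sh)]
      sm <- if (length(sh) >= 2) summarize_draws(sh)
        else c(mean = NA_real_, lo = NA_real_, hi = NA_real_)
      k <- k + 1L
      out[[k]] <- data.frame(level = level, id = gid,
                             metric = fit$spec$metric, component = comp,
                             share_mean = sm[["mean"]], share_lo = sm[["lo"]],
                             share_hi = sm[["hi"]],
                             n_zero_total = dec$n_zero_total,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.decomposition_result <- function(x, ...) {
  n <- length(x$total_change)
  cat("Decomposition of mean-Z change (", n, " input",
      if (n > 1) "s", ")\n", sep = "")
  if (n == 1) {
    cat(sprintf("  total %+0.4f = rural %+0.4f + urban %+0.4f + urbanisation %+0.4f\n",
                x$total_change, x$rural_component, x$urban_component,
                x$urbanisation_component))
    if (!is.na(x$shares[1, 1]))
      cat(sprintf("  shares: rural %0.2f, urban %0.2f, urbanisation %0.2f\n",
                  x$shares[1, 1], x$shares[1, 2], x$shares[1, 3]))
  }
  invisible(x)
}
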