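#' Per-week GPP trends across years
#'
#' Weeks are defined from the first day of the year — week w covers days
#' 7(w-1)+1 to 7w — so that every year contributes the same days of year to
#' a given week; calendar weekdays would drift across years. Days 365/366
#' fall outside week 52 and are excluded, giving every week equal support.
#' For each week, all (year, daily GPP) observations of its seven member
#' days are pooled (about 7 x the number of years, which is what makes the
#' weekly regressions robust where daily ones are noisy) and GPP is
#' regressed on calendar year by ordinary least squares.
#'
#' @param series A [daily_flux()] series.
#' @param alpha Two-sided significance level for flagging trends
#'   (default 0.05).
#' @param min_years Minimum number of distinct years with data in a week
#'   (default 3); weeks below it get `NA` slopes.
#' @return Data frame of class `weekly_trend_series`, one row per week 1-52:
#'   `slope` (gC m\eqn{^{-2}} d\eqn{^{-1}} yr\eqn{^{-1}}), `p_value`,
#'   `significant`, `n_points`, `n_years`.
#' @export
weekly_trends <- function(series, alpha = 0.05, min_years = 3L) {
  stopifnot(inherits(series, "daily_flux"))
  yr <- as.integer(format(series$date, "%Y"))
  doy <- as.integer(format(series$date, "%j"))
  week <- (doy - 1L) %/% 7L + 1L
  rows <- lapply(1:52, function(w) {
    sel <- week == w & !is.na(series$gpp)
    ny <- length(unique(yr[sel]))
    if (ny < min_years)
      return(data.frame(site_id = series$site_id[1], week = w,
                        slope = NA_real_, p_value = NA_real_,
                        significant = NA, n_points = sum(sel), n_years = ny,
                        stringsAsFactors = FALSE))
    fit <- lm(gpp ~ year, data.frame(gpp = series$gpp[sel], year = yr[sel]))
    cf <- summary(fit)$coefficients
    slope <- cf["year", "Estimate"]
    p <- cf["year", "Pr(>|t|)"]
    data.frame(site_id = series$site_id[1], week = w, slope = slope,
               p_value = p, significant = p < alpha, n_points = sum(sel),
               n_years = ny, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("weekly_trend_series", "data.frame")
  out
}

#' Across-year mean transition dates per threshold
#'
#' The anchor for placing the weekly-trend windows of [ptd_gpp_coupling()]:
#' the across-year mean SOS and EOS of a site at each grid threshold and for
#' the derivative method.
#'
#' @param ptd_table A `ptd_table` from [extract_all()] (one site).
#' @return Data frame with `site_id`, `method`, `threshold`, `mean_sos`,
#'   `mean_eos`, `n_years`.
#' @export
mean_ptds <- function(ptd_table) {
  key <- ifelse(ptd_table$method == "derivative", "derivative",
                sprintf("%.2f", ptd_table$threshold))
  rows <- lapply(split(ptd_table, key), function(d) {
    ok <- is.finite(d$sos) & is.finite(d$eos)
    data.frame(site_id = d$site_id[1], method = d$method[1],
               threshold = d$threshold[1],
               mean_sos = if (any(ok)) mean(d$sos[ok]) else NA_real_,
               mean_eos = if (any(ok)) mean(d$eos[ok]) else NA_real_,
               n_years = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Weeks whose 7-day span intersects the day interval [d1, d2].
weeks_touching <- function(d1, d2) {
  w <- 1:52
  start <- 7 * (w - 1) + 1
  end <- 7 * w
  w[end >= d1 & start <= d2]
}

coupling_fit <- function(x, y, metric, method, threshold, min_sites = 3L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_sites || diff(range(x)) < 1e-12)
    return(data.frame(metric = metric, method = method, threshold = threshold,
                      slope = NA_real_, r_squared = NA_real_,
                      n_sites = length(x),
                      issues = if (length(x) < min_sites)
                        "fewer than 3 sites" else "degenerate PTD-trend variance",
                      stringsAsFactors = FALSE))
  fit <- lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0            # flat response: no explained variance
  data.frame(metric = metric, method = method, threshold = threshold,
             slope = unname(coef(fit)[2]), r_squared = r2,
             n_sites = length(x), issues = "", stringsAsFactors = FALSE)
}

grid_entries <- function(trend_tables) {
  all_tr <- do.call(rbind, trend_tables)
  grid <- sort(unique(all_tr$threshold[all_tr$method == "threshold" &
                                         !is.na(all_tr$threshold)]))
  c(as.list(grid), list(NULL))
}

lookup_trend <- function(tr, metric, th) {
  sub <- if (is.null(th)) tr[tr$metric == metric & tr$method == "derivative", ]
    else tr[tr$metric == metric & tr$method == "threshold" &
              !is.na(tr$threshold) & abs(tr$threshold - th) < 1e-9, ]
  if (nrow(sub)) sub$slope_per_decade[1] else NA_real_
}

lookup_mean <- function(mp, col, th) {
  sub <- if (is.null(th)) mp[mp$method == "derivative", ]
    else mp[mp$method == "threshold" & !is.na(mp$threshold) &
              abs(mp$threshold - th) < 1e-9, ]
  if (nrow(sub)) sub[[col]][1] else NA_real_
}

#' Coupling of transition-date trends to GPP trends around the dates
#'
#' Across a cohort of sites, relates the trend in a transition date to the
#' contemporaneous change in productivity: for each site, x is the SOS (or
#' EOS) Theil-Sen trend in days/decade at a given threshold, and y is the
#' mean weekly GPP trend over the weeks intersecting a window of
#' `window_weeks` weeks either side of the site's mean transition date. An
#' ordinary least-squares fit of y on x across sites gives the sensitivity
#' (slope) and its strength (R\eqn{^2}), per threshold and for the
#' derivative method. An advancing SOS paired with positive spring GPP
#' trends produces a negative SOS slope in this convention.
#'
#' @param trend_tables Named list (by site) of [trends_by_threshold()]
#'   tables.
#' @param weekly_tables Named list (by site) of [weekly_trends()] tables.
#' @param mean_ptd_tables Named list (by site) of [mean_ptds()] tables.
#' @param window_weeks Half-window in weeks (default 2, i.e. +/- 14 days).
#' @param min_sites Minimum sites per regression (default 3).
#' @return Data frame of `CouplingResult` rows: `metric`, `method`,
#'   `threshold`, `slope` (gC m\eqn{^{-2}} d\eqn{^{-1}} yr\eqn{^{-1}} per
#'   day decade\eqn{^{-1}}), `r_squared`, `n_sites`, `issues`.
#' @export
ptd_gpp_coupling <- function(trend_tables, weekly_tables, mean_ptd_tables,
                             window_weeks = 2L, min_sites = 3L) {
  sites <- names(trend_tables)
  stopifnot(!is.null(sites), all(sites %in% names(weekly_tables)),
            all(sites %in% names(mean_ptd_tables)))
  entries <- grid_entries(trend_tables)
  out <- lapply(c("SOS", "EOS"), function(metric) {
    col <- if (metric == "SOS") "mean_sos" else "mean_eos"
    do.call(rbind, lapply(entries, function(th) {
      xy <- vapply(sites, function(s) {
        x <- lookup_trend(trend_tables[[s]], metric, th)
        m <- lookup_mean(mean_ptd_tables[[s]], col, th)
        if (!is.finite(m)) return(c(x, NA_real_))
        wk <- weeks_touching(m - 7 * window_weeks, m + 7 * window_weeks)
        y <- mean(weekly_tables[[s]]$slope[weekly_tables[[s]]$week %in% wk],
                  na.rm = TRUE)
        c(x, y)
      }, numeric(2))
      coupling_fit(xy[1, ], xy[2, ], metric,
                   if (is.null(th)) "derivative" else "threshold",
                   if (is.null(th)) NA_real_ else th, min_sites)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Coupling of growing-season-length trends to seasonal GPP trends
#'
#' As [ptd_gpp_coupling()], but x is the site's GSL trend and y is the *sum*
#' of weekly GPP trends over all weeks from the mean SOS to the mean EOS
#' (weeks partially covered by the season are included), i.e. the trend in
#' seasonal productivity. A weak R\eqn{^2} here, alongside strong coupling
#' around the individual dates, indicates that gains at one end of the
#' season are compensated elsewhere in it.
#'
#' @inheritParams ptd_gpp_coupling
#' @return Data frame of `CouplingResult` rows with `metric = "GSL"`.
#' @export
gsl_seasonal_coupling <- function(trend_tables, weekly_tables,
                                  mean_ptd_tables, min_sites = 3L) {
  sites <- names(trend_tables)
  stopifnot(!is.null(sites), all(sites %in% names(weekly_tables)),
            all(sites %in% names(mean_ptd_tables)))
  entries <- grid_entries(trend_tables)
  out <- do.call(rbind, lapply(entries, function(th) {
    xy <- vapply(sites, function(s) {
      x <- lookup_trend(trend_tables[[s]], "GSL", th)
      sos <- lookup_mean(mean_ptd_tables[[s]], "mean_sos", th)
      eos <- lookup_mean(mean_ptd_tables[[s]], "mean_eos", th)
      if (!is.finite(sos) || !is.finite(eos)) return(c(x, NA_real_))
      wk <- weeks_touching(sos, eos)
      y <- sum(weekly_tables[[s]]$slope[weekly_tables[[s]]$week %in% wk],
               na.rm = TRUE)
      c(x, y)
    }, numeric(2))
    coupling_fit(xy[1, ], xy[2, ], "GSL",
                 if (is.null(th)) "derivative" else "threshold",
                 if (is.null(th)) NA_real_ else th, min_sites)
  }))
  rownames(out) <- NULL
  out
}
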