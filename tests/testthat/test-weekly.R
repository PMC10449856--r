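test_that("weeks run from day 1 in 7-day blocks and leap tails are excluded", {
  x <- quick_series(n_years = 4, start_year = 2003)   # includes leap 2004
  wt <- weekly_trends(x)
  expect_equal(wt$week, 1:52)
  expect_true(all(wt$n_points <= 7 * 4))
  expect_equal(wt$n_points[1], 7 * 4)                 # week 1 = DOY 1..7
  # day 365/366 belong to no week: total points = 52*7 per year
  expect_equal(sum(wt$n_points), 52 * 7 * 4)
})

test_that("weekly slopes are zero without an imposed trend and exact with one", {
  x <- quick_series(n_years = 6)
  wt <- weekly_trends(x)
  expect_true(all(abs(wt$slope) < 1e-10))

  # noise-free imposed per-week rates are recovered to machine tolerance
  tr <- trend_spec(weekly_overrides = c("12" = 0.05, "30" = -0.02))
  xt <- quick_series(n_years = 6, trend = tr)
  wtt <- weekly_trends(xt)
  expect_equal(wtt$slope[wtt$week == 12], 0.05, tolerance = 1e-10)
  expect_equal(wtt$slope[wtt$week == 30], -0.02, tolerance = 1e-10)
  expect_lt(max(abs(wtt$slope[!wtt$week %in% c(12, 30)])), 1e-10)
})

test_that("imposed trends in weeks 10-20 are detected there and rarely elsewhere", {
  ov <- setNames(rep(0.05, 11), as.character(10:20))
  x <- quick_series(n_years = 20, noise = 0.05, seed = 1,
                    trend = trend_spec(weekly_overrides = ov))
  wt <- weekly_trends(x)
  in_band <- wt$week %in% 10:20
  hits <- sum(wt$significant[in_band], na.rm = TRUE)
  false_pos <- sum(wt$significant[!in_band], na.rm = TRUE)
  expect_gte(hits, 9)
  expect_lte(false_pos, 2)
  expect_true(all(wt$slope[in_band] > 0))
})

test_that("weeks with too few years yield missing slopes", {
  x <- quick_series(n_years = 2)
  wt <- weekly_trends(x)
  expect_true(all(is.na(wt$slope)))
  expect_equal(wt$n_years[1], 2)
})

test_that("mean transition dates anchor one row per grid entry", {
  x <- quick_series(n_years = 4, start_year = 2000)
  mp <- mean_ptds(extract_all(x))
  expect_equal(nrow(mp), 14)
  expect_equal(sum(mp$method == "derivative"), 1)
  m5 <- mp[mp$method == "threshold" & abs(mp$threshold - 0.5) < 1e-9, ]
  expect_equal(m5$mean_sos, 120, tolerance = 1)
  expect_equal(m5$mean_eos, 280, tolerance = 1)
})

test_that("coupling regression is exact on exactly linear cohorts and invariant", {
  sites <- paste0("S", 1:5)
  xs <- c(-4, -2, 0, 1, 3)
  trend_tables <- mean_tables <- weekly_tables <- list()
  for (i in seq_along(sites)) {
    trend_tables[[sites[i]]] <- data.frame(
      site_id = sites[i], metric = "SOS", method = "threshold",
      threshold = 0.5, slope = xs[i] / 10, slope_per_decade = xs[i],
      ci_low = NA, ci_high = NA, p_value = NA, n_years = 10, issues = "")
    mean_tables[[sites[i]]] <- data.frame(
      site_id = sites[i], method = "threshold", threshold = 0.5,
      mean_sos = 120, mean_eos = 280, n_years = 10)
    wk <- data.frame(site_id = sites[i], week = 1:52,
                     slope = rep(2 * xs[i] + 1, 52), p_value = 0.01,
                     significant = TRUE, n_points = 70, n_years = 10)
    weekly_tables[[sites[i]]] <- wk
  }
  cp <- suppressWarnings(ptd_gpp_coupling(trend_tables, weekly_tables, mean_tables))
  sos <- cp[cp$metric == "SOS" & cp$method == "threshold", ]
  expect_equal(sos$slope, 2, tolerance = 1e-10)
  expect_equal(sos$r_squared, 1, tolerance = 1e-10)
  expect_equal(sos$n_sites, 5)

  # site order and adding a constant to y change nothing
  perm <- rev(sites)
  cp2 <- suppressWarnings(ptd_gpp_coupling(trend_tables[perm], weekly_tables[perm],
                                          mean_tables[perm]))
  expect_equal(cp2[cp2$metric == "SOS" & cp2$method == "threshold", ]$slope,
               sos$slope)
  weekly_shift <- lapply(weekly_tables, function(w) {
    w$slope <- w$slope + 7; w
  })
  cp3 <- suppressWarnings(ptd_gpp_coupling(trend_tables, weekly_shift, mean_tables))
  sos3 <- cp3[cp3$metric == "SOS" & cp3$method == "threshold", ]
  expect_equal(sos3$slope, sos$slope, tolerance = 1e-10)
  expect_equal(sos3$r_squared, sos$r_squared, tolerance = 1e-10)

  # degenerate x variance is reported, not fatal
  degen <- lapply(trend_tables, function(t) { t$slope_per_decade <- 1; t })
  cpd <- ptd_gpp_coupling(degen, weekly_tables, mean_tables)
  expect_true(is.na(cpd$slope[cpd$metric == "SOS" & cpd$method == "threshold"]))
  expect_match(cpd$issues[cpd$metric == "SOS" & cpd$method == "threshold"],
               "degenerate")
})

test_that("advancing SOS raises spring GPP with the constructed sensitivity", {
  rates <- c(-0.5, -0.4, -0.3, -0.2, -0.1, 0)
  sites <- sprintf("C%d", seq_along(rates))
  trend_tables <- weekly_tables <- mean_tables <- list()
  for (i in seq_along(rates)) {
    x <- quick_series(n_years = 15, start_year = 2000, site_id = sites[i],
                      trend = trend_spec(sos_shift_rate = rates[i]))
    ptd <- extract_all(x)
    trend_tables[[sites[i]]] <- trends_by_threshold(ptd)
    weekly_tables[[sites[i]]] <- weekly_trends(x)
    mean_tables[[sites[i]]] <- mean_ptds(ptd)
  }
  cp <- ptd_gpp_coupling(trend_tables, weekly_tables, mean_tables)
  sos5 <- cp[cp$metric == "SOS" & cp$method == "threshold" &
               abs(cp$threshold - 0.5) < 1e-9, ]
  # built-in proportionality: a shift of the rising branch at rate r changes
  # GPP at fixed day d by -r g'(d); per day/decade of SOS trend the mean
  # weekly slope around SOS is -mean(g')/10
  m <- mean_tables[["C6"]]
  m_sos <- m$mean_sos[m$method == "threshold" & abs(m$threshold - 0.5) < 1e-9]
  wk <- phenoflux:::weeks_touching(m_sos - 14, m_sos + 14)
  days <- unlist(lapply(wk, function(w) (7 * (w - 1) + 1):(7 * w)))
  gprime <- 10 * 0.1 * plogis(0.1 * (days - 120)) *
    (1 - plogis(0.1 * (days - 120)))
  expected <- -mean(gprime) / 10
  expect_lt(abs(sos5$slope - expected) / abs(expected), 0.2)
  expect_lt(sos5$slope, 0)
  expect_gt(sos5$r_squared, 0.9)
})

test_that("GSL trends decouple from seasonal GPP under compensating construction", {
  rates <- seq(-0.5, 0, by = 0.1)
  sites <- sprintf("G%d", seq_along(rates))
  season_sum <- function(x, ptd) {
    wt <- weekly_trends(x)
    mp <- mean_ptds(ptd)
    m <- mp[mp$method == "threshold" & abs(mp$threshold - 0.5) < 1e-9, ]
    wk <- phenoflux:::weeks_touching(m$mean_sos, m$mean_eos)
    sum(wt$slope[wt$week %in% wk], na.rm = TRUE)
  }
  run_cohort <- function(amp_rates, noise_seeds = NULL) {
    tt <- wt <- mt <- list(); sums <- numeric(length(rates))
    for (i in seq_along(rates)) {
      x <- quick_series(n_years = 12, start_year = 2000, site_id = sites[i],
                        noise = if (is.null(noise_seeds)) 0 else 0.05,
                        seed = if (is.null(noise_seeds)) 1 else noise_seeds[i],
                        trend = trend_spec(sos_shift_rate = rates[i],
                                           amplitude_rate = amp_rates[i]))
      ptd <- extract_all(x)
      tt[[sites[i]]] <- trends_by_threshold(ptd)
      wt[[sites[i]]] <- weekly_trends(x)
      mt[[sites[i]]] <- mean_ptds(ptd)
      sums[i] <- season_sum(x, ptd)
    }
    list(tt = tt, wt = wt, mt = mt, sums = sums)
  }
  at05 <- function(cp) cp[cp$method == "threshold" &
                            abs(cp$threshold - 0.5) < 1e-9, ]

  # pass 1 (no compensation): seasonal GPP gain tracks the GSL trend
  p1 <- run_cohort(rep(0, length(rates)))
  g1 <- at05(gsl_seasonal_coupling(p1$tt, p1$wt, p1$mt))
  expect_gt(g1$r_squared, 0.8)
  expect_gt(g1$slope, 0)   # longer season, larger uncompensated seasonal gain
  # amplitude-trend sensitivity of the seasonal sum (PTDs are unaffected:
  # min-max normalization is invariant to amplitude scaling)
  xa <- quick_series(n_years = 12, start_year = 2000,
                     trend = trend_spec(amplitude_rate = 0.1))
  amp_sens <- season_sum(xa, extract_all(xa)) / 0.1

  # pass 2: per-site amplitude drifts cancel the shift-driven gain; spring
  # gain is offset by a season-wide loss, so seasonal sums collapse while
  # GSL trends are untouched
  p2 <- run_cohort(-p1$sums / amp_sens, noise_seeds = 100 + seq_along(rates))
  # residual sums are noise-level, well below the uncompensated gains
  expect_lt(max(abs(p2$sums)), 0.35 * max(abs(p1$sums)))
  g2 <- at05(gsl_seasonal_coupling(p2$tt, p2$wt, p2$mt))
  expect_lt(abs(g2$slope), 0.2 * abs(g1$slope))
  expect_lt(g2$r_squared, 0.5)
  xg <- vapply(p2$tt, function(t)
    t$slope_per_decade[t$metric == "GSL" & t$method == "threshold" &
                         abs(t$threshold - 0.5) < 1e-9], numeric(1))
  expect_gt(diff(range(xg)), 2)    # the cohort does carry GSL trends

  # zero GPP trends everywhere: slope 0, R^2 = 0
  flat_weekly <- lapply(p2$wt, function(w) { w$slope <- 0; w })
  gz <- at05(gsl_seasonal_coupling(p2$tt, flat_weekly, p2$mt))
  expect_equal(gz$slope, 0, tolerance = 1e-12)
  expect_equal(gz$r_squared, 0, tolerance = 1e-12)
})

test_that("weekly slopes aggregate to the annual-sum trend on complete years", {
  x <- quick_series(n_years = 8, start_year = 2001,
                    trend = trend_spec(amplitude_rate = 0.05))
  wt <- weekly_trends(x)
  weekly_total <- sum(7 * wt$slope)
  yr <- as.integer(format(x$date, "%Y"))
  annual <- tapply(x$gpp, yr, sum)
  annual_trend <- unname(coef(lm(annual ~ seq_along(annual)))[2])
  expect_equal(weekly_total, annual_trend, tolerance = 0.02 * abs(annual_trend))
})
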