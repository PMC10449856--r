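#' Extract one calendar year with edge padding
#'
#' Returns the focal year's daily GPP flanked by `pad_days` days on each side
#' so that smoothing has support beyond the year boundaries: the last
#' `pad_days` of the preceding and the first `pad_days` of the following
#' calendar year. At the edges of the record, where no neighbouring year
#' exists, the same year's own last/first `pad_days` stand in, which keeps the
#' pad's seasonal state (dormant-season values for mid-latitude sites)
#' appropriate.
#'
#' @param series A [daily_flux()] series.
#' @param year Focal calendar year; must be fully covered by the date grid.
#' @param pad_days Pad length in days (default 30); 0 returns the bare year.
#' @return Data frame with `rel_day` (1..days-in-year indexes the focal year;
#'   the pads run negative/beyond) and `gpp`.
#' @export
pad_year <- function(series, year, pad_days = 30L) {
  stopifnot(inherits(series, "daily_flux"), pad_days >= 0)
  yr <- as.integer(format(series$date, "%Y"))
  focal <- which(yr == year)
  n <- days_in_year(year)
  if (!length(focal)) stop("focal year ", year, " absent from series")
  if (length(focal) < n) stop("focal year ", year, " not fully covered")
  g <- series$gpp
  pre <- if (pad_days == 0) numeric(0)
    else if (focal[1] > pad_days) g[focal[1] - (pad_days:1)]
    else g[focal[n - pad_days + (1:pad_days)]]
  post <- if (pad_days == 0) numeric(0)
    else if (focal[n] + pad_days <= length(g)) g[focal[n] + (1:pad_days)]
    else g[focal[1:pad_days]]
  data.frame(rel_day = seq.int(1L - pad_days, n + pad_days),
             gpp = c(pre, g[focal], post))
}

#' Cumulative sum of a daily GPP segment
#'
#' Running sum of daily GPP in which a missing day contributes a zero
#' increment (a flat step). The cumulative curve integrates away much of the
#' day-to-day flux noise, which is what makes smoothing it more stable than
#' smoothing the raw signal; the zero-increment convention keeps it
#' non-decreasing for non-negative GPP.
#'
#' @param gpp Numeric vector of daily GPP for a contiguous segment; `NA`
#'   allowed.
#' @return Numeric vector of the same length.
#' @export
cumulative_integral <- function(gpp) {
  gpp[is.na(gpp)] <- 0
  cumsum(gpp)
}

#' Least-squares cubic regression spline
#'
#' Fits a cubic regression spline with `knots` interior knots placed at
#' equally spaced quantiles of the predictor, by ordinary least squares on
#' the B-spline basis. The number of interior knots is the single smoothing
#' control. The returned object evaluates the fitted curve and its exact
#' derivatives from the spline coefficients.
#'
#' @param x Predictor (day index).
#' @param y Response; `NA` values are dropped from the fit.
#' @param knots Number of interior knots (>= 4).
#' @return An object of class `pheno_spline`; see [predict.pheno_spline()].
#' @export
spline_fit <- function(x, y, knots) {
  stopifnot(knots >= 4)
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < knots + 4)
    stop("too few data points (", sum(keep), ") for ", knots,
         " interior knots")
  b <- range(x[keep])
  probs <- seq(0, 1, length.out = knots + 2)[-c(1, knots + 2)]
  ik <- as.numeric(quantile(x[keep], probs, names = FALSE))
  eps <- 1e-8 * diff(b)
  ik <- pmin(pmax(ik, b[1] + eps), b[2] - eps)
  kv <- c(rep(b[1], 4), ik, rep(b[2], 4))
  X <- splines::splineDesign(kv, x[keep], ord = 4)
  fit <- stats::lm.fit(X, y[keep])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  structure(list(knot_vector = kv, coef = unname(beta), boundary = b),
            class = "pheno_spline")
}

#' Evaluate a fitted regression spline or its derivatives
#'
#' @param object A `pheno_spline` from [spline_fit()].
#' @param x Evaluation points; clamped to the fitted range.
#' @param deriv Derivative order (0 = the curve itself).
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.pheno_spline <- function(object, x, deriv = 0L, ...) {
  xc <- pmin(pmax(x, object$boundary[1]), object$boundary[2])
  X <- splines::splineDesign(object$knot_vector, xc, ord = 4,
                             derivs = rep(deriv, length(xc)))
  drop(X %*% object$coef)
}

new_smoothed_year <- function(site_id, year, gpp_smooth, method, param,
                              fit = NULL, deriv_order = NA_integer_) {
  n <- length(gpp_smooth)
  structure(data.frame(site_id = site_id, year = year, doy = seq_len(n),
                       gpp_smooth = gpp_smooth, method = method,
                       param = param, stringsAsFactors = FALSE),
            fit = fit, deriv_order = deriv_order,
            class = c("smoothed_year", "data.frame"))
}

check_missing_year <- function(series, year) {
  yr <- as.integer(format(series$date, "%Y"))
  g <- series$gpp[yr == year]
  mf <- mean(is.na(g))
  if (mf > 0.1)
    warning(sprintf("year %d has %.0f%% missing GPP; smoothing may be biased",
                    year, 100 * mf))
  invisible(mf)
}

#' Integral smoothing of one year of daily GPP
#'
#' Smooths the seasonal GPP cycle indirectly: the padded year's *cumulative*
#' GPP is fitted with a cubic regression spline and the smoothed GPP is the
#' analytic first derivative of that fit, evaluated daily over the focal year
#' (pads dropped). Because the cumulative curve has a far higher
#' signal-to-noise ratio than the raw daily fluxes, the result depends much
#' less on the user-chosen number of knots than direct smoothing does — see
#' [knot_sensitivity()].
#'
#' Fewer than 6 knots over-smooths the seasonal transitions and is refused
#' unless `allow_low_knots = TRUE`; many more than ~18 starts chasing
#' synoptic-scale variability.
#'
#' @param series A [daily_flux()] series.
#' @param year Focal calendar year.
#' @param knots Interior knots for the spline on the cumulative curve
#'   (default 10).
#' @param pad_days Edge pad in days (default 30).
#' @param allow_low_knots Permit `knots < 6`.
#' @return A `smoothed_year` data frame (`site_id`, `year`, `doy`,
#'   `gpp_smooth`, `method = "integral_spline"`, `param`), with the fitted
#'   spline attached so derivative-based phenometrics stay analytic.
#' @export
integral_smooth <- function(series, year, knots = 10L, pad_days = 30L,
                            allow_low_knots = FALSE) {
  if (knots < 6 && !allow_low_knots)
    stop("knots < 6 over-smooths seasonal transitions; ",
         "set allow_low_knots = TRUE to override")
  check_missing_year(series, year)
  seg <- pad_year(series, year, pad_days)
  cum <- cumulative_integral(seg$gpp)
  fit <- spline_fit(seg$rel_day, cum, knots)
  doy <- seq_len(days_in_year(year))
  new_smoothed_year(series$site_id[1], year, predict(fit, doy, deriv = 1L),
                    "integral_spline", knots, fit = fit, deriv_order = 1L)
}

#' Direct smoothing of one year of daily GPP
#'
#' Conventional smoothing of the raw daily GPP over the padded year, by a
#' cubic regression spline (`param` = interior knots) or lowess (`param` =
#' smoothing fraction in (0, 1\]); the pads are dropped afterwards. Missing
#' days are excluded from the fit.
#'
#' @inheritParams integral_smooth
#' @param method `"spline"` or `"lowess"`.
#' @param param Interior knots (spline, default 7) or lowess fraction
#'   (default 0.5).
#' @return A `smoothed_year` data frame with method `"direct_spline"` or
#'   `"direct_lowess"`.
#' @export
direct_smooth <- function(series, year, method = c("spline", "lowess"),
                          param = NULL, pad_days = 30L,
                          allow_low_knots = FALSE) {
  method <- match.arg(method)
  check_missing_year(series, year)
  seg <- pad_year(series, year, pad_days)
  doy <- seq_len(days_in_year(year))
  if (method == "spline") {
    if (is.null(param)) param <- 7L
    if (param < 6 && !allow_low_knots)
      stop("knots < 6 over-smooths seasonal transitions; ",
           "set allow_low_knots = TRUE to override")
    fit <- spline_fit(seg$rel_day, seg$gpp, param)
    new_smoothed_year(series$site_id[1], year, predict(fit, doy),
                      "direct_spline", param, fit = fit, deriv_order = 0L)
  } else {
    if (is.null(param)) param <- 0.5
    if (param <= 0 || param > 1)
      stop("lowess fraction must lie in (0, 1]")
    keep <- !is.na(seg$gpp)
    lw <- lowess(seg$rel_day[keep], seg$gpp[keep], f = param)
    vals <- approx(lw$x, lw$y, xout = doy, rule = 2)$y
    new_smoothed_year(series$site_id[1], year, vals, "direct_lowess", param)
  }
}

#' Sensitivity of smoothed GPP to the number of spline knots
#'
#' Recomputes the smoothed seasonal curve for every knot count in
#' `knot_range`, for both direct spline smoothing and integral smoothing,
#' and summarizes the spread as the across-knot standard deviation of the
#' smoothed GPP averaged over days (and over `years`). A smaller sigma means
#' the method is more objective: the analyst's knot choice matters less.
#'
#' @param series A [daily_flux()] series.
#' @param years Calendar years to include.
#' @param knot_range Integer vector of interior knot counts (default 5:18).
#' @param pad_days Edge pad in days.
#' @return One-row data frame of class `sensitivity_result` with
#'   `sigma_dir`, `sigma_int` (gC m\eqn{^{-2}} d\eqn{^{-1}}) and their
#'   difference `sigma_diff = sigma_dir - sigma_int`.
#' @export
knot_sensitivity <- function(series, years, knot_range = 5:18,
                             pad_days = 30L) {
  stopifnot(length(knot_range) >= 1)
  per_year <- vapply(years, function(y) {
    mat_d <- vapply(knot_range, function(k)
      direct_smooth(series, y, "spline", k, pad_days,
                    allow_low_knots = TRUE)$gpp_smooth,
      numeric(days_in_year(y)))
    mat_i <- vapply(knot_range, function(k)
      integral_smooth(series, y, k, pad_days,
                      allow_low_knots = TRUE)$gpp_smooth,
      numeric(days_in_year(y)))
    day_sd <- function(m) if (ncol(m) < 2) rep(0, nrow(m)) else
      apply(m, 1, sd)
    c(dir = mean(day_sd(mat_d)), int = mean(day_sd(mat_i)))
  }, numeric(2))
  sigma_dir <- mean(per_year["dir", ])
  sigma_int <- mean(per_year["int", ])
  structure(data.frame(site_id = series$site_id[1], sigma_dir = sigma_dir,
                       sigma_int = sigma_int,
                       sigma_diff = sigma_dir - sigma_int,
                       knot_min = min(knot_range), knot_max = max(knot_range),
                       n_years = length(years), stringsAsFactors = FALSE),
            class = c("sensitivity_result", "data.frame"))
}
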