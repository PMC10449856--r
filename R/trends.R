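#' Theil-Sen trend estimate with Mann-Kendall significance
#'
#' The Theil-Sen slope is the median of all pairwise slopes
#' \eqn{(y_j - y_i)/(t_j - t_i)} over years \eqn{i < j}; being a median it is
#' robust to the outlier years that short flux records are prone to. The
#' denominator is the difference in calendar years, so series with missing
#' years remain valid. Significance is the two-sided Mann-Kendall test
#' (normal approximation with continuity and tie correction), and the 95%
#' confidence interval is Sen's rank-based interval: order statistics of the
#' enumerated pairwise slopes at ranks set by the Mann-Kendall variance.
#'
#' @param years Calendar years (strictly increasing after removing `NA`
#'   pairs; duplicated years, as arise in bootstrap resamples, contribute no
#'   pairwise slope but are tie-corrected in the variance).
#' @param values Metric values (days, for PTD series); `NA` dropped pairwise.
#' @param conf_level Confidence level for Sen's interval (default 0.95).
#' @return An object of class `trend_result`: list with `slope` (per year),
#'   `slope_per_decade`, `ci_low`, `ci_high` (per year), `p_value`, `n`,
#'   `n_pairs`, `s_statistic`.
#' @examples
#' theil_sen(2001:2005, c(1, 2, 4, 3, 5))
#' @export
theil_sen <- function(years, values, conf_level = 0.95) {
  keep <- is.finite(years) & is.finite(values)
  years <- years[keep]; values <- values[keep]
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  o <- order(years)
  years <- years[o]; values <- values[o]
  if (all(years == years[1])) stop("all years identical; no trend defined")

  dy <- outer(values, values, "-")
  dt <- outer(years, years, "-")
  lower <- lower.tri(dt)                      # pairs i < j in year order
  ok <- lower & dt != 0
  slopes <- dy[ok] / dt[ok]
  slope <- median(slopes)

  s_stat <- sum(sign(dy[ok]))
  # Mann-Kendall variance with tie corrections in values and in years
  tie_term <- function(x) {
    t <- table(x); t <- t[t > 1]
    c(sum(t * (t - 1) * (2 * t + 5)), sum(t * (t - 1) * (t - 2)),
      sum(t * (t - 1)))
  }
  tv <- tie_term(values); tu <- tie_term(years)
  var_s <- (n * (n - 1) * (2 * n + 5) - tv[1] - tu[1]) / 18
  if (n > 2)
    var_s <- var_s + tv[2] * tu[2] / (9 * n * (n - 1) * (n - 2))
  var_s <- var_s + tv[3] * tu[3] / (2 * n * (n - 1))

  if (var_s <= 0) {
    p <- 1
    ci <- c(slope, slope)
  } else {
    z <- (s_stat - sign(s_stat)) / sqrt(var_s)
    p <- min(1, 2 * pnorm(-abs(z)))
    ns <- length(slopes)
    srt <- sort(slopes)
    c_alpha <- qnorm(1 - (1 - conf_level) / 2) * sqrt(var_s)
    l_idx <- max(1L, as.integer(round((ns - c_alpha) / 2)))
    u_idx <- min(ns, as.integer(round((ns + c_alpha) / 2)) + 1L)
    ci <- c(srt[l_idx], srt[u_idx])
  }
  structure(list(slope = slope, slope_per_decade = 10 * slope,
                 ci_low = ci[1], ci_high = ci[2], p_value = p,
                 n = n, n_pairs = length(slopes), s_statistic = s_stat),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Theil-Sen trend: %.4f per year (%.2f per decade), 95%% CI [%.4f, %.4f], MK p = %.4g (n = %d)\n",
    x$slope, x$slope_per_decade, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

# Pull one (metric, threshold/derivative) annual series out of a PTD table.
metric_series <- function(ptd_table, metric = c("SOS", "EOS", "GSL"),
                          threshold = NULL) {
  metric <- match.arg(metric)
  sub <- if (is.null(threshold))
    ptd_table[ptd_table$method == "derivative", ]
  else
    ptd_table[ptd_table$method == "threshold" &
                !is.na(ptd_table$threshold) &
                abs(ptd_table$threshold - threshold) < 1e-9, ]
  col <- c(SOS = "sos", EOS = "eos", GSL = "gsl")[[metric]]
  ok <- is.finite(sub[[col]])
  if (metric == "GSL") ok <- ok & is.finite(sub$sos) & is.finite(sub$eos)
  list(years = sub$year[ok], values = sub[[col]][ok])
}

#' Growing-season-length trend as the trend of the difference
#'
#' The trend in GSL is the Theil-Sen trend of the per-year series
#' EOS \eqn{-} SOS over years where both dates exist — not the difference of
#' the EOS and SOS trends. The two definitions coincide only for exactly
#' linear series; the median of pairwise slopes is not additive, so the
#' difference-of-trends shortcut is biased on nonlinear records.
#'
#' @param ptd_table A `ptd_table` from [extract_all()] (one site).
#' @param threshold Grid threshold, or `NULL` for the derivative method.
#' @param conf_level Confidence level passed to [theil_sen()].
#' @return A `trend_result`.
#' @export
gsl_trend <- function(ptd_table, threshold = NULL, conf_level = 0.95) {
  s <- metric_series(ptd_table, "GSL", threshold)
  if (length(s$years) < 2)
    stop("fewer than 2 years with both SOS and EOS")
  theil_sen(s$years, s$values, conf_level)
}

#' Trend table across the threshold grid
#'
#' One Theil-Sen trend per metric (SOS, EOS, GSL) and per grid threshold,
#' plus the derivative method, for one site's PTD table. Slopes are reported
#' both per year and per decade (slope x 10), the conventional unit for
#' phenological trends. Failures in a single cell (too few years, degenerate
#' series) are recorded in `issues`, not fatal.
#'
#' @param ptd_table A `ptd_table` from [extract_all()] (one site).
#' @param conf_level Confidence level for Sen's interval.
#' @return Data frame with columns `site_id`, `metric`, `method`,
#'   `threshold`, `slope`, `slope_per_decade`, `ci_low`, `ci_high`,
#'   `p_value`, `n_years`, `issues`.
#' @export
trends_by_threshold <- function(ptd_table, conf_level = 0.95) {
  site <- ptd_table$site_id[1]
  grid <- sort(unique(ptd_table$threshold[ptd_table$method == "threshold" &
                                            !is.na(ptd_table$threshold)]))
  entries <- c(as.list(grid), list(NULL))
  rows <- lapply(entries, function(th) {
    do.call(rbind, lapply(c("SOS", "EOS", "GSL"), function(m) {
      s <- metric_series(ptd_table, m, th)
      res <- tryCatch(theil_sen(s$years, s$values, conf_level),
                      error = function(e) e)
      if (inherits(res, "error"))
        data.frame(site_id = site, metric = m,
                   method = if (is.null(th)) "derivative" else "threshold",
                   threshold = if (is.null(th)) NA_real_ else th,
                   slope = NA_real_, slope_per_decade = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                   n_years = length(s$years),
                   issues = conditionMessage(res), stringsAsFactors = FALSE)
      else
        data.frame(site_id = site, metric = m,
                   method = if (is.null(th)) "derivative" else "threshold",
                   threshold = if (is.null(th)) NA_real_ else th,
                   slope = res$slope, slope_per_decade = res$slope_per_decade,
                   ci_low = res$ci_low, ci_high = res$ci_high,
                   p_value = res$p_value, n_years = res$n,
                   issues = "", stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Threshold-uncertainty classification of trend estimates
#'
#' A site's trend in a phenological metric is "uncertain" when it depends
#' strongly on the analyst's threshold choice: the standard deviation (ddof
#' 1) of the per-threshold Theil-Sen slopes, in days per decade, exceeds the
#' metric's cutoff — 0.5 days/decade for SOS and EOS, 1 day/decade for GSL
#' (GSL compounds the spread of both dates). The derivative-method trend is
#' reported alongside but excluded from the spread, which is defined across
#' thresholds only. A confidence interval for the spread itself comes from
#' bootstrapping whole years with replacement and recomputing all
#' per-threshold trends, preserving the within-year threshold structure.
#'
#' @param ptd_table A `ptd_table` from [extract_all()] (one site).
#' @param cutoffs Named vector of cutoffs in days/decade.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Percentile CI level for the bootstrap (default 0.95).
#' @return Data frame, one row per metric: `sigma_trend` (days/decade),
#'   `flag`, `boot_ci_low`, `boot_ci_high`, `n_thresholds`, `issues`.
#' @export
classify_uncertainty <- function(ptd_table,
                                 cutoffs = c(SOS = 0.5, EOS = 0.5, GSL = 1),
                                 n_boot = 1000L, seed = NULL,
                                 conf_level = 0.95) {
  site <- ptd_table$site_id[1]
  grid <- sort(unique(ptd_table$threshold[ptd_table$method == "threshold" &
                                            !is.na(ptd_table$threshold)]))
  slopes_for <- function(tbl, metric) {
    vapply(grid, function(th) {
      s <- metric_series(tbl, metric, th)
      tryCatch(10 * theil_sen(s$years, s$values)$slope,
               error = function(e) NA_real_)
    }, numeric(1))
  }
  years <- sort(unique(ptd_table$year))
  alpha <- (1 - conf_level) / 2

  rows <- lapply(c("SOS", "EOS", "GSL"), function(m) {
    sl <- slopes_for(ptd_table, m)
    valid <- sum(is.finite(sl))
    if (valid < 2)
      return(data.frame(site_id = site, metric = m, sigma_trend = NA_real_,
                        flag = NA, boot_ci_low = NA_real_,
                        boot_ci_high = NA_real_, n_thresholds = valid,
                        issues = "fewer than 2 valid per-threshold trends",
                        stringsAsFactors = FALSE))
    sigma <- sd(sl, na.rm = TRUE)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ys <- sample(years, length(years), replace = TRUE)
        tbl <- do.call(rbind, lapply(ys, function(y)
          ptd_table[ptd_table$year == y, ]))
        bs <- slopes_for(tbl, m)
        if (sum(is.finite(bs)) < 2) NA_real_ else sd(bs, na.rm = TRUE)
      }, numeric(1))
    })
    ci <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
    data.frame(site_id = site, metric = m, sigma_trend = sigma,
               flag = sigma > cutoffs[[m]], boot_ci_low = ci[1],
               boot_ci_high = ci[2], n_thresholds = valid, issues = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
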