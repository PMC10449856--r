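#' Seasonal-cycle specification for the synthetic flux generator
#'
#' Describes one smooth unimodal growing season as a double-logistic curve:
#' a rising logistic branch (green-up) minus a falling one (senescence),
#' scaled by an amplitude and sitting on a winter baseline,
#' \deqn{g(t) = b + A\,[\mathrm{logit}^{-1}(k_s(t - t_s)) -
#'   \mathrm{logit}^{-1}(k_e(t - t_e))].}
#' The double logistic is the standard parametric form for seasonal GPP and
#' greenness curves; its inflections and half-heights are analytic, which is
#' what makes exact ground-truth transition dates ([true_ptd()]) possible.
#'
#' @param amplitude_gpp Seasonal amplitude \eqn{A} above the baseline
#'   (gC m\eqn{^{-2}} d\eqn{^{-1}}), > 0.
#' @param baseline_gpp Winter baseline \eqn{b} (gC m\eqn{^{-2}} d\eqn{^{-1}}),
#'   >= 0.
#' @param sos_inflection_doy,eos_inflection_doy Day-of-year of the green-up /
#'   senescence inflection points \eqn{t_s < t_e} (real-valued; before any
#'   phase shift).
#' @param sos_slope,eos_slope Logistic steepness \eqn{k_s, k_e} (d\eqn{^{-1}}),
#'   > 0. Roughly, the rise from 12% to 88% of amplitude takes \eqn{4/k} days.
#' @param phase_shift_doy Circular phase shift in days. 0 keeps a
#'   northern-hemisphere mid-year peak; ~182 moves the peak to the year
#'   boundary, emulating a southern-hemisphere site whose growing season
#'   straddles two calendar years.
#' @param second_season Optional second `season_spec` added to the first to
#'   build a bimodal year (double-cropping, Mediterranean sites). Its seasonal
#'   integral (amplitude x inflection spacing) must be strictly smaller than
#'   the primary season's so the "most productive season" is unambiguous.
#'
#' @return An object of class `season_spec`.
#' @seealso [generate_series()], [true_ptd()]
#' @export
season_spec <- function(amplitude_gpp, baseline_gpp = 0,
                        sos_inflection_doy, eos_inflection_doy,
                        sos_slope, eos_slope,
                        phase_shift_doy = 0, second_season = NULL) {
  stopifnot(amplitude_gpp > 0, baseline_gpp >= 0,
            sos_slope > 0, eos_slope > 0,
            eos_inflection_doy > sos_inflection_doy)
  if (!is.null(second_season)) {
    stopifnot(inherits(second_season, "season_spec"))
    if (!is.null(second_season$second_season))
      stop("only one secondary season is supported")
    int1 <- amplitude_gpp * (eos_inflection_doy - sos_inflection_doy)
    int2 <- second_season$amplitude_gpp *
      (second_season$eos_inflection_doy - second_season$sos_inflection_doy)
    if (int2 >= int1)
      stop("second season's integral must be strictly smaller than the primary season's")
  }
  structure(list(amplitude_gpp = amplitude_gpp, baseline_gpp = baseline_gpp,
                 sos_inflection_doy = sos_inflection_doy,
                 eos_inflection_doy = eos_inflection_doy,
                 sos_slope = sos_slope, eos_slope = eos_slope,
                 phase_shift_doy = phase_shift_doy,
                 second_season = second_season),
            class = "season_spec")
}

#' Year-over-year trend specification for the synthetic generator
#'
#' Linear drifts imposed on the seasonal cycle: in simulation year `k`
#' (0-based) the green-up inflection sits at
#' `sos_inflection_doy + k * sos_shift_rate`, and analogously for the
#' senescence inflection and the amplitude. Per-week GPP drifts can be
#' superimposed to plant localized productivity trends.
#'
#' @param sos_shift_rate,eos_shift_rate Inflection drift in days yr\eqn{^{-1}}
#'   (negative `sos_shift_rate` = advancing spring).
#' @param amplitude_rate Amplitude drift in gC m\eqn{^{-2}} d\eqn{^{-1}}
#'   yr\eqn{^{-1}}.
#' @param weekly_overrides Named numeric vector mapping week index (1-52,
#'   week w = days 7(w-1)+1..7w) to an additive GPP drift
#'   (gC m\eqn{^{-2}} d\eqn{^{-1}} yr\eqn{^{-1}}) applied to every day of
#'   that week.
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(sos_shift_rate = 0, eos_shift_rate = 0,
                       amplitude_rate = 0, weekly_overrides = NULL) {
  if (!is.null(weekly_overrides)) {
    wk <- as.integer(names(weekly_overrides))
    if (anyNA(wk) || any(wk < 1L | wk > 52L))
      stop("weekly_overrides must be named by week indices 1-52")
  }
  structure(list(sos_shift_rate = sos_shift_rate,
                 eos_shift_rate = eos_shift_rate,
                 amplitude_rate = amplitude_rate,
                 weekly_overrides = weekly_overrides),
            class = "trend_spec")
}

#' Noise and data-gap specification for the synthetic generator
#'
#' Daily noise is Gaussian and heteroscedastic: the standard deviation is
#' `noise_sd_frac` times the instantaneous noise-free signal, floored at 5%
#' of the seasonal amplitude so winter days are not noise-free. This mimics
#' how random flux error scales with flux magnitude. A fraction `gap_frac`
#' of days, drawn uniformly, is flagged poor-quality (`nee_qc = 0`).
#'
#' @param noise_sd_frac Noise standard deviation as a fraction of the daily
#'   signal (>= 0).
#' @param gap_frac Fraction of days flagged poor-quality (0 <= gap_frac < 1).
#' @param rng_seed Integer seed; the generator is deterministic given the
#'   seed and restores the caller's RNG state.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(noise_sd_frac = 0, gap_frac = 0, rng_seed = 1L) {
  stopifnot(noise_sd_frac >= 0, gap_frac >= 0, gap_frac < 1)
  structure(list(noise_sd_frac = noise_sd_frac, gap_frac = gap_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "noise_spec")
}

# Unphased double-logistic of one season in simulation year k, without
# baseline. `t` may be fractional.
dl_branch_value <- function(t, season, k = 0, trend = trend_spec()) {
  ts <- season$sos_inflection_doy + k * trend$sos_shift_rate
  te <- season$eos_inflection_doy + k * trend$eos_shift_rate
  stats::plogis(season$sos_slope * (t - ts)) -
    stats::plogis(season$eos_slope * (t - te))
}

# Noise-free GPP at calendar day-of-year `doy` of simulation year k
# (vectorized over both), including baseline, amplitude drift, optional
# second season and circular phase shift. The phase wrap is taken modulo
# 365; the leap day replays the curve value one day into the wrap, which
# keeps the series continuous.
clean_gpp <- function(doy, season, trend, k) {
  p <- season$phase_shift_doy
  u <- ((doy - 1 - p) %% 365) + 1
  amp <- season$amplitude_gpp + k * trend$amplitude_rate
  if (any(amp <= 0))
    stop("amplitude drift drove the seasonal amplitude below zero")
  g <- amp * dl_branch_value(u, season, k, trend)
  if (!is.null(season$second_season)) {
    s2 <- season$second_season
    g <- g + s2$amplitude_gpp * dl_branch_value(u, s2, k, trend_spec())
  }
  season$baseline_gpp + g
}

# Width of the season support at a tiny tail threshold; used to reject
# phase-shifted configurations whose season cannot fit one calendar year.
season_support_days <- function(season) {
  tail_gap <- log(0.99 / 0.01)
  (season$eos_inflection_doy - season$sos_inflection_doy) +
    tail_gap * (1 / season$sos_slope + 1 / season$eos_slope)
}

#' Simulate a multi-year daily GPP series with known phenology
#'
#' Builds a calendar-dated daily GPP record (leap days included) from a
#' double-logistic seasonal cycle with imposed year-over-year drifts,
#' heteroscedastic Gaussian noise and poor-quality gaps. The output uses the
#' same container as tower data read with [read_daily_flux()], so every
#' downstream stage (smoothing, transition-date extraction, trends) runs
#' unchanged on simulated input, with [true_ptd()] providing exact ground
#' truth.
#'
#' @param season A [season_spec()].
#' @param trend A [trend_spec()].
#' @param noise A [noise_spec()].
#' @param n_years Number of simulated calendar years (>= 1).
#' @param start_year First calendar year.
#' @param site_id Site label stored in the series.
#' @return A `daily_flux` data frame (see [daily_flux()]) with columns
#'   `site_id`, `date`, `gpp`, `nee_qc`; `nee_qc` is 1 on clean days and 0 on
#'   gap days.
#' @examples
#' se <- season_spec(10, 1, 120, 280, 0.1, 0.1)
#' x <- generate_series(se, trend_spec(sos_shift_rate = -0.3),
#'                      noise_spec(0.1, 0.05, rng_seed = 42), n_years = 5,
#'                      start_year = 2000)
#' range(x$date)
#' @export
generate_series <- function(season, trend = trend_spec(),
                            noise = noise_spec(), n_years, start_year = 2000L,
                            site_id = "SYN-001") {
  stopifnot(inherits(season, "season_spec"), inherits(trend, "trend_spec"),
            inherits(noise, "noise_spec"), n_years >= 1)
  if (season$phase_shift_doy != 0 && season_support_days(season) > 366)
    stop("phase-shifted season support exceeds 366 days; it cannot wrap a calendar year")

  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1L)),
               by = "day")
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  k <- yr - start_year

  clean <- clean_gpp(doy, season, trend, k)
  if (!is.null(trend$weekly_overrides)) {
    week <- (doy - 1L) %/% 7L + 1L             # days 365/366 land in week 53
    for (w in names(trend$weekly_overrides)) {
      sel <- week == as.integer(w)
      clean[sel] <- clean[sel] + k[sel] * trend$weekly_overrides[[w]]
    }
  }

  with_seed(noise$rng_seed, {
    gpp <- clean
    if (noise$noise_sd_frac > 0) {
      sdv <- noise$noise_sd_frac * pmax(clean, 0.05 * season$amplitude_gpp)
      gpp <- clean + rnorm(length(clean), sd = sdv)
    }
    qc <- rep(1, length(clean))
    if (noise$gap_frac > 0) {
      n_gap <- round(noise$gap_frac * length(clean))
      qc[sample.int(length(clean), n_gap)] <- 0
    }
    daily_flux(site_id, dates, gpp, qc)
  })
}

#' Exact transition dates of the noise-free synthetic seasonal curve
#'
#' Closed-form threshold-crossing days of the normalized double-logistic for
#' simulation year `year_index`, obtained by inverting each logistic branch
#' analytically: the green-up branch crosses a normalized threshold \eqn{q} at
#' \eqn{t_s + \log(q/(1-q))/k_s} and the senescence branch at
#' \eqn{t_e - \log(q/(1-q))/k_e}. Branches are treated independently, which
#' is exact in the limit of well-separated inflections (the regime the
#' fixtures use). For bimodal specifications the primary (most productive)
#' season governs. Results are mapped through the circular phase shift to
#' signed day coordinates of the calendar year containing the seasonal peak,
#' so a southern-hemisphere green-up may legitimately be reported as a
#' non-positive day (previous calendar year).
#'
#' @param season A [season_spec()].
#' @param trend A [trend_spec()] (only the inflection drifts matter here).
#' @param year_index 0-based simulation year.
#' @param threshold Normalized threshold in (0, 1).
#' @return A list with `sos`, `eos` (signed fractional day coordinates) and
#'   `gsl = eos - sos`.
#' @export
true_ptd <- function(season, trend = trend_spec(), year_index = 0,
                     threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  k <- year_index
  ts <- season$sos_inflection_doy + k * trend$sos_shift_rate
  te <- season$eos_inflection_doy + k * trend$eos_shift_rate
  # normalized peak of the double logistic; < 1 when branches overlap
  pk <- stats::optimize(function(t) dl_branch_value(t, season, k, trend),
                        interval = c(ts - 20 / season$sos_slope,
                                     te + 20 / season$eos_slope),
                        maximum = TRUE)
  if (threshold >= pk$objective)
    stop_phenoflux(sprintf(
      "threshold %.3f is never reached (normalized seasonal maximum %.3f)",
      threshold, pk$objective), "phenoflux_no_season")
  lo <- log(threshold / (1 - threshold))
  sos <- ts + lo / season$sos_slope
  eos <- te - lo / season$eos_slope
  p <- season$phase_shift_doy
  if (p != 0) {
    peak_cal <- ((pk$maximum + p - 1) %% 365) + 1
    shift <- (pk$maximum + p) - peak_cal        # multiple of 365
    sos <- sos + p - shift
    eos <- eos + p - shift
  }
  list(sos = sos, eos = eos, gsl = eos - sos)
}

#' Write a synthetic series with a sidecar parameter file
#'
#' Writes the series in the FLUXNET FULLSET CSV dialect (via
#' [write_daily_flux()]) and a plain key-value text file recording every
#' generator parameter and the RNG seed, so a simulated dataset is fully
#' reproducible from its files alone.
#'
#' @param series A `daily_flux` series from [generate_series()].
#' @param csv_path Output CSV path.
#' @param season,trend,noise The specification objects used to generate it.
#' @param sidecar_path Output text path; default replaces the CSV extension
#'   with `_params.txt`.
#' @return Invisibly, the sidecar path.
#' @export
write_synthetic <- function(series, csv_path, season, trend, noise,
                            sidecar_path = sub("\\.csv$", "_params.txt",
                                               csv_path)) {
  write_daily_flux(series, csv_path)
  kv <- c(site_id = series$site_id[1],
          amplitude_gpp = season$amplitude_gpp,
          baseline_gpp = season$baseline_gpp,
          sos_inflection_doy = season$sos_inflection_doy,
          eos_inflection_doy = season$eos_inflection_doy,
          sos_slope = season$sos_slope, eos_slope = season$eos_slope,
          phase_shift_doy = season$phase_shift_doy,
          bimodal = as.integer(!is.null(season$second_season)),
          sos_shift_rate = trend$sos_shift_rate,
          eos_shift_rate = trend$eos_shift_rate,
          amplitude_rate = trend$amplitude_rate,
          noise_sd_frac = noise$noise_sd_frac, gap_frac = noise$gap_frac,
          rng_seed = noise$rng_seed)
  if (!is.null(trend$weekly_overrides))
    kv <- c(kv, setNames(trend$weekly_overrides,
                         paste0("weekly_override_",
                                names(trend$weekly_overrides))))
  writeLines(paste(names(kv), kv, sep = " = "), sidecar_path)
  invisible(sidecar_path)
}
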