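# Shared fixtures: a canonical temperate unimodal season and small builders.

std_season <- function(...) {
  season_spec(amplitude_gpp = 10, baseline_gpp = 1,
              sos_inflection_doy = 120, eos_inflection_doy = 280,
              sos_slope = 0.1, eos_slope = 0.1, ...)
}

quick_series <- function(n_years = 3, seed = 1, noise = 0, gaps = 0,
                         season = std_season(), trend = trend_spec(),
                         start_year = 2001, site_id = "SYN-001") {
  generate_series(season, trend, noise_spec(noise, gaps, seed), n_years,
                  start_year, site_id)
}

# Noise-free closed-form daily curve for a given simulation year.
clean_curve <- function(doy, season = std_season(), trend = trend_spec(),
                        k = 0) {
  phenoflux:::clean_gpp(doy, season, trend, k)
}

# A smoothed_year built directly from values (no fit attached), for unit
# tests of normalization/peak/crossing logic on hand-crafted shapes.
make_smoothed <- function(vals, year = 2001, site = "TST") {
  phenoflux:::new_smoothed_year(site, year, vals, "direct_spline", 7)
}

# Symmetric triangle curve over a 365-day year, apex at `peak`.
triangle_year <- function(peak = 183, height = 10) {
  doy <- 1:365
  height * pmax(0, 1 - abs(doy - peak) / (peak - 1))
}

# Brute-force Theil-Sen + order-statistics oracle: explicit double loop.
bf_theil_sen <- function(years, values) {
  sl <- c()
  n <- length(values)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (years[j] != years[i])
      sl <- c(sl, (values[j] - values[i]) / (years[j] - years[i]))
  list(slope = median(sl), slopes = sort(sl))
}

# Minimal hand-built PTD table: per-threshold SOS/EOS linear in year.
toy_ptd_table <- function(site = "TST", years = 2001:2010,
                          thresholds = seq(0.1, 0.7, 0.05),
                          sos_slope_fun = function(th) 0,
                          eos_slope_fun = function(th) 0) {
  rows <- do.call(rbind, lapply(thresholds, function(th) {
    k <- years - years[1]
    data.frame(site_id = site, year = years, method = "threshold",
               threshold = th, sos = 100 + k * sos_slope_fun(th),
               eos = 280 + k * eos_slope_fun(th),
               gsl = 180 + k * (eos_slope_fun(th) - sos_slope_fun(th)),
               issues = "", stringsAsFactors = FALSE)
  }))
  class(rows) <- c("ptd_table", "data.frame")
  rows
}
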