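#' Min-max normalization of a smoothed year
#'
#' Rescales the smoothed seasonal GPP curve to \[0, 1\] using the focal
#' calendar year's minimum and maximum, so that threshold phenometrics are
#' comparable across sites and years regardless of absolute productivity.
#'
#' @param smooth A `smoothed_year` from [integral_smooth()] or
#'   [direct_smooth()].
#' @return A `normalized_year` data frame (`doy`, `gpp_smooth`, `gpp_norm`)
#'   carrying the year min/max and the spline fit as attributes.
#' @export
normalize_year <- function(smooth) {
  stopifnot(inherits(smooth, "smoothed_year"))
  g <- smooth$gpp_smooth
  lo <- min(g); hi <- max(g)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 1e-10 * max(abs(hi), 1))
    stop_phenoflux(sprintf("year %d is degenerate: smoothed GPP is flat",
                           smooth$year[1]), "phenoflux_degenerate_year")
  structure(data.frame(site_id = smooth$site_id, year = smooth$year,
                       doy = smooth$doy, gpp_smooth = g,
                       gpp_norm = (g - lo) / (hi - lo),
                       stringsAsFactors = FALSE),
            year_min = lo, year_max = hi,
            fit = attr(smooth, "fit"), deriv_order = attr(smooth, "deriv_order"),
            class = c("normalized_year", "data.frame"))
}

# Maximal runs where gpp_norm >= floor, as a data.frame of start/end indices.
season_segments <- function(norm, season_floor) {
  above <- norm$gpp_norm >= season_floor
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Day of the governing seasonal peak
#'
#' Splits the year into candidate growing seasons (maximal runs with
#' normalized GPP at or above `season_floor`) and selects the most productive
#' one — the run with the largest integral of smoothed GPP — so that years
#' with two growth cycles still yield a single start and end of season. Ties
#' go to the earliest run. Unimodal years reduce to the global argmax.
#'
#' @param norm A `normalized_year` from [normalize_year()].
#' @param season_floor Normalized level delimiting a growing season
#'   (default 0.2).
#' @return The day-of-year of the peak of the governing season.
#' @export
governing_peak <- function(norm, season_floor = 0.2) {
  stopifnot(inherits(norm, "normalized_year"))
  seg <- season_segments(norm, season_floor)
  if (!nrow(seg))
    stop_phenoflux("no growing season reaches the season floor",
                   "phenoflux_degenerate_year")
  integrals <- mapply(function(s, e) sum(norm$gpp_smooth[s:e]),
                      seg$start, seg$end)
  w <- which.max(integrals)                 # first maximum = earliest run
  idx <- seg$start[w]:seg$end[w]
  norm$doy[idx[which.max(norm$gpp_norm[idx])]]
}

new_ptd_record <- function(site_id, year, method, threshold, sos, eos,
                           issues = "") {
  data.frame(site_id = site_id, year = year, method = method,
             threshold = threshold, sos = sos, eos = eos, gsl = eos - sos,
             issues = issues, stringsAsFactors = FALSE)
}

# Interpolated x-coordinates of upward (dir = +1) or downward (dir = -1)
# crossings of `v` through `th` along coordinates `x`.
crossings <- function(x, v, th, dir, interpolate = TRUE) {
  i <- if (dir > 0) which(v[-length(v)] < th & v[-1] >= th)
       else         which(v[-length(v)] >= th & v[-1] < th)
  if (!length(i)) return(numeric(0))
  if (!interpolate) return(if (dir > 0) x[i + 1] else x[i])
  x[i] + (th - v[i]) / (v[i + 1] - v[i]) * (x[i + 1] - x[i])
}

#' Threshold-method transition dates for one year
#'
#' Finds where the normalized seasonal curve crosses a fixed threshold: the
#' start of season (SOS) is the upward crossing nearest to and before the
#' governing peak, the end of season (EOS) the downward crossing nearest to
#' and after it — the nearest-to-peak rule resolves the multiple crossings
#' that noisy shoulder seasons produce. Crossing days are located by linear
#' interpolation between the bracketing days, giving fractional day
#' coordinates (set `interpolate = FALSE` for integer days).
#'
#' When the curve does not cross the threshold twice within the focal year —
#' asymmetric seasons, or southern-hemisphere sites whose season straddles
#' the year boundary — the search continues into the neighbouring year's
#' normalized curve and the result is reported in signed day coordinates
#' relative to Jan 1 of the focal year: SOS <= 0 means the previous calendar
#' year, EOS beyond the year length means the next.
#'
#' @param norm Focal `normalized_year`.
#' @param threshold Normalized threshold in (0, 1); the conventional grid is
#'   0.1-0.7 in steps of 0.05.
#' @param prev,nxt Optional neighbouring `normalized_year`s for the
#'   cross-year search.
#' @param season_floor Passed to [governing_peak()].
#' @param interpolate Fractional-day crossings (default) or integer days.
#' @return A one-row `PTDRecord` data frame: `site_id`, `year`, `method`,
#'   `threshold`, `sos`, `eos`, `gsl = eos - sos`, `issues`.
#' @export
threshold_ptd <- function(norm, threshold, prev = NULL, nxt = NULL,
                          season_floor = 0.2, interpolate = TRUE) {
  stopifnot(threshold > 0, threshold < 1)
  peak <- governing_peak(norm, season_floor)
  n_focal <- nrow(norm)
  x <- norm$doy; v <- norm$gpp_norm
  if (!is.null(prev)) {
    x <- c(prev$doy - nrow(prev), x)
    v <- c(prev$gpp_norm, v)
  }
  if (!is.null(nxt)) {
    x <- c(x, nxt$doy + n_focal)
    v <- c(v, nxt$gpp_norm)
  }
  up <- crossings(x, v, threshold, +1, interpolate)
  dn <- crossings(x, v, threshold, -1, interpolate)
  up <- up[up <= peak]
  dn <- dn[dn >= peak]
  if (!length(up))
    stop_phenoflux(sprintf(
      "threshold %.2f not crossed upward before the peak (year %d)",
      threshold, norm$year[1]), "phenoflux_no_season")
  if (!length(dn))
    stop_phenoflux(sprintf(
      "threshold %.2f not crossed downward after the peak (year %d)",
      threshold, norm$year[1]), "phenoflux_no_season")
  new_ptd_record(norm$site_id[1], norm$year[1], "threshold", threshold,
                 max(up), min(dn))
}

#' First-derivative transition dates for one year
#'
#' Assigns SOS to the day with the maximum first derivative of the smoothed
#' GPP curve and EOS to the day with the minimum, searched on the daily grid
#' restricted to the governing season's rise (before the peak) and fall
#' (after it) so that secondary growth cycles cannot capture the extrema.
#' The derivative is evaluated analytically from the spline coefficients
#' when the smoothed year carries its fit (integral or direct spline
#' smoothing); otherwise central differences are used.
#'
#' Curves whose derivative is essentially constant over the rise or fall
#' (e.g. linear ramps) have no well-defined extremum; such records are
#' returned with a note in `issues` rather than an error.
#'
#' Note that the input should be a *direct* smooth of GPP (or any curve whose
#' first derivative varies smoothly). An integral-smoothed year is
#' unsuitable here: its GPP curve is already the first derivative of a cubic
#' fit, so its own derivative is piecewise linear and the extrema snap to
#' the fixed spline knots, which freezes the dates and destroys their
#' trends. [extract_all()] therefore pairs integral smoothing (threshold
#' method) with direct spline smoothing (derivative method).
#'
#' @param smooth A `smoothed_year`.
#' @param season_floor Passed to [governing_peak()].
#' @return A one-row `PTDRecord` data frame with `method = "derivative"`.
#' @export
derivative_ptd <- function(smooth, season_floor = 0.2) {
  norm <- normalize_year(smooth)
  peak <- governing_peak(norm, season_floor)
  doy <- norm$doy
  fit <- attr(norm, "fit"); dord <- attr(norm, "deriv_order")
  d <- if (!is.null(fit) && !is.na(dord))
    predict(fit, doy, deriv = dord + 1L)
  else {
    g <- norm$gpp_smooth
    c(g[2] - g[1], (g[-(1:2)] - g[-((length(g) - 1):length(g))]) / 2,
      g[length(g)] - g[length(g) - 1])
  }
  # search window: the near-zero-floor run containing the governing peak
  run <- season_segments(norm, 0.02)
  w <- which(run$start <= peak & run$end >= peak)
  lo <- run$start[w[1]]; hi <- run$end[w[1]]
  rise <- lo:peak; fall <- peak:hi
  issues <- character(0)
  flat <- function(z) diff(range(z)) < 1e-6 * max(abs(z), 1e-12)
  # flatness judged away from the peak itself, where the derivative pivots
  if (length(rise) > 2 && flat(d[rise[-length(rise)]]))
    issues <- c(issues, "constant derivative on rise; SOS unreliable")
  if (length(fall) > 2 && flat(d[fall[-1]]))
    issues <- c(issues, "constant derivative on fall; EOS unreliable")
  new_ptd_record(norm$site_id[1], norm$year[1], "derivative", NA_real_,
                 doy[rise[which.max(d[rise])]], doy[fall[which.min(d[fall])]],
                 paste(issues, collapse = "; "))
}

#' Configuration for whole-record PTD extraction
#'
#' @param thresholds Threshold grid (default 0.1-0.7 step 0.05, 13 values).
#' @param knots Interior knots for integral smoothing (default 10).
#' @param pad_days Edge pad in days (default 30).
#' @param season_floor Growing-season floor for peak assignment (default 0.2).
#' @param good_day_rule,qc_year_threshold Data-quality filters, see
#'   [assess_years()].
#' @param filter_usable Restrict extraction to usable years (default TRUE).
#' @param interpolate Fractional-day crossings (default TRUE).
#' @return A list of class `ptd_config`.
#' @export
ptd_config <- function(thresholds = seq(0.1, 0.7, by = 0.05), knots = 10L,
                       pad_days = 30L, season_floor = 0.2,
                       good_day_rule = 0.8, qc_year_threshold = 0.7,
                       filter_usable = TRUE, interpolate = TRUE) {
  structure(list(thresholds = thresholds, knots = knots, pad_days = pad_days,
                 season_floor = season_floor, good_day_rule = good_day_rule,
                 qc_year_threshold = qc_year_threshold,
                 filter_usable = filter_usable, interpolate = interpolate),
            class = "ptd_config")
}

#' Extract all transition dates for one site
#'
#' Runs the full per-year pipeline over every usable year of a daily flux
#' record: integral smoothing, min-max normalization, one threshold-method
#' PTD record per grid threshold plus one derivative-method record (the
#' latter from a direct spline smooth with the same knot count, since the
#' integral fit's derivative is piecewise linear and unusable for extremum
#' dates — see [derivative_ptd()]).
#' Neighbouring years' normalized curves are supplied for the cross-year
#' search whenever they are available. Per-year or per-threshold failures
#' (e.g. a threshold that is never crossed) are recorded in the `issues`
#' column with `NA` dates; they never abort the site.
#'
#' @param series A [daily_flux()] series.
#' @param config A [ptd_config()].
#' @return A `PTDRecord` table: one row per (year, threshold) plus one
#'   derivative row per year.
#' @examples
#' se <- season_spec(10, 1, 120, 280, 0.1, 0.1)
#' x <- generate_series(se, n_years = 3, start_year = 2001)
#' ptd <- extract_all(x)
#' head(ptd)
#' @export
extract_all <- function(series, config = ptd_config()) {
  stopifnot(inherits(series, "daily_flux"), inherits(config, "ptd_config"))
  yr <- as.integer(format(series$date, "%Y"))
  covered <- Filter(function(y) sum(yr == y) == days_in_year(y),
                    sort(unique(yr)))
  q <- assess_years(series, config$good_day_rule, config$qc_year_threshold)
  target <- if (config$filter_usable)
    intersect(covered, q$year[q$usable]) else covered

  cache <- new.env(parent = emptyenv())
  get_smooth <- function(y) {
    key <- as.character(y)
    if (!is.null(cache[[key]])) return(cache[[key]]$smooth)
    if (!(y %in% covered)) return(NULL)
    sm <- tryCatch(integral_smooth(series, y, config$knots, config$pad_days),
                   error = function(e) NULL)
    nm <- if (is.null(sm)) NULL else
      tryCatch(normalize_year(sm), error = function(e) NULL)
    cache[[key]] <- list(smooth = sm, norm = nm)
    sm
  }
  get_norm <- function(y) {
    get_smooth(y)
    val <- cache[[as.character(y)]]
    if (is.null(val)) NULL else val$norm
  }

  rows <- lapply(target, function(y) {
    nm <- get_norm(y)
    if (is.null(nm))
      return(new_ptd_record(series$site_id[1], y, "threshold", NA_real_,
                            NA_real_, NA_real_, "year could not be smoothed"))
    prev <- get_norm(y - 1L); nxt <- get_norm(y + 1L)
    th_rows <- lapply(config$thresholds, function(th)
      tryCatch(threshold_ptd(nm, th, prev, nxt, config$season_floor,
                             config$interpolate),
               error = function(e)
                 new_ptd_record(series$site_id[1], y, "threshold", th,
                                NA_real_, NA_real_, conditionMessage(e))))
    dv <- tryCatch(derivative_ptd(
      direct_smooth(series, y, "spline", config$knots, config$pad_days),
      config$season_floor),
      error = function(e)
        new_ptd_record(series$site_id[1], y, "derivative", NA_real_,
                       NA_real_, NA_real_, conditionMessage(e)))
    do.call(rbind, c(th_rows, list(dv)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ptd_table", "data.frame")
  out
}
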