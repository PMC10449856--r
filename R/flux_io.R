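#' Daily flux series container
#'
#' A thin data-frame class holding one site's calendar-dated daily GPP record:
#' columns `site_id`, `date` (class `Date`, strictly increasing, expanded to a
#' contiguous daily range with `NA` for absent days), `gpp`
#' (gC m\eqn{^{-2}} d\eqn{^{-1}}, night-time-partitioned, `NA` when missing)
#' and `nee_qc` (fraction in \[0, 1\] of good-quality NEE half-hours for the
#' day; GPP is partitioned from NEE, so its quality is inherited from the NEE
#' quality flag).
#'
#' @param site_id Site label (recycled).
#' @param date `Date` vector.
#' @param gpp,nee_qc Numeric vectors, `NA` allowed.
#' @return A data frame of class `daily_flux`.
#' @export
daily_flux <- function(site_id, date, gpp, nee_qc) {
  stopifnot(inherits(date, "Date"), length(gpp) == length(date),
            length(nee_qc) == length(date))
  if (is.unsorted(date, strictly = TRUE)) {
    o <- order(date)
    if (anyDuplicated(date)) stop("duplicate dates in daily flux series")
    date <- date[o]; gpp <- gpp[o]; nee_qc <- nee_qc[o]
  }
  if (any(nee_qc < 0 | nee_qc > 1, na.rm = TRUE))
    stop("nee_qc must lie in [0, 1]")
  # expand to a contiguous daily grid; absent days become missing values
  full <- seq(date[1], date[length(date)], by = "day")
  if (length(full) > length(date)) {
    idx <- match(full, date)
    gpp <- gpp[idx]; nee_qc <- nee_qc[idx]; date <- full
  }
  structure(data.frame(site_id = rep_len(site_id[1], length(date)),
                       date = date, gpp = gpp, nee_qc = nee_qc,
                       stringsAsFactors = FALSE),
            class = c("daily_flux", "data.frame"))
}

#' Read a daily flux table in the FLUXNET FULLSET dialect
#'
#' Parses a comma-separated daily FULLSET file with columns `TIMESTAMP`
#' (YYYYMMDD), `GPP_NT_VUT_REF` (daily GPP from the night-time partitioning)
#' and `NEE_VUT_REF_QC` (fraction of good-quality NEE half-hours). The -9999
#' missing sentinel is mapped to `NA`, rows are sorted by date, and the record
#' is expanded to a contiguous daily range.
#'
#' @param path Path to the CSV file.
#' @param site_id Site label; defaults to the file name without extension.
#' @param dialect Format tag; only `"fluxnet_fullset"` is implemented.
#' @return A [daily_flux()] series.
#' @export
read_daily_flux <- function(path, site_id = NULL,
                            dialect = "fluxnet_fullset") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("TIMESTAMP", "GPP_NT_VUT_REF", "NEE_VUT_REF_QC")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dates <- as.Date(as.character(df$TIMESTAMP), format = "%Y%m%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1]
    stop(sprintf("unparseable TIMESTAMP %s at data row %d",
                 df$TIMESTAMP[bad], bad))
  }
  desent <- function(x) { x <- as.numeric(x); x[x == -9999] <- NA_real_; x }
  if (is.null(site_id))
    site_id <- sub("\\.[^.]*$", "", basename(path))
  daily_flux(site_id, dates, desent(df$GPP_NT_VUT_REF),
             desent(df$NEE_VUT_REF_QC))
}

#' Write a daily flux series in the FLUXNET FULLSET dialect
#'
#' Inverse of [read_daily_flux()]: `TIMESTAMP` as YYYYMMDD, missing values as
#' -9999, values printed with six decimals.
#'
#' @param series A [daily_flux()] series.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_daily_flux <- function(series, path) {
  stopifnot(inherits(series, "daily_flux"))
  sent <- function(x) ifelse(is.na(x), "-9999", sprintf("%.6f", x))
  out <- data.frame(TIMESTAMP = format(series$date, "%Y%m%d"),
                    GPP_NT_VUT_REF = sent(series$gpp),
                    NEE_VUT_REF_QC = sent(series$nee_qc))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-year data-quality assessment
#'
#' A day counts as good when its NEE quality fraction is at least
#' `good_day_rule`; a calendar year is usable when its fraction of good days
#' (denominator: 365 or 366) strictly exceeds `qc_year_threshold`. The 70%
#' year rule is the standard inclusion filter for trend-grade flux records;
#' the per-day cutoff is exposed because archives differ in how the daily
#' `NEE_VUT_REF_QC` fraction maps to "original or good-quality gap-filled".
#'
#' @param series A [daily_flux()] series.
#' @param good_day_rule Minimum `nee_qc` for a day to count as good
#'   (default 0.8).
#' @param qc_year_threshold Strict lower bound on the good-day fraction for a
#'   usable year (default 0.7).
#' @return Data frame with columns `site_id`, `year`, `n_good`,
#'   `frac_good_days`, `usable`, one row per calendar year touched by the
#'   series. Years with all-missing quality get `frac_good_days = 0`.
#' @export
assess_years <- function(series, good_day_rule = 0.8,
                         qc_year_threshold = 0.7) {
  stopifnot(inherits(series, "daily_flux"))
  yr <- as.integer(format(series$date, "%Y"))
  good <- !is.na(series$nee_qc) & series$nee_qc >= good_day_rule
  years <- sort(unique(yr))
  n_good <- vapply(years, function(y) sum(good[yr == y]), integer(1))
  frac <- n_good / days_in_year(years)
  data.frame(site_id = series$site_id[1], year = years, n_good = n_good,
             frac_good_days = frac, usable = frac > qc_year_threshold,
             stringsAsFactors = FALSE)
}

#' Select sites with enough usable years for trend analysis
#'
#' Retains sites whose count of usable years strictly exceeds `min_years`
#' ("more than 10 years" in the standard filter), the record length below
#' which decadal phenological trends are not considered reliable.
#'
#' @param quality A data frame with columns `site_id`, `usable` (e.g. several
#'   [assess_years()] tables row-bound together), or a list of such tables.
#' @param min_years Strict lower bound on the usable-year count (default 10).
#' @return Character vector of retained site ids, sorted.
#' @export
select_trend_sites <- function(quality, min_years = 10L) {
  if (is.list(quality) && !is.data.frame(quality))
    quality <- do.call(rbind, quality)
  stopifnot(all(c("site_id", "usable") %in% names(quality)),
            nrow(quality) > 0)
  counts <- tapply(quality$usable, quality$site_id, sum)
  sort(names(counts)[counts > min_years])
}
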