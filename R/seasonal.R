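#' Detrend a monthly time series against a smoothed annual-mean trend
#'
#' Computes monthly anomalies relative to the (slowly varying) annual mean:
#' annual means are computed per year, a cubic smoothing spline is fit
#' through them at mid-year positions, the spline is evaluated at month
#' midpoints (365-day no-leap calendar) and subtracted from the raw series.
#' Because the smoothing-spline penalty leaves linear functions untouched,
#' any linear secular trend is removed exactly regardless of `spar`.
#'
#' If `data` carries dplyr groups (e.g. grouped by cell), the detrend is
#' applied within each group.
#'
#' @param data Data frame with integer columns `year`, `month` (1-12) and the
#'   value column; one row per (year, month), no missing months.
#' @param value Name of the value column (string). Default `"value"`.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]; `NULL`
#'   (default) selects it by generalized cross-validation.
#'
#' @return `data` with two added columns: `<value>_trend` (the spline trend at
#'   each month) and `<value>_anom` (raw minus trend). First and last years
#'   are flagged in the logical column `edge_year` (spline boundary years,
#'   lower confidence).
#'
#' @examples
#' x <- expand.grid(month = 1:12, year = 2001:2010)
#' x$value <- 2 * sin(2 * pi * x$month / 12) + 0.3 * (x$year - 2000)
#' detrend_monthly(x)
#' @export
detrend_monthly <- function(data, value = "value", spar = NULL) {
  if (dplyr::is_grouped_df(data)) {
    return(dplyr::group_modify(
      data,
      function(d, key) detrend_monthly(d, value = value, spar = spar)
    ))
  }
  if (!all(c("year", "month", value) %in% names(data))) {
    rlang::abort("detrend_monthly(): need columns year, month and the value column")
  }
  data <- dplyr::arrange(tibble::as_tibble(data), .data$year, .data$month)
  years <- sort(unique(data$year))
  if (length(years) < 4) {
    rlang::abort("detrend_monthly(): need at least 4 years of data for the trend spline")
  }
  if (!identical(as.integer(data$month), rep(1:12, length(years))) ||
      !all(diff(years) == 1)) {
    rlang::abort("detrend_monthly(): series must cover each month of a contiguous year range")
  }
  y <- data[[value]]
  annual <- tapply(y, data$year, mean)
  if (stats::var(annual) < .Machine$double.eps * max(1, mean(annual)^2)) {
    trend <- rep(mean(annual), nrow(data))   # constant series: spline is flat
  } else {
    # knots sit at the mean month midpoint (not 0.5: months differ in length),
    # so a linear trend detrends exactly and re-detrending is a no-op
    x_ann <- years + mean(month_midpoint_days(1:12)) / 365
    fit <- stats::smooth.spline(x_ann, as.numeric(annual), spar = spar)
    month_mid <- rep(years, each = 12) + (month_midpoint_days(1:12) / 365)
    trend <- stats::predict(fit, month_mid)$y
  }
  data[[paste0(value, "_trend")]] <- trend
  data[[paste0(value, "_anom")]] <- y - trend
  data$edge_year <- data$year %in% range(years)
  data
}

# mid-month positions (days from Jan 1) on a 365-day climatological calendar
month_midpoint_days <- function(month) {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  (cumsum(len) - len / 2)[month]
}

#' Decadal climatology of monthly anomalies
#'
#' Month-wise mean of detrended monthly anomalies over a decade (or any full
#' year range), with the annual mean of the undetrended series stored
#' alongside. This is the 12-point "primed" annual cycle that the Taylor
#' decompositions and timing diagnostics consume.
#'
#' @param data Output of [detrend_monthly()] (ungrouped; apply per group
#'   upstream if needed).
#' @param start,end First and last year of the decade (inclusive); every year
#'   in the range must be present.
#' @param value Name of the raw value column.
#'
#' @return A 12-row tibble with columns `month`, `anom` (mean monthly anomaly)
#'   and `annual_mean` (scalar, repeated), plus attribute `decade =
#'   c(start, end)`. The 12 anomalies average to ~0.
#'
#' @export
decadal_climatology <- function(data, start, end, value = "value") {
  acol <- paste0(value, "_anom")
  if (!all(c("year", "month", value, acol) %in% names(data))) {
    rlang::abort("decadal_climatology(): run detrend_monthly() first")
  }
  have <- unique(data$year)
  if (!all(start:end %in% have)) {
    rlang::abort(sprintf(
      "decadal_climatology(): decade %d-%d not fully covered by the series", start, end
    ))
  }
  d <- dplyr::filter(data, .data$year >= start, .data$year <= end)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$month),
    anom = mean(.data[[acol]]),
    .groups = "drop"
  )
  out$annual_mean <- mean(d[[value]])
  attr(out, "decade") <- c(start, end)
  out
}

#' Mean anomaly over a set of summer months
#'
#' Arithmetic mean of a climatology's anomalies over the configured summer
#' window. The default window is June, August and September; the preset
#' `summer_months("jja")` gives June-August instead. Both are provided
#' because published usage differs; neither is silently preferred.
#'
#' @param clim Output of [decadal_climatology()] (12 rows).
#' @param months Integer months of the summer window, subset of 1:12.
#' @return The scalar mean anomaly over the window.
#' @export
summer_anomaly <- function(clim, months = summer_months()) {
  if (!length(months) || !all(months %in% 1:12)) {
    rlang::abort("summer_anomaly(): months must be a nonempty subset of 1:12")
  }
  mean(clim$anom[match(months, clim$month)])
}

#' Summer-window presets
#'
#' @param preset `"jas_skip_jul"` (June, August, September; the default used
#'   in the summer-anomaly maps) or `"jja"` (June-August).
#' @return Integer vector of months.
#' @export
summer_months <- function(preset = c("jas_skip_jul", "jja")) {
  preset <- match.arg(preset)
  switch(preset, jas_skip_jul = c(6L, 8L, 9L), jja = c(6L, 7L, 8L))
}
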