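#' Climate-CO2 separation of the decadal change in pCO2 anomalies
#'
#' Attributes the change in the monthly pCO2 anomaly between a modern and a
#' future decade to (i) changed sensitivities (the geochemical effect of
#' higher atmospheric CO2), (ii) changed driver anomalies (the radiative
#' effect of physical climate change) and (iii) their synergy:
#'
#' \deqn{\Delta p' = \sum_i \Delta\gamma_i X'_{i,0}
#'   + \sum_i \gamma_{i,0} \Delta X'_i + \sum_i \Delta\gamma_i \Delta X'_i}
#'
#' where the 0 subscript is the modern decade and Delta the modern-to-future
#' change. The identity `total = delta_sens + delta_anom + synergy` holds to
#' machine precision by construction. `delta_anom_star = delta_anom + synergy`
#' is the driver-anomaly effect with the synergy folded in (the future state
#' minus the state computed with only increased sensitivities).
#'
#' @param modern_sens,future_sens 12-row monthly sensitivity tables (columns
#'   `month`, `dpco2_dtemp`, `dpco2_dsal`, `dpco2_dalk`, `dpco2_ddic`).
#' @param modern_anoms,future_anoms Outputs of [driver_anomalies()] for the
#'   two decades.
#'
#' @return An object of class `pco2_separation`: a list with `components`
#'   (12-row tibble: `month`, `delta_sens`, `delta_anom`, `synergy`,
#'   `delta_anom_star`, `total`), `modern_total` and `future_total` (the
#'   Taylor-basis reconstructed anomalies of the two decades). Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
separate_climate_co2 <- function(modern_sens, modern_anoms,
                                 future_sens, future_anoms) {
  g0 <- effective_gamma(modern_sens)
  g1 <- effective_gamma(future_sens)
  a0 <- dplyr::arrange(tibble::as_tibble(modern_anoms), .data$month)
  a1 <- dplyr::arrange(tibble::as_tibble(future_anoms), .data$month)
  if (!identical(a0$month, a1$month)) {
    rlang::abort("separate_climate_co2(): month bases differ between decades")
  }
  anom_cols <- c(temp = "temp_anom", sal = "sal_anom", alk = "alk_anom", dic = "dic_anom")
  delta_sens <- delta_anom <- synergy <- m0 <- m1 <- numeric(12)
  for (i in names(anom_cols)) {
    x0 <- a0[[anom_cols[i]]]
    x1 <- a1[[anom_cols[i]]]
    delta_sens <- delta_sens + (g1[[i]] - g0[[i]]) * x0
    delta_anom <- delta_anom + g0[[i]] * (x1 - x0)
    synergy <- synergy + (g1[[i]] - g0[[i]]) * (x1 - x0)
    m0 <- m0 + g0[[i]] * x0
    m1 <- m1 + g1[[i]] * x1
  }
  comp <- tibble::tibble(
    month = a0$month,
    delta_sens = delta_sens,
    delta_anom = delta_anom,
    synergy = synergy,
    delta_anom_star = delta_anom + synergy,
    total = delta_sens + delta_anom + synergy
  )
  structure(
    list(components = comp, modern_total = m0, future_total = m1),
    class = "pco2_separation"
  )
}

#' @export
print.pco2_separation <- function(x, ...) {
  cat("Climate-CO2 separation of decadal change in monthly pCO2 anomalies\n")
  print(x$components, ...)
  invisible(x)
}

#' Summer enhancement of pCO2 anomalies from changed driver seasonalities
#'
#' Quantifies how much larger the future summer pCO2 anomaly is than it would
#' have been had only the sensitivities changed (no physical climate change),
#' in percent of the modern summer anomaly. Both an extreme-based statistic
#' (maximum monthly anomaly in the summer window) and a seasonal-mean variant
#' are returned, each relative to the absolute and to the signed modern value
#' (the two references are both emitted and labelled; they differ in sign
#' when the modern summer anomaly is negative).
#'
#' @param sep A `pco2_separation` object.
#' @param summer Integer months of the summer window (default June-September).
#'
#' @return A one-row tibble: `modern_extreme`, `sens_only_extreme`,
#'   `future_extreme` (uatm), `enhancement_extreme_uatm` (the absolute
#'   enhancement), `enhancement_extreme_pct_abs`,
#'   `enhancement_extreme_pct_signed`, and the same set for the summer
#'   seasonal mean (`*_mean*`). The percent variants blow up when the modern
#'   summer reference is near zero; the uatm columns are always stable.
#' @export
summer_enhancement <- function(sep, summer = 6:9) {
  stopifnot(inherits(sep, "pco2_separation"))
  comp <- sep$components
  idx <- comp$month %in% summer
  if (!any(idx)) rlang::abort("summer_enhancement(): empty summer window")
  modern <- sep$modern_total
  sens_only <- modern + comp$delta_sens
  future <- modern + comp$total
  ext <- function(v) max(v[idx])
  avg <- function(v) mean(v[idx])
  tibble::tibble(
    modern_extreme = ext(modern),
    sens_only_extreme = ext(sens_only),
    future_extreme = ext(future),
    enhancement_extreme_uatm = ext(future) - ext(sens_only),
    enhancement_extreme_pct_abs = 100 * (ext(future) - ext(sens_only)) / abs(ext(modern)),
    enhancement_extreme_pct_signed = 100 * (ext(future) - ext(sens_only)) / ext(modern),
    modern_mean = avg(modern),
    sens_only_mean = avg(sens_only),
    future_mean = avg(future),
    enhancement_mean_uatm = avg(future) - avg(sens_only),
    enhancement_mean_pct_abs = 100 * (avg(future) - avg(sens_only)) / abs(avg(modern)),
    enhancement_mean_pct_signed = 100 * (avg(future) - avg(sens_only)) / avg(modern)
  )
}
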