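#' Driver anomalies (and salinity-normalized anomalies) from a monthly climatology
#'
#' Takes a 12-month climatology of the four pCO2 drivers and derives the
#' monthly anomalies relative to the annual mean, together with the
#' salinity-normalized alkalinity/DIC quantities (sX = X * S0 / S, with S0 the
#' annual-mean salinity) and their anomalies, as used by the freshwater-
#' separated Taylor layout.
#'
#' @param states 12-row data frame with columns `month`, `temp`, `sal`, `alk`,
#'   `dic` holding the decadal monthly climatological means (raw units).
#'
#' @return A 12-row tibble with the input columns plus `s0`, `temp_anom`,
#'   `sal_anom`, `alk_anom`, `dic_anom`, `s_alk`, `s_dic`, `s_alk_anom`,
#'   `s_dic_anom`.
#' @export
driver_anomalies <- function(states) {
  need <- c("month", "temp", "sal", "alk", "dic")
  if (!all(need %in% names(states)) || nrow(states) != 12) {
    rlang::abort("driver_anomalies(): need a 12-row climatology with month, temp, sal, alk, dic")
  }
  if (any(states$sal <= 0)) {
    rlang::abort("driver_anomalies(): salinity must be positive in every month")
  }
  s <- dplyr::arrange(tibble::as_tibble(states), .data$month)
  s0 <- mean(s$sal)
  dplyr::mutate(
    s,
    s0 = s0,
    temp_anom = .data$temp - mean(.data$temp),
    sal_anom = .data$sal - mean(.data$sal),
    alk_anom = .data$alk - mean(.data$alk),
    dic_anom = .data$dic - mean(.data$dic),
    s_alk = .data$alk * s0 / .data$sal,
    s_dic = .data$dic * s0 / .data$sal,
    s_alk_anom = .data$s_alk - mean(.data$s_alk),
    s_dic_anom = .data$s_dic - mean(.data$s_dic)
  )
}

# Effective gamma of the "basic approach": arithmetic mean of the monthly
# sensitivity and the annual-mean (mean-of-12) sensitivity.
effective_gamma <- function(sens) {
  need <- c("dpco2_dtemp", "dpco2_dsal", "dpco2_dalk", "dpco2_ddic")
  if (!all(need %in% names(sens)) || nrow(sens) != 12) {
    rlang::abort("need 12 monthly sensitivities (columns dpco2_dtemp, dpco2_dsal, dpco2_dalk, dpco2_ddic)")
  }
  s <- dplyr::arrange(tibble::as_tibble(sens), .data$month)
  g <- lapply(need, function(v) (s[[v]] + mean(s[[v]])) / 2)
  names(g) <- c("temp", "sal", "alk", "dic")
  g
}

new_term_series <- function(df, layout, decade = NULL) {
  out <- tibble::as_tibble(df)
  class(out) <- c("term_series", class(out))
  attr(out, "layout") <- layout
  attr(out, "decade") <- decade
  out
}

check_same_decade <- function(a, b, what) {
  da <- attr(a, "decade")
  db <- attr(b, "decade")
  if (!is.null(da) && !is.null(db) && !identical(da, db)) {
    rlang::abort(paste0(what, ": inputs are from different decades (",
                        paste(da, collapse = "-"), " vs ", paste(db, collapse = "-"), ")"))
  }
}

#' Standard Taylor decomposition of monthly pCO2 anomalies
#'
#' First-order decomposition of the monthly pCO2 anomaly into thermal, haline,
#' alkalinity and DIC contributions: `term_i[m] = gamma_i[m] * X'_i[m]`, where
#' each effective sensitivity `gamma_i[m]` is the arithmetic mean of the
#' monthly sensitivity and the annual-mean sensitivity ("basic approach").
#' Second-order terms, driver covariances and the small phosphorus/silicon
#' contributions are neglected, so the reconstruction differs from the actual
#' anomaly by a closure error that is reported, never hidden.
#'
#' @param anoms Output of [driver_anomalies()] for one cell and decade.
#' @param sens 12-row data frame of monthly sensitivities (columns `month`,
#'   `dpco2_dtemp`, `dpco2_dsal`, `dpco2_dalk`, `dpco2_ddic`), e.g. from
#'   [carbonate_sensitivities()] on the climatological monthly states.
#' @param actual Optional 12-vector of the directly computed monthly pCO2
#'   anomalies (uatm), stored as `actual_total` for closure assessment.
#'
#' @return A 12-row `term_series` tibble with columns `month`, `thermal`,
#'   `haline`, `alkalinity`, `dic`, `reconstructed_total` (exact sum of the
#'   four terms) and, if supplied, `actual_total`.
#' @export
taylor_terms <- function(anoms, sens, actual = NULL) {
  check_same_decade(anoms, sens, "taylor_terms()")
  g <- effective_gamma(sens)
  a <- dplyr::arrange(tibble::as_tibble(anoms), .data$month)
  out <- tibble::tibble(
    month = a$month,
    thermal = g$temp * a$temp_anom,
    haline = g$sal * a$sal_anom,
    alkalinity = g$alk * a$alk_anom,
    dic = g$dic * a$dic_anom
  )
  out$reconstructed_total <- out$thermal + out$haline + out$alkalinity + out$dic
  if (!is.null(actual)) {
    stopifnot(length(actual) == 12)
    out$actual_total <- actual
  }
  new_term_series(out, "standard", attr(anoms, "decade"))
}

#' Freshwater-separated Taylor decomposition
#'
#' Splits the alkalinity and DIC contributions into a salinity-driven part
#' (freshwater fluxes: precipitation/evaporation, rivers, ice melt and
#' formation) and a biogeochemical part driven by the salinity-normalized
#' quantities. The biogeochemical terms retain the S/S0 prefactor
#' (`(S/S0) * gamma_X * sX'`), which matters where short-term salinity
#' variations are substantial, as in the Arctic. The salinity-driven terms
#' are computed as the exact complement `gamma_X * (X' - (S/S0) sX')`, equal
#' to the first-order dilution form `(X/S) * gamma_X * S'` for small
#' anomalies; this makes the freshwater and standard layouts sum to exactly
#' the same total.
#'
#' @inheritParams taylor_terms
#'
#' @return A 12-row `term_series` tibble with columns `month`, `thermal`,
#'   `haline` (direct salinity term), `fw_alkalinity`, `fw_dic` (freshwater/
#'   dilution-driven), `bio_alkalinity`, `bio_dic` (biogeochemically driven),
#'   `reconstructed_total` and optionally `actual_total`.
#' @export
freshwater_terms <- function(anoms, sens, actual = NULL) {
  check_same_decade(anoms, sens, "freshwater_terms()")
  if (!all(c("s0", "s_alk_anom", "s_dic_anom") %in% names(anoms))) {
    rlang::abort("freshwater_terms(): anoms must come from driver_anomalies()")
  }
  if (any(anoms$sal <= 0)) {
    rlang::abort("freshwater_terms(): salinity must be positive in every month")
  }
  g <- effective_gamma(sens)
  a <- dplyr::arrange(tibble::as_tibble(anoms), .data$month)
  srat <- a$sal / a$s0
  out <- tibble::tibble(
    month = a$month,
    thermal = g$temp * a$temp_anom,
    haline = g$sal * a$sal_anom,
    bio_alkalinity = srat * g$alk * a$s_alk_anom,
    bio_dic = srat * g$dic * a$s_dic_anom
  )
  out$fw_alkalinity <- g$alk * a$alk_anom - out$bio_alkalinity
  out$fw_dic <- g$dic * a$dic_anom - out$bio_dic
  out <- out[, c("month", "thermal", "haline", "fw_alkalinity", "fw_dic",
                 "bio_alkalinity", "bio_dic")]
  out$reconstructed_total <- out$thermal + out$haline + out$fw_alkalinity +
    out$fw_dic + out$bio_alkalinity + out$bio_dic
  if (!is.null(actual)) {
    stopifnot(length(actual) == 12)
    out$actual_total <- actual
  }
  new_term_series(out, "freshwater", attr(anoms, "decade"))
}

#' Incremental (year-pair) decomposition for a strongly changed future decade
#'
#' The basic decomposition degrades when month-to-month changes become
#' dramatic by the end of the century: it linearizes the whole modern-to-
#' future change in one step. This revision instead accumulates many small
#' first-order steps: (1) for each month, the change of each driver between
#' consecutive years (between Januaries, between Februaries, ...) is
#' multiplied by the average sensitivity of the year pair; (2) those products
#' are summed across years, per month and term, giving a decomposition of the
#' total modern-to-future change; (3) the summed change is added to the
#' modern-decade terms, and each term is re-centered over the 12 months so
#' the result is again a decomposition of the monthly anomaly relative to the
#' annual mean.
#'
#' Year pairs are weighted so that the telescoped sum reproduces exactly the
#' difference of the two decadal climatologies: pairs strictly between the
#' decades get weight 1, pairs overlapping a decade get the fractional weight
#' implied by averaging ten lagged year ranges. With constant sensitivities
#' the result therefore reduces exactly to the basic decomposition applied to
#' the future decade.
#'
#' Each year-pair driver change is taken as the change of the detrended
#' monthly anomaly plus the (month-independent) step of the annual-mean
#' trend. Keeping the trend step is essential: the accumulated products
#' track the full path of the system through states of growing sensitivity,
#' which is what lets the sum reproduce the modern-to-future change of the
#' reconstruction. Using the anomaly change (rather than the raw monthly
#' difference) merely keeps the detrending spline's within-year ramp - an
#' artifact of trend interpolation, identical in sign across months - out of
#' the seasonal decomposition.
#'
#' @param yearly Data frame with one row per (year, month): columns `year`,
#'   `month`, the raw per-year monthly drivers `temp`, `sal`, `alk`, `dic`,
#'   their detrended monthly anomalies `temp_anom`, `sal_anom`, `alk_anom`,
#'   `dic_anom` (from [detrend_monthly()]) and per-year monthly
#'   sensitivities `dpco2_dtemp`, `dpco2_dsal`, `dpco2_dalk`, `dpco2_ddic`
#'   evaluated at the raw states. Years must be contiguous and cover
#'   `modern[1]:future[2]`.
#' @param modern_terms `term_series` for the modern decade (standard layout)
#'   from [taylor_terms()].
#' @param modern,future Length-2 integer vectors: first and last year of the
#'   modern and future decades.
#'
#' @return A 12-row `term_series` (standard layout) for the future decade.
#' @export
incremental_terms <- function(yearly, modern_terms, modern, future) {
  stopifnot(length(modern) == 2, length(future) == 2)
  if (!identical(attr(modern_terms, "layout"), "standard")) {
    rlang::abort("incremental_terms(): modern_terms must use the standard layout")
  }
  years <- sort(unique(yearly$year))
  span <- modern[1]:future[2]
  if (!all(span %in% years)) {
    rlang::abort("incremental_terms(): yearly coverage has a gap over the modern-to-future span")
  }
  nd <- modern[2] - modern[1] + 1            # decade length (10)
  if (future[2] - future[1] + 1 != nd) {
    rlang::abort("incremental_terms(): modern and future decades must have equal length")
  }
  drivers <- c(temp = "temp", sal = "sal", alk = "alk", dic = "dic")
  anoms <- paste0(drivers, "_anom")
  names(anoms) <- names(drivers)
  gammas <- c(temp = "dpco2_dtemp", sal = "dpco2_dsal", alk = "dpco2_dalk", dic = "dpco2_ddic")
  terms <- c(temp = "thermal", sal = "haline", alk = "alkalinity", dic = "dic")
  if (!all(c(drivers, anoms, gammas) %in% names(yearly))) {
    rlang::abort("incremental_terms(): yearly needs raw drivers, detrended anomalies and sensitivities")
  }
  y <- dplyr::arrange(
    dplyr::filter(tibble::as_tibble(yearly), .data$year %in% span),
    .data$month, .data$year
  )
  pair_years <- modern[1]:(future[2] - 1)    # pair y -> y+1
  # weight of pair y: number of lag offsets k in 0..nd-1 with
  # modern[1]+k <= y <= future[1]+k-1, divided by nd
  w <- (pmin(nd - 1, pair_years - modern[1]) -
          pmax(0, pair_years - future[1] + 1) + 1) / nd
  w <- pmin(pmax(w, 0), 1)
  delta <- tibble::tibble(month = 1:12)
  for (i in seq_along(drivers)) {
    acc <- numeric(12)
    for (j in seq_along(pair_years)) {
      yr <- pair_years[j]
      a0 <- y[y$year == yr, ]
      a1 <- y[y$year == yr + 1, ]
      gbar <- (a0[[gammas[i]]] + a1[[gammas[i]]]) / 2
      trend_step <- mean(a1[[drivers[i]]] - a1[[anoms[i]]]) -
        mean(a0[[drivers[i]]] - a0[[anoms[i]]])
      dx <- (a1[[anoms[i]]] - a0[[anoms[i]]]) + trend_step
      acc <- acc + w[j] * gbar * dx
    }
    delta[[terms[i]]] <- acc
  }
  m <- dplyr::arrange(tibble::as_tibble(modern_terms), .data$month)
  recenter <- function(x) x - mean(x)
  out <- tibble::tibble(
    month = 1:12,
    thermal = recenter(m$thermal + delta$thermal),
    haline = recenter(m$haline + delta$haline),
    alkalinity = recenter(m$alkalinity + delta$alkalinity),
    dic = recenter(m$dic + delta$dic)
  )
  out$reconstructed_total <- out$thermal + out$haline + out$alkalinity + out$dic
  new_term_series(out, "standard", future)
}

#' Thermal / non-thermal split of a term series
#'
#' @param terms A `term_series` from any layout.
#' @return A 12-row tibble with `month`, `thermal`, `nonthermal`
#'   (`reconstructed_total - thermal`, so the two add to the reconstruction
#'   exactly) and, when `actual_total` is available, `nonthermal_residual`
#'   (`actual_total - thermal`; the difference between the two non-thermal
#'   estimates is the closure error).
#' @export
thermal_nonthermal_split <- function(terms) {
  t <- dplyr::arrange(tibble::as_tibble(terms), .data$month)
  out <- tibble::tibble(
    month = t$month,
    thermal = t$thermal,
    nonthermal = t$reconstructed_total - t$thermal
  )
  if ("actual_total" %in% names(t)) {
    out$nonthermal_residual <- t$actual_total - t$thermal
  }
  out
}

#' Closure error of a Taylor reconstruction
#'
#' @param terms A `term_series` carrying `actual_total`.
#' @return A list with `max_abs` (uatm), `amplitude` (max - min of the actual
#'   anomalies, uatm) and `rel` (`max_abs / amplitude`).
#' @export
term_closure <- function(terms) {
  if (!"actual_total" %in% names(terms)) {
    rlang::abort("term_closure(): term series has no actual_total")
  }
  err <- terms$reconstructed_total - terms$actual_total
  amp <- diff(range(terms$actual_total))
  list(max_abs = max(abs(err)), amplitude = amp, rel = max(abs(err)) / amp)
}
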