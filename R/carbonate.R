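#' Build a table of seawater surface states
#'
#' Convenience constructor for the tabular state format used throughout the
#' package: one row per (cell, month, ...) sample with the four pCO2 drivers
#' plus nutrients.
#'
#' @param temp Temperature (degC), in \[-2, 40\].
#' @param sal Practical salinity, in \[0, 45\].
#' @param alk Total alkalinity (umol kg-1), >= 0.
#' @param dic Total dissolved inorganic carbon (umol kg-1), >= 0.
#' @param phos Total dissolved inorganic phosphorus (umol kg-1), >= 0.
#' @param sil Total dissolved silicon (umol kg-1), >= 0.
#'
#' @return A tibble with columns `temp`, `sal`, `alk`, `dic`, `phos`, `sil`.
#' @examples
#' seawater_state(temp = 2, sal = 33, alk = 2130, dic = 2000)
#' @export
seawater_state <- function(temp, sal, alk, dic, phos = 0, sil = 0) {
  out <- tibble::tibble(
    temp = as.numeric(temp), sal = as.numeric(sal),
    alk = as.numeric(alk), dic = as.numeric(dic),
    phos = as.numeric(rep_len(phos, length(temp))),
    sil = as.numeric(rep_len(sil, length(temp)))
  )
  validate_state(out)
  out
}

validate_state <- function(data, where = "seawater state") {
  need <- c("temp", "sal", "alk", "dic")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    rlang::abort(paste0(where, ": missing columns ", paste(miss, collapse = ", ")))
  }
  bad <- which(
    !is.finite(data$temp) | data$temp < -2 | data$temp > 40 |
      !is.finite(data$sal) | data$sal < 0 | data$sal > 45 |
      !is.finite(data$alk) | data$alk < 0 |
      !is.finite(data$dic) | data$dic < 0
  )
  if (length(bad)) {
    ex <- bad[1]
    rlang::abort(sprintf(
      "%s: %d row(s) outside valid ranges (first: row %d, temp=%.3g sal=%.3g alk=%.3g dic=%.3g)",
      where, length(bad), ex, data$temp[ex], data$sal[ex], data$alk[ex], data$dic[ex]
    ))
  }
  invisible(data)
}

# Total alkalinity residual (mol kg-1) at total-scale [H+], vectorized.
# Includes carbonate, borate, water, free-H, phosphate and silicate terms;
# NH3/H2S and the HSO4/HF alkalinity terms are omitted (negligible here;
# sulfate/fluoride enter only through pH-scale handling).
ta_residual <- function(h, k, alk, dic, phos, sil) {
  d <- h^2 + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / d
  co3 <- dic * k$K1 * k$K2 / d
  boh4 <- k$BT * k$KB / (k$KB + h)
  oh <- k$KW / h
  hfree <- h / (1 + k$ST / k$KS)
  dp <- h^3 + k$K1p * h^2 + k$K1p * k$K2p * h + k$K1p * k$K2p * k$K3p
  palk <- phos * (k$K1p * k$K2p * h + 2 * k$K1p * k$K2p * k$K3p - h^3) / dp
  sialk <- sil * k$KSi / (k$KSi + h)
  hco3 + 2 * co3 + boh4 + oh - hfree + palk + sialk - alk
}

# Safeguarded Newton on [H+] with a bisection bracket over pH in [1, 13].
# Vectorized over states. Returns [H+] (mol kg-1, total scale).
solve_h_total <- function(k, alk, dic, phos, sil,
                          tol = 1e-12, max_iter = 100) {
  n <- length(alk)
  lo <- rep(1e-13, n)
  hi <- rep(1e-1, n)
  flo <- ta_residual(lo, k, alk, dic, phos, sil)
  fhi <- ta_residual(hi, k, alk, dic, phos, sil)
  # residual is strictly decreasing in H; a physical root needs flo>0>fhi
  nophys <- which(flo < 0 | fhi > 0)
  if (length(nophys)) {
    ex <- nophys[1]
    rlang::abort(sprintf(
      "solve_carbonate(): no physical root for %d state(s) (first: row %d, alk=%.4g dic=%.4g umol/kg)",
      length(nophys), ex, alk[ex] * 1e6, dic[ex] * 1e6
    ))
  }
  h <- rep(1e-8, n)   # initial guess pH 8.0
  done <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    f <- ta_residual(h, k, alk, dic, phos, sil)
    pos <- f > 0
    lo <- ifelse(pos & !done, h, lo)
    hi <- ifelse(!pos & !done, h, hi)
    dh <- h * 1e-7
    fp <- (ta_residual(h + dh, k, alk, dic, phos, sil) - f) / dh
    hn <- h - f / fp
    bad <- !is.finite(hn) | hn <= lo | hn >= hi
    hn[bad] <- sqrt(lo[bad] * hi[bad])
    step <- abs(hn - h) / h
    done <- done | step < tol
    h <- ifelse(done, h, hn)
    if (all(done)) break
  }
  if (!all(done)) {
    ex <- which(!done)[1]
    rlang::abort(sprintf(
      "solve_carbonate(): no convergence after %d iterations for %d state(s) (first: row %d, alk=%.4g dic=%.4g umol/kg)",
      max_iter, sum(!done), ex, alk[ex] * 1e6, dic[ex] * 1e6
    ))
  }
  h
}

#' Solve the seawater CO2 equilibrium system
#'
#' Finds the total-scale \[H+\] that balances total alkalinity for each row of
#' `data` and returns the full carbonate speciation. Alkalinity includes
#' carbonate, borate, water, free-hydrogen, phosphate and silicate terms.
#' Root finding is a safeguarded Newton iteration on \[H+\] (initial guess
#' pH 8) with a bisection bracket over pH \[1, 13\]; convergence is declared at
#' a relative \[H+\] step below `tol`.
#'
#' By construction the solution satisfies, exactly, carbon conservation
#' (`co2star + hco3 + co3 = dic`) and the Henry/K1 identity
#' `pco2 = h * hco3 / (cf * K0 * K1)` (unit-consistent).
#'
#' @param data Data frame with columns `temp` (degC), `sal`, `alk`, `dic`
#'   (umol kg-1) and optionally `phos`, `sil` (umol kg-1, default 0).
#' @param constants_set Constants registry name; see [carb_constants()].
#' @param tol Relative \[H+\] convergence tolerance.
#'
#' @return The input tibble plus columns `ph` (total scale), `h` (mol kg-1),
#'   `pco2` (uatm), `co2star`, `hco3`, `co3` (umol kg-1), `k0` (mol kg-1
#'   atm-1), `k1`, `k2`, `cf`. The attribute `constants_set` records the
#'   constants used.
#'
#' @examples
#' solve_carbonate(seawater_state(2, 33, 2130, 2000))
#' @export
solve_carbonate <- function(data, constants_set = "lueker2000_total",
                            tol = 1e-12) {
  validate_state(data, "solve_carbonate()")
  if (!"phos" %in% names(data)) data$phos <- 0
  if (!"sil" %in% names(data)) data$sil <- 0
  if (any(data$phos < 0) || any(data$sil < 0)) {
    rlang::abort("solve_carbonate(): negative nutrient concentration")
  }
  k <- carb_constants(data$temp, data$sal, set = constants_set)
  alk <- data$alk * 1e-6
  dic <- data$dic * 1e-6
  phos <- data$phos * 1e-6
  sil <- data$sil * 1e-6
  h <- solve_h_total(k, alk, dic, phos, sil, tol = tol)
  d <- h^2 + k$K1 * h + k$K1 * k$K2
  co2star <- dic * h^2 / d
  hco3 <- dic * k$K1 * h / d
  co3 <- dic * k$K1 * k$K2 / d
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    ph = -log10(h),
    h = h,
    pco2 = co2star / (k$K0 * k$cf) * 1e6,
    co2star = co2star * 1e6,
    hco3 = hco3 * 1e6,
    co3 = co3 * 1e6,
    k0 = k$K0, k1 = k$K1, k2 = k$K2, cf = k$cf
  )
  attr(out, "constants_set") <- constants_set
  out
}

#' Finite-difference step sizes for pCO2 sensitivities
#'
#' Absolute central-difference steps per driver. Defaults are small relative
#' to each driver's characteristic scale (about 1e-4 of typical seasonal
#' ranges): 1e-3 degC, 1e-3 salinity, 0.1 umol kg-1 for alkalinity and DIC.
#'
#' @param temp,sal,alk,dic Absolute step per driver.
#' @return A named list of steps.
#' @export
sens_steps <- function(temp = 1e-3, sal = 1e-3, alk = 0.1, dic = 0.1) {
  stopifnot(temp > 0, sal > 0, alk > 0, dic > 0)
  list(temp = temp, sal = sal, alk = alk, dic = dic)
}

perturbed_pco2 <- function(data, driver, delta, constants_set) {
  d <- data
  d[[driver]] <- d[[driver]] + delta
  solve_carbonate(d, constants_set = constants_set)$pco2
}

#' Numerical sensitivities of pCO2 to its four drivers
#'
#' Central finite differences of pCO2 with respect to temperature, salinity,
#' total alkalinity and DIC, each perturbed separately with the other drivers
#' held fixed. If a perturbed state falls outside the valid ranges the step is
#' halved once; if still invalid the function fails.
#'
#' @inheritParams solve_carbonate
#' @param steps Step sizes from [sens_steps()].
#'
#' @return The input tibble plus `pco2` and the sensitivity columns
#'   `dpco2_dtemp` (uatm degC-1), `dpco2_dsal` (uatm per salinity unit),
#'   `dpco2_dalk`, `dpco2_ddic` (uatm per umol kg-1). For ocean-like states
#'   `dpco2_dtemp > 0`, `dpco2_ddic > 0` and `dpco2_dalk < 0`.
#'
#' @examples
#' carbonate_sensitivities(seawater_state(2, 33, 2130, 2000))
#' @export
carbonate_sensitivities <- function(data, steps = sens_steps(),
                                    constants_set = "lueker2000_total") {
  validate_state(data, "carbonate_sensitivities()")
  if (!"phos" %in% names(data)) data$phos <- 0
  if (!"sil" %in% names(data)) data$sil <- 0
  base <- solve_carbonate(data, constants_set = constants_set)
  limits <- list(temp = c(-2, 40), sal = c(0, 45), alk = c(0, Inf), dic = c(0, Inf))
  out <- tibble::as_tibble(data)
  out$pco2 <- base$pco2
  for (drv in c("temp", "sal", "alk", "dic")) {
    hstep <- rep(steps[[drv]], nrow(out))
    lim <- limits[[drv]]
    outside <- data[[drv]] - hstep < lim[1] | data[[drv]] + hstep > lim[2]
    hstep[outside] <- hstep[outside] / 2
    still <- data[[drv]] - hstep < lim[1] | data[[drv]] + hstep > lim[2]
    if (any(still)) {
      rlang::abort(sprintf(
        "carbonate_sensitivities(): perturbed %s out of range for %d state(s) even after halving the step",
        drv, sum(still)
      ))
    }
    up <- perturbed_pco2(data, drv, hstep, constants_set)
    dn <- perturbed_pco2(data, drv, -hstep, constants_set)
    out[[paste0("dpco2_d", drv)]] <- (up - dn) / (2 * hstep)
  }
  attr(out, "constants_set") <- constants_set
  out
}

#' Relative temperature sensitivity of pCO2 versus \[CO2*\]
#'
#' For a closed system (alkalinity and DIC held fixed), computes the ratio
#' (d ln pCO2 / dT) / (d ln \[CO2*\] / dT) by central differences. The two
#' log-derivatives differ exactly by -d ln(K0 cf)/dT (Henry's law at fixed
#' composition), so the ratio exceeds 1 wherever CO2 solubility falls with
#' warming. For modern polar surface waters (T near 0 degC, alkalinity
#' 2130 and DIC 2000 umol kg-1) the ratio is about 7; it decreases toward
#' warmer water (about 3 at 25 degC).
#'
#' @inheritParams solve_carbonate
#' @param step Temperature step (degC) for the central difference.
#'
#' @return The input tibble plus `dlnpco2_dtemp`, `dlnco2star_dtemp`
#'   (degC-1) and their ratio `ratio` (dimensionless).
#'
#' @examples
#' temperature_sensitivity_ratio(seawater_state(-1, 33, 2130, 2000))
#' @export
temperature_sensitivity_ratio <- function(data, step = 1e-3,
                                          constants_set = "lueker2000_total") {
  validate_state(data, "temperature_sensitivity_ratio()")
  up <- data
  up$temp <- up$temp + step
  dn <- data
  dn$temp <- dn$temp - step
  su <- solve_carbonate(up, constants_set = constants_set)
  sd <- solve_carbonate(dn, constants_set = constants_set)
  dlnp <- (log(su$pco2) - log(sd$pco2)) / (2 * step)
  dlnc <- (log(su$co2star) - log(sd$co2star)) / (2 * step)
  # below ~1e-6 the central difference is dominated by solver noise
  if (any(abs(dlnc) < 1e-6)) {
    rlang::abort("temperature_sensitivity_ratio(): d ln [CO2*]/dT is zero within step noise; ratio undefined")
  }
  dplyr::mutate(tibble::as_tibble(data),
    dlnpco2_dtemp = dlnp,
    dlnco2star_dtemp = dlnc,
    ratio = dlnp / dlnc
  )
}
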