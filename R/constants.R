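#' Equilibrium constants of the seawater CO2 system
#'
#' Evaluates the dissociation/solubility constants and conservative element
#' totals needed to solve the surface seawater CO2 system, on the total pH
#' scale, at 1 atm total pressure (surface only).
#'
#' The default (and currently only) set, `"lueker2000_total"`, is:
#' * `K0` CO2 solubility, Weiss (1974), mol kg-1 atm-1;
#' * `K1`, `K2` carbonic acid, Lueker et al. (2000), total scale;
#' * `KB` boric acid, Dickson (1990), total scale;
#' * `KW` water, Millero (1995), converted SWS -> total;
#' * `KS` bisulfate, Dickson (1990), free scale (used for scale conversions
#'   and the free-hydrogen term of total alkalinity);
#' * `K1p`, `K2p`, `K3p` phosphoric acid and `KSi` silicic acid,
#'   Millero (1995), converted SWS -> total;
#' * `KF` hydrogen fluoride, Perez & Fraga (1987), used only for the
#'   SWS -> total scale conversion;
#' * total boron from Lee et al. (2010), total sulfate and fluoride from
#'   standard salinity proportionality;
#' * `cf` fugacity coefficient from the Weiss (1974) virial expansion of CO2
#'   at 1 atm (dimensionless, slightly below 1).
#'
#' @param temperature Temperature in degrees Celsius (vectorized).
#' @param salinity Practical salinity (vectorized, recycled against
#'   `temperature`).
#' @param set Name of the constants set. Only `"lueker2000_total"` is
#'   available; the argument exists so alternative formulations can be added
#'   without changing calling code.
#'
#' @return A list of numeric vectors (`K0`, `K1`, `K2`, `KB`, `KW`, `KS`,
#'   `KF`, `K1p`, `K2p`, `K3p`, `KSi`, `BT`, `ST`, `FT`, `cf`), all in
#'   mol kg-1 where dimensional, plus the attribute `constants_set`.
#'
#' @examples
#' k <- carb_constants(2, 33)
#' k$K0   # CO2 solubility at 2 degC, S = 33
#' @export
carb_constants <- function(temperature, salinity, set = "lueker2000_total") {
  if (!identical(set, "lueker2000_total")) {
    rlang::abort(paste0("unknown constants set: ", set))
  }
  n <- max(length(temperature), length(salinity))
  T <- rep_len(as.numeric(temperature), n)
  S <- rep_len(as.numeric(salinity), n)
  if (any(!is.finite(T)) || any(!is.finite(S))) {
    rlang::abort("carb_constants(): non-finite temperature or salinity")
  }
  TK <- T + 273.15
  lnT <- log(TK)
  sqS <- sqrt(S)
  I <- 19.924 * S / (1000 - 1.005 * S)
  sqI <- sqrt(I)

  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  K0 <- exp(lnK0)

  pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * lnT - 0.011555 * S + 0.0001152 * S^2
  pK2 <- 471.78 / TK + 25.9290 - 3.16967 * lnT - 0.01781 * S + 0.0001122 * S^2
  K1 <- 10^(-pK1)
  K2 <- 10^(-pK2)

  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 - 0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * S -
    (24.4344 + 25.085 * sqS + 0.2474 * S) * lnT + 0.053105 * sqS * TK
  KB <- exp(lnKB)

  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnT +
    (-13856 / TK + 324.57 - 47.986 * lnT) * sqI +
    (35474 / TK - 771.54 + 114.723 * lnT) * I -
    (2698 / TK) * I^1.5 + (1776 / TK) * I^2 + log(1 - 0.001005 * S)
  KS <- exp(lnKS)

  ST <- 0.14 / 96.062 * S / 1.80655
  FT <- 0.000067 / 18.9984 * S / 1.80655
  KFt <- exp(874 / TK - 9.68 + 0.111 * sqS)   # total scale
  KFf <- KFt / (1 + ST / KS)                  # free scale
  sws2tot <- (1 + ST / KS) / (1 + ST / KS + FT / KFf)

  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnT +
    (118.67 / TK - 5.977 + 1.0495 * lnT) * sqS - 0.01615 * S
  KW <- exp(lnKW) * sws2tot

  lnK1p <- -4576.752 / TK + 115.525 - 18.453 * lnT +
    (-106.736 / TK + 0.69171) * sqS + (-0.65643 / TK - 0.01844) * S
  lnK2p <- -8814.715 / TK + 172.0883 - 27.927 * lnT +
    (-160.340 / TK + 1.3566) * sqS + (0.37335 / TK - 0.05778) * S
  lnK3p <- -3070.75 / TK - 18.141 +
    (17.27039 / TK + 2.81197) * sqS + (-44.99486 / TK - 0.09984) * S
  lnKSi <- -8904.2 / TK + 117.385 - 19.334 * lnT +
    (-458.79 / TK + 3.5913) * sqI + (188.74 / TK - 1.5998) * I +
    (-12.1652 / TK + 0.07871) * I^2 + log(1 - 0.001005 * S)

  BT <- 0.0004326 * S / 35

  # Weiss (1974) virial coefficients, cm3 mol-1; xCO2 << 1 so the cross term
  # reduces to 2*delta. R = 82.05746 cm3 atm mol-1 K-1, P = 1 atm.
  Bv <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
  dv <- 57.7 - 0.118 * TK
  cf <- exp((Bv + 2 * dv) / (82.05746 * TK))

  out <- list(
    K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS, KF = KFf,
    K1p = exp(lnK1p) * sws2tot, K2p = exp(lnK2p) * sws2tot,
    K3p = exp(lnK3p) * sws2tot, KSi = exp(lnKSi) * sws2tot,
    BT = BT, ST = ST, FT = FT, cf = cf
  )
  attr(out, "constants_set") <- set
  out
}
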