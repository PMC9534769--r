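#' Atmospheric CO2 scenario configuration
#'
#' @param kind `"one_percent"` (compound 1 percent per year growth, doubling
#'   at year 70 and quadrupling at year 140 of the run), `"rcp_like"` (slow
#'   historical rise accelerating to `end_ppm` by the final year, a smooth
#'   quartic ramp emulating a high-end concentration pathway) or `"flat"`
#'   (constant).
#' @param years Integer years covered by the scenario.
#' @param start_ppm Starting (preindustrial) concentration, ppm.
#' @param end_ppm Final concentration for `"rcp_like"`, ppm.
#' @param rate Annual growth rate for `"one_percent"`.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(kind = c("rcp_like", "one_percent", "flat"),
                            years = 1850:2100, start_ppm = 284,
                            end_ppm = 936, rate = 0.01) {
  kind <- match.arg(kind)
  stopifnot(start_ppm > 0, end_ppm > 0, rate > 0, length(years) >= 1)
  structure(
    list(kind = kind, years = as.integer(years), start_ppm = start_ppm,
         end_ppm = end_ppm, rate = rate),
    class = "scenario_config"
  )
}

#' Annual atmospheric CO2 series of a scenario
#'
#' @param config A [scenario_config()].
#' @return A tibble `year`, `ppm`. Deterministic; for the growth pathways the
#'   series is strictly increasing.
#' @export
co2_pathway <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  y <- config$years
  t <- seq_along(y) - 1
  ppm <- switch(config$kind,
    one_percent = config$start_ppm * (1 + config$rate)^t,
    flat = rep(config$start_ppm, length(y)),
    rcp_like = {
      s <- t / max(t, 1)
      config$start_ppm + (config$end_ppm - config$start_ppm) * s^4
    }
  )
  tibble::tibble(year = y, ppm = ppm)
}

#' Emulator parameters for the synthetic Earth-system-model fields
#'
#' Defaults describe a modern polar ocean in the biologically dominated
#' regime: a broad summer pCO2 minimum from DIC drawdown, seasonal ice whose
#' retreat advances with warming, summer-amplified surface warming tied to
#' earlier retreat, a secular DIC trend tracking atmospheric CO2, and
#' melt-season freshening that dilutes salinity and alkalinity.
#'
#' @param warming_per_doubling Annual-mean surface warming per CO2 doubling
#'   (degC); polar-amplified.
#' @param ice_retreat_sensitivity Months of retreat advance per degC of
#'   warming.
#' @param summer_warming_gain Extra open-water summer temperature maximum per
#'   month of earlier retreat (degC month-1).
#' @param bio_drawdown Peak biological DIC drawdown (umol kg-1) in fully
#'   seasonally open cells; scaled down where ice cover persists.
#' @param npp_phase_advance Months of earlier NPP peak per month of earlier
#'   ice retreat.
#' @param ct_trend_coupling Fraction of the equilibrium surface-DIC rise
#'   (relative to the atmospheric pathway) actually realized; 1 = full
#'   equilibration, <1 = air-sea disequilibrium.
#' @param melt_dilution Salinity reduction (psu) at full melt openness;
#'   alkalinity and the non-biological part of DIC dilute proportionally.
#' @param alk0 Reference total alkalinity (umol kg-1) at the reference
#'   salinity.
#' @param noise_sd Named list of Gaussian noise standard deviations per field
#'   (`temp` degC, `sal`, `alk`, `dic` umol kg-1, `ice`, `npp`).
#' @return An `emulator_params` list.
#' @export
emulator_params <- function(warming_per_doubling = 2.5,
                            ice_retreat_sensitivity = 0.6,
                            summer_warming_gain = 2.0,
                            bio_drawdown = 35,
                            npp_phase_advance = 0.4,
                            ct_trend_coupling = 0.8,
                            melt_dilution = 1.2,
                            alk0 = 2220,
                            noise_sd = list(temp = 0.25, sal = 0.08, alk = 4,
                                            dic = 4, ice = 0.02, npp = 0.05)) {
  structure(
    list(
      warming_per_doubling = warming_per_doubling,
      ice_retreat_sensitivity = ice_retreat_sensitivity,
      summer_warming_gain = summer_warming_gain,
      bio_drawdown = bio_drawdown,
      npp_phase_advance = npp_phase_advance,
      ct_trend_coupling = ct_trend_coupling,
      melt_dilution = melt_dilution,
      alk0 = alk0,
      noise_sd = noise_sd
    ),
    class = "emulator_params"
  )
}

#' Equilibrium surface DIC for a target pCO2
#'
#' Inverts the carbonate system: finds the DIC at which seawater pCO2 equals
#' `target_pco2` for given temperature, salinity and alkalinity (Newton
#' iteration on DIC, vectorized).
#'
#' @param target_pco2 Target pCO2 (uatm).
#' @param temp,sal,alk State variables (degC, psu, umol kg-1).
#' @param tol Convergence tolerance on pCO2 (uatm).
#' @return DIC (umol kg-1).
#' @export
dic_equilibrium <- function(target_pco2, temp, sal, alk, tol = 1e-8) {
  n <- max(length(target_pco2), length(temp), length(sal), length(alk))
  st <- tibble::tibble(
    temp = rep_len(temp, n), sal = rep_len(sal, n),
    alk = rep_len(alk, n), dic = rep_len(alk, n) * 0.92
  )
  tgt <- rep_len(target_pco2, n)
  for (it in 1:60) {
    p <- solve_carbonate(st)$pco2
    st2 <- st
    st2$dic <- st$dic + 0.5
    slope <- (solve_carbonate(st2)$pco2 - p) / 0.5
    step <- (tgt - p) / slope
    st$dic <- pmin(pmax(st$dic + step, 0.5 * st$alk), 1.2 * st$alk)
    if (max(abs(tgt - p)) < tol) break
  }
  st$dic
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

cell_parameters <- function(grid, pathway, params) {
  cp <- grid[grid$domain, c("cell", "lat", "area", "shelf")]
  cp$r0 <- 6.5 + 0.35 * (cp$lat - 70)
  cp$g0 <- 9.5 + 0.1 * (cp$lat - 70)
  cp$s0_ice <- clamp(0.08 + 0.09 * (cp$lat - 72), 0.02, 0.95)
  cp$tmax0 <- pmax(0.3, 1.5 - 0.2 * (cp$lat - 70))
  cp$bio_scale <- 0.2 + 0.8 * (1 - cp$s0_ice)
  cp$s0_sal <- 32.5 - 0.05 * (cp$lat - 70)
  # secular DIC baseline per latitude band and year: preindustrial
  # equilibrium plus a fraction of the equilibrium rise along the pathway
  bands <- unique(cp[, c("lat", "s0_sal")])
  by <- tidyr::expand_grid(bands, pathway)
  ctpre <- dic_equilibrium(pathway$ppm[1], -1, bands$s0_sal, params$alk0)
  cteq <- dic_equilibrium(by$ppm, -1, by$s0_sal, params$alk0)
  by$ct_base <- rep(ctpre, each = nrow(pathway)) +
    params$ct_trend_coupling * (cteq - rep(ctpre, each = nrow(pathway)))
  list(cellpar = cp, ct_base = by[, c("lat", "year", "ct_base")])
}

#' Generate synthetic ESM-like monthly surface fields
#'
#' Produces monthly fields of temperature, salinity, alkalinity, DIC, sea-ice
#' concentration and NPP for every ocean cell of `grid` along the scenario's
#' CO2 pathway, plus a truth record computed from the noise-free construction
#' (see [synthetic_truth()]). The same seed reproduces the output exactly.
#'
#' @param params [emulator_params()].
#' @param scenario [scenario_config()].
#' @param grid Grid tibble from [polar_cap_grid()].
#' @param seed Integer RNG seed for the field noise.
#' @param noise Add Gaussian noise at `params$noise_sd`? (`FALSE` gives the
#'   deterministic construction.)
#' @param truth Compute and attach the truth record?
#' @param summer Summer window used for the truth crossover.
#' @return A `synth_fields` list: `fields` (tibble: `cell`, `year`, `month`,
#'   `ppm`, `temp`, `sal`, `alk`, `dic`, `ice`, `npp`), `truth`, `grid`,
#'   `scenario`, `params`, `seed`.
#' @export
generate_fields <- function(params, scenario, grid, seed = 1L,
                            noise = TRUE, truth = TRUE, summer = 6:9) {
  stopifnot(inherits(params, "emulator_params"),
            inherits(scenario, "scenario_config"))
  pathway <- co2_pathway(scenario)
  cpar <- cell_parameters(grid, pathway, params)
  cellpar <- dplyr::left_join(
    tidyr::expand_grid(cpar$cellpar, year = pathway$year),
    cpar$ct_base, by = c("lat", "year")
  )
  # construct_fields expects one row per cell with ct_base varying by year;
  # fold the year dependence in by passing per-(cell, year) parameters
  base <- construct_per_year(cellpar, pathway, params)
  check_physical(base)
  fields <- base
  if (noise) {
    fields <- with_seed(seed, add_noise(base, params$noise_sd))
  }
  tr <- NULL
  if (truth) {
    tr <- synthetic_truth(base, grid, summer = summer)
  }
  structure(
    list(fields = fields, truth = tr, grid = grid, scenario = scenario,
         params = params, seed = as.integer(seed)),
    class = "synth_fields"
  )
}

construct_per_year <- function(cellpar_year, pathway, params) {
  d <- tidyr::expand_grid(cellpar_year, month = 1:12)
  d <- dplyr::left_join(d, pathway, by = "year")
  W <- params$warming_per_doubling * log2(d$ppm / pathway$ppm[1])
  r <- clamp(d$r0 - params$ice_retreat_sensitivity * W, 4, 11.5)
  g <- clamp(d$g0 + 0.5 * (d$r0 - r), r + 1, 12.5)
  w_ice <- clamp(0.97 - 0.03 * W, 0.5, 0.99)
  s_ice <- clamp(d$s0_ice - 0.25 * W, 0.01, 0.96)
  open <- stats::plogis((d$month - r) / 0.4) * stats::plogis((g - d$month) / 0.4)
  ice <- clamp(s_ice + (w_ice - s_ice) * (1 - open), 0, 1)
  tmax <- d$tmax0 + params$summer_warming_gain * pmax(0, d$r0 - r) + 0.3 * W
  mT <- clamp(8.2 - 0.2 * (d$r0 - r), 7, 9)
  topen <- tmax * exp(-(d$month - mT)^2 / (2 * 1.8^2))
  temp <- ice * (-1.75) + (1 - ice) * topen
  p_npp <- clamp(7.2 - params$npp_phase_advance * (d$r0 - r), 5, 8)
  npp <- d$bio_scale * (1 + 0.05 * W) * exp(-(d$month - p_npp)^2 / (2 * 1.3^2))
  # DIC deficit: sharp drawdown at the bloom, slow resupply through winter
  # (mixing/remineralization), so DIC peaks in spring just before the bloom
  p_dd <- p_npp
  dpre <- (p_dd - d$month) %% 12
  dpost <- (d$month - p_dd) %% 12
  shape <- pmax(exp(-dpre^2 / (2 * 1.1^2)), pmax(0, 1 - dpost / 8))
  drawdown <- params$bio_drawdown * d$bio_scale * shape
  melt <- pmax(0, w_ice - ice)
  sal <- d$s0_sal - params$melt_dilution * melt
  alk <- params$alk0 * sal / d$s0_sal
  dic <- d$ct_base * sal / d$s0_sal - drawdown
  out <- tibble::tibble(
    cell = d$cell, year = d$year, month = d$month, ppm = d$ppm,
    temp = temp, sal = sal, alk = alk, dic = dic, ice = ice, npp = npp
  )
  dplyr::arrange(out, .data$cell, .data$year, .data$month)
}

check_physical <- function(base) {
  for (v in c("temp", "sal", "alk", "dic", "ice", "npp")) {
    lim <- switch(v, temp = c(-2, 40), sal = c(0, 45), ice = c(0, 1),
                  alk = c(0, Inf), dic = c(0, Inf), npp = c(0, Inf))
    bad <- which(base[[v]] < lim[1] | base[[v]] > lim[2] | !is.finite(base[[v]]))
    if (length(bad)) {
      ex <- bad[1]
      rlang::abort(sprintf(
        "generate_fields(): unphysical %s = %.4g at cell %d, year %d, month %d",
        v, base[[v]][ex], base$cell[ex], base$year[ex], base$month[ex]
      ))
    }
  }
  invisible(base)
}

add_noise <- function(base, sd) {
  n <- nrow(base)
  base$temp <- pmax(-1.9, base$temp + stats::rnorm(n, 0, sd$temp))
  base$sal <- pmax(0, base$sal + stats::rnorm(n, 0, sd$sal))
  base$alk <- pmax(0, base$alk + stats::rnorm(n, 0, sd$alk))
  base$dic <- pmax(0, base$dic + stats::rnorm(n, 0, sd$dic))
  base$ice <- clamp(base$ice + stats::rnorm(n, 0, sd$ice), 0, 1)
  base$npp <- pmax(0, base$npp * (1 + stats::rnorm(n, 0, sd$npp)))
  base
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Truth record of a synthetic scenario
#'
#' Computes, from the noise-free construction, the quantities a correct
#' analysis should recover: per-decade basin-mean monthly pCO2 anomalies,
#' the three-stage classification, the constructed crossover CO2 level
#' (linear interpolation of the summer-minus-winter margin zero crossing
#' over decade-mean CO2), the exact one-at-a-time thermal/non-thermal split
#' of the basin-mean climatological state, and decadal ice retreat/growth
#' dates.
#'
#' @param base Noise-free fields tibble (from the internal construction).
#' @param grid Grid tibble.
#' @param summer Summer window (months).
#' @return A list: `decades` (tibble: `decade_start`, `ppm`, `stage`,
#'   `margin`, `retreat_month`, `growth_month`), `anomalies` (tibble:
#'   `decade_start`, `ppm`, `month`, `anom`, `thermal`, `nonthermal`),
#'   `crossover_ppm` (NA if never reached), `crossover_decade`.
#' @export
synthetic_truth <- function(base, grid, summer = 6:9) {
  years <- sort(unique(base$year))
  n_dec <- length(years) %/% 10
  if (n_dec < 2) rlang::abort("synthetic_truth(): need at least 2 full decades")
  dec_start <- years[1] + 10 * (seq_len(n_dec) - 1)
  areas <- grid$area[match(sort(unique(base$cell)), grid$cell)]
  rows <- list()
  anom_rows <- list()
  for (ds in dec_start) {
    d <- base[base$year >= ds & base$year <= ds + 9, ]
    clim <- dplyr::summarise(
      dplyr::group_by(d, .data$cell, .data$month),
      temp = mean(.data$temp), sal = mean(.data$sal),
      alk = mean(.data$alk), dic = mean(.data$dic),
      ice = mean(.data$ice), .groups = "drop"
    )
    clim$pco2 <- solve_carbonate(clim[, c("temp", "sal", "alk", "dic")])$pco2
    # area-weighted basin means per month
    bm <- dplyr::summarise(
      dplyr::group_by(clim, .data$month),
      dplyr::across(c("temp", "sal", "alk", "dic", "pco2"),
                    ~ sum(.x * areas) / sum(areas)),
      .groups = "drop"
    )
    anom <- bm$pco2 - mean(bm$pco2)
    # exact one-at-a-time thermal component of the basin-mean state
    ref <- tibble::tibble(
      temp = mean(bm$temp), sal = mean(bm$sal),
      alk = mean(bm$alk), dic = mean(bm$dic)
    )
    tvar <- tibble::tibble(temp = bm$temp, sal = ref$sal, alk = ref$alk, dic = ref$dic)
    th <- solve_carbonate(tvar)$pco2 - solve_carbonate(ref)$pco2
    th <- th - mean(th)
    ice_d <- ice_transition_dates(
      dplyr::left_join(clim[, c("cell", "month", "ice")],
                       grid[, c("cell", "area")], by = "cell")
    )
    ppm_mid <- mean(base$ppm[base$year >= ds & base$year <= ds + 9])
    rows[[length(rows) + 1]] <- tibble::tibble(
      decade_start = ds, ppm = ppm_mid,
      stage = stage_classify(anom, summer = summer),
      margin = max(anom[summer]) - max(anom[-summer]),
      retreat_month = ice_d$mean$retreat_month,
      growth_month = ice_d$mean$growth_month
    )
    anom_rows[[length(anom_rows) + 1]] <- tibble::tibble(
      decade_start = ds, ppm = ppm_mid, month = 1:12,
      anom = anom, thermal = th, nonthermal = anom - th
    )
  }
  decades <- dplyr::bind_rows(rows)
  cross_ppm <- NA_real_
  cross_dec <- NA_integer_
  pos <- which(decades$margin > 0)
  if (length(pos)) {
    j <- pos[1]
    cross_dec <- decades$decade_start[j]
    if (j == 1) {
      cross_ppm <- decades$ppm[1]
    } else {
      f <- decades$margin[j - 1] / (decades$margin[j - 1] - decades$margin[j])
      cross_ppm <- decades$ppm[j - 1] + f * (decades$ppm[j] - decades$ppm[j - 1])
    }
  }
  list(
    decades = decades,
    anomalies = dplyr::bind_rows(anom_rows),
    crossover_ppm = cross_ppm,
    crossover_decade = cross_dec
  )
}
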