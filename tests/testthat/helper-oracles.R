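# Independent oracles and fixture builders used across the test files.

# Draw n random ocean-like surface states (seeded by the caller).
random_states <- function(n) {
  seawater_state(
    temp = stats::runif(n, -1.8, 28),
    sal = stats::runif(n, 28, 37),
    alk = stats::runif(n, 2050, 2450),
    dic = stats::runif(n, 1850, 2250),
    phos = stats::runif(n, 0, 2),
    sil = stats::runif(n, 0, 60)
  )
}

# Brute-force bisection of the total-alkalinity balance over pH in [2, 12],
# written independently of the package's Newton solver. Uses the same
# constants (the constants are not under test here, the root-finding is).
bisect_ph <- function(state, iter = 60) {
  k <- carb_constants(state$temp, state$sal)
  alk <- state$alk * 1e-6
  dic <- state$dic * 1e-6
  phos <- state$phos * 1e-6
  sil <- state$sil * 1e-6
  resid <- function(ph) {
    h <- 10^(-ph)
    d <- h^2 + k$K1 * h + k$K1 * k$K2
    hco3 <- dic * k$K1 * h / d
    co3 <- dic * k$K1 * k$K2 / d
    dp <- h^3 + k$K1p * h^2 + k$K1p * k$K2p * h + k$K1p * k$K2p * k$K3p
    hco3 + 2 * co3 +
      k$BT * k$KB / (k$KB + h) +
      k$KW / h -
      h / (1 + k$ST / k$KS) +
      phos * (k$K1p * k$K2p * h + 2 * k$K1p * k$K2p * k$K3p - h^3) / dp +
      sil * k$KSi / (k$KSi + h) -
      alk
  }
  lo <- rep(2, nrow(state))
  hi <- rep(12, nrow(state))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    f <- resid(mid)
    # residual decreases with H, so increases with pH
    hi <- ifelse(f > 0, mid, hi)
    lo <- ifelse(f > 0, lo, mid)
  }
  (lo + hi) / 2
}

# Independent secant estimate of d pCO2 / d driver (one-sided differences at
# a coarser step than the package's central differences).
secant_sensitivity <- function(state, driver, h) {
  up <- state
  up[[driver]] <- up[[driver]] + h
  (solve_carbonate(up)$pco2 - solve_carbonate(state)$pco2) / h
}

# A 12-month cell climatology with mild smooth seasonal cycles around a
# polar mean state; returns the states plus the directly solved pCO2.
smooth_cell_climatology <- function(t_amp = 2, dic_amp = 25, sal_amp = 0.4,
                                    alk_prop = TRUE) {
  m <- 1:12
  sal <- 32.5 - sal_amp * exp(-(m - 8)^2 / 6)
  alk <- if (alk_prop) 2220 * sal / 32.5 else rep(2220, 12)
  st <- tibble::tibble(
    month = m,
    temp = -0.5 + t_amp * exp(-(m - 8)^2 / 8),
    sal = sal,
    alk = alk,
    dic = 2050 - dic_amp * exp(-(m - 7.5)^2 / 5)
  )
  st$pco2 <- solve_carbonate(st[, c("temp", "sal", "alk", "dic")])$pco2
  st
}

# Small fast grid + scenario for pipeline-level tests.
tiny_grid <- function() polar_cap_grid(dlat = 8, dlon = 45)
default_scenario <- function() scenario_config("rcp_like")

# Stress configuration: strong warming/drawdown, high-end pathway, no noise -
# the regime where single-step linearization of the modern-to-future change
# degrades and the year-pair incremental decomposition is expected to win.
stress_params <- function() {
  emulator_params(summer_warming_gain = 4.5, bio_drawdown = 70,
                  warming_per_doubling = 4.0)
}
stress_scenario <- function() scenario_config("rcp_like", end_ppm = 1400)
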