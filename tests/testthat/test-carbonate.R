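test_that("solved states satisfy the Henry/K1 identity and carbon conservation", {
  sol <- solve_carbonate(seawater_state(2, 33, 2130, 2000))
  # pCO2 = [H+][HCO3-] / (Cf K0 K1), unit-consistent (mol kg-1, atm)
  rhs <- sol$h * (sol$hco3 * 1e-6) / (sol$cf * sol$k0 * sol$k1) * 1e6
  expect_lt(abs(sol$pco2 - rhs) / sol$pco2, 1e-8)
  expect_lt(abs(sol$co2star + sol$hco3 + sol$co3 - sol$dic) / sol$dic, 1e-6)
  expect_gt(sol$cf, 0.99)
  expect_lte(sol$cf, 1.0)
  # plausible polar surface chemistry
  expect_gt(sol$ph, 7.5)
  expect_lt(sol$ph, 8.5)
})

test_that("carbon-free water carries no CO2", {
  sol <- solve_carbonate(seawater_state(2, 33, 2130, 0))
  expect_equal(sol$pco2, 0)
  expect_equal(sol$co2star, 0)
  expect_gt(sol$ph, 8)   # alkalinity without DIC is basic
})

test_that("Newton solver matches the brute-force bisection oracle", {
  withr::with_seed(42, {
    st <- random_states(100)
  })
  sol <- solve_carbonate(st)
  ph_oracle <- bisect_ph(st)
  expect_lt(max(abs(sol$ph - ph_oracle)), 1e-8)
  # identity and conservation hold for every state
  rhs <- sol$h * (sol$hco3 * 1e-6) / (sol$cf * sol$k0 * sol$k1) * 1e6
  expect_lt(max(abs(sol$pco2 - rhs) / sol$pco2), 1e-8)
  expect_lt(max(abs(sol$co2star + sol$hco3 + sol$co3 - sol$dic) / sol$dic), 1e-6)
})

test_that("pCO2 is monotone in DIC (up) and alkalinity (down)", {
  dic_grid <- seawater_state(2, 33, 2130, seq(1900, 2100, by = 10))
  p_dic <- solve_carbonate(dic_grid)$pco2
  expect_true(all(diff(p_dic) > 0))
  alk_grid <- seawater_state(2, 33, seq(2050, 2300, by = 10), 2000)
  p_alk <- solve_carbonate(alk_grid)$pco2
  expect_true(all(diff(p_alk) < 0))
})

test_that("[H+] is near-proportional to pCO2 at fixed temperature", {
  st <- seawater_state(2, 33, 2130, seq(1900, 2100, by = 5))
  sol <- solve_carbonate(st)
  expect_gt(stats::cor(sol$h, sol$pco2), 0.999)
})

test_that("invalid states are rejected with informative errors", {
  expect_error(solve_carbonate(seawater_state(2, 33, 2130, 2000)[, -1]),
               "missing columns")
  bad <- tibble::tibble(temp = 45, sal = 33, alk = 2130, dic = 2000)
  expect_error(solve_carbonate(bad), "outside valid ranges")
  bad2 <- tibble::tibble(temp = 2, sal = 33, alk = 2130, dic = -5)
  expect_error(solve_carbonate(bad2), "outside valid ranges")
})

test_that("sensitivities carry the chemical sign pattern (+, ., -, +)", {
  withr::with_seed(7, st <- random_states(20))
  sens <- carbonate_sensitivities(st)
  expect_true(all(sens$dpco2_dtemp > 0))
  expect_true(all(sens$dpco2_dalk < 0))
  expect_true(all(sens$dpco2_ddic > 0))
})

test_that("central differences are step-converged (halving changes < 1e-4 relative)", {
  st <- seawater_state(2, 33, 2130, 2000)
  s1 <- carbonate_sensitivities(st, steps = sens_steps())
  s2 <- carbonate_sensitivities(st, steps = sens_steps(temp = 5e-4, sal = 5e-4,
                                                       alk = 0.05, dic = 0.05))
  for (v in c("dpco2_dtemp", "dpco2_dsal", "dpco2_dalk", "dpco2_ddic")) {
    expect_lt(abs(s1[[v]] - s2[[v]]) / abs(s1[[v]]), 1e-4)
  }
})

test_that("sensitivities agree with an independent secant estimate", {
  st <- seawater_state(2, 33, 2130, 2000)
  sens <- carbonate_sensitivities(st)
  # coarse one-sided secants bracket the central-difference values
  for (drv in c("temp", "dic", "alk")) {
    h <- switch(drv, temp = 0.05, dic = 2, alk = 2)
    up <- secant_sensitivity(st, drv, h)
    dn <- secant_sensitivity(st, drv, -h)
    v <- sens[[paste0("dpco2_d", drv)]]
    expect_gt(v, min(up, dn) - 1e-9)
    expect_lt(v, max(up, dn) + 1e-9)
  }
  # normalized temperature sensitivity in the expected polar band
  expect_gt(sens$dpco2_dtemp / sens$pco2, 0.035)
  expect_lt(sens$dpco2_dtemp / sens$pco2, 0.055)
})

test_that("out-of-range perturbations shrink the step once, then fail", {
  # at temp = -1.9995 the full 1e-3 step undershoots -2 but the halved works
  edge <- seawater_state(-1.9995, 33, 2130, 2000)
  expect_silent(carbonate_sensitivities(edge))
  at_edge <- seawater_state(-2, 33, 2130, 2000)
  expect_error(carbonate_sensitivities(at_edge), "out of range")
})

test_that("closed-system pCO2/[CO2*] temperature-sensitivity ratio behaves", {
  polar <- seawater_state(-1, 33, 2130, 2000)
  r <- temperature_sensitivity_ratio(polar)
  expect_gt(r$ratio, 6)
  expect_lt(r$ratio, 8)
  # exact Henry's-law identity: dln pCO2/dT - dln CO2*/dT = -dln(K0 cf)/dT
  h <- 1e-3
  ku <- carb_constants(-1 + h, 33)
  kd <- carb_constants(-1 - h, 33)
  dlnk <- (log(ku$K0 * ku$cf) - log(kd$K0 * kd$cf)) / (2 * h)
  expect_lt(abs((r$dlnpco2_dtemp - r$dlnco2star_dtemp) - (-dlnk)), 1e-6)
  # ratio matches independent secant construction
  h2 <- 0.02
  pu <- solve_carbonate(seawater_state(-1 + h2, 33, 2130, 2000))
  pd <- solve_carbonate(seawater_state(-1 - h2, 33, 2130, 2000))
  r2 <- (log(pu$pco2) - log(pd$pco2)) / (log(pu$co2star) - log(pd$co2star))
  expect_lt(abs(r$ratio - r2) / r2, 1e-3)
  # the ratio declines toward warm water
  warm <- temperature_sensitivity_ratio(seawater_state(25, 33, 2130, 2000))
  expect_lt(warm$ratio, 4)
})
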