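const_sens <- function(gt = 12, gs = 8, ga = -1.6, gd = 2.1) {
  tibble::tibble(month = 1:12, dpco2_dtemp = gt, dpco2_dsal = gs,
                 dpco2_dalk = ga, dpco2_ddic = gd)
}

flat_states <- function() {
  tibble::tibble(month = 1:12, temp = 0, sal = 33, alk = 2200, dic = 2050)
}

test_that("zero anomalies give zero terms; a single driver gives a single term", {
  a0 <- driver_anomalies(flat_states())
  t0 <- taylor_terms(a0, const_sens())
  expect_equal(t0$reconstructed_total, rep(0, 12))
  st <- flat_states()
  st$temp <- st$temp + sin(2 * pi * (1:12) / 12)
  a1 <- driver_anomalies(st)
  t1 <- taylor_terms(a1, const_sens())
  expect_equal(t1$reconstructed_total, t1$thermal)
  expect_equal(t1$haline, rep(0, 12))
  expect_equal(t1$thermal, 12 * (st$temp - mean(st$temp)), tolerance = 1e-12)
})

test_that("terms add to the reconstruction exactly and closure is reported", {
  st <- smooth_cell_climatology()
  anoms <- driver_anomalies(st[, c("month", "temp", "sal", "alk", "dic")])
  sens <- carbonate_sensitivities(st[, c("month", "temp", "sal", "alk", "dic")])
  actual <- st$pco2 - mean(st$pco2)
  terms <- taylor_terms(anoms, sens, actual = actual)
  expect_equal(terms$reconstructed_total,
               terms$thermal + terms$haline + terms$alkalinity + terms$dic)
  cl <- term_closure(terms)
  expect_lt(cl$rel, 0.05)   # mild smooth anomalies: second-order terms small
})

test_that("effective sensitivities average the monthly and annual-mean values", {
  s <- const_sens()
  s$dpco2_ddic <- 1:12
  a <- driver_anomalies(flat_states())
  a$dic_anom <- rep(c(-1, 1), 6)
  tt <- taylor_terms(a, s)
  expect_equal(tt$dic, (1:12 + mean(1:12)) / 2 * rep(c(-1, 1), 6))
})

test_that("freshwater layout collapses correctly in the limiting regimes", {
  # constant salinity: no freshwater terms, bio terms equal the standard ones
  st <- flat_states()
  st$dic <- 2050 - 25 * exp(-((1:12) - 7)^2 / 5)
  st$alk <- 2200 + 5 * sin(2 * pi * (1:12) / 12)
  a <- driver_anomalies(st)
  s <- const_sens()
  std <- taylor_terms(a, s)
  fw <- freshwater_terms(a, s)
  expect_equal(fw$fw_alkalinity, rep(0, 12), tolerance = 1e-12)
  expect_equal(fw$fw_dic, rep(0, 12), tolerance = 1e-12)
  expect_equal(fw$bio_alkalinity, std$alkalinity, tolerance = 1e-12)
  expect_equal(fw$bio_dic, std$dic, tolerance = 1e-12)

  # pure melt dilution: bio terms vanish, salinity-driven terms carry it all
  m <- 1:12
  sal <- 32.5 - 1.2 * exp(-(m - 8)^2 / 4)
  st2 <- tibble::tibble(month = m, temp = 0, sal = sal,
                        alk = 2220 * sal / 32.5, dic = 2050 * sal / 32.5)
  a2 <- driver_anomalies(st2)
  fw2 <- freshwater_terms(a2, s)
  std2 <- taylor_terms(a2, s)
  expect_equal(fw2$bio_alkalinity, rep(0, 12), tolerance = 1e-9)
  expect_equal(fw2$bio_dic, rep(0, 12), tolerance = 1e-9)
  expect_equal(fw2$haline + fw2$fw_alkalinity + fw2$fw_dic,
               std2$reconstructed_total, tolerance = 1e-9)
})

test_that("freshwater and standard layouts reconstruct the same total", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      st <- tibble::tibble(
        month = 1:12,
        temp = stats::runif(12, -1.5, 2.5),
        sal = 32 + stats::rnorm(12, 0, 0.6),
        alk = 2200 + stats::rnorm(12, 0, 30),
        dic = 2050 + stats::rnorm(12, 0, 30)
      )
      a <- driver_anomalies(st)
      s <- carbonate_sensitivities(st[, c("month", "temp", "sal", "alk", "dic")])
      expect_equal(freshwater_terms(a, s)$reconstructed_total,
                   taylor_terms(a, s)$reconstructed_total,
                   tolerance = 1e-6)
    }
  })
})

make_yearly <- function(years, states_fun, sens_fun) {
  rows <- lapply(years, function(y) {
    st <- states_fun(y)
    ann <- colMeans(st[, c("temp", "sal", "alk", "dic")])
    tibble::tibble(
      year = y, month = 1:12,
      temp = st$temp, sal = st$sal, alk = st$alk, dic = st$dic,
      temp_anom = st$temp - ann["temp"], sal_anom = st$sal - ann["sal"],
      alk_anom = st$alk - ann["alk"], dic_anom = st$dic - ann["dic"],
      dpco2_dtemp = sens_fun(y)$dpco2_dtemp,
      dpco2_dsal = sens_fun(y)$dpco2_dsal,
      dpco2_dalk = sens_fun(y)$dpco2_dalk,
      dpco2_ddic = sens_fun(y)$dpco2_ddic
    )
  })
  dplyr::bind_rows(rows)
}

test_that("incremental decomposition is stationary under stationary drivers", {
  states_fun <- function(y) {
    tibble::tibble(temp = sin(2 * pi * (1:12) / 12), sal = rep(33, 12),
                   alk = rep(2200, 12), dic = 2050 + cos(2 * pi * (1:12) / 12) * 20)
  }
  yearly <- make_yearly(2006:2100, states_fun, function(y) const_sens())
  am <- driver_anomalies(cbind(tibble::tibble(month = 1:12), states_fun(2006)))
  attr(am, "decade") <- c(2006, 2015)
  modern <- taylor_terms(am, const_sens())
  fut <- incremental_terms(yearly, modern, modern = c(2006, 2015),
                           future = c(2091, 2100))
  expect_equal(fut$thermal, modern$thermal, tolerance = 1e-10)
  expect_equal(fut$dic, modern$dic, tolerance = 1e-10)
})

test_that("with constant sensitivities the year-pair sum telescopes to the basic result", {
  # linear-in-time drivers: anomaly shape grows linearly with year
  states_fun <- function(y) {
    f <- (y - 2006) / 94
    tibble::tibble(
      temp = (1 + 2 * f) * sin(2 * pi * (1:12) / 12),
      sal = rep(33, 12),
      alk = rep(2200, 12) + 0.3 * (y - 2006),
      dic = 2050 + (1 + f) * cos(2 * pi * (1:12) / 12) * 20 + 0.5 * (y - 2006)
    )
  }
  yearly <- make_yearly(2006:2100, states_fun, function(y) const_sens())
  dec_clim <- function(years) {
    sts <- lapply(years, states_fun)
    out <- Reduce(`+`, sts) / length(sts)
    cbind(tibble::tibble(month = 1:12), out)
  }
  am <- driver_anomalies(dec_clim(2006:2015))
  af <- driver_anomalies(dec_clim(2091:2100))
  modern <- taylor_terms(am, const_sens())
  basic_future <- taylor_terms(af, const_sens())
  incr_future <- incremental_terms(yearly, modern, modern = c(2006, 2015),
                                   future = c(2091, 2100))
  for (v in c("thermal", "haline", "alkalinity", "dic", "reconstructed_total")) {
    expect_equal(incr_future[[v]], basic_future[[v]], tolerance = 1e-8)
  }
})

test_that("incremental decomposition rejects gappy year coverage", {
  states_fun <- function(y) tibble::tibble(temp = 1:12 * 0.1, sal = 33,
                                           alk = 2200, dic = 2050)
  yearly <- make_yearly(c(2006:2050, 2052:2100), states_fun, function(y) const_sens())
  am <- driver_anomalies(cbind(tibble::tibble(month = 1:12), states_fun(2006)))
  modern <- taylor_terms(am, const_sens())
  expect_error(
    incremental_terms(yearly, modern, c(2006, 2015), c(2091, 2100)),
    "gap"
  )
})

test_that("thermal/non-thermal split is exact by construction", {
  st <- flat_states()
  st$temp <- sin(2 * pi * (1:12) / 12)
  a <- driver_anomalies(st)
  tt <- taylor_terms(a, const_sens())
  sp <- thermal_nonthermal_split(tt)
  expect_equal(sp$nonthermal, rep(0, 12))
  st2 <- smooth_cell_climatology()
  a2 <- driver_anomalies(st2[, c("month", "temp", "sal", "alk", "dic")])
  s2 <- carbonate_sensitivities(st2[, c("month", "temp", "sal", "alk", "dic")])
  t2 <- taylor_terms(a2, s2, actual = st2$pco2 - mean(st2$pco2))
  sp2 <- thermal_nonthermal_split(t2)
  expect_equal(sp2$thermal + sp2$nonthermal, t2$reconstructed_total)
  expect_equal(sp2$nonthermal_residual - sp2$nonthermal,
               t2$actual_total - t2$reconstructed_total)
})

test_that("closure error grows with imposed anomaly amplitude", {
  rels <- vapply(c(1, 2, 4), function(scale) {
    st <- smooth_cell_climatology(t_amp = 2 * scale, dic_amp = 25 * scale)
    a <- driver_anomalies(st[, c("month", "temp", "sal", "alk", "dic")])
    s <- carbonate_sensitivities(st[, c("month", "temp", "sal", "alk", "dic")])
    term_closure(taylor_terms(a, s, actual = st$pco2 - mean(st$pco2)))$rel
  }, numeric(1))
  expect_true(all(diff(rels) > 0))
})
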