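test_that("extreme months follow maxima/minima with earliest-month tie-break", {
  cyc <- cos(2 * pi * ((1:12) - 7) / 12)   # peaks in July
  e <- extreme_months(cyc)
  expect_equal(e$high_month, 7L)
  expect_equal(e$low_month, 1L)
  tied <- rep(0, 12); tied[c(4, 9)] <- 5
  expect_equal(extreme_months(tied)$high_month, 4L)
  deg <- extreme_months(rep(2, 12))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$high_month))
  expect_error(extreme_months(1:11), "12 finite")
})

test_that("ice transition dates follow the 0.15 threshold walk", {
  d <- tidyr::expand_grid(cell = 1:3, month = 1:12)
  d$area <- 1
  # cell 1: ice-bound all year; cell 2: retreat June, growth September;
  # cell 3: retreat August
  d$ice <- 0.9
  d$ice[d$cell == 2] <- rep(c(rep(0.8, 5), rep(0.1, 3), rep(0.8, 4)))[d$month[d$cell == 2]]
  d$ice[d$cell == 3] <- rep(c(rep(0.8, 7), rep(0.05, 2), rep(0.8, 3)))[d$month[d$cell == 3]]
  out <- ice_transition_dates(d)
  expect_true(is.na(out$cells$retreat_month[out$cells$cell == 1]))
  expect_equal(out$cells$retreat_month[out$cells$cell == 2], 6L)
  expect_equal(out$cells$growth_month[out$cells$cell == 2], 9L)
  expect_equal(out$cells$retreat_month[out$cells$cell == 3], 8L)
  expect_true(out$cells$late_summer_transition[out$cells$cell == 2])
  expect_false(out$cells$late_summer_transition[out$cells$cell == 3])
  # equal-area mean over the two retreating cells
  expect_equal(out$mean$retreat_month, 7)
  expect_error(ice_transition_dates(dplyr::mutate(d, ice = ice * 2)),
               "outside")
})

test_that("stage classification distinguishes the three seasonal shapes", {
  winter_max <- c(8, 10, 9, 6, 2, -3, -9, -10, -7, -2, 2, 4)
  expect_equal(stage_classify(winter_max), 1L)
  secondary <- winter_max; secondary[8] <- 3   # positive local max in August
  expect_equal(stage_classify(secondary), 2L)
  summer_max <- winter_max; summer_max[8] <- 14
  expect_equal(stage_classify(summer_max), 3L)
  # a positive but non-local-max summer value is not stage 2
  ramp <- c(10, 8, 6, 4, 2, 1, 2, 3, 4, 6, 8, 9)
  expect_equal(stage_classify(ramp), 1L)
})

make_levels <- function(ppms, winter_amp = 10, summer_fun) {
  dplyr::bind_rows(lapply(seq_along(ppms), function(i) {
    a <- winter_amp * cos(2 * pi * ((1:12) - 3) / 12)
    a[8] <- a[8] + summer_fun(ppms[i])
    tibble::tibble(co2_ppm = ppms[i], month = 1:12, anom = a - mean(a))
  }))
}

test_that("crossover detection recovers a constructed transition level", {
  ppms <- seq(300, 1000, by = 25)
  # August bump grows linearly and overtakes the March maximum exactly at
  # 700 ppm (August baseline is 10*cos(5*pi/6) = -8.66; March peak is +10)
  lv <- make_levels(ppms, winter_amp = 10,
                    summer_fun = function(p) 18.6603 + 25 * (p - 700) / 100)
  cross <- detect_crossover(lv, summer = 6:9)
  expect_equal(nrow(cross), 1)
  expect_lt(abs(cross$co2_ppm - 700), 25)   # within one CO2 grid step
  expect_equal(cross$month, 8L)
})

test_that("a stationary cycle never crosses over; detection is shift-invariant", {
  ppms <- seq(300, 900, by = 50)
  lv <- make_levels(ppms, summer_fun = function(p) -5)
  expect_equal(nrow(detect_crossover(lv)), 0)
  lv2 <- make_levels(ppms, summer_fun = function(p) 10 + (p - 600) / 10)
  c1 <- detect_crossover(lv2)
  lv3 <- dplyr::mutate(lv2, anom = anom + 42)
  c2 <- detect_crossover(lv3)
  expect_equal(c1$co2_ppm, c2$co2_ppm)
  expect_error(detect_crossover(lv2[seq(nrow(lv2), 1), ]), "increasing")
})

test_that("timing curves unwrap the circular month axis before smoothing", {
  ppms <- seq(300, 800, by = 20)
  # high month drifts Nov -> Dec -> Jan -> Feb (wraps through December)
  drift <- round(11 + 4 * (ppms - 300) / 500)
  lv <- dplyr::bind_rows(lapply(seq_along(ppms), function(i) {
    m <- ((drift[i] - 1) %% 12) + 1
    a <- rep(0, 12); a[m] <- 5; a[((m + 5) %% 12) + 1] <- -5
    tibble::tibble(co2_ppm = ppms[i], month = 1:12, anom = a)
  }))
  tc <- timing_curve(lv)
  expect_s3_class(tc, "timing_curve")
  # smoothed curve must not jump by ~11 months at the wrap
  jumps <- abs(diff(tc$high_month))
  jumps <- pmin(jumps, 12 - jumps)
  expect_lt(max(jumps), 1.5)
})

test_that("stage sequence along a monotone scenario is non-decreasing", {
  ppms <- seq(300, 1000, by = 25)
  lv <- make_levels(ppms, summer_fun = function(p) -8 + (p - 300) / 20)
  st <- stage_sequence(lv, summer = 6:9)
  expect_true(all(diff(st$stage) >= 0))
  expect_equal(sort(unique(st$stage)), c(1L, 2L, 3L))
})

test_that("debiased shelf summer maximum matches hand computation", {
  grid <- tibble::tibble(cell = 1:4, area = c(1, 2, 3, 10),
                         shelf = c(TRUE, TRUE, TRUE, FALSE))
  clim <- function(cells, f) {
    d <- tidyr::expand_grid(cell = cells, month = 1:12)
    d$temp <- f(d$cell, d$month)
    d
  }
  obs <- clim(1:4, function(c, m) 2 + sin(2 * pi * m / 12) + c)
  hist <- clim(1:4, function(c, m) 2 + sin(2 * pi * m / 12) + c + 2)  # +2 bias
  fut <- clim(1:4, function(c, m) 8 + 2 * sin(2 * pi * m / 12) + c + 2)
  got <- debias_summer_max(hist, obs, fut, grid)
  # per-cell debiased future = 8 + 2 sin + c; annual max = 10 + c
  expect_equal(got, (11 * 1 + 12 * 2 + 13 * 3) / 6)
  # zero bias reduces to the raw area-weighted future maxima
  got0 <- debias_summer_max(obs, obs, fut, grid)
  expect_equal(got0, got + 2)
  expect_error(debias_summer_max(hist, obs, fut,
                                 dplyr::mutate(grid, shelf = FALSE)),
               "empty shelf")
})
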