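#' Months of the annual high and low of a 12-point cycle
#'
#' Selects the integer months of the maximum and minimum from 12 basin (or
#' cell) monthly values. Ties are broken to the earliest month. An all-equal
#' cycle is reported as degenerate rather than assigned an arbitrary month.
#'
#' @param x Numeric vector of 12 monthly values (month order 1-12).
#' @param tol Values within `tol` of each other are considered tied for the
#'   degeneracy check.
#' @return A one-row tibble: `high_month`, `low_month` (integer or NA),
#'   `degenerate` (logical).
#' @export
extreme_months <- function(x, tol = 0) {
  if (length(x) != 12 || any(!is.finite(x))) {
    rlang::abort("extreme_months(): need 12 finite monthly values")
  }
  if (diff(range(x)) <= tol) {
    return(tibble::tibble(high_month = NA_integer_, low_month = NA_integer_,
                          degenerate = TRUE))
  }
  tibble::tibble(
    high_month = which.max(x),          # which.max/min take the earliest tie
    low_month = which.min(x),
    degenerate = FALSE
  )
}

#' Sea-ice retreat and growth dates
#'
#' Per cell, the retreat month is the first month sea-ice concentration drops
#' below `threshold` and the growth month the first later month it rises back
#' to or above it. Cells that never drop below the threshold (or are ice free
#' all year) have no event and are excluded from the area-weighted mean month
#' indices. A cell whose retreat month falls on or before July is flagged as
#' a "late-summer transition" cell (ice gone before 1 August).
#'
#' @param data Data frame with columns `cell`, `month`, `ice` (concentration
#'   in \[0, 1\]) and `area`; 12 rows per cell.
#' @param threshold Ice-concentration threshold (default 0.15).
#' @return A list with `cells` (tibble: `cell`, `retreat_month`,
#'   `growth_month`, `late_summer_transition`) and `mean` (one-row tibble of
#'   area-weighted mean retreat/growth month over cells with events).
#' @export
ice_transition_dates <- function(data, threshold = 0.15) {
  if (!all(c("cell", "month", "ice", "area") %in% names(data))) {
    rlang::abort("ice_transition_dates(): need columns cell, month, ice, area")
  }
  if (any(data$ice < 0 | data$ice > 1)) {
    rlang::abort("ice_transition_dates(): ice concentration outside [0, 1]")
  }
  one <- function(d) {
    d <- dplyr::arrange(d, .data$month)
    below <- d$ice < threshold
    r <- if (any(below) && !all(below)) which(below)[1] else NA_integer_
    g <- NA_integer_
    if (!is.na(r)) {
      after <- which(!below & seq_len(12) > r)
      if (length(after)) g <- after[1]
    }
    tibble::tibble(
      retreat_month = r, growth_month = g,
      late_summer_transition = !is.na(r) && r <= 7,
      area = d$area[1]
    )
  }
  cells <- dplyr::group_modify(dplyr::group_by(data, .data$cell), function(d, key) one(d))
  cells <- dplyr::ungroup(cells)
  has_r <- !is.na(cells$retreat_month)
  has_g <- !is.na(cells$growth_month)
  mean_tbl <- tibble::tibble(
    retreat_month = if (any(has_r)) {
      sum((cells$retreat_month * cells$area)[has_r]) / sum(cells$area[has_r])
    } else NA_real_,
    growth_month = if (any(has_g)) {
      sum((cells$growth_month * cells$area)[has_g]) / sum(cells$area[has_g])
    } else NA_real_
  )
  list(cells = dplyr::select(cells, -"area"), mean = mean_tbl)
}

#' Three-stage classification of an annual pCO2-anomaly cycle
#'
#' Stage 1: no maximum in the summer window. Stage 2: a positive local
#' (secondary) maximum in the summer window, but the annual maximum falls
#' elsewhere. Stage 3: the annual maximum itself falls in the summer window.
#' Local maxima are assessed on the circular 12-month topology.
#'
#' @param anom 12 monthly anomalies (month order 1-12) or a climatology tibble
#'   from [decadal_climatology()].
#' @param summer Integer months of the summer window (default June-September).
#' @return Integer stage (1, 2 or 3).
#' @export
stage_classify <- function(anom, summer = 6:9) {
  if (is.data.frame(anom)) anom <- anom$anom[order(anom$month)]
  if (length(anom) != 12) rlang::abort("stage_classify(): need 12 monthly anomalies")
  if (which.max(anom) %in% summer) return(3L)
  prev <- anom[c(12, 1:11)]
  nxt <- anom[c(2:12, 1)]
  local_max <- anom >= prev & anom >= nxt & anom > 0
  if (any(local_max[summer])) return(2L)
  1L
}

# Unwrap a circular month sequence (period 12) to a continuous branch.
unwrap_months <- function(m) {
  d <- diff(m)
  d <- d - 12 * round(d / 12)
  c(m[1], m[1] + cumsum(d))
}

#' Timing of the annual high and low along a CO2 pathway
#'
#' For each atmospheric CO2 level (one decadal climatology per level), takes
#' the basin-mean 12-month anomaly cycle, records the integer months of the
#' annual high and low, and fits a cubic smoothing spline through each timing
#' sequence (after unwrapping the circular month index to a continuous
#' branch) to suppress interannual variation.
#'
#' @param levels_data Data frame with columns `co2_ppm`, `month`, `anom`
#'   (basin-mean monthly anomaly), 12 rows per CO2 level; `co2_ppm` strictly
#'   increasing across levels.
#' @param spar Smoothing parameter for [stats::smooth.spline()] on the timing
#'   sequences; the fixed default 0.6 gives moderate smoothing (`NULL` uses
#'   generalized cross-validation, which can be unstable on short level
#'   sequences).
#' @return A `timing_curve` tibble: `co2_ppm`, `high_month_raw`,
#'   `low_month_raw` (integer), `high_month`, `low_month` (spline-smoothed,
#'   real-valued, mapped back to \[1, 13)). Degenerate levels carry NA.
#' @export
timing_curve <- function(levels_data, spar = 0.6) {
  lv <- check_levels(levels_data)
  ext <- do.call(rbind, lapply(lv, function(d) extreme_months(d$anom[order(d$month)])))
  co2 <- vapply(lv, function(d) d$co2_ppm[1], numeric(1))
  out <- tibble::tibble(
    co2_ppm = co2,
    high_month_raw = ext$high_month,
    low_month_raw = ext$low_month
  )
  smooth_branch <- function(m) {
    ok <- !is.na(m)
    if (sum(ok) < 4) return(as.numeric(m))
    u <- unwrap_months(m[ok])
    fit <- stats::smooth.spline(co2[ok], u, spar = spar)
    s <- rep(NA_real_, length(m))
    s[ok] <- stats::predict(fit, co2[ok])$y
    ((s - 1) %% 12) + 1
  }
  out$high_month <- smooth_branch(out$high_month_raw)
  out$low_month <- smooth_branch(out$low_month_raw)
  class(out) <- c("timing_curve", class(out))
  out
}

check_levels <- function(levels_data) {
  if (!all(c("co2_ppm", "month", "anom") %in% names(levels_data))) {
    rlang::abort("need columns co2_ppm, month, anom")
  }
  if (is.unsorted(unique(levels_data$co2_ppm), strictly = TRUE)) {
    rlang::abort("CO2 levels must be strictly increasing")
  }
  lv <- split(tibble::as_tibble(levels_data), levels_data$co2_ppm)
  if (length(lv) < 3) rlang::abort("need at least 3 CO2 levels")
  if (any(vapply(lv, nrow, 1L) != 12)) {
    rlang::abort("each CO2 level needs 12 monthly values")
  }
  lv[order(as.numeric(names(lv)))]
}

#' Detect the high/low crossover along a CO2 pathway
#'
#' Finds the lowest atmospheric CO2 level at which the summer extreme of the
#' basin-mean pCO2 anomaly becomes the annual maximum - the stage 2-to-3
#' transition of the smoothed series, equivalent to the timing curves of the
#' annual high and low crossing where both are well defined. Each month's
#' anomaly is first smoothed across CO2 levels with a cubic smoothing spline;
#' the crossover CO2 value is then interpolated from the zero crossing of the
#' margin (summer maximum minus outside-summer maximum). Detection is
#' invariant to adding a constant to all anomalies of a level.
#'
#' @inheritParams timing_curve
#' @param summer Integer months of the summer window.
#' @param spar Smoothing parameter for the across-level splines (fixed
#'   moderate default; `NULL` = generalized cross-validation).
#' @return A one-row tibble `co2_ppm`, `month` (the summer month holding the
#'   maximum at crossover), or a zero-row tibble if crossover is never
#'   reached.
#' @export
detect_crossover <- function(levels_data, summer = 6:9, spar = 0.6) {
  lv <- check_levels(levels_data)
  co2 <- vapply(lv, function(d) d$co2_ppm[1], numeric(1))
  amat <- vapply(lv, function(d) d$anom[order(d$month)], numeric(12))  # 12 x nlev
  nlev <- length(co2)
  if (nlev >= 5) {
    for (m in 1:12) {
      fit <- stats::smooth.spline(co2, amat[m, ], spar = spar)
      amat[m, ] <- stats::predict(fit, co2)$y
    }
  }
  margin <- apply(amat, 2, function(a) max(a[summer]) - max(a[-summer]))
  pos <- which(margin > 0)
  if (!length(pos)) {
    return(tibble::tibble(co2_ppm = numeric(0), month = integer(0)))
  }
  j <- pos[1]
  if (j == 1) {
    ppm <- co2[1]
  } else {
    # linear interpolation of the margin zero crossing
    f <- margin[j - 1] / (margin[j - 1] - margin[j])
    ppm <- co2[j - 1] + f * (co2[j] - co2[j - 1])
  }
  month_at <- summer[which.max(amat[summer, j])]
  tibble::tibble(co2_ppm = ppm, month = as.integer(month_at))
}

#' Stage sequence along a CO2 pathway
#'
#' Classifies each CO2 level's (optionally across-level smoothed) basin-mean
#' cycle into the three stages.
#'
#' @inheritParams detect_crossover
#' @param smooth Smooth each month's anomaly across levels first (as in
#'   [detect_crossover()]).
#' @return A tibble `co2_ppm`, `stage`.
#' @export
stage_sequence <- function(levels_data, summer = 6:9, spar = 0.6, smooth = TRUE) {
  lv <- check_levels(levels_data)
  co2 <- vapply(lv, function(d) d$co2_ppm[1], numeric(1))
  amat <- vapply(lv, function(d) d$anom[order(d$month)], numeric(12))
  if (smooth && length(co2) >= 5) {
    for (m in 1:12) {
      fit <- stats::smooth.spline(co2, amat[m, ], spar = spar)
      amat[m, ] <- stats::predict(fit, co2)$y
    }
  }
  tibble::tibble(
    co2_ppm = co2,
    stage = apply(amat, 2, stage_classify, summer = summer)
  )
}

#' Debiased area-weighted summer temperature maximum over shelf cells
#'
#' Removes the per-cell, per-month model bias (historical model climatology
#' minus observational climatology), applies it to the future climatology,
#' takes each cell's annual maximum of the debiased values, and area-averages
#' over the shelf cells.
#'
#' @param model_hist,obs,model_future Data frames with columns `cell`,
#'   `month`, `temp` on a common grid (12 rows per cell).
#' @param grid Data frame with columns `cell`, `area` and logical `shelf`.
#' @return The debiased area-weighted mean summer maximum (degC).
#' @export
debias_summer_max <- function(model_hist, obs, model_future, grid) {
  shelf <- grid[grid$shelf, ]
  if (nrow(shelf) == 0) rlang::abort("debias_summer_max(): empty shelf mask")
  key <- function(d) d[order(d$cell, d$month), ]
  mh <- key(model_hist[model_hist$cell %in% shelf$cell, ])
  ob <- key(obs[obs$cell %in% shelf$cell, ])
  mf <- key(model_future[model_future$cell %in% shelf$cell, ])
  if (!identical(mh$cell, ob$cell) || !identical(mh$cell, mf$cell)) {
    rlang::abort("debias_summer_max(): climatologies not on a common grid")
  }
  deb <- mf$temp - (mh$temp - ob$temp)
  mx <- tapply(deb, mf$cell, max)
  a <- shelf$area[match(names(mx), as.character(shelf$cell))]
  sum(mx * a) / sum(a)
}
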