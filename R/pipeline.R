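#' Pipeline configuration
#'
#' Bundles and validates everything [run_pipeline()] needs: the scenario and
#' emulator (or user-supplied fields), the grid, the decades to compare, the
#' summer windows, spline settings and the ensemble seeds.
#'
#' @param scenario [scenario_config()].
#' @param params [emulator_params()].
#' @param grid Grid tibble from [polar_cap_grid()].
#' @param modern,future Length-2 year ranges of the modern and future decades.
#' @param summer Summer window (months) for stages/crossover/enhancement.
#' @param summer_anom_months Months averaged by [summer_anomaly()] reports.
#' @param spar Smoothing parameter for the detrending splines (`NULL` = GCV).
#' @param timing_spar Smoothing parameter for across-level timing splines.
#' @param seeds Integer vector of ensemble member seeds.
#' @param noise Add generator noise?
#' @param run_incremental Compute the (more expensive) year-pair incremental
#'   decomposition of the future decade?
#' @param fields Optional list of `synth_fields` objects (one per member) to
#'   analyse instead of generating; seeds are then ignored.
#' @param out_dir Optional directory: per-member and ensemble reports are
#'   written there as CSV/JSON.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            params = emulator_params(),
                            grid = polar_cap_grid(dlat = 6, dlon = 30),
                            modern = c(2006, 2015), future = c(2091, 2100),
                            summer = 6:9,
                            summer_anom_months = summer_months(),
                            spar = NULL, timing_spar = 0.6,
                            seeds = 1:9, noise = TRUE,
                            run_incremental = TRUE,
                            fields = NULL, out_dir = NULL) {
  yrs <- scenario$years
  for (dec in list(modern, future)) {
    if (length(dec) != 2 || !all(dec[1]:dec[2] %in% yrs)) {
      rlang::abort("pipeline_config(): comparison decades must lie within the scenario years")
    }
  }
  if (modern[1] >= future[1]) {
    rlang::abort("pipeline_config(): modern decade must precede the future decade")
  }
  structure(
    list(scenario = scenario, params = params, grid = grid,
         modern = modern, future = future, summer = summer,
         summer_anom_months = summer_anom_months, spar = spar,
         timing_spar = timing_spar, seeds = as.integer(seeds), noise = noise,
         run_incremental = run_incremental, fields = fields,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

detrend_fields <- function(fields, vars, spar = NULL) {
  out <- fields
  for (v in vars) {
    det <- dplyr::ungroup(detrend_monthly(
      dplyr::group_by(fields[, c("cell", "year", "month", v)], .data$cell),
      value = v, spar = spar
    ))
    det <- dplyr::arrange(det, .data$cell, .data$year, .data$month)
    out[[paste0(v, "_anom")]] <- det[[paste0(v, "_anom")]]
  }
  out
}

center <- function(x) x - mean(x)

# per-cell decadal climatological states + detrended anomalies
decade_cell_summary <- function(fields, decade) {
  d <- fields[fields$year >= decade[1] & fields$year <= decade[2], ]
  s0 <- dplyr::summarise(dplyr::group_by(d, .data$cell), s0 = mean(.data$sal),
                         .groups = "drop")
  d <- dplyr::left_join(d, s0, by = "cell")
  clim <- dplyr::summarise(
    dplyr::group_by(d, .data$cell, .data$month),
    temp = mean(.data$temp), sal = mean(.data$sal),
    alk = mean(.data$alk), dic = mean(.data$dic),
    ice = mean(.data$ice),
    temp_anom = mean(.data$temp_anom), sal_anom = mean(.data$sal_anom),
    alk_anom = mean(.data$alk_anom), dic_anom = mean(.data$dic_anom),
    pco2_anom = mean(.data$pco2_anom),
    s_alk_anom = mean(.data$alk_anom * .data$s0 / .data$sal),
    s_dic_anom = mean(.data$dic_anom * .data$s0 / .data$sal),
    s0 = .data$s0[1],
    .groups = "drop"
  )
  # anomalies relative to the annual mean: re-center within each cell
  dplyr::mutate(
    dplyr::group_by(clim, .data$cell),
    dplyr::across(dplyr::ends_with("_anom"), center),
    .keep = "all"
  ) |> dplyr::ungroup()
}

cell_anoms <- function(cs, cell_id, decade) {
  a <- cs[cs$cell == cell_id, ]
  a <- dplyr::arrange(a, .data$month)
  out <- tibble::tibble(
    month = a$month, temp = a$temp, sal = a$sal, alk = a$alk, dic = a$dic,
    s0 = a$s0,
    temp_anom = a$temp_anom, sal_anom = a$sal_anom,
    alk_anom = a$alk_anom, dic_anom = a$dic_anom,
    s_alk_anom = a$s_alk_anom, s_dic_anom = a$s_dic_anom
  )
  attr(out, "decade") <- decade
  out
}

aggregate_terms <- function(term_list, weights) {
  w <- weights / sum(weights)
  cols <- setdiff(names(term_list[[1]]), "month")
  out <- term_list[[1]]
  for (cc in cols) {
    acc <- 0
    for (i in seq_along(term_list)) acc <- acc + w[i] * term_list[[i]][[cc]]
    out[[cc]] <- acc
  }
  new_term_series(out, attr(term_list[[1]], "layout"), attr(term_list[[1]], "decade"))
}

analyse_member <- function(synth, config) {
  grid <- synth$grid
  fields <- synth$fields
  dom <- grid[grid$domain, ]
  fields <- fields[fields$cell %in% dom$cell, ]
  fields$pco2 <- solve_carbonate(
    fields[, c("temp", "sal", "alk", "dic")]
  )$pco2
  fields <- detrend_fields(fields, c("pco2", "temp", "sal", "alk", "dic"),
                           spar = config$spar)
  cells <- sort(unique(fields$cell))
  areas <- dom$area[match(cells, dom$cell)]

  cs_modern <- decade_cell_summary(fields, config$modern)
  cs_future <- decade_cell_summary(fields, config$future)
  state_cols <- c("cell", "month", "temp", "sal", "alk", "dic")
  sens_modern <- carbonate_sensitivities(cs_modern[, state_cols])
  sens_future <- carbonate_sensitivities(cs_future[, state_cols])

  terms_m <- list(); terms_m_fw <- list(); terms_f <- list()
  seps <- list()
  for (i in seq_along(cells)) {
    cc <- cells[i]
    am <- cell_anoms(cs_modern, cc, config$modern)
    af <- cell_anoms(cs_future, cc, config$future)
    sm <- sens_modern[sens_modern$cell == cc, ]
    sf <- sens_future[sens_future$cell == cc, ]
    attr(sm, "decade") <- config$modern
    attr(sf, "decade") <- config$future
    pm <- cs_modern$pco2_anom[cs_modern$cell == cc][order(cs_modern$month[cs_modern$cell == cc])]
    pf <- cs_future$pco2_anom[cs_future$cell == cc][order(cs_future$month[cs_future$cell == cc])]
    terms_m[[i]] <- taylor_terms(am, sm, actual = pm)
    terms_m_fw[[i]] <- freshwater_terms(am, sm, actual = pm)
    terms_f[[i]] <- taylor_terms(af, sf, actual = pf)
    seps[[i]] <- separate_climate_co2(sm, am, sf, af)
  }
  basin_terms_modern <- aggregate_terms(terms_m, areas)
  basin_terms_modern_fw <- aggregate_terms(terms_m_fw, areas)
  basin_terms_future_basic <- aggregate_terms(terms_f, areas)

  sep_comp <- Reduce(`+`, lapply(seq_along(seps), function(i) {
    as.matrix(seps[[i]]$components[, -1]) * areas[i]
  })) / sum(areas)
  basin_sep <- structure(
    list(
      components = tibble::as_tibble(cbind(tibble::tibble(month = 1:12),
                                           tibble::as_tibble(sep_comp))),
      modern_total = Reduce(`+`, lapply(seq_along(seps), function(i) {
        seps[[i]]$modern_total * areas[i]
      })) / sum(areas),
      future_total = Reduce(`+`, lapply(seq_along(seps), function(i) {
        seps[[i]]$future_total * areas[i]
      })) / sum(areas)
    ),
    class = "pco2_separation"
  )
  enh <- summer_enhancement(basin_sep, summer = config$summer)

  terms_future_incr <- NULL
  if (config$run_incremental) {
    span <- config$modern[1]:config$future[2]
    yd <- fields[fields$year %in% span,
                 c("cell", "year", "month", "temp", "sal", "alk", "dic",
                   "temp_anom", "sal_anom", "alk_anom", "dic_anom")]
    ysens <- carbonate_sensitivities(yd[, c("temp", "sal", "alk", "dic")])
    yd <- dplyr::bind_cols(
      yd,
      ysens[, c("dpco2_dtemp", "dpco2_dsal", "dpco2_dalk", "dpco2_ddic")]
    )
    incr <- vector("list", length(cells))
    for (i in seq_along(cells)) {
      incr[[i]] <- incremental_terms(
        yd[yd$cell == cells[i], ], terms_m[[i]],
        modern = config$modern, future = config$future
      )
      incr[[i]]$actual_total <- terms_f[[i]]$actual_total
    }
    terms_future_incr <- aggregate_terms(incr, areas)
  }

  # timing: basin-mean anomaly climatology per full decade along the pathway
  years <- sort(unique(fields$year))
  n_dec <- length(years) %/% 10
  dec_of_year <- function(y) {
    k <- (y - years[1]) %/% 10
    ifelse(k < n_dec, years[1] + 10 * k, NA_integer_)
  }
  fields$decade_start <- dec_of_year(fields$year)
  fd <- fields[!is.na(fields$decade_start), ]
  cellclim <- dplyr::summarise(
    dplyr::group_by(fd, .data$decade_start, .data$cell, .data$month),
    anom = mean(.data$pco2_anom), ppm = mean(.data$ppm), .groups = "drop"
  )
  cellclim$w <- areas[match(cellclim$cell, cells)]
  levels_data <- dplyr::summarise(
    dplyr::group_by(cellclim, .data$decade_start, .data$month),
    anom = sum(.data$anom * .data$w) / sum(.data$w),
    co2_ppm = mean(.data$ppm), .groups = "drop"
  )
  levels_data <- dplyr::group_by(levels_data, .data$decade_start) |>
    dplyr::mutate(anom = center(.data$anom)) |>
    dplyr::ungroup()
  levels_data <- dplyr::arrange(levels_data[, c("co2_ppm", "month", "anom",
                                                "decade_start")], .data$co2_ppm, .data$month)
  if (length(unique(levels_data$co2_ppm)) >= 3) {
    curve <- timing_curve(levels_data, spar = config$timing_spar)
    crossover <- detect_crossover(levels_data, summer = config$summer,
                                  spar = config$timing_spar)
    stages <- stage_sequence(levels_data, summer = config$summer,
                             spar = config$timing_spar)
  } else {
    # stationary pathway: no CO2 axis to evolve along, hence no crossover
    curve <- NULL
    crossover <- tibble::tibble(co2_ppm = numeric(0), month = integer(0))
    stages <- NULL
  }

  ice_modern <- ice_transition_dates(
    dplyr::left_join(
      dplyr::summarise(
        dplyr::group_by(
          fields[fields$year >= config$modern[1] & fields$year <= config$modern[2], ],
          .data$cell, .data$month),
        ice = mean(.data$ice), .groups = "drop"),
      grid[, c("cell", "area")], by = "cell")
  )
  ice_future <- ice_transition_dates(
    dplyr::left_join(
      dplyr::summarise(
        dplyr::group_by(
          fields[fields$year >= config$future[1] & fields$year <= config$future[2], ],
          .data$cell, .data$month),
        ice = mean(.data$ice), .groups = "drop"),
      grid[, c("cell", "area")], by = "cell")
  )

  list(
    seed = synth$seed,
    terms_modern = basin_terms_modern,
    terms_modern_fw = basin_terms_modern_fw,
    terms_future_basic = basin_terms_future_basic,
    terms_future_incremental = terms_future_incr,
    closure = list(
      modern = term_closure(basin_terms_modern),
      future_basic = term_closure(basin_terms_future_basic),
      future_incremental = if (!is.null(terms_future_incr)) {
        term_closure(terms_future_incr)
      } else NULL
    ),
    separation = basin_sep,
    enhancement = enh,
    timing = list(curve = curve, crossover = crossover, stages = stages,
                  levels = levels_data),
    ice = list(modern = ice_modern, future = ice_future),
    truth = synth$truth
  )
}

#' Run the full analysis pipeline
#'
#' For each ensemble member: generate (or take) monthly fields, solve the
#' carbonate system per cell and month, detrend, build decadal
#' climatologies, decompose the pCO2 anomalies (standard, freshwater and -
#' optionally - incremental layouts), run the climate-CO2 separation with
#' summer-enhancement statistics, and extract timing diagnostics (timing
#' curve, crossover, stage sequence, ice dates). Ensemble statistics
#' (mean +- 1 s.d. across members) are reported for the headline numbers.
#' The pipeline is a pure function of (config, seeds).
#'
#' @param config A [pipeline_config()].
#' @return A `pco2_pipeline` list: `members` (per-seed results), `ensemble`
#'   (one-row tibble of ensemble statistics), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  members <- list()
  if (!is.null(config$fields)) {
    synths <- config$fields
  } else {
    synths <- lapply(config$seeds, function(s) {
      generate_fields(config$params, config$scenario, config$grid,
                      seed = s, noise = config$noise, truth = TRUE,
                      summer = config$summer)
    })
  }
  for (i in seq_along(synths)) {
    members[[i]] <- analyse_member(synths[[i]], config)
  }
  cross <- vapply(members, function(m) {
    if (nrow(m$timing$crossover)) m$timing$crossover$co2_ppm else NA_real_
  }, numeric(1))
  truth_cross <- vapply(members, function(m) {
    if (!is.null(m$truth)) m$truth$crossover_ppm else NA_real_
  }, numeric(1))
  enh_ext <- vapply(members, function(m) m$enhancement$enhancement_extreme_pct_abs, numeric(1))
  enh_mean <- vapply(members, function(m) m$enhancement$enhancement_mean_pct_abs, numeric(1))
  closure_modern <- vapply(members, function(m) m$closure$modern$rel, numeric(1))
  ensemble <- tibble::tibble(
    n_members = length(members),
    crossover_ppm_mean = mean(cross, na.rm = TRUE),
    crossover_ppm_sd = stats::sd(cross, na.rm = TRUE),
    truth_crossover_ppm_mean = mean(truth_cross, na.rm = TRUE),
    enhancement_extreme_pct_mean = mean(enh_ext),
    enhancement_extreme_pct_sd = stats::sd(enh_ext),
    enhancement_mean_pct_mean = mean(enh_mean),
    enhancement_mean_pct_sd = stats::sd(enh_mean),
    closure_modern_rel_mean = mean(closure_modern)
  )
  out <- structure(
    list(members = members, ensemble = ensemble, config = config),
    class = "pco2_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_reports(out, config$out_dir)
  out
}

#' @export
print.pco2_pipeline <- function(x, ...) {
  cat("pCO2 seasonal-phenology pipeline:", length(x$members), "member(s)\n")
  print(x$ensemble, ...)
  invisible(x)
}

write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    constants_set = "lueker2000_total",
    seeds = result$config$seeds,
    scenario = result$config$scenario$kind
  )
  jsonlite::write_json(meta, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(result$ensemble, file.path(out_dir, "ensemble.csv"),
                   row.names = FALSE)
  for (i in seq_along(result$members)) {
    m <- result$members[[i]]
    tag <- sprintf("member%02d", i)
    utils::write.csv(generics::tidy(m$terms_modern),
                     file.path(out_dir, paste0(tag, "_terms_modern.csv")),
                     row.names = FALSE)
    utils::write.csv(m$timing$curve,
                     file.path(out_dir, paste0(tag, "_timing.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(crossover = m$timing$crossover,
           enhancement = m$enhancement),
      file.path(out_dir, paste0(tag, "_summary.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  invisible(out_dir)
}
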