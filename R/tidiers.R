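#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Taylor term series into long format
#'
#' @param x A `term_series`.
#' @param ... Unused.
#' @return A long tibble `month`, `term`, `value` (uatm); the layout is kept
#'   in the `layout` column.
#' @export
tidy.term_series <- function(x, ...) {
  layout <- attr(x, "layout")
  out <- tidyr::pivot_longer(tibble::as_tibble(x), -"month",
                             names_to = "term", values_to = "value")
  out$layout <- layout
  out
}

#' @rdname tidy.term_series
#' @export
glance.term_series <- function(x, ...) {
  cl <- if ("actual_total" %in% names(x)) term_closure(x) else NULL
  tibble::tibble(
    layout = attr(x, "layout") %||% NA_character_,
    amplitude = diff(range(x$reconstructed_total)),
    closure_max_abs = cl$max_abs %||% NA_real_,
    closure_rel = cl$rel %||% NA_real_
  )
}

#' Tidy a climate-CO2 separation
#'
#' @param x A `pco2_separation`.
#' @param ... Unused.
#' @return Long tibble `month`, `component`, `value` including the modern and
#'   future reconstructed anomalies.
#' @export
tidy.pco2_separation <- function(x, ...) {
  wide <- dplyr::mutate(x$components,
                        modern = x$modern_total, future = x$future_total)
  tidyr::pivot_longer(wide, -"month", names_to = "component", values_to = "value")
}

#' @rdname tidy.pco2_separation
#' @export
glance.pco2_separation <- function(x, ...) {
  summer_enhancement(x)
}

#' Tidy a timing curve
#'
#' @param x A `timing_curve`.
#' @param ... Unused.
#' @return Long tibble `co2_ppm`, `extreme` ("high"/"low"), `month_raw`,
#'   `month_smooth`.
#' @export
tidy.timing_curve <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(co2_ppm = x$co2_ppm, extreme = "high",
                   month_raw = x$high_month_raw, month_smooth = x$high_month),
    tibble::tibble(co2_ppm = x$co2_ppm, extreme = "low",
                   month_raw = x$low_month_raw, month_smooth = x$low_month)
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `pco2_pipeline`.
#' @param ... Unused.
#' @return The ensemble statistics tibble (one row).
#' @export
glance.pco2_pipeline <- function(x, ...) {
  x$ensemble
}

`%||%` <- function(a, b) if (is.null(a)) b else a
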