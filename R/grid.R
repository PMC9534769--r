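#' Idealized polar-cap analysis grid with masks and spherical areas
#'
#' Builds a regular latitude-longitude grid covering a polar cap, with
#' spherical cell areas, a configurable land sector, a shelf/basin partition
#' from an idealized depth field (shallow peripheral bands, deep central
#' basin), and a domain mask (all ocean cells of the cap). The real Arctic
#' domain is bounded by gateway sections whose coordinates are not
#' reproducible here; a user-supplied domain mask can be attached instead via
#' the `domain` column of the returned tibble (see [apply_domain_mask()]).
#'
#' @param lat_min Equatorward edge of the cap (degrees north).
#' @param lat_max Poleward edge (cell centers stay south of 90).
#' @param dlat,dlon Grid resolution in degrees.
#' @param shelf_depth Depth threshold (m) separating shelf from basin.
#' @param shelf_bands Number of southernmost latitude bands given the shallow
#'   `shelf_depth_value`; the rest get `basin_depth_value`.
#' @param shelf_depth_value,basin_depth_value Idealized bottom depths (m).
#' @param land_sector Length-2 numeric: longitudes (degrees, \[0, 360)) of a
#'   land sector applied to the southernmost band (set to `NULL` for no
#'   land).
#'
#' @return A tibble with one row per cell: `cell`, `lat`, `lon` (centers),
#'   `area` (m2), `depth` (m), `land`, `domain`, `shelf`, `basin` (logical)
#'   and `region` ("land", "shelf" or "basin"). Invariants: `domain` excludes
#'   land; `shelf | basin` partitions the domain.
#' @export
polar_cap_grid <- function(lat_min = 70, lat_max = 90, dlat = 4, dlon = 15,
                           shelf_depth = 500, shelf_bands = 2,
                           shelf_depth_value = 150, basin_depth_value = 3000,
                           land_sector = c(0, 90)) {
  if (lat_min >= lat_max || dlat <= 0 || dlon <= 0) {
    rlang::abort("polar_cap_grid(): inconsistent grid configuration")
  }
  lats <- seq(lat_min + dlat / 2, lat_max - dlat / 2, by = dlat)
  lons <- seq(dlon / 2, 360 - dlon / 2, by = dlon)
  g <- tidyr::expand_grid(lat = lats, lon = lons)
  g <- dplyr::arrange(g, .data$lat, .data$lon)
  g$cell <- seq_len(nrow(g))
  R <- 6371e3
  g$area <- R^2 * (dlon * pi / 180) *
    (sin((g$lat + dlat / 2) * pi / 180) - sin((g$lat - dlat / 2) * pi / 180))
  band <- match(g$lat, lats)
  g$depth <- ifelse(band <= shelf_bands, shelf_depth_value, basin_depth_value)
  g$land <- FALSE
  if (!is.null(land_sector)) {
    g$land <- band == 1 & g$lon >= land_sector[1] & g$lon < land_sector[2]
  }
  g$domain <- !g$land
  g$shelf <- g$domain & g$depth < shelf_depth
  g$basin <- g$domain & !g$shelf
  g$region <- ifelse(g$land, "land", ifelse(g$shelf, "shelf", "basin"))
  dplyr::select(
    g, "cell", "lat", "lon", "area", "depth",
    "land", "domain", "shelf", "basin", "region"
  )
}

#' Replace the domain mask of a grid with a user-supplied one
#'
#' @param grid A grid tibble from [polar_cap_grid()] or [read_grid_csv()].
#' @param domain Logical vector (length `nrow(grid)`) or a data frame with
#'   columns `cell` and `domain`.
#' @return The grid with `domain`, `shelf`, `basin` and `region` updated;
#'   land cells can never enter the domain.
#' @export
apply_domain_mask <- function(grid, domain) {
  if (is.data.frame(domain)) {
    domain <- domain$domain[match(grid$cell, domain$cell)]
  }
  if (length(domain) != nrow(grid) || any(is.na(domain))) {
    rlang::abort("apply_domain_mask(): domain mask does not match the grid")
  }
  grid$domain <- as.logical(domain) & !grid$land
  grid$shelf <- grid$domain & grid$depth < 500
  grid$basin <- grid$domain & !grid$shelf
  grid$region <- ifelse(grid$land, "land", ifelse(grid$shelf, "shelf",
    ifelse(grid$basin, "basin", "outside")))
  grid
}

#' Read / write a grid as CSV
#'
#' @param path File path.
#' @param grid Grid tibble (for writing).
#' @return `read_grid_csv()` returns the grid tibble.
#' @export
read_grid_csv <- function(path) {
  g <- tibble::as_tibble(utils::read.csv(path))
  for (v in c("land", "domain", "shelf", "basin")) {
    if (v %in% names(g)) g[[v]] <- as.logical(g[[v]])
  }
  g
}

#' @rdname read_grid_csv
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Area-weighted mean of a field over a mask
#'
#' @param x Numeric field values (one per cell).
#' @param area Cell areas (same length).
#' @param mask Logical mask of cells to include (default all).
#' @return `sum(x * area * mask) / sum(area * mask)`.
#' @export
area_weighted_mean <- function(x, area, mask = TRUE) {
  mask <- rep_len(mask, length(x))
  if (length(area) != length(x)) {
    rlang::abort("area_weighted_mean(): x and area lengths differ")
  }
  if (!any(mask)) rlang::abort("area_weighted_mean(): empty mask")
  sum(x[mask] * area[mask]) / sum(area[mask])
}

#' Nearest-neighbour regridding on the sphere
#'
#' Each destination cell takes the value of the great-circle-nearest unmasked
#' source cell. Destination cells with no unmasked source within
#' `cutoff_km` are returned as NA (masked).
#'
#' @param src Data frame with columns `lat`, `lon` and the value column;
#'   optionally a logical `mask` column (TRUE = excluded, e.g. land).
#' @param dst Data frame with columns `lat`, `lon`.
#' @param value Name of the value column in `src`.
#' @param cutoff_km Great-circle search cutoff in kilometres.
#' @return `dst` with the regridded `value` column added.
#' @export
regrid_nearest <- function(src, dst, value = "value", cutoff_km = Inf) {
  if ("mask" %in% names(src)) src <- src[!src$mask, , drop = FALSE]
  if (!nrow(src)) rlang::abort("regrid_nearest(): no unmasked source cells")
  to_xyz <- function(lat, lon) {
    la <- lat * pi / 180
    lo <- lon * pi / 180
    cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  A <- to_xyz(dst$lat, dst$lon)
  B <- to_xyz(src$lat, src$lon)
  dots <- pmin(pmax(A %*% t(B), -1), 1)
  nearest <- max.col(dots, ties.method = "first")
  dist_km <- acos(dots[cbind(seq_len(nrow(A)), nearest)]) * 6371
  out <- tibble::as_tibble(dst)
  out[[value]] <- src[[value]][nearest]
  out[[value]][dist_km > cutoff_km] <- NA
  out
}
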