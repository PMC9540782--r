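# The emission engine: combine daily flux curves, the lake-area grid, the
# emission-season grid, episodic fluxes and the large-lake scaling factor
# into a daily 0.25-degree emission climatology, then aggregate to zonal,
# type, pathway and global totals with strict mass closure.

PATHWAYS_ALL <- c("diffusion", "ebullition", "iceout_spring", "fall_turnover")

#' Scaling factor applied to fluxes from lakes >= 5,000 km^2
#'
#' Large lakes emit far less CH4 per m^2 than small lakes; per-area emission
#' rates observed on lakes < 5,000 km^2 are scaled by this factor (baseline
#' 0.1 of the small-lake rate, explored over 0-0.25 in the uncertainty
#' budget) when applied to large-lake area.
#' @export
SCALE_LARGE_DEFAULT <- 0.1

#' Compute the daily gridded emission climatology
#'
#' Per cell and day, open-water (diffusion + ebullition) emission is the
#' type's daily flux curve applied to `area_small + scale_large * area_large`
#' inside the cell's emission season and zero outside it; episodic series add
#' the ice-out/spring-turnover and fall-turnover releases. Units: g CH4 per
#' cell per day.
#'
#' @param areas `lake_area_grid`.
#' @param type_map Type-code matrix.
#' @param curves `daily_flux_curves`.
#' @param season `season_grid`.
#' @param e5 Named per-type deep-water production rates
#'   ([deep_water_rates_by_type()]); `NULL` disables episodic fluxes.
#' @param params `episodic_params`.
#' @param scale_large Large-lake flux scaling factor.
#' @return An `emission_grid`: list with `daily` (list of `[n_cell, 365]`
#'   matrices in g/day by pathway, cells in column-major grid order), `grid`,
#'   `type_map`, `areas`, `season`.
#' @export
compute_daily_emissions <- function(areas, type_map, curves, season,
                                    e5 = NULL, params = episodic_params(),
                                    scale_large = SCALE_LARGE_DEFAULT) {
  grid <- areas$grid
  stopifnot(all(dim(type_map) == grid_dims(grid)),
            identical(grid_dims(season$grid), grid_dims(grid)))
  nc <- n_cells(grid)
  eff_area <- as.vector(areas$area_small + scale_large * areas$area_large)
  tvec <- as.vector(type_map)
  thaw <- as.vector(season$thaw)
  len <- as.vector(season$season_length)
  nf <- as.vector(season$no_freeze)
  freeze <- as.vector(season$freeze)

  present <- unique(tvec[eff_area > 0])
  missing_curves <- present[!vapply(present, function(t)
    !is.null(curves$curves[[t]]), logical(1))]
  if (length(missing_curves) > 0) {
    stop(sprintf("no flux curves for type(s) present in area grid: %s",
                 paste(missing_curves, collapse = ", ")))
  }

  daily <- list(
    diffusion = matrix(0, nc, DAYS_IN_YEAR),
    ebullition = matrix(0, nc, DAYS_IN_YEAR),
    iceout_spring = matrix(0, nc, DAYS_IN_YEAR),
    fall_turnover = matrix(0, nc, DAYS_IN_YEAR)
  )

  active <- which(eff_area > 0)
  # season mask per active cell: day d emits iff (d - thaw) mod 365 < length
  doy <- matrix(1:DAYS_IN_YEAR, length(active), DAYS_IN_YEAR, byrow = TRUE)
  mask <- ((doy - thaw[active]) %% DAYS_IN_YEAR) < len[active]

  for (t in present) {
    sel <- which(tvec[active] == t)
    if (length(sel) == 0) next
    rows <- active[sel]
    w <- eff_area[rows] * FLUX_AREA_TO_G_PER_DAY
    for (pw in c("diffusion", "ebullition")) {
      f <- daily_curve(curves, t, pw)
      daily[[pw]][rows, ] <- (w %o% f) * mask[sel, , drop = FALSE]
    }
  }

  if (!is.null(e5)) {
    freezing <- active[!nf[active]]
    for (i in freezing) {
      ei <- e5[[tvec[i]]]
      if (!is.finite(ei) || ei <= 0) next
      w <- eff_area[i] * FLUX_AREA_TO_G_PER_DAY
      daily$iceout_spring[i, ] <-
        w * ice_out_spring_flux(thaw[i], freeze[i], len[i], FALSE, ei, params)
      daily$fall_turnover[i, ] <-
        w * fall_turnover_flux(thaw[i], freeze[i], len[i], FALSE, ei, params)
    }
  }

  structure(list(grid = grid, daily = daily, type_map = type_map,
                 areas = areas, season = season, scale_large = scale_large),
            class = "emission_grid")
}

#' Aggregate an emission grid to all reporting levels
#'
#' Computes annual per-cell totals, per-pathway and per-type totals, zonal
#' 5-degree sums, 20-degree-zone daily curves, and the global total, and
#' asserts closure (global = sum of zones = sum of types = sum of pathways)
#' to 1e-6 relative.
#'
#' @param em An `emission_grid`.
#' @return List of tibbles/vectors: `global_Tg`, `pathway_Tg`, `type_Tg`,
#'   `zonal_5deg`, `daily_20deg`, `annual_cell_g`, `annual_per_m2_cell`,
#'   `annual_per_m2_lake`.
#' @export
aggregate_emissions <- function(em) {
  grid <- em$grid
  nc <- n_cells(grid)
  annual_cell <- rowSums(do.call(cbind, lapply(em$daily, rowSums)))
  annual_by_pathway <- vapply(em$daily, function(m) sum(m) * G_TO_TG, numeric(1))
  global <- sum(annual_by_pathway)

  tvec <- as.vector(em$type_map)
  type_Tg <- tibble::tibble(
    lake_type = lake_types(),
    emission_Tg = unname(vapply(lake_types(), function(t)
      sum(annual_cell[tvec == t]) * G_TO_TG, numeric(1)))
  )

  latc <- rep(grid$lat, times = length(grid$lon))
  zone5 <- floor(latc / 5) * 5
  zonal <- tibble::tibble(zone_south = sort(unique(zone5)))
  zonal$emission_Tg <- vapply(zonal$zone_south, function(z)
    sum(annual_cell[zone5 == z]) * G_TO_TG, numeric(1))

  zone20 <- floor(latc / 20) * 20
  zones20 <- sort(unique(zone20))
  daily_20 <- lapply(stats::setNames(names(em$daily), names(em$daily)), function(pw) {
    m <- vapply(zones20, function(z)
      colSums(em$daily[[pw]][zone20 == z, , drop = FALSE]) * G_TO_TG,
      numeric(DAYS_IN_YEAR))
    colnames(m) <- paste0("zone_", zones20)
    m
  })

  cell_area <- as.vector(grid$cell_area)
  lake_area <- as.vector(em$areas$area_small + em$areas$area_large)
  per_m2_cell <- annual_cell / (cell_area * 1e6)
  per_m2_lake <- rep(NA_real_, nc)
  nz <- lake_area > 0
  per_m2_lake[nz] <- annual_cell[nz] / (lake_area[nz] * 1e6)

  closure <- c(sum(type_Tg$emission_Tg), sum(zonal$emission_Tg),
               sum(annual_by_pathway))
  if (global > 0 && any(abs(closure - global) / global > 1e-6)) {
    stop(sprintf("closure violation: global %.8g vs %s", global,
                 paste(signif(closure, 8), collapse = ", ")))
  }

  list(global_Tg = global, pathway_Tg = annual_by_pathway, type_Tg = type_Tg,
       zonal_5deg = zonal, daily_20deg = daily_20,
       annual_cell_g = annual_cell,
       annual_per_m2_cell = per_m2_cell, annual_per_m2_lake = per_m2_lake)
}

#' Annual emission for one lake type from mean fluxes and season lengths
#'
#' Closed-form type total: `area x mean emission-season flux x season length`
#' summed over the two size classes, converted from
#' mg m^-2 d^-1 x km^2 x days to Tg CH4 yr^-1.
#'
#' @param area_small,area_large Lake area (km^2) below / at-or-above
#'   5,000 km^2.
#' @param flux_small,flux_large Mean daily emission-season flux
#'   (mg m^-2 d^-1) per size class.
#' @param season_small,season_large Mean emission-season length (days).
#' @return Annual emission (Tg CH4 yr^-1).
#' @export
annual_type_total <- function(area_small, area_large = 0,
                              flux_small, flux_large = 0,
                              season_small, season_large = 0) {
  stopifnot(area_small >= 0, area_large >= 0,
            season_small >= 0, season_large >= 0)
  flux_to_Tg(flux_small, area_small, season_small) +
    (if (area_large > 0) flux_to_Tg(flux_large, area_large, season_large) else 0)
}
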