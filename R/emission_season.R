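# Climatological emission seasons from multi-year thaw/freeze observations.
#
# Two phenology sources are merged: direct lake-ice phenology where a cell
# contains lakes >= 50 km^2, and landscape freeze/thaw state elsewhere. The
# emission season runs from the climatological thaw date to the freeze date;
# cells that never freeze emit year-round (365 days).

#' Reduce per-year thaw/freeze dates to a climatological season grid
#'
#' Per-year thaw and freeze days-of-year are averaged to climatological dates
#' (rounded to the nearest day). When a cell's dates straddle the new year
#' (range > 182 days across years) a circular mean is used so Southern
#' Hemisphere and maritime cells do not average to mid-year nonsense. Cells
#' with no finite dates in any year are flagged `no_freeze` with a 365-day
#' season.
#'
#' @param thaw_years,freeze_years Numeric arrays `[n_lat, n_lon, n_years]` of
#'   day-of-year; `NA` in all years marks a never-freezing cell.
#' @param grid A `ch4_grid`.
#' @param source Label recorded on the output ("lake-ice-phenology" or
#'   "landscape-FT").
#' @return A `season_grid`: list with matrices `thaw`, `freeze`,
#'   `season_length`, logical `no_freeze`, character `source`.
#' @export
climatological_dates <- function(thaw_years, freeze_years, grid,
                                 source = "landscape-FT") {
  stopifnot(length(dim(thaw_years)) == 3, all(dim(thaw_years) == dim(freeze_years)),
            all(dim(thaw_years)[1:2] == grid_dims(grid)))
  thaw <- apply(thaw_years, c(1, 2), doy_mean)
  freeze <- apply(freeze_years, c(1, 2), doy_mean)
  no_freeze <- is.na(thaw) | is.na(freeze)
  season_grid(grid, thaw, freeze, no_freeze, source)
}

# Mean of day-of-year values; circular when the spread indicates wrap-around.
doy_mean <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) == 0) return(NA_real_)
  if (max(d) - min(d) > 182) {
    ang <- d / DAYS_IN_YEAR * 2 * pi
    m <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * DAYS_IN_YEAR
    wrap_doy(round(m))
  } else {
    wrap_doy(round(mean(d)))
  }
}

#' Construct a season grid from climatological dates
#'
#' @param grid A `ch4_grid`.
#' @param thaw,freeze Matrices of climatological day-of-year (NA where
#'   `no_freeze`).
#' @param no_freeze Logical matrix; `TRUE` cells get a 365-day season.
#' @param source Character scalar or matrix recording the phenology source.
#' @return `season_grid` object.
#' @export
season_grid <- function(grid, thaw, freeze, no_freeze = is.na(thaw),
                        source = "landscape-FT") {
  stopifnot(all(dim(thaw) == grid_dims(grid)))
  bad <- !no_freeze & (thaw < 1 | thaw > 365 | freeze < 1 | freeze > 365)
  if (any(bad, na.rm = TRUE)) stop("day-of-year outside 1..365")
  len <- (freeze - thaw) %% DAYS_IN_YEAR
  len[!is.na(len) & len == 0] <- DAYS_IN_YEAR
  len[no_freeze] <- DAYS_IN_YEAR
  thaw[no_freeze] <- 1
  freeze[no_freeze] <- NA_real_
  if (is.character(source) && length(source) == 1) {
    source <- matrix(source, nrow(thaw), ncol(thaw))
  }
  structure(list(grid = grid, thaw = thaw, freeze = freeze,
                 season_length = len, no_freeze = no_freeze, source = source),
            class = "season_grid")
}

#' Merge lake-ice and landscape freeze/thaw season grids
#'
#' Cells containing lakes >= 50 km^2 (per `large_lake_mask`) take the
#' lake-ice phenology; all other cells take landscape freeze/thaw. A masked
#' cell missing from the lake-ice source falls back to landscape values; the
#' fallback count is attached as attribute `n_fallback`.
#'
#' @param lake_ice,landscape `season_grid` objects on the same grid.
#' @param large_lake_mask Logical matrix marking cells with lakes >= 50 km^2.
#' @return Merged `season_grid` with per-cell `source`.
#' @export
merge_season_sources <- function(lake_ice, landscape, large_lake_mask) {
  stopifnot(identical(grid_dims(lake_ice$grid), grid_dims(landscape$grid)),
            all(dim(large_lake_mask) == grid_dims(landscape$grid)))
  # lake-ice cell is "missing" if not flagged no-freeze yet has no dates
  missing_li <- is.na(lake_ice$thaw) & !lake_ice$no_freeze
  use_li <- large_lake_mask & !missing_li

  pick <- function(a, b) { a[!use_li] <- b[!use_li]; a }
  thaw <- pick(lake_ice$thaw, landscape$thaw)
  freeze <- pick(lake_ice$freeze, landscape$freeze)
  nf <- pick(lake_ice$no_freeze, landscape$no_freeze)
  out <- season_grid(landscape$grid, thaw, freeze, nf)
  src <- matrix("landscape-FT", nrow(thaw), ncol(thaw))
  src[use_li] <- "lake-ice-phenology"
  out$source <- src
  attr(out, "n_fallback") <- sum(large_lake_mask & missing_li)
  out
}

#' Resolve season cells that are missing but contain lakes
#'
#' Lake-bearing cells with no phenology default to a year-round (no-freeze)
#' season when equatorward of `lat_limit` degrees; poleward missing cells are
#' a hard error, since a freezing cell without dates cannot be upscaled.
#'
#' @param season A `season_grid`.
#' @param areas A `lake_area_grid` on the same grid.
#' @param lat_limit Absolute latitude below which missing cells are assumed
#'   never to freeze (default 40).
#' @return `season_grid` with missing low-latitude cells set to no-freeze.
#' @export
fill_missing_seasons <- function(season, areas, lat_limit = 40) {
  has_lake <- (areas$area_small + areas$area_large) > 0
  missing <- is.na(season$thaw) & !season$no_freeze & has_lake
  if (!any(missing)) return(season)
  latf <- abs(lat_field(season$grid))
  if (any(missing & latf >= lat_limit)) {
    stop(sprintf("%d lake cells poleward of %g deg lack phenology",
                 sum(missing & latf >= lat_limit), lat_limit))
  }
  season$no_freeze[missing] <- TRUE
  season$season_length[missing] <- DAYS_IN_YEAR
  season$thaw[missing] <- 1
  season$freeze[missing] <- NA_real_
  season
}

#' Mean emission-season length by lake type, lake-area weighted
#'
#' @param season A `season_grid`.
#' @param areas A `lake_area_grid`.
#' @param type_map Type-code matrix.
#' @return Tibble `lake_type`, `mean_season_days`.
#' @export
mean_season_by_type <- function(season, areas, type_map) {
  w <- areas$area_small + areas$area_large
  tibble::tibble(
    lake_type = lake_types(),
    mean_season_days = unname(vapply(lake_types(), function(t) {
      sel <- type_map == t & w > 0
      if (!any(sel)) return(NA_real_)
      sum(season$season_length[sel] * w[sel]) / sum(w[sel])
    }, numeric(1)))
  )
}
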