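# Regular latitude-longitude grid at 0.25 degree resolution. Coordinates are
# cell centres; the global convention is lat -89.875..89.875, lon
# -179.875..179.875. Fields on the grid are matrices [n_lat, n_lon].

EARTH_RADIUS_KM <- 6371

#' Define a regular lat-lon grid of cell centres
#'
#' @param lat_range,lon_range Length-2 numeric bounds (degrees). Bounds are
#'   interpreted as outer cell edges; centres are placed at `edge + res/2`.
#' @param res Grid resolution in degrees (default 0.25).
#' @return An object of class `ch4_grid`: list with `lat`, `lon` centre
#'   vectors, `res`, and `cell_area` (km^2 per cell, a matrix).
#' @export
grid_spec <- function(lat_range = c(-90, 90), lon_range = c(-180, 180),
                      res = 0.25) {
  stopifnot(length(lat_range) == 2, length(lon_range) == 2, res > 0,
            lat_range[1] < lat_range[2], lon_range[1] < lon_range[2])
  lat <- seq(lat_range[1] + res / 2, lat_range[2] - res / 2, by = res)
  lon <- seq(lon_range[1] + res / 2, lon_range[2] - res / 2, by = res)
  g <- structure(list(lat = lat, lon = lon, res = res), class = "ch4_grid")
  g$cell_area <- matrix(cell_area_km2(lat, res), nrow = length(lat),
                        ncol = length(lon))
  g
}

#' Spherical-Earth area of a grid cell by latitude
#'
#' Area of a `res` x `res` cell centred at latitude `lat` on a sphere of
#' radius 6,371 km (cosine-latitude weighting via the difference of sines).
#'
#' @param lat Cell-centre latitude(s), degrees.
#' @param res Cell size in degrees.
#' @return Cell area(s) in km^2.
#' @export
cell_area_km2 <- function(lat, res = 0.25) {
  half <- res / 2
  dlam <- res * pi / 180
  EARTH_RADIUS_KM^2 * dlam *
    (sin(pmin(lat + half, 90) * pi / 180) - sin(pmax(lat - half, -90) * pi / 180))
}

#' @export
print.ch4_grid <- function(x, ...) {
  cat(sprintf("<ch4_grid> %d x %d cells at %.2f deg (lat %.3f..%.3f, lon %.3f..%.3f)\n",
              length(x$lat), length(x$lon), x$res,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

n_cells <- function(grid) length(grid$lat) * length(grid$lon)

grid_dims <- function(grid) c(length(grid$lat), length(grid$lon))

# Matrix of cell-centre latitudes, same shape as a grid field.
lat_field <- function(grid) {
  matrix(grid$lat, nrow = length(grid$lat), ncol = length(grid$lon))
}

#' Locate the grid cell containing given coordinates
#'
#' @param grid A `ch4_grid`.
#' @param lat,lon Point coordinates (degrees).
#' @return Integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the grid extent.
#' @export
cell_index <- function(grid, lat, lon) {
  half <- grid$res / 2
  r <- round((lat - grid$lat[1]) / grid$res) + 1
  c <- round((lon - grid$lon[1]) / grid$res) + 1
  bad <- lat < grid$lat[1] - half | lat > grid$lat[length(grid$lat)] + half |
    lon < grid$lon[1] - half | lon > grid$lon[length(grid$lon)] + half
  r[bad] <- NA_integer_
  c[bad] <- NA_integer_
  cbind(row = as.integer(r), col = as.integer(c))
}

#' Serialize a grid field as tidy (lat, lon, value) rows
#'
#' @param grid A `ch4_grid`.
#' @param field Matrix on the grid.
#' @param name Column name for the value.
#' @return A tibble with columns `lat`, `lon`, `<name>`.
#' @export
grid_to_tidy <- function(grid, field, name = "value") {
  out <- tibble::tibble(
    lat = rep(grid$lat, times = length(grid$lon)),
    lon = rep(grid$lon, each = length(grid$lat)),
    value = as.vector(field)
  )
  names(out)[3] <- name
  out
}
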