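#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats setNames
"_PACKAGE"

# 365-day no-leap climatological calendar used throughout the package.
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
DAYS_IN_YEAR <- 365L

#' Month midpoints on the 365-day climatological calendar
#'
#' Returns the day-of-year at the centre of each calendar month. These are the
#' anchor days at which monthly-mean daily fluxes are placed before periodic
#' cubic-spline interpolation to a daily annual cycle.
#'
#' @return Numeric vector of length 12 (e.g. 16 for January, 45.5 for February).
#' @export
month_midpoints <- function() {
  ends <- cumsum(DAYS_IN_MONTH)
  ends - DAYS_IN_MONTH / 2 + 0.5
}

#' Wrap a day-of-year onto 1..365
#'
#' Modular day arithmetic for the climatological year, used wherever emission
#' windows or season bounds cross the new-year boundary.
#'
#' @param d Integer day(s), possibly outside 1..365.
#' @return Integer day(s) in 1..365.
#' @export
wrap_doy <- function(d) {
  ((as.integer(round(d)) - 1L) %% DAYS_IN_YEAR) + 1L
}

#' Month of a given day-of-year
#' @param doy Day-of-year in 1..365.
#' @return Integer month 1..12.
#' @export
doy_month <- function(doy) {
  findInterval(doy, c(0, cumsum(DAYS_IN_MONTH)) + 0.5)
}

# Unit chain, centralized so conversions cannot drift between modules:
#   mg CH4 m^-2 d^-1  x  km^2  ->  g CH4 d^-1  (x 1e3)
#   g                          ->  Tg          (x 1e-12)
FLUX_AREA_TO_G_PER_DAY <- 1e3
G_TO_TG <- 1e-12

#' Convert an areal flux applied over an area and duration to teragrams
#'
#' @param flux_mg_m2_d Flux in mg CH4 m^-2 d^-1.
#' @param area_km2 Area in km^2.
#' @param days Number of emission days.
#' @return Mass in Tg CH4.
#' @export
flux_to_Tg <- function(flux_mg_m2_d, area_km2, days) {
  flux_mg_m2_d * area_km2 * days * FLUX_AREA_TO_G_PER_DAY * G_TO_TG
}
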