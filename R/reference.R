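# Published global inventory parameters by ecoclimatic lake type: areas by
# size class, mean emission-season lengths, mean emission-season fluxes, and
# the resulting annual totals. The table is internally closed arithmetic
# (area x flux x season reproduces each printed annual total), which makes it
# the fixture for closure checks and for the global-budget accounting.

#' Reference type-level inventory parameters
#'
#' Global lake areas (10^3 km^2) by size class, measurement counts, mean
#' emission-season lengths (days) and mean daily emission-season fluxes
#' (mg CH4 m^-2 d^-1) for the seven ecoclimatic lake types, with the annual
#' emission totals (Tg CH4 yr^-1) they imply. High-latitude types have no
#' large-lake (>= 5,000 km^2) area.
#'
#' @return Tibble with one row per lake type.
#' @export
type_reference <- function() {
  tibble::tribble(
    ~lake_type, ~n_diffusion, ~n_ebullition,
    ~area_small_1e3km2, ~area_large_1e3km2,
    ~season_small_days, ~season_large_days,
    ~flux_small, ~flux_large, ~annual_Tg,
    "thermokarst", 70L, 17L, 234, 0, 107, NA, 80, NA, 2.0,
    "glacial", 66L, 30L, 357, 0, 117, NA, 31, NA, 1.3,
    "peat_pond", 42L, 1L, 69, 0, 167, NA, 94, NA, 1.1,
    "organic", NA_integer_, NA_integer_, 49, 0, 183, NA, 89, NA, 0.8,
    "boreal", 130L, 4L, 407, 218, 152, 135, 65, 7, 4.2,
    "temperate", 280L, 121L, 427, 674, 289, 206, 65, 9, 9.3,
    "tropical", 86L, 34L, 204, 167, 363, 365, 235, 23, 18.8
  )
}

#' Reference episodic and pathway emission totals (Tg CH4 yr^-1)
#'
#' Global annual totals by pathway accompanying [type_reference()]:
#' diffusion, ebullition, ice-out + spring turnover, fall turnover, and the
#' overall total with its quadrature uncertainty.
#'
#' @return Named list of Tg values.
#' @export
emission_reference <- function() {
  list(diffusion_Tg = 14.1, ebullition_Tg = 23.4,
       iceout_spring_Tg = 3.1, fall_turnover_Tg = 1.0,
       total_de_Tg = 37.5, total_Tg = 41.6, total_uncertainty_Tg = 18.3,
       large_lake_Tg = 2.9,
       area_small_1e3km2 = 1747, area_large_1e3km2 = 1059,
       area_total_1e3km2 = 2806)
}

#' Recompute annual type totals from the reference parameters
#'
#' Applies [annual_type_total()] to each row of [type_reference()], treating
#' a missing season or flux for an absent size class as zero area.
#'
#' @param ref Reference tibble (default [type_reference()]).
#' @return The tibble with a computed `annual_Tg_computed` column.
#' @export
reference_type_totals <- function(ref = type_reference()) {
  ref$annual_Tg_computed <- mapply(function(as, al, fs, fl, ss, sl) {
    annual_type_total(as * 1e3, ifelse(al > 0, al * 1e3, 0),
                      fs, ifelse(al > 0, fl, 0),
                      ss, ifelse(al > 0, sl, 0))
  }, ref$area_small_1e3km2, ref$area_large_1e3km2,
     ref$flux_small, ref$flux_large,
     ref$season_small_days, ref$season_large_days)
  ref
}

#' Large-lake (>= 5,000 km^2) annual emission from the reference parameters
#'
#' @param ref Reference tibble.
#' @return Tg CH4 yr^-1 emitted from large-lake area.
#' @export
reference_large_lake_total <- function(ref = type_reference()) {
  with(ref[ref$area_large_1e3km2 > 0, ],
       sum(flux_to_Tg(flux_large, area_large_1e3km2 * 1e3, season_large_days)))
}

#' Revised freshwater CH4 budget accounting
#'
#' Substitutes a freshwater aquatic emission built from river, reservoir and
#' lake components for the prior assumption in the global CH4 budget, and
#' propagates the change through the bottom-up total and the bottom-up minus
#' top-down imbalance.
#'
#' @param rivers_Tg,reservoirs_Tg,lakes_Tg Component emissions
#'   (defaults 27, 10, 42 Tg yr^-1).
#' @param prior_freshwater_Tg Freshwater emission assumed in the prior budget
#'   (default 159).
#' @param bottom_up_Tg,imbalance_Tg Prior bottom-up total (737) and
#'   bottom-up/top-down imbalance (112).
#' @return List: `freshwater_Tg`, `revised_bottom_up_Tg`,
#'   `revised_imbalance_Tg`.
#' @export
freshwater_budget_revision <- function(rivers_Tg = 27, reservoirs_Tg = 10,
                                       lakes_Tg = 42,
                                       prior_freshwater_Tg = 159,
                                       bottom_up_Tg = 737,
                                       imbalance_Tg = 112) {
  fresh <- rivers_Tg + reservoirs_Tg + lakes_Tg
  reduction <- prior_freshwater_Tg - fresh
  list(freshwater_Tg = fresh,
       revised_bottom_up_Tg = bottom_up_Tg - reduction,
       revised_imbalance_Tg = imbalance_Tg - reduction)
}
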