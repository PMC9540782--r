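# Ice-out / spring-turnover and fall-turnover fluxes.
#
# An accumulation-oxidation model: CH4 produced at deep-water temperature
# (5 deg C) accumulates under ice (spring release) or below the thermocline
# (fall release) after a 60-day oxygen-depletion lag; oxidation removes most
# of the store (75% spring, 89% fall) and the remainder is emitted in a short
# window tied to the thaw or freeze date.

#' Parameters of the accumulation-oxidation episodic-flux model
#'
#' @param t_deep Deep-water temperature (deg C) at which CH4 production is
#'   evaluated; default 5 (maximum-density temperature plus ~1 deg metabolic
#'   heating).
#' @param lag_spring,lag_fall Days after freeze (resp. thaw) before oxygen
#'   depletion lets CH4 accumulate; default 60, assumed to vary +/- 15.
#' @param ox_spring,ox_fall Fraction of the accumulated store oxidized before
#'   emission; defaults 0.75 (ice-out + spring turnover) and 0.89 (fall
#'   turnover).
#' @param spring_window Emission window length (days) centred on the thaw
#'   date; default 14 (+/- 7 days).
#' @param fall_window Emission window (days) immediately before the freeze
#'   date; default 7.
#' @return Validated `episodic_params` list.
#' @export
episodic_params <- function(t_deep = 5, lag_spring = 60, lag_fall = 60,
                            ox_spring = 0.75, ox_fall = 0.89,
                            spring_window = 14, fall_window = 7) {
  stopifnot(lag_spring >= 0, lag_fall >= 0,
            ox_spring >= 0, ox_spring < 1, ox_fall >= 0, ox_fall < 1,
            spring_window >= 1, fall_window >= 1)
  structure(list(t_deep = t_deep, lag_spring = lag_spring, lag_fall = lag_fall,
                 ox_spring = ox_spring, ox_fall = ox_fall,
                 spring_window = spring_window, fall_window = fall_window),
            class = "episodic_params")
}

#' Ebullition rate rescaled to deep-water temperature
#'
#' CH4 production feeding the under-ice and below-thermocline store is taken
#' as the type's reference ebullition flux rescaled along the exponential
#' temperature relationship to `t_deep`:
#' `E5 = ref * exp(b * (t_deep - t_ref))`.
#'
#' @param ref_flux Reference ebullition flux (mg m^-2 d^-1).
#' @param t_ref Temperature (deg C) at which `ref_flux` applies.
#' @param b Ebullition temperature sensitivity (per deg C).
#' @param t_deep Deep-water temperature (default 5 deg C).
#' @return Non-negative production rate at `t_deep` (mg m^-2 d^-1).
#' @export
deep_water_ebullition_rate <- function(ref_flux, t_ref, b, t_deep = 5) {
  pmax(0, ref_flux * exp(b * (t_deep - t_ref)))
}

#' Per-type deep-water production rates from the compilation
#'
#' The reference flux and temperature for each type are the means of the
#' corrected ebullition fluxes and their observation temperatures; the
#' organic type uses peat pond data via the alias table.
#'
#' @param records Corrected, type-assigned records.
#' @param model Ebullition `temp_flux_model` (for the slope `b`).
#' @param params `episodic_params`.
#' @return Named numeric vector: E5 (mg m^-2 d^-1) per lake type.
#' @export
deep_water_rates_by_type <- function(records, model, params = episodic_params()) {
  eb <- records[!is.na(records$pathway) & records$pathway == "ebullition" &
                  is.finite(records$flux) & records$flux > 0, , drop = FALSE]
  e5 <- stats::setNames(rep(NA_real_, length(lake_types())), lake_types())
  for (ty in lake_types()) {
    src <- if (ty %in% eb$lake_type) ty else TYPE_ALIAS[ty]
    sub <- eb[!is.na(src) & eb$lake_type == src, , drop = FALSE]
    if (nrow(sub) == 0) next
    e5[ty] <- deep_water_ebullition_rate(mean(sub$flux), mean(sub$air_temp_obs),
                                         model$b, params$t_deep)
  }
  e5
}

# Stored mass (mg m^-2) at release, spring and fall.
stored_spring_mass <- function(season_length, e5, params) {
  ice_period <- DAYS_IN_YEAR - season_length
  e5 * pmax(0, ice_period - params$lag_spring) * (1 - params$ox_spring)
}

stored_fall_mass <- function(season_length, e5, params) {
  e5 * pmax(0, season_length - params$lag_fall) * (1 - params$ox_fall)
}

# Window days for the spring release: +/- spring_window/2 around thaw. Days
# in the post-thaw half that would run past the freeze date are clipped and
# the mass renormalized over the remaining days; the pre-thaw half is the
# ice-melt release itself and always emits.
spring_window_days <- function(thaw, season_length, params) {
  half <- params$spring_window %/% 2
  days <- wrap_doy(seq(thaw - half, thaw + half - 1))
  offset <- (days - thaw) %% DAYS_IN_YEAR
  keep <- offset >= DAYS_IN_YEAR - half | offset < pmin(half, season_length)
  days[keep]
}

fall_window_days <- function(thaw, freeze, season_length, params) {
  days <- wrap_doy(seq(freeze - params$fall_window, freeze - 1))
  keep <- ((days - thaw) %% DAYS_IN_YEAR) < season_length
  days[keep]
}

#' Daily ice-out + spring-turnover flux series for one cell
#'
#' CH4 accumulates at rate E5 during the ice period beyond the oxygen
#' depletion lag; the unoxidized remainder is emitted evenly over the window
#' centred on the thaw date. Never-freezing cells return a zero series.
#'
#' @param thaw,freeze Climatological day-of-year for the cell.
#' @param season_length Emission-season length (days).
#' @param no_freeze Logical; `TRUE` returns zeros.
#' @param e5 Deep-water production rate (mg m^-2 d^-1).
#' @param params `episodic_params`.
#' @return Numeric vector of 365 daily fluxes (mg m^-2 d^-1) summing exactly
#'   to the stored mass.
#' @export
ice_out_spring_flux <- function(thaw, freeze, season_length, no_freeze, e5,
                                params = episodic_params()) {
  out <- numeric(DAYS_IN_YEAR)
  if (isTRUE(no_freeze) || !is.finite(e5) || e5 <= 0) return(out)
  stored <- stored_spring_mass(season_length, e5, params)
  if (stored <= 0) return(out)
  days <- spring_window_days(thaw, season_length, params)
  out[days] <- stored / length(days)
  out
}

#' Daily fall-turnover flux series for one cell
#'
#' CH4 accumulating below the thermocline over the open-water season beyond
#' the lag is emitted evenly over the days immediately before freeze.
#'
#' @inheritParams ice_out_spring_flux
#' @return Numeric vector of 365 daily fluxes (mg m^-2 d^-1).
#' @export
fall_turnover_flux <- function(thaw, freeze, season_length, no_freeze, e5,
                               params = episodic_params()) {
  out <- numeric(DAYS_IN_YEAR)
  if (isTRUE(no_freeze) || !is.finite(e5) || e5 <= 0) return(out)
  stored <- stored_fall_mass(season_length, e5, params)
  if (stored <= 0) return(out)
  days <- fall_window_days(thaw, freeze, season_length, params)
  if (length(days) == 0) return(out)
  out[days] <- stored / length(days)
  out
}
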