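# Temperature-driven flux seasonality.
#
# Lake CH4 fluxes rise exponentially with air temperature. An ordinary
# least-squares fit of ln(flux) on temperature (one pooled model per pathway)
# provides the sensitivity used to project each corrected measurement to all
# twelve months of its site's temperature climatology. Projected records are
# averaged into a type x pathway x month table and interpolated with a
# periodic cubic spline to a 365-day annual cycle.

# The organic lake type has no direct measurements; its emission rates are
# copied from peat ponds.
TYPE_ALIAS <- c(organic = "peat_pond")

#' Fit the exponential temperature-flux relationship for a pathway
#'
#' OLS of `ln(flux)` on air temperature over diel-corrected records of one
#' pathway. Non-positive fluxes cannot enter the log fit and are excluded
#' (their count is reported). The fit is refused with an error when fewer
#' than `min_n` usable records remain or the design is singular (all records
#' at one temperature).
#'
#' @param records Diel-corrected tibble with `pathway`, `flux`,
#'   `air_temp_obs`.
#' @param pathway `"diffusion"` or `"ebullition"`.
#' @param min_n Minimum usable records (default 10).
#' @return A `temp_flux_model`: list with `pathway`, intercept `a`
#'   (ln mg m^-2 d^-1), slope `b` (per deg C), `n`, `r2`, `sigma`,
#'   `n_excluded`, and the slope's standard error `b_se`.
#' @export
fit_temp_flux <- function(records, pathway, min_n = 10) {
  sub <- records[!is.na(records$pathway) & records$pathway == pathway, , drop = FALSE]
  usable <- is.finite(sub$flux) & sub$flux > 0 & is.finite(sub$air_temp_obs)
  n_excluded <- sum(!usable)
  sub <- sub[usable, , drop = FALSE]
  if (nrow(sub) < min_n) {
    stop(sprintf("temperature-flux fit refused for %s: %d usable records (< %d)",
                 pathway, nrow(sub), min_n))
  }
  if (stats::sd(sub$air_temp_obs) == 0) {
    stop(sprintf("temperature-flux fit refused for %s: singular design (one temperature)",
                 pathway))
  }
  fit <- stats::lm(log(flux) ~ air_temp_obs, data = sub)
  s <- suppressWarnings(summary(fit))  # zero-residual fits are legitimate here
  structure(list(pathway = pathway,
                 a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 b_se = s$coefficients["air_temp_obs", "Std. Error"],
                 n = nrow(sub), r2 = s$r.squared, sigma = s$sigma,
                 n_excluded = n_excluded),
            class = "temp_flux_model")
}

#' @export
print.temp_flux_model <- function(x, ...) {
  cat(sprintf("<temp_flux_model> %s: ln(flux) = %.3f + %.4f T (n = %d, R2 = %.3f)\n",
              x$pathway, x$a, x$b, x$n, x$r2))
  invisible(x)
}

#' Project corrected measurements to monthly-mean daily fluxes
#'
#' Each record's corrected flux is carried through its site's seasonal
#' temperature cycle: `flux(m) = flux * exp(b * (T_m - T_anchor))` where
#' `T_anchor` is the site's climatological temperature for the measurement
#' month, so the projection returns the corrected flux exactly in that month.
#' Records whose site climatology is unavailable (outside the grid) are
#' skipped; their ids are attached as attribute `skipped`.
#'
#' @param records Diel-corrected, type-assigned tibble.
#' @param models Named list of `temp_flux_model`s by pathway.
#' @param layers `geo_layers` providing `monthly_temp`.
#' @return Long tibble: `record_id`, `lake_type`, `pathway`, `month`,
#'   `flux_monthly` plus the record's corrected `flux`.
#' @export
project_to_months <- function(records, models, layers) {
  idx <- cell_index(layers$grid, records$lat, records$lon)
  ok <- !is.na(idx[, "row"])
  skipped <- records$record_id[!ok]
  rec <- records[ok, , drop = FALSE]
  idx <- idx[ok, , drop = FALSE]
  n <- nrow(rec)
  b <- vapply(rec$pathway, function(p) models[[p]]$b, numeric(1))
  t_site <- matrix(NA_real_, n, 12)
  for (m in 1:12) t_site[, m] <- layers$monthly_temp[cbind(idx[, "row"], idx[, "col"], m)]
  t_anchor <- t_site[cbind(seq_len(n), rec$month)]
  out <- tibble::tibble(
    record_id = rep(rec$record_id, each = 12),
    lake_type = rep(rec$lake_type, each = 12),
    pathway = rep(rec$pathway, each = 12),
    month = rep(1:12, times = n),
    flux = rep(rec$flux, each = 12),
    flux_monthly = as.vector(t(rec$flux * exp(b * (t_site - t_anchor))))
  )
  attr(out, "skipped") <- skipped
  out
}

#' Aggregate projected records to a type x pathway x month flux table
#'
#' Arithmetic mean across records within each type x pathway x month cell,
#' with the sample count and coefficient of variation retained for the
#' uncertainty budget. The organic type, which has no measurements of its
#' own, is filled from peat pond values via the alias table. Types present in
#' the area grid but absent from the table (after aliasing) are a hard error.
#'
#' @param projected Output of [project_to_months()].
#' @param required_types Types that must have values (e.g. those with lake
#'   area on the grid).
#' @return A `monthly_flux_table` tibble: `lake_type`, `pathway`, `month`,
#'   `flux` (mg m^-2 d^-1), `n`, `cv`.
#' @export
aggregate_monthly <- function(projected, required_types = lake_types()) {
  tab <- dplyr::summarise(
    dplyr::group_by(projected, .data$lake_type, .data$pathway, .data$month),
    n = dplyr::n(),
    cv = ifelse(mean(.data$flux_monthly) != 0,
                stats::sd(.data$flux_monthly) / abs(mean(.data$flux_monthly)), 0),
    flux = mean(.data$flux_monthly),
    .groups = "drop"
  )
  tab$cv[is.na(tab$cv)] <- 0
  tab$aliased <- FALSE
  for (to in names(TYPE_ALIAS)) {
    if (!to %in% tab$lake_type) {
      src <- tab[tab$lake_type == TYPE_ALIAS[[to]], , drop = FALSE]
      if (nrow(src) > 0) {
        src$lake_type <- to
        src$aliased <- TRUE
        tab <- dplyr::bind_rows(tab, src)
      }
    }
  }
  have <- unique(tab$lake_type[!is.na(tab$flux)])
  gaps <- setdiff(required_types, have)
  if (length(gaps) > 0) {
    stop(sprintf("no flux data (even via alias) for lake type(s): %s",
                 paste(gaps, collapse = ", ")))
  }
  class(tab) <- c("monthly_flux_table", class(tab))
  tab
}

#' Interpolate monthly flux anchors to a 365-day annual cycle
#'
#' A periodic cubic spline is passed through the twelve monthly values placed
#' at month-midpoint days of the 365-day climatological calendar, so the
#' daily curve matches every monthly anchor and has no year-boundary
#' discontinuity. Negative interpolated ebullition values are clipped to
#' zero (diffusive uptake may stay negative).
#'
#' @param table A `monthly_flux_table`.
#' @return A `daily_flux_curves` object: named list
#'   `curves[[lake_type]][[pathway]]` of 365 daily fluxes, plus the anchor
#'   table.
#' @export
spline_to_daily <- function(table) {
  mids <- month_midpoints()
  curves <- list()
  combos <- unique(table[, c("lake_type", "pathway")])
  for (i in seq_len(nrow(combos))) {
    ty <- combos$lake_type[i]; pw <- combos$pathway[i]
    sub <- table[table$lake_type == ty & table$pathway == pw, , drop = FALSE]
    sub <- sub[order(sub$month), , drop = FALSE]
    if (nrow(sub) != 12) {
      stop(sprintf("%s/%s: %d monthly anchors (need 12)", ty, pw, nrow(sub)))
    }
    f <- stats::splinefun(c(mids, mids[1] + DAYS_IN_YEAR),
                          c(sub$flux, sub$flux[1]), method = "periodic")
    y <- f(1:DAYS_IN_YEAR)
    if (pw == "ebullition") y <- pmax(y, 0)
    curves[[ty]][[pw]] <- y
  }
  structure(list(curves = curves, anchors = table), class = "daily_flux_curves")
}

#' Look up a daily curve
#' @param curves A `daily_flux_curves`.
#' @param lake_type,pathway Selection.
#' @return Numeric vector of 365 daily fluxes (mg m^-2 d^-1).
#' @export
daily_curve <- function(curves, lake_type, pathway) {
  y <- curves$curves[[lake_type]][[pathway]]
  if (is.null(y)) stop(sprintf("no daily curve for %s/%s", lake_type, pathway))
  y
}
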