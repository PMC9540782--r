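# Ingest and prepare the flux-measurement compilation.
#
# Records are aggregated flux values with sampling metadata. Preparation:
# read -> filter (direct-method lake records with pathway, month and sampling
# window present) -> disaggregate reported averages into component
# observations -> diel-correct daytime-only values (x 0.7) -> assign an
# ecoclimatic lake type (explicit label wins, else the classified grid cell).

REQUIRED_COLUMNS <- c("record_id", "site_id", "lat", "lon", "pathway", "flux",
                      "month", "sampling_window", "method")

#' Diel scaling factor converting daytime-only fluxes to 24-h means
#' @export
DIEL_FACTOR <- 0.7

#' Read a flux-measurement compilation CSV
#'
#' Required columns: `record_id`, `site_id`, `lat`, `lon`, `pathway`, `flux`,
#' `month`, `sampling_window`, `method`. Optional columns (`lake_type`,
#' `system_class`, `air_temp_obs`, `components`, `n_underlying`, ...) are
#' carried through when present. Months given as names ("July", "jul") are
#' parsed; unparseable optional values become missing rather than errors.
#'
#' @param path CSV file path.
#' @return Tibble of flux records.
#' @export
read_compilation <- function(path) {
  if (!file.exists(path)) stop(sprintf("compilation file not found: %s", path))
  rec <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(rec))
  if (length(missing_cols) > 0) {
    stop(sprintf("compilation is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  rec$lat <- num(rec$lat)
  rec$lon <- num(rec$lon)
  rec$flux <- num(rec$flux)
  rec$month <- parse_month(rec$month)
  rec$sampling_window <- ifelse(rec$sampling_window %in% c("daytime", "24h"),
                                rec$sampling_window, NA_character_)
  if ("air_temp_obs" %in% names(rec)) rec$air_temp_obs <- num(rec$air_temp_obs)
  if ("n_underlying" %in% names(rec)) rec$n_underlying <- num(rec$n_underlying)
  if ("true_flux_24h" %in% names(rec)) rec$true_flux_24h <- num(rec$true_flux_24h)
  if (!"system_class" %in% names(rec)) rec$system_class <- "lake"
  if (!"lake_type" %in% names(rec)) rec$lake_type <- NA_character_
  bad_lat <- !is.na(rec$lat) & abs(rec$lat) > 90
  if (any(bad_lat)) stop("latitude outside [-90, 90]")
  rec
}

#' Parse month values given as numbers or English month names
#' @param x Character or numeric vector.
#' @return Integer months 1..12, `NA` where unparseable.
#' @export
parse_month <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.integer(x))
  out[!is.na(out) & (out < 1 | out > 12)] <- NA_integer_
  named <- is.na(out) & !is.na(x)
  if (any(named)) {
    idx <- match(tolower(substr(x[named], 1, 3)), tolower(month.abb))
    out[named] <- idx
  }
  out
}

#' Filter the compilation to usable direct lake measurements
#'
#' Keeps direct-method lake records with pathway, month and sampling window
#' all present. Each rejected record carries exactly one primary reason, in
#' precedence order: `indirect`, `beaver_pond`, `missing_pathway`,
#' `missing_month`, `missing_window`. Filtering never raises.
#'
#' @param records Tibble from [read_compilation()] or the generator.
#' @return List `kept` (tibble) and `rejected` (tibble with `reason` column).
#' @export
filter_records <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  fill <- function(reason, cond, label) {
    ifelse(is.na(reason) & cond, label, reason)
  }
  reason <- fill(reason, !is.na(records$method) & records$method == "indirect",
                 "indirect")
  reason <- fill(reason, !is.na(records$system_class) &
                   records$system_class == "beaver_pond", "beaver_pond")
  reason <- fill(reason, is.na(records$pathway), "missing_pathway")
  reason <- fill(reason, is.na(records$month), "missing_month")
  reason <- fill(reason, is.na(records$sampling_window), "missing_window")
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = records[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Expand records reported as averages of listed component observations
#'
#' A record whose `components` field lists k individual fluxes (";"-separated)
#' is replaced by k records inheriting all metadata; its reported mean is
#' checked against the component mean and a warning is logged if they differ
#' by more than 1\% (components are used regardless). Records without
#' components pass through unchanged.
#'
#' @param records Tibble with optional `components` column.
#' @return Tibble with one row per individual observation.
#' @export
disaggregate_records <- function(records) {
  if (!"components" %in% names(records)) return(records)
  has <- !is.na(records$components) & nzchar(records$components)
  if (!any(has)) return(records)
  plain <- records[!has, , drop = FALSE]
  pieces <- lapply(which(has), function(i) {
    comp <- as.numeric(strsplit(records$components[i], ";")[[1]])
    if (length(comp) == 0 || anyNA(comp)) {
      warning(sprintf("record %s: unparseable components; left aggregated",
                      records$record_id[i]))
      return(records[i, , drop = FALSE])
    }
    m <- records$flux[i]
    if (is.finite(m) && m != 0 && abs(mean(comp) - m) / abs(m) > 0.01) {
      warning(sprintf("record %s: component mean %.4g differs from reported %.4g; using components",
                      records$record_id[i], mean(comp), m))
    }
    out <- records[rep(i, length(comp)), , drop = FALSE]
    out$flux <- comp
    out$record_id <- paste0(records$record_id[i], ".", seq_along(comp))
    out$components <- NA_character_
    out$n_underlying <- 1
    out
  })
  out <- dplyr::bind_rows(plain, dplyr::bind_rows(pieces))
  out[order(out$record_id), , drop = FALSE]
}

#' Convert daytime-only fluxes to 24-h means
#'
#' Daytime-only measurements (sampled between 07:00 and 20:00 local time) are
#' multiplied by the diel scaling factor 0.7; 24-h measurements are used as
#' reported. The correction is recorded in a `diel_corrected` column and a
#' second application is refused.
#'
#' @param records Filtered tibble (sampling window must be present).
#' @param factor Diel scaling factor (default [DIEL_FACTOR]).
#' @return Tibble with corrected `flux` and `diel_corrected = TRUE`.
#' @export
apply_diel_correction <- function(records, factor = DIEL_FACTOR) {
  if (isTRUE(attr(records, "diel_corrected")) ||
      ("diel_corrected" %in% names(records) && any(records$diel_corrected))) {
    stop("diel correction already applied; refusing to apply twice")
  }
  if (anyNA(records$sampling_window)) {
    stop("sampling window missing; records must be filtered before diel correction")
  }
  records$flux <- ifelse(records$sampling_window == "daytime",
                         records$flux * factor, records$flux)
  records$diel_corrected <- TRUE
  records
}

#' Assign an ecoclimatic lake type to each record
#'
#' An explicit `lake_type` label wins; otherwise the record takes the type of
#' the classified grid cell containing its coordinates. Records that cannot
#' be assigned (coordinates outside the grid and no label) are rejected with
#' reason `out_of_domain`.
#'
#' @param records Tibble of records.
#' @param type_map Character type matrix from [classify_ecoclimatic()].
#' @param grid The `ch4_grid` the map lives on.
#' @return List `assigned` (tibble, `lake_type` complete) and `rejected`.
#' @export
assign_lake_type <- function(records, type_map, grid) {
  need <- is.na(records$lake_type)
  idx <- cell_index(grid, records$lat, records$lon)
  grid_type <- rep(NA_character_, nrow(records))
  ok <- !is.na(idx[, "row"])
  grid_type[ok] <- type_map[idx[ok, , drop = FALSE]]
  records$lake_type[need] <- grid_type[need]
  bad <- is.na(records$lake_type)
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- "out_of_domain"
  list(assigned = records[!bad, , drop = FALSE], rejected = rejected)
}

#' Fill missing observation temperatures from the site climatology
#'
#' Records lacking a contemporaneous air temperature take the site's
#' climatological air temperature for the measurement month; the fallback is
#' flagged in `temp_imputed`.
#'
#' @param records Tibble with `month` present.
#' @param layers `geo_layers` with `monthly_temp`.
#' @return Tibble with complete `air_temp_obs`.
#' @export
fill_missing_temps <- function(records, layers) {
  idx <- cell_index(layers$grid, records$lat, records$lon)
  need <- is.na(records$air_temp_obs)
  records$temp_imputed <- need
  if (any(need)) {
    i <- which(need & !is.na(idx[, "row"]))
    records$air_temp_obs[i] <-
      layers$monthly_temp[cbind(idx[i, "row"], idx[i, "col"], records$month[i])]
  }
  records
}
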