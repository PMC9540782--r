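# Ecoclimatic lake-type classification and the lake-area grid.
#
# Seven lake types are distinguished by permafrost state, ground-ice content,
# soil organic carbon (SOC) and annual soil temperature. The decision tree is
# evaluated in fixed precedence so every cell gets exactly one type.

#' Canonical ecoclimatic lake-type codes
#'
#' Internal codes (and display labels) for the seven ecoclimatic lake types:
#' thermokarst, glacial/postglacial, peat pond, organic, other boreal,
#' temperate, and tropical/subtropical.
#'
#' @return Character vector of the seven type codes, in classification order.
#' @export
lake_types <- function() {
  c("thermokarst", "glacial", "peat_pond", "organic",
    "boreal", "temperate", "tropical")
}

#' @rdname lake_types
#' @export
lake_type_labels <- function() {
  c(thermokarst = "Thermokarst", glacial = "Glacial/Postglacial",
    peat_pond = "Peat pond", organic = "Organic", boreal = "Other Boreal",
    temperate = "Temperate", tropical = "Tropical/Subtropical")
}

#' Default classification thresholds
#'
#' @param t_trop Annual soil temperature (deg C) separating temperate from
#'   tropical/subtropical lakes. Default 20.0; its assumed uncertainty is
#'   +/- 2.5 deg C.
#' @param t_bor Annual soil temperature (deg C) separating boreal from
#'   temperate lakes. Not fixed by the source classification table; default
#'   8.0 deg C is a documented convention.
#' @param soc SOC threshold (kgC m^-2, depth-weighted to 1 m). Default 10.
#' @param ice Ground-ice threshold (% volume). Default 10.
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function(t_trop = 20, t_bor = 8, soc = 10, ice = 10) {
  stopifnot(t_bor < t_trop)
  list(t_trop = t_trop, t_bor = t_bor, soc = soc, ice = ice)
}

#' Classify grid cells into ecoclimatic lake types
#'
#' Decision tree in fixed precedence:
#' \enumerate{
#'   \item permafrost C or D, ground ice >= 10\% -> thermokarst
#'   \item permafrost C or D, ground ice < 10\% -> glacial/postglacial
#'   \item permafrost S or I, SOC >= 10, ground ice >= 10\% -> peat pond
#'   \item permafrost S or I, SOC >= 10, ground ice < 10\% -> organic
#'   \item otherwise by annual soil temperature: >= `t_trop` ->
#'     tropical/subtropical; in [`t_bor`, `t_trop`) -> temperate; below
#'     `t_bor` -> other boreal.
#' }
#' Cells matching no explicit branch (sporadic/isolated permafrost with
#' SOC < 10, or permafrost-free cells with SOC >= 10) fall through to the
#' temperature branches; their count is attached as attribute `n_fallback`
#' so the convention stays visible.
#'
#' @param layers A `geo_layers` list with matrices `soc`, `permafrost`
#'   (values "C","D","S","I","None"), `ground_ice`, `annual_soil_temp`.
#' @param thresholds See [classification_thresholds()].
#' @return Character matrix of type codes with attribute `n_fallback`.
#' @export
classify_ecoclimatic <- function(layers, thresholds = classification_thresholds()) {
  soc <- layers$soc
  pf <- layers$permafrost
  ice <- layers$ground_ice
  temp <- layers$annual_soil_temp
  stopifnot(all(dim(soc) == dim(pf)), all(dim(soc) == dim(ice)),
            all(dim(soc) == dim(temp)))
  if (any(soc < 0, na.rm = TRUE)) stop("SOC must be non-negative")
  if (any(ice < 0 | ice > 100, na.rm = TRUE)) stop("ground ice must be in [0, 100] %")

  pf_cd <- pf %in% c("C", "D")
  pf_si <- pf %in% c("S", "I")
  dim(pf_cd) <- dim(pf_si) <- dim(soc)

  type <- matrix(NA_character_, nrow(soc), ncol(soc))
  type[pf_cd & ice >= thresholds$ice] <- "thermokarst"
  type[pf_cd & ice < thresholds$ice] <- "glacial"
  type[pf_si & soc >= thresholds$soc & ice >= thresholds$ice] <- "peat_pond"
  type[pf_si & soc >= thresholds$soc & ice < thresholds$ice] <- "organic"

  rest <- is.na(type)
  # cells the explicit criteria do not cover, resolved by temperature
  fallback <- rest & ((pf_si & soc < thresholds$soc) | (!pf_cd & !pf_si & soc >= thresholds$soc))
  type[rest & temp >= thresholds$t_trop] <- "tropical"
  type[rest & temp >= thresholds$t_bor & temp < thresholds$t_trop] <- "temperate"
  type[rest & temp < thresholds$t_bor] <- "boreal"

  stopifnot(!anyNA(type))
  attr(type, "n_fallback") <- sum(fallback)
  type
}

#' Merge primary and small-lake area sources into one lake-area grid
#'
#' The primary source resolves lakes >= 0.1 km^2; the small-lake source adds
#' water bodies 0.002-0.1 km^2 but includes rivers and reservoirs, whose area
#' fractions are subtracted (clamped at zero) before merging:
#' `merged = primary + max(0, small - river - reservoir)`.
#'
#' @param primary,small,river,reservoir Area matrices (km^2 per cell) on the
#'   same grid. `river` and `reservoir` are areas to remove from `small`.
#' @return Matrix of merged lake area (km^2 per cell).
#' @export
merge_area_sources <- function(primary, small, river = 0 * primary,
                               reservoir = 0 * primary) {
  dims <- lapply(list(primary, small, river, reservoir), dim)
  if (length(unique(dims)) != 1) {
    stop(sprintf("grid mismatch in area sources: %s",
                 paste(vapply(dims, function(d) paste(d, collapse = "x"), ""),
                       collapse = " vs ")))
  }
  if (any(primary < 0) || any(small < 0)) stop("areas must be non-negative")
  primary + pmax(0, small - river - reservoir)
}

#' Assemble the lake-area grid split by size class
#'
#' @param grid A `ch4_grid`.
#' @param area_small Matrix, lake area (km^2) from lakes < 5,000 km^2 per cell.
#' @param area_large Matrix, lake area (km^2) from lakes >= 5,000 km^2 per cell.
#' @return `lake_area_grid` object.
#' @export
lake_area_grid <- function(grid, area_small, area_large = 0 * area_small) {
  stopifnot(all(dim(area_small) == grid_dims(grid)),
            all(dim(area_large) == grid_dims(grid)))
  if (any(area_small < 0) || any(area_large < 0)) {
    stop("lake areas must be non-negative")
  }
  tot <- area_small + area_large
  if (any(tot > grid$cell_area * (1 + 1e-9))) {
    stop("lake area exceeds cell geographic area")
  }
  structure(list(grid = grid, area_small = area_small, area_large = area_large),
            class = "lake_area_grid")
}

#' Lake area totals by ecoclimatic type and size class
#'
#' @param areas A `lake_area_grid`.
#' @param type_map Character matrix of type codes from [classify_ecoclimatic()].
#' @return Tibble with columns `lake_type`, `area_small_km2`, `area_large_km2`.
#' @export
type_area_table <- function(areas, type_map) {
  tibble::tibble(
    lake_type = lake_types(),
    area_small_km2 = unname(vapply(lake_types(), function(t) {
      sum(areas$area_small[type_map == t])
    }, numeric(1))),
    area_large_km2 = unname(vapply(lake_types(), function(t) {
      sum(areas$area_large[type_map == t])
    }, numeric(1)))
  )
}
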