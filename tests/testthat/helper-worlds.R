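# Shared fixture builders: small synthetic worlds generated in code.

# Pole-to-pole strip one cell-column wide per degree of longitude; small
# enough for fast pipeline runs while containing every ecoclimatic type.
tiny_config <- function(seed = 42, ...) {
  generator_config(seed = seed, lon_range = c(0, 1), ...)
}

# Noise-free, temperature-flat world where the pipeline total has a closed
# form: every corrected flux equals alpha exactly.
flat_config <- function(seed = 11, alpha_d = 8, alpha_e = 12, ...) {
  generator_config(seed = seed, lon_range = c(0, 1),
                   sigma_log = 0,
                   beta = c(diffusion = 0, ebullition = 0),
                   alpha = list(diffusion = alpha_d, ebullition = alpha_e),
                   frac_components = 0, frac_missing = 0,
                   frac_indirect = 0, frac_beaver = 0, ...)
}

# A single-type single-cell world assembled by hand for engine oracles.
one_cell_world <- function(area_small = 10, area_large = 0,
                           thaw = 100, freeze = 250, no_freeze = FALSE,
                           flux_d = 5, flux_e = 7) {
  grid <- grid_spec(c(50, 50.25), c(0, 0.25))
  tm <- matrix("temperate", 1, 1)
  areas <- lake_area_grid(grid, matrix(area_small, 1, 1),
                          matrix(area_large, 1, 1))
  season <- season_grid(grid, matrix(ifelse(no_freeze, NA, thaw), 1, 1),
                        matrix(ifelse(no_freeze, NA, freeze), 1, 1),
                        matrix(no_freeze, 1, 1))
  curves <- constant_curves(list(temperate = c(diffusion = flux_d,
                                               ebullition = flux_e)))
  list(grid = grid, type_map = tm, areas = areas, season = season,
       curves = curves)
}

# Build daily_flux_curves with constant values per type/pathway.
constant_curves <- function(spec) {
  curves <- list()
  rows <- list()
  for (ty in names(spec)) {
    for (pw in names(spec[[ty]])) {
      curves[[ty]][[pw]] <- rep(spec[[ty]][[pw]], 365)
      rows[[length(rows) + 1]] <- tibble::tibble(
        lake_type = ty, pathway = pw, month = 1:12,
        flux = spec[[ty]][[pw]], n = 1L, cv = 0, aliased = FALSE)
    }
  }
  structure(list(curves = curves, anchors = dplyr::bind_rows(rows)),
            class = "daily_flux_curves")
}

# Independent brute-force oracle for open-water emission of a single cell:
# loop over days, test season membership, accumulate grams.
brute_force_cell_total <- function(area_eff_km2, curve, thaw, season_length) {
  tot <- 0
  for (d in 1:365) {
    if (((d - thaw) %% 365) < season_length) {
      tot <- tot + curve[d] * area_eff_km2 * 1e3
    }
  }
  tot
}
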