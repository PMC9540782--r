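# Synthetic-world generator.
#
# Emulates every pipeline input with known ground truth: a flux-measurement
# compilation with exponential temperature dependence, diel structure and
# planted metadata defects; gridded geophysical layers constructed so all
# seven ecoclimatic type signatures occur; multi-year thaw/freeze phenology
# from two sources; and a lake-area grid split by size class. A single seed
# drives deterministic per-component substreams so each piece can be
# regenerated independently.

#' Configuration for the synthetic-world generator
#'
#' Defaults reproduce the structure of the study conditions: 575 lake sites
#' aggregating to roughly 881 flux values (about 76\% diffusion), a daytime
#' flux excess of 1/0.7 over the 24-h mean, lognormal flux scatter, and a
#' small planted fraction of indirect-method, beaver-pond and
#' metadata-incomplete records to exercise the filters.
#'
#' @param seed Integer master seed; substream seeds are derived from it.
#' @param n_sites Number of lake systems (default 575).
#' @param lat_range,lon_range Grid extent (degrees); default a 0.25-degree
#'   pole-to-pole strip 5 degrees wide, wide enough in latitude to contain
#'   every ecoclimatic type.
#' @param res Grid resolution in degrees.
#' @param alpha Named list per pathway of per-type base fluxes at 0 deg C
#'   (mg CH4 m^-2 d^-1); scalar values are recycled over the seven types.
#' @param beta Named vector of temperature sensitivities (per deg C) for
#'   `diffusion` and `ebullition`.
#' @param diel_day_multiplier Ratio of daytime to 24-h mean flux (>= 1;
#'   default 1/0.7, the inverse of the diel correction factor).
#' @param sigma_log SD of lognormal multiplicative flux noise.
#' @param frac_daytime Fraction of records sampled daytime-only.
#' @param frac_indirect Fraction measured by indirect (acoustic) methods.
#' @param frac_beaver Fraction of systems that are beaver ponds.
#' @param frac_missing Fraction of records with missing metadata, split
#'   evenly across month, sampling window and pathway.
#' @param frac_unlabeled Fraction of records without an explicit lake-type
#'   label (type must then come from the classified grid).
#' @param frac_components Fraction of records carrying disaggregatable
#'   component observations.
#' @param t_equator Annual-mean air temperature at the equator (deg C).
#' @param lapse Cooling of annual-mean temperature per degree latitude.
#' @param seasonal_amp_per_deg Seasonal temperature amplitude per degree of
#'   absolute latitude (deg C); 0 gives a season-free world.
#' @param lat_no_freeze Absolute latitude below which cells never freeze.
#' @param n_years Years of synthetic phenology per source.
#' @param phenology_jitter_sd SD (days) of interannual thaw/freeze jitter.
#' @param lake_frac_mean Mean lake fraction of cell area in lake cells.
#' @param frac_lake_cells Fraction of cells containing lakes.
#' @param frac_large_cells Fraction of lake cells that also hold part of a
#'   lake >= 5,000 km^2.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_sites = 575L,
                             lat_range = c(-90, 90),
                             lon_range = c(0, 5),
                             res = 0.25,
                             alpha = list(diffusion = 8, ebullition = 12),
                             beta = c(diffusion = 0.06, ebullition = 0.11),
                             diel_day_multiplier = 1 / 0.7,
                             sigma_log = 0.3,
                             frac_daytime = 0.8,
                             frac_indirect = 0.03,
                             frac_beaver = 0.02,
                             frac_missing = 0.06,
                             frac_unlabeled = 0.2,
                             frac_components = 0.1,
                             t_equator = 28,
                             lapse = 0.55,
                             seasonal_amp_per_deg = 0.35,
                             lat_no_freeze = 40,
                             n_years = 13L,
                             phenology_jitter_sd = 5,
                             lake_frac_mean = 0.02,
                             frac_lake_cells = 0.5,
                             frac_large_cells = 0.02) {
  types <- lake_types()
  expand <- function(a) {
    if (length(a) == 1) a <- rep(a, length(types))
    if (is.null(names(a)) || !all(types %in% names(a))) names(a) <- types
    a[types]
  }
  alpha <- list(diffusion = expand(alpha$diffusion),
                ebullition = expand(alpha$ebullition))
  if (any(unlist(alpha) <= 0)) stop("alpha must be positive")
  if (any(beta < 0)) stop("beta must be non-negative")
  if (sigma_log < 0) stop("sigma_log must be non-negative")
  if (diel_day_multiplier < 1) stop("diel_day_multiplier must be >= 1")
  fr <- c(frac_daytime, frac_indirect, frac_beaver, frac_missing,
          frac_unlabeled, frac_components)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  structure(list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    lat_range = lat_range, lon_range = lon_range, res = res,
    alpha = alpha, beta = beta,
    diel_day_multiplier = diel_day_multiplier, sigma_log = sigma_log,
    frac_daytime = frac_daytime, frac_indirect = frac_indirect,
    frac_beaver = frac_beaver, frac_missing = frac_missing,
    frac_unlabeled = frac_unlabeled, frac_components = frac_components,
    t_equator = t_equator, lapse = lapse,
    seasonal_amp_per_deg = seasonal_amp_per_deg,
    lat_no_freeze = lat_no_freeze, n_years = as.integer(n_years),
    phenology_jitter_sd = phenology_jitter_sd,
    lake_frac_mean = lake_frac_mean, frac_lake_cells = frac_lake_cells,
    frac_large_cells = frac_large_cells
  ), class = "generator_config")
}

# Deterministic substream seeds (kept well below 2^31).
substream_seed <- function(cfg, component) {
  offsets <- c(layers = 11L, phenology = 23L, areas = 37L, records = 53L,
               mc = 71L)
  (cfg$seed %% 20000000L) * 100L + offsets[[component]]
}

#' Generate gridded geophysical layers and a temperature climatology
#'
#' Annual-mean air temperature declines linearly with absolute latitude from
#' `t_equator`; the monthly cycle is a sinusoid whose amplitude grows with
#' latitude and peaks in July (January in the Southern Hemisphere). Annual
#' soil temperature is taken equal to annual-mean air temperature so that the
#' classification and the flux-temperature model see a consistent world.
#' Permafrost bands, ground ice and SOC are laid out so that every one of the
#' seven type signatures occurs, including fallback cells (sporadic/isolated
#' permafrost with SOC below threshold). The intended type of every cell is
#' recorded as ground truth, derived from the band layout rather than by
#' running the classifier.
#'
#' @param cfg A `generator_config`.
#' @return A `geo_layers` list: matrices `soc`, `permafrost`, `ground_ice`,
#'   `annual_soil_temp`; array `monthly_temp` `[n_lat, n_lon, 12]`; `grid`;
#'   and `true_type` (ground-truth type map).
#' @export
generate_geophysical_layers <- function(cfg) {
  set.seed(substream_seed(cfg, "layers"))
  grid <- grid_spec(cfg$lat_range, cfg$lon_range, cfg$res)
  nl <- length(grid$lat); nn <- length(grid$lon)
  latm <- lat_field(grid)
  alat <- abs(latm)

  t_ann <- cfg$t_equator - cfg$lapse * alat
  amp <- cfg$seasonal_amp_per_deg * alat
  peak_month <- ifelse(latm >= 0, 7, 1)
  monthly <- array(NA_real_, c(nl, nn, 12))
  for (m in 1:12) {
    monthly[, , m] <- t_ann + amp * cos(2 * pi * (m - peak_month) / 12)
  }

  pf <- matrix("None", nl, nn)
  pf[alat >= 56 & alat < 61] <- "I"
  pf[alat >= 61 & alat < 66] <- "S"
  pf[alat >= 66 & alat < 72] <- "D"
  pf[alat >= 72] <- "C"

  # ground ice alternates by longitude column; SOC by latitude row, so both
  # branches of every permafrost band are populated
  ice <- matrix(0, nl, nn)
  col_even <- matrix(rep(seq_len(nn) %% 2 == 0, each = nl), nl, nn)
  ice[pf != "None"] <- ifelse(col_even[pf != "None"], 20, 5)
  soc <- matrix(4, nl, nn)
  row_mod <- matrix(rep(seq_len(nl) %% 3, times = nn), nl, nn)
  in_si <- pf %in% c("S", "I"); dim(in_si) <- dim(pf)
  soc[in_si] <- ifelse(row_mod[in_si] == 0, 5, 15)

  thr <- classification_thresholds()
  true_type <- matrix(NA_character_, nl, nn)
  in_cd <- pf %in% c("C", "D"); dim(in_cd) <- dim(pf)
  true_type[in_cd & ice >= 10] <- "thermokarst"
  true_type[in_cd & ice < 10] <- "glacial"
  true_type[in_si & soc >= 10 & ice >= 10] <- "peat_pond"
  true_type[in_si & soc >= 10 & ice < 10] <- "organic"
  rest <- is.na(true_type)
  true_type[rest & t_ann >= thr$t_trop] <- "tropical"
  true_type[rest & t_ann >= thr$t_bor & t_ann < thr$t_trop] <- "temperate"
  true_type[rest & t_ann < thr$t_bor] <- "boreal"

  structure(list(grid = grid, soc = soc, permafrost = pf, ground_ice = ice,
                 annual_soil_temp = t_ann, monthly_temp = monthly,
                 true_type = true_type),
            class = "geo_layers")
}

#' Generate multi-year thaw/freeze phenology from two synthetic sources
#'
#' Thaw dates advance and freeze dates retreat linearly poleward of
#' `lat_no_freeze`; equatorward cells never freeze. Southern Hemisphere dates
#' are shifted half a year so they straddle the new-year boundary. Each year
#' jitters around the climatological date, and the lake-ice source holds ice
#' a few days longer than the landscape source.
#'
#' @param cfg A `generator_config`.
#' @param grid A `ch4_grid` (defaults to the config extent).
#' @return List with arrays `thaw`/`freeze` `[n_lat, n_lon, n_years]` for
#'   `landscape` and `lake_ice` sources.
#' @export
generate_phenology <- function(cfg, grid = grid_spec(cfg$lat_range, cfg$lon_range, cfg$res)) {
  set.seed(substream_seed(cfg, "phenology"))
  nl <- length(grid$lat); nn <- length(grid$lon); ny <- cfg$n_years
  latm <- lat_field(grid)
  alat <- abs(latm)
  freezes <- alat >= cfg$lat_no_freeze

  base_thaw <- 60 + 2.5 * (alat - cfg$lat_no_freeze)
  base_freeze <- 330 - 2.5 * (alat - cfg$lat_no_freeze)
  sh <- latm < 0
  base_thaw[sh] <- wrap_doy(base_thaw[sh] + 183)
  base_freeze[sh] <- wrap_doy(base_freeze[sh] + 183)

  one_source <- function(offset) {
    thaw <- array(NA_real_, c(nl, nn, ny))
    freeze <- array(NA_real_, c(nl, nn, ny))
    for (y in seq_len(ny)) {
      jt <- matrix(stats::rnorm(nl * nn, 0, cfg$phenology_jitter_sd), nl, nn)
      jf <- matrix(stats::rnorm(nl * nn, 0, cfg$phenology_jitter_sd), nl, nn)
      ty <- wrap_doy(base_thaw + offset + jt)
      fy <- wrap_doy(base_freeze - offset + jf)
      ty[!freezes] <- NA_real_
      fy[!freezes] <- NA_real_
      thaw[, , y] <- ty
      freeze[, , y] <- fy
    }
    list(thaw = thaw, freeze = freeze)
  }
  list(landscape = one_source(0), lake_ice = one_source(4))
}

#' Generate the lake-area grid and its upstream source components
#'
#' Lake cells get a random lake fraction of cell area; a small share of lake
#' cells also carry area from lakes >= 5,000 km^2. The merged small-lake area
#' is decomposed into consistent primary/small-source/river/reservoir
#' components so the source-merging step can be exercised end to end.
#'
#' @param cfg A `generator_config`.
#' @param grid A `ch4_grid`.
#' @return List: `areas` (`lake_area_grid`), `large_lake_mask` (cells with
#'   lakes >= 50 km^2), and `sources` (primary, small, river, reservoir
#'   matrices with `merge_area_sources(sources) == area_small`).
#' @export
generate_lake_areas <- function(cfg, grid = grid_spec(cfg$lat_range, cfg$lon_range, cfg$res)) {
  set.seed(substream_seed(cfg, "areas"))
  nl <- length(grid$lat); nn <- length(grid$lon)
  has_lake <- matrix(stats::runif(nl * nn) < cfg$frac_lake_cells, nl, nn)
  frac <- matrix(stats::runif(nl * nn, 0, 2 * cfg$lake_frac_mean), nl, nn)
  area_small <- grid$cell_area * frac * has_lake

  is_large <- has_lake & matrix(stats::runif(nl * nn) < cfg$frac_large_cells, nl, nn)
  area_large <- grid$cell_area * 0.3 * is_large

  # decompose small-lake area into sources: primary holds 80%, the rest comes
  # from the small-lake source after river/reservoir removal
  primary <- 0.8 * area_small
  net_small <- 0.2 * area_small
  river <- 0.1 * net_small
  reservoir <- 0.05 * net_small
  small <- net_small + river + reservoir

  list(areas = lake_area_grid(grid, area_small, area_large),
       large_lake_mask = is_large | area_small >= 50,
       sources = list(primary = primary, small = small, river = river,
                      reservoir = reservoir))
}

#' Generate the synthetic flux-measurement compilation
#'
#' Sites are placed in lake cells; each site contributes one or more
#' aggregated flux values. A record's expected 24-h flux is
#' `alpha[type, pathway] * exp(beta[pathway] * T)` at the site's
#' climatological air temperature for the sampled month, multiplied by
#' lognormal noise; daytime-only records are inflated by
#' `diel_day_multiplier`. Planted fractions of indirect-method, beaver-pond,
#' metadata-missing, unlabeled and component-carrying records exercise
#' the compilation filters, the grid-based type assignment and the
#' disaggregation step.
#'
#' @param cfg A `generator_config`.
#' @param layers Output of [generate_geophysical_layers()].
#' @param areas Optional output of [generate_lake_areas()]; when supplied,
#'   sites are placed only in lake-bearing cells.
#' @return Tibble of flux records (one row per aggregated value) with the
#'   compilation schema plus ground-truth columns `true_lake_type` and
#'   `true_flux_24h`.
#' @export
generate_flux_records <- function(cfg, layers, areas = NULL) {
  set.seed(substream_seed(cfg, "records"))
  grid <- layers$grid
  nl <- length(grid$lat); nn <- length(grid$lon)
  lakey <- if (is.null(areas)) matrix(TRUE, nl, nn) else
    (areas$areas$area_small + areas$areas$area_large) > 0
  ok_cells <- which(lakey)
  if (length(ok_cells) == 0) stop("no lake cells to place sites in")

  # sites are stratified by lake type with the composition of real flux
  # compilations, which oversample well-studied temperate systems and still
  # cover every high-latitude type
  comp_w <- c(thermokarst = 87, glacial = 96, peat_pond = 43, organic = 0,
              boreal = 134, temperate = 401, tropical = 120)
  site_type <- sample(names(comp_w), cfg$n_sites, replace = TRUE,
                      prob = comp_w / sum(comp_w))
  cell_type <- layers$true_type[ok_cells]
  site_cell <- vapply(site_type, function(ty) {
    pool <- ok_cells[cell_type == ty]
    if (length(pool) == 0) pool <- ok_cells
    pool[sample.int(length(pool), 1)]
  }, numeric(1))
  extra <- stats::rpois(cfg$n_sites, 881 / 575 - 1)
  n_rec_site <- 1L + extra
  rec_site <- rep(seq_len(cfg$n_sites), n_rec_site)
  n <- length(rec_site)

  cell <- site_cell[rec_site]
  row <- ((cell - 1) %% nl) + 1
  col <- ((cell - 1) %/% nl) + 1
  lat <- grid$lat[row] + stats::runif(n, -grid$res / 2, grid$res / 2) * 0.9
  lon <- grid$lon[col] + stats::runif(n, -grid$res / 2, grid$res / 2) * 0.9
  type <- layers$true_type[cbind(row, col)]

  # month sampled with warm-season bias, as field campaigns are
  month <- integer(n)
  for (i in seq_len(n)) {
    temps <- layers$monthly_temp[row[i], col[i], ]
    w <- exp(temps / 5)
    month[i] <- sample.int(12, 1, prob = w / sum(w))
  }
  t_month <- layers$monthly_temp[cbind(row, col, month)]

  pathway <- ifelse(stats::runif(n) < 207 / 881, "ebullition", "diffusion")
  daytime <- stats::runif(n) < cfg$frac_daytime
  alpha <- mapply(function(p, ty) cfg$alpha[[p]][[ty]], pathway, type)
  beta <- cfg$beta[pathway]
  noise <- if (cfg$sigma_log > 0) {
    exp(stats::rnorm(n, -cfg$sigma_log^2 / 2, cfg$sigma_log))
  } else rep(1, n)
  flux_24h <- unname(alpha * exp(beta * t_month) * noise)
  flux <- flux_24h * ifelse(daytime, cfg$diel_day_multiplier, 1)

  method <- ifelse(stats::runif(n) < cfg$frac_indirect, "indirect", "direct")
  system_class <- ifelse(stats::runif(n) < cfg$frac_beaver, "beaver_pond", "lake")
  miss <- stats::runif(n) < cfg$frac_missing
  miss_field <- sample(c("month", "window", "pathway"), n, replace = TRUE)

  sampling_window <- ifelse(daytime, "daytime", "24h")
  month_out <- month
  month_out[miss & miss_field == "month"] <- NA_integer_
  sampling_window[miss & miss_field == "window"] <- NA_character_
  pathway_out <- pathway
  pathway_out[miss & miss_field == "pathway"] <- NA_character_

  label <- type
  label[stats::runif(n) < cfg$frac_unlabeled] <- NA_character_

  components <- rep(NA_character_, n)
  has_comp <- stats::runif(n) < cfg$frac_components
  k <- sample(2:4, n, replace = TRUE)
  for (i in which(has_comp)) {
    w <- stats::rgamma(k[i], 2)
    comp <- flux[i] * w / sum(w) * k[i]
    components[i] <- paste(signif(comp, 8), collapse = ";")
  }

  tibble::tibble(
    record_id = sprintf("R%04d", seq_len(n)),
    site_id = sprintf("S%04d", rec_site),
    lat = lat, lon = lon,
    lake_type = label,
    lake_area_class = "<5000",
    pathway = pathway_out,
    flux = flux,
    month = month_out,
    sampling_window = sampling_window,
    air_temp_obs = t_month,
    method = method,
    system_class = system_class,
    n_underlying = ifelse(has_comp, k, 1L),
    components = components,
    true_lake_type = type,
    true_flux_24h = flux_24h
  )
}

#' Generate a complete synthetic world
#'
#' Bundles layers, phenology, lake areas and the flux compilation generated
#' from one seed, together with the ground truth needed for recovery tests.
#'
#' @param cfg A `generator_config`.
#' @return A `synthetic_world` list: `cfg`, `grid`, `layers`, `phenology`,
#'   `areas`, `large_lake_mask`, `area_sources`, `records`.
#' @export
generate_world <- function(cfg = generator_config()) {
  layers <- generate_geophysical_layers(cfg)
  phen <- generate_phenology(cfg, layers$grid)
  ar <- generate_lake_areas(cfg, layers$grid)
  records <- generate_flux_records(cfg, layers, ar)
  structure(list(cfg = cfg, grid = layers$grid, layers = layers,
                 phenology = phen, areas = ar$areas,
                 large_lake_mask = ar$large_lake_mask,
                 area_sources = ar$sources, records = records),
            class = "synthetic_world")
}

#' Write a synthetic world's compilation to CSV
#'
#' @param world A `synthetic_world`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compilation_csv <- function(world, path) {
  readr::write_csv(world$records, path)
  invisible(path)
}
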