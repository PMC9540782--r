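test_that("noise-free constant-model records all equal alpha", {
  cfg <- flat_config(alpha_d = 50, alpha_e = 50,
                     diel_day_multiplier = 1, frac_daytime = 0)
  w <- generate_world(cfg)
  expect_true(all(abs(w$records$flux - 50) < 1e-9))
})

test_that("temperature sensitivity enters the generator as exp(beta T)", {
  cfg <- generator_config(sigma_log = 0, beta = c(diffusion = 0.1, ebullition = 0.1))
  # closed form: flux ratio between 10 C and 0 C is e
  a <- cfg$alpha$diffusion[["temperate"]] * exp(0.1 * 10)
  b <- cfg$alpha$diffusion[["temperate"]] * exp(0.1 * 0)
  expect_equal(a / b, exp(1), tolerance = 1e-12)
  # and generated 24-h fluxes follow it record by record
  w <- generate_world(generator_config(seed = 2, lon_range = c(0, 1),
                                       sigma_log = 0, frac_components = 0,
                                       frac_missing = 0))
  expctd <- mapply(function(p, ty, t)
    w$cfg$alpha[[p]][[ty]] * exp(w$cfg$beta[[p]] * t),
    w$records$pathway, w$records$true_lake_type, w$records$air_temp_obs)
  expect_equal(w$records$true_flux_24h, unname(expctd), tolerance = 1e-12)
})

test_that("log-flux sample mean recovers log alpha + beta T within 3 SE", {
  cfg <- generator_config(seed = 9, n_sites = 2000, sigma_log = 0.3,
                          lon_range = c(0, 1), frac_components = 0,
                          frac_missing = 0)
  w <- generate_world(cfg)
  r <- w$records
  mu <- log(mapply(function(p, ty) cfg$alpha[[p]][[ty]], r$pathway,
                   r$true_lake_type)) +
    unname(cfg$beta[r$pathway]) * r$air_temp_obs - cfg$sigma_log^2 / 2
  z <- log(r$true_flux_24h) - mu
  se <- cfg$sigma_log / sqrt(nrow(r))
  expect_lt(abs(mean(z)), 3 * se)
})

test_that("rejected configs: non-positive alpha or sigma, bad fractions", {
  expect_error(generator_config(alpha = list(diffusion = -1, ebullition = 2)),
               "alpha")
  expect_error(generator_config(sigma_log = -0.1), "sigma")
  expect_error(generator_config(diel_day_multiplier = 0.5), "diel")
  expect_error(generator_config(frac_daytime = 1.2), "fraction")
})

test_that("geophysical layers have the intended latitudinal structure", {
  cfg <- tiny_config()
  lay <- generate_geophysical_layers(cfg)
  eq_row <- which.min(abs(lay$grid$lat))
  expect_gt(lay$annual_soil_temp[eq_row, 1], 20)
  # zero seasonal amplitude makes the monthly cycle flat
  lay0 <- generate_geophysical_layers(tiny_config(seasonal_amp_per_deg = 0))
  expect_equal(apply(lay0$monthly_temp, c(1, 2), function(x) diff(range(x))),
               matrix(0, length(lay0$grid$lat), length(lay0$grid$lon)))
  # soil annual mean equals annual-mean air temperature by construction
  expect_equal(lay$annual_soil_temp, apply(lay$monthly_temp, c(1, 2), mean),
               tolerance = 1e-9)
})

test_that("classification round-trips the generator's intended type map", {
  for (seed in c(1, 7, 23)) {
    lay <- generate_geophysical_layers(tiny_config(seed = seed))
    got <- classify_ecoclimatic(lay)
    expect_equal(as.vector(got), as.vector(lay$true_type))
    expect_setequal(unique(as.vector(lay$true_type)), lake_types())
  }
})

test_that("phenology: no-freeze cells, zero jitter, climatology recovery", {
  cfg0 <- tiny_config(phenology_jitter_sd = 0)
  ph0 <- generate_phenology(cfg0)
  grid <- grid_spec(cfg0$lat_range, cfg0$lon_range, cfg0$res)
  s0 <- climatological_dates(ph0$landscape$thaw, ph0$landscape$freeze, grid)
  # equatorward of the freeze line: no freeze and a full-year season
  eq <- abs(lat_field(grid)) < cfg0$lat_no_freeze
  expect_true(all(s0$no_freeze[eq]))
  expect_true(all(s0$season_length[eq] == 365))
  # with zero jitter every year equals the climatology
  expect_equal(ph0$landscape$thaw[, , 1], ph0$landscape$thaw[, , 5])
  nf <- !s0$no_freeze
  expect_equal(s0$thaw[nf], wrap_doy(ph0$landscape$thaw[, , 1][nf]))

  # 13 jittered years: climatological thaw within 3 SE of the generator mean
  cfg <- tiny_config(seed = 4, phenology_jitter_sd = 5, n_years = 13)
  ph <- generate_phenology(cfg)
  s <- climatological_dates(ph$landscape$thaw, ph$landscape$freeze, grid)
  base <- generate_phenology(tiny_config(seed = 4, phenology_jitter_sd = 0))
  b1 <- base$landscape$thaw[, , 1]
  sel <- !s$no_freeze & abs(lat_field(grid)) < 80  # away from wrap edge cases
  se_cell <- 5 / sqrt(13)
  dev <- abs(s$thaw[sel] - b1[sel])
  dev <- pmin(dev, 365 - dev)
  # per-cell deviations behave like means of 13 jittered years (+/- rounding)
  expect_lt(mean(dev), 3 * se_cell)
  expect_lt(max(dev), 6 * se_cell + 0.5)
})

test_that("every generated world represents all seven ecoclimatic types", {
  for (seed in c(3, 14)) {
    w <- generate_world(tiny_config(seed = seed))
    tvec <- as.vector(w$layers$true_type)
    lake <- as.vector(w$areas$area_small + w$areas$area_large) > 0
    expect_setequal(unique(tvec[lake]), lake_types())
    # organic lakes carry no measurements of their own (rates come from peat
    # ponds); every other type is sampled
    expect_setequal(unique(w$records$true_lake_type),
                    setdiff(lake_types(), "organic"))
  }
})

test_that("area source decomposition merges back to the small-class area", {
  w <- generate_world(tiny_config(seed = 5))
  merged <- merge_area_sources(w$area_sources$primary, w$area_sources$small,
                               w$area_sources$river, w$area_sources$reservoir)
  expect_equal(merged, w$areas$area_small, tolerance = 1e-12)
})
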