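make_records <- function(n, b, sigma = 0, a = log(20), temps = NULL,
                         pathway = "diffusion", seed = 1) {
  set.seed(seed)
  t <- if (is.null(temps)) runif(n, -5, 25) else temps
  tibble::tibble(record_id = sprintf("R%d", seq_len(n)),
                 lake_type = "temperate", pathway = pathway,
                 flux = exp(a + b * t + rnorm(n, 0, sigma)),
                 air_temp_obs = t, month = 7L)
}

test_that("temperature-flux fit recovers known slopes and refuses bad input", {
  m <- fit_temp_flux(make_records(50, b = 0.11), "diffusion")
  expect_equal(m$b, 0.11, tolerance = 1e-10)
  expect_equal(m$a, log(20), tolerance = 1e-10)

  # noisy slope recovery within the 95% CI
  m2 <- fit_temp_flux(make_records(500, b = 0.11, sigma = 0.3, seed = 5),
                      "diffusion")
  expect_lt(abs(m2$b - 0.11), 1.96 * m2$b_se)

  expect_error(fit_temp_flux(make_records(5, b = 0.1), "diffusion"), "refused")
  expect_error(fit_temp_flux(make_records(50, b = 0.1, temps = rep(10, 50)),
                             "diffusion"), "singular")
  # non-positive fluxes are excluded and counted, not fatal
  r <- make_records(30, b = 0)
  r$flux[1:3] <- -1
  m3 <- fit_temp_flux(r, "diffusion")
  expect_equal(m3$n_excluded, 3)
  expect_equal(m3$n, 27)
})

fake_layers <- function(tempcurve) {
  grid <- grid_spec(c(50, 50.25), c(0, 0.25))
  monthly <- array(rep(tempcurve, each = 1), c(1, 1, 12))
  structure(list(grid = grid, monthly_temp = monthly), class = "geo_layers")
}

test_that("monthly projection follows exp(b dT) anchored at the sampled month", {
  tempcurve <- c(-5, -3, 0, 4, 9, 14, 17, 16, 12, 7, 2, -4)
  layers <- fake_layers(tempcurve)
  rec <- tibble::tibble(record_id = "R1", lake_type = "temperate",
                        pathway = "diffusion", flux = 40, month = 7L,
                        lat = 50.1, lon = 0.1, air_temp_obs = 17)
  models <- list(diffusion = list(b = 0.1))

  out <- project_to_months(rec, models, layers)
  expect_equal(nrow(out), 12)
  # anchor consistency: the measurement month returns the corrected flux
  expect_equal(out$flux_monthly[out$month == 7], 40)
  # closed form at 10 degrees below the anchor
  expect_equal(out$flux_monthly[out$month == 7] /
                 out$flux_monthly[out$month == 7 - 2][1],
               exp(0.1 * (17 - tempcurve[5])), tolerance = 1e-12)

  # b = 0: all months equal the corrected flux
  out0 <- project_to_months(rec, list(diffusion = list(b = 0)), layers)
  expect_equal(out0$flux_monthly, rep(40, 12))

  # monotonicity: with b > 0, projected flux strictly follows month warmth
  expect_equal(order(out$flux_monthly), order(tempcurve))
  expect_true(all(diff(out$flux_monthly[order(tempcurve)]) > 0))
})

test_that("records outside the grid are skipped with their ids logged", {
  layers <- fake_layers(rep(10, 12))
  rec <- tibble::tibble(record_id = c("in", "out"), lake_type = "temperate",
                        pathway = "diffusion", flux = 10, month = 1L,
                        lat = c(50.1, 10), lon = c(0.1, 50),
                        air_temp_obs = 10)
  out <- project_to_months(rec, list(diffusion = list(b = 0.1)), layers)
  expect_equal(unique(out$record_id), "in")
  expect_equal(attr(out, "skipped"), "out")
})

test_that("monthly aggregation averages records and aliases organic", {
  proj <- tibble::tibble(
    record_id = rep(c("a", "b"), each = 12),
    lake_type = "peat_pond", pathway = "ebullition",
    month = rep(1:12, 2),
    flux = 20, flux_monthly = rep(c(10, 30), each = 12)
  )
  tab <- aggregate_monthly(proj, required_types = c("peat_pond", "organic"))
  expect_equal(tab$flux[tab$lake_type == "peat_pond"], rep(20, 12))
  org <- tab[tab$lake_type == "organic", ]
  expect_equal(org$flux, rep(20, 12))
  expect_true(all(org$aliased))
  # cv recorded for the uncertainty budget: sd(10,30)/20
  expect_equal(unique(tab$cv), sd(c(10, 30)) / 20)
  # a required type with no data at all is a hard error naming the gap
  expect_error(aggregate_monthly(proj, required_types = c("peat_pond", "tropical")),
               "tropical")
})

test_that("periodic spline hits anchors, preserves constants, integrates well", {
  const <- tibble::tibble(lake_type = "boreal", pathway = "diffusion",
                          month = 1:12, flux = 7, n = 1L, cv = 0)
  cc <- spline_to_daily(const)
  expect_equal(daily_curve(cc, "boreal", "diffusion"), rep(7, 365),
               tolerance = 1e-9)

  mids <- month_midpoints()
  vals <- 50 + 30 * sin(2 * pi * (mids - 15) / 365)
  tab <- tibble::tibble(lake_type = "boreal", pathway = "diffusion",
                        month = 1:12, flux = vals, n = 1L, cv = 0)
  cv <- spline_to_daily(tab)
  y <- daily_curve(cv, "boreal", "diffusion")
  # interpolation condition at integer anchor days
  expect_equal(y[16], vals[1], tolerance = 1e-9)
  expect_equal(y[197], vals[7], tolerance = 1e-9)
  # quadrature: annual mean of daily curve close to day-weighted monthly mean
  wmean <- sum(vals * c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)) / 365
  expect_equal(mean(y), wmean, tolerance = 0.02)

  # ebullition curves are clipped at zero
  spiky <- tibble::tibble(lake_type = "boreal", pathway = "ebullition",
                          month = 1:12,
                          flux = c(0, 0, 0, 0, 100, 0, 0, 0, 0, 0, 0, 0),
                          n = 1L, cv = 0)
  ye <- daily_curve(spline_to_daily(spiky), "boreal", "ebullition")
  expect_true(all(ye >= 0))
})
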