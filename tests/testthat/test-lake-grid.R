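layers_of <- function(soc, pf, ice, temp) {
  n <- length(soc)
  structure(list(soc = matrix(soc, n, 1), permafrost = matrix(pf, n, 1),
                 ground_ice = matrix(ice, n, 1),
                 annual_soil_temp = matrix(temp, n, 1)),
            class = "geo_layers")
}

test_that("classification criteria match the type definitions", {
  cases <- list(
    # permafrost/ground-ice branches
    list(soc = 0, pf = "C", ice = 15, temp = -10, want = "thermokarst"),
    list(soc = 0, pf = "D", ice = 15, temp = -10, want = "thermokarst"),
    list(soc = 0, pf = "C", ice = 5, temp = -10, want = "glacial"),
    list(soc = 12, pf = "S", ice = 15, temp = -2, want = "peat_pond"),
    list(soc = 12, pf = "S", ice = 5, temp = -2, want = "organic"),
    list(soc = 12, pf = "I", ice = 5, temp = -2, want = "organic"),
    # temperature branches (no permafrost, SOC below threshold)
    list(soc = 2, pf = "None", ice = 0, temp = 25, want = "tropical"),
    list(soc = 2, pf = "None", ice = 0, temp = 20, want = "tropical"),
    list(soc = 2, pf = "None", ice = 0, temp = 19.9, want = "temperate"),
    list(soc = 2, pf = "None", ice = 0, temp = 8, want = "temperate"),
    list(soc = 2, pf = "None", ice = 0, temp = 3, want = "boreal")
  )
  for (cs in cases) {
    got <- classify_ecoclimatic(layers_of(cs$soc, cs$pf, cs$ice, cs$temp))
    expect_equal(as.vector(got), cs$want, info = paste(unlist(cs), collapse = "/"))
  }
})

test_that("fallback cells resolve by temperature and are counted", {
  # sporadic permafrost with SOC below threshold matches no explicit branch
  lay <- layers_of(c(5, 5), c("S", "I"), c(5, 20), c(3, 9))
  got <- classify_ecoclimatic(lay)
  expect_equal(as.vector(got), c("boreal", "temperate"))
  expect_equal(attr(got, "n_fallback"), 2)
  # permafrost-free with high SOC also falls through
  lay2 <- layers_of(15, "None", 0, 25)
  got2 <- classify_ecoclimatic(lay2)
  expect_equal(as.vector(got2), "tropical")
  expect_equal(attr(got2, "n_fallback"), 1)
})

test_that("classification is total, deterministic and order-invariant", {
  lay <- generate_geophysical_layers(tiny_config(seed = 19))
  t1 <- classify_ecoclimatic(lay)
  expect_false(anyNA(t1))
  expect_identical(t1, classify_ecoclimatic(lay))
  # permuting rows permutes the map identically
  p <- sample(nrow(lay$soc))
  layp <- lay
  for (f in c("soc", "permafrost", "ground_ice", "annual_soil_temp")) {
    layp[[f]] <- lay[[f]][p, , drop = FALSE]
  }
  expect_equal(as.vector(classify_ecoclimatic(layp)),
               as.vector(t1[p, , drop = FALSE]))
})

test_that("threshold sweep moves only the temperate/tropical boundary", {
  lay <- generate_geophysical_layers(tiny_config(seed = 2))
  base <- classify_ecoclimatic(lay)
  warm <- classify_ecoclimatic(lay, classification_thresholds(t_trop = 17.5))
  changed <- base != warm
  expect_true(all(base[changed] == "temperate" & warm[changed] == "tropical"))
  expect_gt(sum(changed), 0)
})

test_that("area-source merging clamps and reproduces the global-sum identity", {
  p <- matrix(c(1, 2), 1, 2)
  s <- matrix(c(0.5, 1.0), 1, 2)
  expect_equal(merge_area_sources(p, s), p + s)
  # masks larger than the small-lake source clamp its contribution at zero
  expect_equal(merge_area_sources(p, matrix(1, 1, 2), matrix(0.6, 1, 2),
                                  matrix(0.6, 1, 2)), p)
  expect_error(merge_area_sources(p, matrix(1, 2, 2)), "mismatch")

  # synthetic primary/small sources scaled to the global inventory:
  # 2,640 + 166 (x10^3 km^2) merge to 2,806 x10^3 km^2
  grid <- grid_spec(c(0, 10), c(0, 10))
  nc <- prod(dim(grid$cell_area))
  primary <- matrix(2640e3 / nc, nrow(grid$cell_area), ncol(grid$cell_area))
  small <- matrix(166e3 / nc, nrow(grid$cell_area), ncol(grid$cell_area))
  merged <- merge_area_sources(primary, small)
  expect_equal(sum(merged) / 1e3, 2806, tolerance = 1e-9)
})

test_that("lake-area grid validates and tabulates by type and size class", {
  grid <- grid_spec(c(0, 0.5), c(0, 0.5))
  a <- matrix(1, 2, 2)
  expect_error(lake_area_grid(grid, -a), "non-negative")
  expect_error(lake_area_grid(grid, a * 1e6), "exceeds")
  areas <- lake_area_grid(grid, a, a * 2)
  tm <- matrix(c("tropical", "tropical", "temperate", "boreal"), 2, 2)
  tab <- type_area_table(areas, tm)
  expect_equal(tab$area_small_km2[tab$lake_type == "tropical"], 2)
  expect_equal(tab$area_large_km2[tab$lake_type == "tropical"], 4)
  expect_equal(sum(tab$area_small_km2), sum(a))

  # synthetic world: type areas match generator ground truth exactly
  w <- generate_world(tiny_config(seed = 6))
  tm2 <- classify_ecoclimatic(w$layers)
  t1 <- type_area_table(w$areas, tm2)
  t2 <- type_area_table(w$areas, w$layers$true_type)
  expect_equal(t1, t2)
})

test_that("cell areas follow the cosine-latitude profile and sum to the sphere", {
  expect_gt(cell_area_km2(0.125), cell_area_km2(60.125))
  g <- grid_spec(res = 2)  # coarse grid for a fast whole-sphere sum
  expect_equal(sum(g$cell_area), 4 * pi * 6371^2, tolerance = 1e-9)
})
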