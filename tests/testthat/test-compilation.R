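write_rec_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}

base_record <- function(...) {
  rec <- tibble::tibble(record_id = "R1", site_id = "S1", lat = 60.1,
                        lon = 0.1, pathway = "diffusion", flux = 10,
                        month = 6L, sampling_window = "24h",
                        method = "direct", system_class = "lake",
                        lake_type = NA_character_)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

test_that("reading: header-only, named months, count preservation", {
  empty <- base_record()[0, ]
  expect_equal(nrow(read_compilation(write_rec_csv(empty))), 0)

  df <- base_record()
  df$month <- "July"
  got <- read_compilation(write_rec_csv(df))
  expect_equal(got$month, 7L)
  expect_equal(parse_month(c("3", "Jul", "december", "smarch", "13")),
               c(3L, 7L, 12L, NA, NA))

  # a synthetic compilation the size of the real one survives the round trip
  w <- generate_world(tiny_config(seed = 8))
  n <- nrow(w$records)
  path <- write_rec_csv(w$records)
  back <- read_compilation(path)
  expect_equal(nrow(back), n)
  expect_equal(back$flux, w$records$flux, tolerance = 1e-9)

  df2 <- df[, setdiff(names(df), "pathway")]
  expect_error(read_compilation(write_rec_csv(df2)), "pathway")
  expect_error(read_compilation("/nonexistent/file.csv"), "not found")
})

test_that("filtering keeps only fully-specified direct lake records", {
  recs <- dplyr::bind_rows(
    base_record(),
    base_record(record_id = "R2", method = "indirect"),
    base_record(record_id = "R3", system_class = "beaver_pond"),
    base_record(record_id = "R4", pathway = NA),
    base_record(record_id = "R5", month = NA),
    base_record(record_id = "R6", sampling_window = NA),
    # precedence: indirect wins over every later reason
    base_record(record_id = "R7", method = "indirect", month = NA,
                sampling_window = NA)
  )
  out <- filter_records(recs)
  expect_equal(out$kept$record_id, "R1")
  expect_equal(out$rejected$reason[match(paste0("R", 2:7), out$rejected$record_id)],
               c("indirect", "beaver_pond", "missing_pathway", "missing_month",
                 "missing_window", "indirect"))
  expect_equal(nrow(out$kept) + nrow(out$rejected), nrow(recs))
})

test_that("planted defect fractions are recovered in the rejection tally", {
  cfg <- tiny_config(seed = 21, frac_indirect = 0.1, frac_beaver = 0.1,
                     frac_missing = 0.15)
  w <- generate_world(cfg)
  out <- filter_records(w$records)
  r <- w$records
  expect_equal(sum(out$rejected$reason == "indirect"),
               sum(r$method == "indirect"))
  expect_equal(sum(out$rejected$reason == "beaver_pond"),
               sum(r$system_class == "beaver_pond" & r$method != "indirect"))
  expect_equal(nrow(out$kept) + nrow(out$rejected), nrow(r))
  expect_equal(sum(out$rejected$reason == "missing_pathway"),
               sum(is.na(r$pathway) & r$method == "direct" &
                     r$system_class == "lake"))
})

test_that("disaggregation expands component lists and preserves counts", {
  recs <- dplyr::bind_rows(
    base_record(components = "5;15"),
    base_record(record_id = "R2", components = NA_character_),
    base_record(record_id = "R3", flux = 6, components = "2;4;12")
  )
  out <- disaggregate_records(recs)
  expect_equal(nrow(out), nrow(recs) + (2 - 1) + (3 - 1))
  expect_setequal(out$flux[startsWith(out$record_id, "R1")], c(5, 15))
  expect_equal(out$flux[out$record_id == "R2"], 10)
  # metadata inherited
  expect_true(all(out$month == 6))
  # component mean inconsistent with the reported average -> warning, kept
  bad <- base_record(record_id = "R9", flux = 100, components = "5;15")
  expect_warning(got <- disaggregate_records(bad), "differs")
  expect_setequal(got$flux, c(5, 15))
})

test_that("diel correction: x0.7 daytime, 24h as reported, refuse twice", {
  recs <- dplyr::bind_rows(
    base_record(sampling_window = "daytime", flux = 100),
    base_record(record_id = "R2", sampling_window = "24h", flux = 100)
  )
  out <- apply_diel_correction(recs)
  expect_equal(out$flux, c(70, 100))
  expect_error(apply_diel_correction(out), "twice")

  miss <- base_record(sampling_window = NA)
  expect_error(apply_diel_correction(miss), "missing")

  # linearity on a mixed synthetic set
  w <- generate_world(tiny_config(seed = 13))
  kept <- filter_records(w$records)$kept
  corr <- apply_diel_correction(kept)
  day <- kept$sampling_window == "daytime"
  expect_equal(sum(corr$flux), 0.7 * sum(kept$flux[day]) + sum(kept$flux[!day]))
})

test_that("diel correction recovers the 24-h mean of diel-structured fluxes", {
  # daytime fluxes are 1/0.7 of the 24-h mean; correcting must undo it exactly
  w <- generate_world(tiny_config(seed = 17, sigma_log = 0.3))
  kept <- filter_records(w$records)$kept
  corr <- apply_diel_correction(kept)
  expect_equal(corr$flux, kept$true_flux_24h, tolerance = 1e-9)
})

test_that("type assignment: explicit label wins, else classified cell", {
  w <- generate_world(tiny_config(seed = 31))
  tm <- classify_ecoclimatic(w$layers)
  recs <- dplyr::bind_rows(
    base_record(lake_type = "thermokarst", lat = 0.125),  # label beats cell
    base_record(record_id = "R2", lat = 0.125, lon = 0.125),  # tropical cell
    base_record(record_id = "R3", lat = 40, lon = 90)  # off-grid, no label
  )
  out <- assign_lake_type(recs, tm, w$grid)
  expect_equal(out$assigned$lake_type[out$assigned$record_id == "R1"],
               "thermokarst")
  expect_equal(out$assigned$lake_type[out$assigned$record_id == "R2"],
               "tropical")
  expect_equal(out$rejected$reason, "out_of_domain")

  # synthetic world: grid-assigned labels match the generator's ground truth
  r <- w$records
  r$lake_type <- NA_character_
  got <- assign_lake_type(r, tm, w$grid)
  expect_equal(nrow(got$rejected), 0)
  expect_equal(got$assigned$lake_type, r$true_lake_type)
})
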