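two_cycle_csv <- function(path, dup = FALSE, bad_rate = FALSE,
                          drop_col = NULL) {
  sys <- dplyr::bind_rows(
    make_cycle(system_code = "VNID", cycle_index = 1L, season = "wet",
               climate_zone = "tropical"),
    make_cycle(system_code = "VNID", cycle_index = if (dup) 1L else 2L,
               season = "dry", climate_zone = "tropical"))
  if (bad_rate) sys$n_fertilizer <- c("120", "abc")
  if (!is.null(drop_col)) sys[[drop_col]] <- NULL
  # write manually to keep malformed content intact
  out <- sys
  for (lc in c("pesticide_applications", "field_operations",
               "organic_amendments")) out[[lc]] <- ""
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  path
}

test_that("cycle rows group into systems and enforce integrity", {
  f <- withr::local_tempfile(fileext = ".csv")
  two_cycle_csv(f)
  sys <- read_systems(f)
  expect_s3_class(sys, "rb_systems")
  expect_equal(nrow(sys), 2)
  expect_equal(unique(sys$system_code), "VNID")
  expect_equal(sys$cycle_index, c(1, 2))

  g <- withr::local_tempfile(fileext = ".csv")
  two_cycle_csv(g, dup = TRUE)
  expect_error(read_systems(g), class = "rb_integrity_error")
})

test_that("schema and parse failures are typed and informative", {
  f <- withr::local_tempfile(fileext = ".csv")
  two_cycle_csv(f, drop_col = "yield_potential")
  expect_error(read_systems(f), regexp = "yield_potential",
               class = "rb_schema_error")

  g <- withr::local_tempfile(fileext = ".csv")
  two_cycle_csv(g, bad_rate = TRUE)
  expect_error(read_systems(g), regexp = "row 2", class = "rb_parse_error")

  expect_error(read_systems("no/such/file.csv"), class = "rb_schema_error")
})

test_that("a generated cohort survives CSV and JSON round trips exactly", {
  sys <- generate_cohort(global_cohort_spec(seed = 3))
  ref <- as.data.frame(sys[order(sys$system_code, sys$cycle_index), ])
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_systems(sys, f)
    back <- read_systems(f)
    expect_equal(as.data.frame(back[, names(ref)]), ref,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("malformed inputs never produce silent NaN", {
  sys <- make_cycle()
  bad <- sys; bad$harvested_area <- 0
  expect_error(validate_systems(bad), class = "rb_validation_error")
  bad <- sys; bad$cultivation_days <- 30
  expect_error(validate_systems(bad), class = "rb_validation_error")
  bad <- sys; bad$n_fertilizer <- -5
  expect_error(validate_systems(bad), class = "rb_validation_error")
  bad <- sys; bad$straw_management <- "composted"
  expect_error(validate_systems(bad), class = "rb_validation_error")
  four <- dplyr::bind_rows(lapply(1:4, function(i) {
    x <- make_cycle(cycle_index = as.integer(i)); x
  }))
  expect_error(validate_systems(four), class = "rb_integrity_error")
})

test_that("survey noise is flagged, not silently accepted", {
  noisy <- make_cycle(yield_actual = 11, yield_potential = 10)
  expect_warning(validate_systems(noisy), class = "rb_yield_warning")

  wet <- make_cycle(water_regime = "rainfed", irrigation = 500,
                    water_regime_class = "rainfed_regular")
  expect_warning(out <- validate_systems(wet),
                 class = "rb_irrigation_warning")
  expect_equal(out$irrigation, 0)
})

test_that("replicate_cycle copies the single reported cycle", {
  f <- withr::local_tempfile(fileext = ".csv")
  one <- make_cycle(system_code = "NGID")
  one$replicate_cycle <- TRUE
  write_systems(one, f)
  sys <- read_systems(f)
  expect_equal(nrow(sys), 2)
  expect_equal(sys$cycle_index, c(1, 2))
  expect_equal(sys$yield_actual[1], sys$yield_actual[2])
  # writing the replicated pair collapses it back to one flagged row
  g <- withr::local_tempfile(fileext = ".csv")
  write_systems(sys, g)
  raw <- utils::read.csv(g)
  expect_equal(nrow(raw), 1)
})

test_that("a mapping file renames external headers to the schema", {
  f <- withr::local_tempfile(fileext = ".csv")
  sys <- make_cycle()
  out <- sys
  for (lc in c("pesticide_applications", "field_operations",
               "organic_amendments")) out[[lc]] <- ""
  names(out)[names(out) == "yield_actual"] <- "grain_yield_mg_ha"
  names(out)[names(out) == "system_code"] <- "code"
  utils::write.csv(as.data.frame(out), f, row.names = FALSE)
  expect_error(read_systems(f), class = "rb_schema_error")
  m <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(grain_yield_mg_ha = "yield_actual",
                        code = "system_code"), m)
  sys2 <- read_systems(f, mapping = m)
  expect_equal(sys2$yield_actual, sys$yield_actual)
})

test_that("metric tables round-trip through tidy CSV", {
  sys <- generate_cohort(cohort_spec(n_systems = 4, seed = 2))
  met <- system_metrics(sys, default_config())
  f <- withr::local_tempfile(fileext = ".csv")
  write_metrics(met, f)
  back <- read_metrics(f)
  expect_equal(back$value, met$value, tolerance = 1e-9)
  expect_equal(back$metric, met$metric)
  # one row per (system, basis, metric)
  expect_equal(nrow(met), 4 * 2 * (12 + 7))

  empty <- met[0, ]
  g <- withr::local_tempfile(fileext = ".csv")
  write_metrics(empty, g)
  expect_equal(nrow(utils::read.csv(g)), 0)
})
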