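test_that("starting data maps rows to observed panel entries and skips blanks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "iso_code,country,year,gdlcode,level,region,lifexp,msch",
    "AAA,Aland,2000,AAAr01,subnational,North,70.1,",
    "AAA,Aland,2001,AAAr01,subnational,North,70.6,"
  ), path)
  got <- read_starting_data(path)
  expect_equal(nrow(got$panel), 2)
  expect_true(all(got$panel$observed))
  expect_equal(got$panel$indicator, c("lifexp", "lifexp"))
  expect_equal(got$panel$value, c(70.1, 70.6))
})

test_that("schema and integrity violations are rejected by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "iso_code,country,year,level,lifexp",
    "AAA,Aland,2000,subnational,70.1"
  ), path)
  expect_error(read_starting_data(path), "gdlcode",
               class = "shdikit_schema_error")

  writeLines(c(
    "iso_code,year,gdlcode,lifexp",
    "AAA,2000,AAAr01,70.1",
    "AAA,2000,AAAr01,70.2"
  ), path)
  expect_error(read_starting_data(path), "duplicate",
               class = "shdikit_integrity_error")
})

test_that("starting data round-trips exactly through write and read", {
  fx <- two_region_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_starting_data(fx$panel, fx$regions, path)
  back <- read_starting_data(path)
  orig <- dplyr::arrange(fx$panel, gdlcode, indicator, year)
  expect_equal(back$panel$value, orig$value)
  expect_equal(back$panel$gdlcode, orig$gdlcode)
  expect_equal(back$panel$year, orig$year)
  expect_equal(back$panel$indicator, orig$indicator)
})

test_that("database writer emits the published column order and a national row", {
  fx <- two_region_fixture(years = 2000)
  idx <- compute_indices(fx$panel)
  path <- withr::local_tempfile(fileext = ".csv")
  write_database(fx$panel, idx, fx$regions, path)
  out <- read_database(path)
  expect_equal(names(out), c(
    "iso_code", "country", "year", "gdlcode", "level", "region",
    "shdi", "healthindex", "incindex", "edindex",
    "lifexp", "lgnic", "esch", "msch"
  ))
  expect_equal(nrow(out), 3) # 2 subnational + 1 national
  expect_equal(sum(out$level == "national"), 1)
})

test_that("database rows count (regions + 1 national) x years per country", {
  w <- tiny_world(n_countries = 2, regions = c(3, 3), seed = 5,
                  years = 2000:2004)
  idx <- compute_indices(w$panel)
  path <- withr::local_tempfile(fileext = ".csv")
  write_database(w$panel, idx, w$regions, path)
  out <- read_database(path)
  expect_equal(nrow(out), 2 * (3 + 1) * 5)
})

test_that("database values round-trip to six decimals and gaps are refused", {
  fx <- two_region_fixture()
  idx <- compute_indices(fx$panel)
  path <- withr::local_tempfile(fileext = ".csv")
  write_database(fx$panel, idx, fx$regions, path)
  out <- read_database(path)
  sub <- out[out$level == "subnational", ]
  key <- paste(sub$gdlcode, sub$year)
  for (ind in c("lifexp", "lgnic", "esch", "msch")) {
    orig <- fx$panel[fx$panel$indicator == ind, ]
    expect_equal(
      sub[[ind]][match(paste(orig$gdlcode, orig$year), key)],
      orig$value,
      tolerance = 1e-6
    )
  }
  expect_error(
    write_database(fx$panel[-1, ], idx, fx$regions, path),
    class = "shdikit_completeness_error"
  )
})

test_that("quality flags serialize per the published coding and round-trip", {
  fx <- two_region_fixture(years = 2000:2001)
  gdl <- c("AAAr01", "AAAr02")
  flags <- tidyr::expand_grid(
    gdlcode = gdl, year = 2000:2001,
    indicator = c("lifexp", "lgnic", "esch", "msch")
  ) |>
    dplyr::mutate(polated = 0L, polyears = 0L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_quality(flags, fx$regions, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_true(all(out$lgnic_polated == 0) && all(out$msch_polyears == 0))

  flags$polated[flags$indicator == "lifexp" & flags$year == 2001] <- 1L
  flags$polyears[flags$indicator == "lifexp" & flags$year == 2001] <- 3L
  write_quality(flags, fx$regions, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(out$lifexp_polated[out$year == 2001], c(1, 1))
  expect_equal(out$lifexp_polyears[out$year == 2001], c(3, 3))

  back <- read_quality(path)
  orig <- dplyr::arrange(flags, gdlcode, indicator, year)
  expect_equal(back$polated, orig$polated)
  expect_equal(back$polyears, orig$polyears)

  flags$polated[1] <- 9L
  expect_error(write_quality(flags, fx$regions, path),
               class = "shdikit_value_error")
})

test_that("region metadata invariants are enforced", {
  fx <- two_region_fixture()
  bad <- fx$regions
  bad$population[2] <- -1
  expect_error(write_regions(bad, tempfile()),
               class = "shdikit_domain_error")
  dup_nat <- dplyr::bind_rows(fx$regions, fx$regions[1, ])
  expect_error(validate_regions <- shdikit:::validate_regions(dup_nat),
               class = "shdikit_integrity_error")
})
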