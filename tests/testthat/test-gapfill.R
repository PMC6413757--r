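test_that("gap plans pick the right method and anchors per year", {
  p <- plan_gaps(c(1995, 2005), 1990:2010)
  expect_equal(p$method[p$year == 2000], "interpolate")
  expect_equal(p$anchor1[p$year == 2000], 1995)
  expect_equal(p$anchor2[p$year == 2000], 2005)
  expect_equal(p$gap_length[p$year == 2000], 5)
  # asymmetric interior gap: the larger anchor distance counts
  expect_equal(p$gap_length[p$year == 1996], 9)

  p1 <- plan_gaps(2000, 1990:2010)
  expect_equal(p1$method[p1$year == 1990], "extrapolate-future")
  expect_equal(p1$gap_length[p1$year == 1990], 10)
  expect_equal(p1$method[p1$year == 2005], "extrapolate-past")
  expect_equal(p1$anchor1[p1$year == 2005], 2000)

  p0 <- plan_gaps(integer(), 1990:1992)
  expect_true(all(p0$method == "national"))
})

test_that("interpolation blends linearly and stays within its anchors", {
  expect_equal(interpolate_region(10, 20, 2000, 2010, 2005), 15)
  expect_equal(interpolate_region(10, 20, 2000, 2010, 2002), 12)
  expect_equal(interpolate_region(7, 7, 2000, 2010, 2004), 7)
  expect_error(interpolate_region(10, 20, 2000, 2010, 2011),
               class = "shdikit_value_error")
  # sandwich property over many random anchor pairs
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100)
    v <- interpolate_region(a, b, 1990, 2000, sample(1991:1999, 1))
    expect_gte(v, min(a, b)); expect_lte(v, max(a, b))
  }
})

test_that("extrapolation carries values; the rescale supplies the trend", {
  expect_equal(extrapolate_region(7.3), 7.3)
  fx <- two_region_fixture(years = 2000:2005)
  masked <- mask_panel(fx$panel, 2000, pattern = "trailing")
  f <- fill_panel(masked, fx$national, fx$regions)
  # regional ratios in every carried year equal those of the anchor year
  lif <- f$panel |>
    dplyr::filter(indicator == "lifexp") |>
    tidyr::pivot_wider(id_cols = year, names_from = gdlcode,
                       values_from = value)
  ratio <- lif$AAAr02 / lif$AAAr01
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-12)
  expect_anchored(f$panel, fx$national, fx$regions)
})

test_that("a fully observed panel gets only real flags and scaled values", {
  fx <- two_region_fixture()
  f <- fill_panel(fx$panel, fx$national, fx$regions)
  expect_true(all(f$flags$polated == 0))
  expect_true(all(f$flags$polyears == 0))
  direct <- anchor_to_national(fx$panel, fx$national, fx$regions)
  expect_equal(
    dplyr::arrange(f$panel, gdlcode, indicator, year)$value,
    dplyr::arrange(direct$panel, gdlcode, indicator, year)$value
  )
})

test_that("interior gaps recover linear truth after rescaling", {
  w <- generate_world(world_spec(
    n_countries = 3, regions_per_country = c(3, 6), seed = 19,
    trend = "linear",
    noise_sd = c(lifexp = 0, lgnic = 0, esch = 0, msch = 0)
  ))
  masked <- mask_panel(w$panel, seq(1990, 2017, by = 5),
                       pattern = "interior")
  f <- fill_panel(masked, w$national, w$regions)
  truth <- w$panel |> dplyr::rename(truth = value)
  cmp <- f$panel |>
    dplyr::inner_join(
      truth |> dplyr::select(gdlcode, year, indicator, truth),
      by = c("gdlcode", "year", "indicator")
    ) |>
    dplyr::inner_join(
      f$flags |> dplyr::select(gdlcode, year, indicator, polated),
      by = c("gdlcode", "year", "indicator")
    ) |>
    dplyr::filter(polated %in% c(0L, 1L))
  expect_gt(sum(cmp$polated == 1L), 0)
  expect_lt(max(abs(cmp$value - cmp$truth)), 1e-6)
})

test_that("flag histogram mirrors the constructed mask exactly", {
  fx <- two_region_fixture(years = 1990:2009)
  masked <- mask_panel(fx$panel, c(1994, 2003), pattern = "mixed")
  f <- fill_panel(masked, fx$national, fx$regions)
  per_region <- f$flags |> dplyr::filter(gdlcode == "AAAr01",
                                         indicator == "lifexp")
  expect_equal(sum(per_region$polated == 0), 2) # the two survey years
  expect_equal(sum(per_region$polated == 1), 2003 - 1994 - 1)
  expect_equal(sum(per_region$polated == 3), 1994 - 1990) # before first
  expect_equal(sum(per_region$polated == 2), 2009 - 2003) # after last
  expect_equal(
    per_region$polyears[per_region$year == 1990], 4L # anchored at 1994
  )
})

test_that("countries with no data fall back to national values, code 4", {
  fx <- two_region_fixture(years = 2000:2002)
  no_esch <- fx$panel |> dplyr::filter(indicator != "esch")
  f <- fill_panel(no_esch, fx$national, fx$regions)
  esch_flags <- f$flags |> dplyr::filter(indicator == "esch")
  expect_true(all(esch_flags$polated == 4L))
  expect_true(all(esch_flags$polyears == 0L))
  esch_vals <- f$panel |> dplyr::filter(indicator == "esch")
  expect_equal(
    esch_vals$value[esch_vals$year == 2001],
    rep(fx$national$expschun[2], 2)
  )
})

test_that("a gap in the national series is a hard error", {
  fx <- two_region_fixture(years = 2000:2002)
  holey <- fx$national
  holey$lifexpun[2] <- NA
  expect_error(fill_panel(fx$panel, holey, fx$regions),
               class = "shdikit_domain_error")
  expect_error(fill_panel(fx$panel, fx$national[-2, ], fx$regions),
               class = "shdikit_domain_error")
})
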