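# Fixture builders used across the suite. Everything is generated in code;
# no data files.

tiny_world <- function(n_countries = 3, regions = c(2, 5), seed = 42, ...) {
  generate_world(world_spec(
    n_countries = n_countries, regions_per_country = regions,
    seed = seed, ...
  ))
}

# Hand-built two-region country over a short window, for exact arithmetic.
# Populations 1 and 3 so the weighted mean is (v1 + 3 v2) / 4.
two_region_fixture <- function(years = 2000:2002) {
  regions <- tibble::tibble(
    iso_code = "AAA", country = "Aland",
    gdlcode = c("AAAt", "AAAr01", "AAAr02"),
    level = c("national", "subnational", "subnational"),
    region = c("Total", "North", "South"),
    population = c(4, 1, 3)
  )
  national <- tibble::tibble(
    iso_code = "AAA", year = years,
    hdiun = NA_real_,
    lifexpun = 70 + 0.5 * (years - years[1]),
    gnicun = 8000 * 1.02^(years - years[1]),
    expschun = 12 + 0.1 * (years - years[1]),
    yrschun = 8 + 0.1 * (years - years[1]),
    population = 4
  )
  grid <- expand.grid(
    gdlcode = c("AAAr01", "AAAr02"), year = years,
    indicator = c("lifexp", "lgnic", "esch", "msch"),
    stringsAsFactors = FALSE
  )
  offsets <- c(AAAr01 = 0.9, AAAr02 = 1.05)
  nat_of <- function(ind, yr) {
    i <- match(yr, years)
    switch(ind,
      lifexp = national$lifexpun[i], lgnic = log(national$gnicun[i]),
      esch = national$expschun[i], msch = national$yrschun[i]
    )
  }
  panel <- tibble::as_tibble(grid) |>
    dplyr::mutate(
      value = unname(mapply(nat_of, indicator, year) * offsets[gdlcode]),
      observed = TRUE
    ) |>
    dplyr::arrange(gdlcode, indicator, year)
  list(regions = regions, national = national, panel = panel)
}

# One-country world with linearly drifting regional shares: regional value =
# national(t) * (share_r + drift_r * (t - t0)), drifts summing to zero and
# equal populations, so the anchored trajectories curve gently and carry
# errors grow linearly with gap length.
drifting_panel <- function(years = 1990:2017, n_regions = 4,
                           drift = 0.004) {
  regions <- tibble::tibble(
    iso_code = "DDD", country = "Driftland",
    gdlcode = c("DDDt", sprintf("DDDr%02d", seq_len(n_regions))),
    level = c("national", rep("subnational", n_regions)),
    region = c("Total", sprintf("R%02d", seq_len(n_regions))),
    population = c(n_regions, rep(1, n_regions))
  )
  national <- tibble::tibble(
    iso_code = "DDD", year = years,
    hdiun = NA_real_,
    lifexpun = 55 + 0.6 * (years - years[1]),
    gnicun = exp(8 + 0.03 * (years - years[1])),
    expschun = 8 + 0.25 * (years - years[1]),
    yrschun = 5 + 0.2 * (years - years[1]),
    population = n_regions
  )
  share0 <- seq(0.85, 1.15, length.out = n_regions)
  drifts <- drift * scale(seq_len(n_regions), scale = FALSE)[, 1]
  rows <- list()
  for (ind in c("lifexp", "lgnic", "esch", "msch")) {
    nat <- switch(ind,
      lifexp = national$lifexpun, lgnic = log(national$gnicun),
      esch = national$expschun, msch = national$yrschun
    )
    for (r in seq_len(n_regions)) {
      share <- share0[r] + drifts[r] * (years - years[1])
      rows[[paste(ind, r)]] <- tibble::tibble(
        gdlcode = sprintf("DDDr%02d", r), year = years,
        indicator = ind, value = nat * share, observed = TRUE
      )
    }
  }
  list(regions = regions, national = national,
       panel = dplyr::bind_rows(rows))
}

expect_anchored <- function(panel, national, regions, tol = 1e-9) {
  sub <- regions |>
    dplyr::filter(level == "subnational") |>
    dplyr::select(gdlcode, iso_code, population)
  wm <- panel |>
    dplyr::inner_join(sub, by = "gdlcode") |>
    dplyr::group_by(iso_code, year, indicator) |>
    dplyr::summarise(wm = weighted_mean(value, population),
                     .groups = "drop")
  nat <- shdikit:::national_long(national, unique(panel$indicator))
  j <- dplyr::inner_join(wm, nat, by = c("iso_code", "year", "indicator"))
  expect_true(nrow(j) > 0)
  expect_lt(max(abs(j$wm - j$national) / abs(j$national)), tol)
  invisible(max(abs(j$wm - j$national) / abs(j$national)))
}
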