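#' Specification of a synthetic multi-country world
#'
#' Describes the shape of a synthetic panel: number of countries, range of
#' regions per country (at least two, as even very small countries are split
#' in two; at most 51, the largest real subdivision count), year window,
#' survey years, indicator noise, and the generative parameters linking the
#' proxy covariates to income and life expectancy. The seed fully determines
#' the generated world.
#'
#' @param n_countries Number of countries.
#' @param regions_per_country Length-2 range from which each country's
#'   number of subnational regions is drawn uniformly.
#' @param years Integer vector of consecutive years (default 1990–2017).
#' @param survey_years Default survey years used by [mask_panel()] when a
#'   mask is requested (subset of `years`); `NULL` keeps everything observed.
#' @param seed Integer seed; fully determines the generated world.
#' @param noise_sd Named per-indicator standard deviation of the Gaussian
#'   cell-level noise, on the indicator scale (truncated to validity ranges).
#' @param region_disp Standard deviation of the persistent multiplicative
#'   regional offsets around the national trajectory.
#' @param trend `"logistic"` (smooth saturating growth toward the goalposts,
#'   the realistic default) or `"linear"` (exactly linear national and
#'   regional trajectories, useful for exactness checks).
#' @param bridge_params Generative bridge parameters, see
#'   [default_bridge_params()].
#' @return A `shdikit_world_spec` list.
#' @export
world_spec <- function(n_countries = 10,
                       regions_per_country = c(2, 12),
                       years = 1990:2017,
                       survey_years = NULL,
                       seed = 1L,
                       noise_sd = c(lifexp = 0.5, lgnic = 0.05,
                                    esch = 0.2, msch = 0.2),
                       region_disp = 0.08,
                       trend = c("logistic", "linear"),
                       bridge_params = default_bridge_params()) {
  trend <- match.arg(trend)
  if (n_countries < 1) stop_value("spec error: need at least one country")
  if (length(years) < 1) stop_value("spec error: empty year window")
  if (length(regions_per_country) == 1) {
    regions_per_country <- rep(regions_per_country, 2)
  }
  if (regions_per_country[1] < 2 || regions_per_country[2] > 51 ||
      regions_per_country[1] > regions_per_country[2]) {
    stop_value("regions_per_country must be a range within [2, 51]")
  }
  if (!is.null(survey_years) && !all(unlist(survey_years) %in% years)) {
    stop_value("survey_years must be a subset of the year window")
  }
  structure(
    list(
      n_countries = as.integer(n_countries),
      regions_per_country = as.integer(regions_per_country),
      years = as.integer(years),
      survey_years = survey_years,
      seed = as.integer(seed),
      noise_sd = noise_sd,
      region_disp = region_disp,
      trend = trend,
      bridge_params = bridge_params
    ),
    class = "shdikit_world_spec"
  )
}

#' Default generative bridge parameters
#'
#' Parameters of the relations linking the proxies to the indicators they
#' stand in for: log GNI per capita is linear in the wealth index
#' (`lgnic = intercept + slope * iwi + year_coef * (year - 2000) + eps`),
#' and life expectancy is quadratic in under-five mortality
#' (`lifexp = intercept + linear * u5m + quad * u5m^2 +
#' year_coef * (year - 2000) + eps`). The defaults span the plausible
#' indicator ranges: a wealth index of 0–100 maps onto log incomes of about
#' 4.6–11.2, and under-five mortality of 0–190 per 1000 onto life
#' expectancies of about 85 down to the low 40s.
#'
#' @return Named list with `iwi` and `u5m` components.
#' @export
default_bridge_params <- function() {
  list(
    iwi = list(intercept = 4.6, slope = 0.066, year_coef = 0.002,
               noise_sd = 0.04),
    u5m = list(intercept = 85, linear = -0.45, quad = 0.0012,
               year_coef = 0.01, noise_sd = 0.25)
  )
}

#' Generate a synthetic world: regions, ground-truth panel, national series
#'
#' Each country receives a smooth national trajectory per indicator (within
#' the goalposts), persistent multiplicative regional offsets, Gaussian
#' cell-level noise, and log-normal region populations held constant over
#' time. Regional values are then anchored so that for every country-year
#' the population-weighted regional mean equals the national value exactly
#' (by construction, the same device the pipeline uses). The national HDI
#' (`hdiun`) is computed from the national indicator values with the index
#' module, so index-reproduction checks have an exact reference.
#'
#' @param spec A [world_spec()].
#' @return List with `regions` (metadata incl. one national record per
#'   country), `panel` (complete observed ground truth, long form) and
#'   `national` (complete national reference series).
#' @export
generate_world <- function(spec) {
  if (!inherits(spec, "shdikit_world_spec")) {
    stop_value("spec error: not a world_spec object")
  }
  set.seed(spec$seed)
  years <- spec$years
  n_y <- length(years)

  country_tabs <- lapply(seq_len(spec$n_countries), function(i) {
    iso <- sprintf("C%02d", i)
    rng <- seq(spec$regions_per_country[1], spec$regions_per_country[2])
    n_r <- rng[sample.int(length(rng), 1)]
    pop <- rlnorm(n_r, meanlog = 13, sdlog = 0.7)
    gdl <- sprintf("%sr%02d", iso, seq_len(n_r))

    nat <- vapply(SHDI_INDICATORS, function(ind) {
      national_trajectory(ind, years, spec$trend)
    }, numeric(n_y))

    # persistent multiplicative regional offsets, truncated near 1
    share <- vapply(SHDI_INDICATORS, function(ind) {
      clip_range(rnorm(n_r, 1, spec$region_disp), c(0.6, 1.4))
    }, numeric(n_r))

    cells <- lapply(SHDI_INDICATORS, function(ind) {
      nat_t <- nat[, ind]
      raw <- outer(share[, ind], nat_t) # regions x years
      sd_i <- spec$noise_sd[[ind]] %||% 0
      if (sd_i > 0) {
        rng <- indicator_range(ind)
        raw <- clip_range(raw + rnorm(length(raw), 0, sd_i), rng)
      }
      # anchor each year so the weighted mean equals the national value
      wm <- as.vector(pop %*% raw) / sum(pop)
      raw <- sweep(raw, 2, nat_t / wm, `*`)
      tibble(
        gdlcode = rep(gdl, times = n_y),
        year = rep(years, each = n_r),
        indicator = ind,
        value = as.vector(raw),
        observed = TRUE
      )
    })

    regions <- dplyr::bind_rows(
      tibble(
        iso_code = iso, country = paste("Country", iso),
        gdlcode = paste0(iso, "t"), level = "national",
        region = "Total", population = sum(pop)
      ),
      tibble(
        iso_code = iso, country = paste("Country", iso),
        gdlcode = gdl, level = "subnational",
        region = sprintf("Region %02d", seq_len(n_r)), population = pop
      )
    )
    national <- tibble(
      iso_code = iso, year = years,
      lifexpun = nat[, "lifexp"],
      gnicun = exp(nat[, "lgnic"]),
      expschun = nat[, "esch"],
      yrschun = nat[, "msch"],
      population = sum(pop)
    )
    list(regions = regions, panel = dplyr::bind_rows(cells),
         national = national)
  })

  national <- dplyr::bind_rows(lapply(country_tabs, `[[`, "national"))
  nat_panel <- national |>
    dplyr::transmute(
      gdlcode = .data$iso_code, year = .data$year,
      lifexp = .data$lifexpun, lgnic = log(.data$gnicun),
      esch = .data$expschun, msch = .data$yrschun
    ) |>
    tidyr::pivot_longer(dplyr::all_of(SHDI_INDICATORS),
      names_to = "indicator", values_to = "value"
    )
  hdi <- compute_indices(nat_panel) |>
    dplyr::select(iso_code = "gdlcode", "year", hdiun = "shdi")
  national <- national |>
    dplyr::inner_join(hdi, by = c("iso_code", "year")) |>
    dplyr::select("iso_code", "year", "hdiun", "lifexpun", "gnicun",
                  "expschun", "yrschun", "population")

  list(
    regions = dplyr::bind_rows(lapply(country_tabs, `[[`, "regions")),
    panel = dplyr::bind_rows(lapply(country_tabs, `[[`, "panel")) |>
      dplyr::arrange(.data$gdlcode, .data$indicator, .data$year),
    national = national
  )
}

# Smooth national trajectory within the goalposts for one indicator.
national_trajectory <- function(indicator, years, trend) {
  t0 <- years - years[1]
  n <- length(years)
  span <- switch(indicator,
    lifexp = c(20, 85), esch = c(0, 18), msch = c(0, 15),
    lgnic = log(c(100, 75000))
  )
  if (trend == "logistic") {
    a <- switch(indicator,
      lifexp = runif(1, 0.3, 2.0), esch = runif(1, -0.5, 1.5),
      msch = runif(1, -1.0, 1.5), lgnic = runif(1, -1.0, 2.0)
    )
    b <- runif(1, 0.01, 0.05)
    span[1] + diff(span) * plogis(a + b * t0)
  } else {
    v0 <- span[1] + diff(span) * runif(1, 0.4, 0.7)
    s_max <- (span[1] + 0.95 * diff(span) - v0) / max(t0, 1)
    s <- runif(1, 0.1, 0.8) * s_max
    v0 + s * t0
  }
}

#' Mask a ground-truth panel down to survey years
#'
#' Emulates the sparse, irregular observation pattern of household surveys
#' and censuses: cells are observed only at survey years; all other years
#' have their value removed and `observed = FALSE`. The `pattern` argument
#' controls where the resulting gaps sit by augmenting the survey set with
#' window endpoints: `"interior"` adds both endpoints (all gaps bracketed,
#' interpolation-testable), `"leading"` adds only the last year (gaps at the
#' start, backward-extrapolation-testable), `"trailing"` adds only the first
#' year, and `"mixed"` uses the survey years verbatim.
#'
#' The input truth is not modified; retain it to score recovery.
#'
#' @param truth Complete long panel.
#' @param survey_years Integer vector of survey years (applied to every
#'   country), or a named list `iso_code -> years` together with `regions`.
#' @param pattern One of `"mixed"`, `"interior"`, `"leading"`, `"trailing"`.
#' @param regions Region metadata, required when `survey_years` is a
#'   per-country list.
#' @param indicators Indicators to mask (default: the four index
#'   indicators).
#' @return The masked panel.
#' @export
mask_panel <- function(truth, survey_years,
                       pattern = c("mixed", "interior", "leading",
                                   "trailing"),
                       regions = NULL, indicators = SHDI_INDICATORS) {
  pattern <- match.arg(pattern)
  window <- range(truth$year)
  augment <- function(sy) {
    if (length(sy) == 0) stop_value("survey_years must be nonempty")
    sy <- as.integer(sy)
    switch(pattern,
      mixed = sy,
      interior = union(sy, window),
      leading = union(sy, window[2]),
      trailing = union(sy, window[1])
    )
  }
  if (is.list(survey_years)) {
    if (is.null(regions)) {
      stop_value("per-country survey_years require region metadata")
    }
    obs_map <- lapply(survey_years, augment)
    iso_of <- setNames(regions$iso_code, regions$gdlcode)
    keep <- mapply(
      function(iso, yr) yr %in% (obs_map[[iso]] %||% integer()),
      iso_of[truth$gdlcode], truth$year
    )
  } else {
    obs_years <- augment(survey_years)
    keep <- truth$year %in% obs_years
  }
  mask <- truth$indicator %in% indicators & !keep
  out <- truth
  out$value[mask] <- NA_real_
  out$observed[mask] <- FALSE
  out
}

#' Attach proxy covariates to a ground-truth panel
#'
#' Draws the wealth index and under-five mortality consistently with the
#' generative bridge relations: `iwi` such that
#' `lgnic = intercept + slope * iwi + year_coef * (year - 2000) + eps`
#' (then clipped to \[0, 100\]), and `u5m` as the root of the decreasing
#' branch of the quadratic `lifexp = intercept + linear * u5m + quad * u5m^2
#' + year_coef * (year - 2000) + eps` (clipped to \[0, 1000\]). With zero
#' noise the relations hold exactly cell by cell. The generative parameters
#' are recorded in the `bridge_params` attribute for recovery tests.
#'
#' @param truth Panel containing `lgnic` and `lifexp` rows.
#' @param bridge_params See [default_bridge_params()].
#' @param seed Integer seed for the noise draws.
#' @return The input panel with `iwi` and `u5m` rows appended.
#' @export
generate_proxies <- function(truth, bridge_params = default_bridge_params(),
                             seed = 1L) {
  if (!all(c("lgnic", "lifexp") %in% truth$indicator)) {
    stop_value("panel must contain lgnic and lifexp to generate proxies")
  }
  set.seed(seed)
  bp_i <- bridge_params$iwi
  bp_u <- bridge_params$u5m

  lg <- truth[truth$indicator == "lgnic", ]
  eps <- rnorm(nrow(lg), 0, bp_i$noise_sd)
  iwi <- (lg$value - eps - bp_i$intercept -
            bp_i$year_coef * (lg$year - 2000)) / bp_i$slope
  lg$indicator <- "iwi"
  lg$value <- clip_range(iwi, indicator_range("iwi"))

  le <- truth[truth$indicator == "lifexp", ]
  eps <- rnorm(nrow(le), 0, bp_u$noise_sd)
  cprime <- bp_u$intercept + bp_u$year_coef * (le$year - 2000)
  disc <- bp_u$linear^2 - 4 * bp_u$quad * (cprime - (le$value - eps))
  disc <- pmax(disc, 0)
  u5m <- (-bp_u$linear - sqrt(disc)) / (2 * bp_u$quad)
  le$indicator <- "u5m"
  le$value <- clip_range(u5m, indicator_range("u5m"))

  out <- dplyr::bind_rows(truth, lg, le) |>
    dplyr::arrange(.data$gdlcode, .data$indicator, .data$year)
  attr(out, "bridge_params") <- bridge_params
  out
}

#' Simulate a clean national panel from a generative bridge relation
#'
#' Proxy-first simulation for parameter-recovery studies: each country gets
#' a smooth proxy trajectory, and the target indicator is generated from the
#' forward bridge relation plus independent Gaussian noise — the textbook
#' regression setting, so ordinary least squares on the simulated panel is
#' unbiased for the generative coefficients.
#'
#' @param target `"lifexp"` (quadratic in `u5m`) or `"lgnic"` (linear in
#'   `iwi`).
#' @param n_countries Number of countries.
#' @param years Year vector.
#' @param params Generative parameters (one component of
#'   [default_bridge_params()]); defaults to that component.
#' @param seed Integer seed.
#' @return Tibble `iso_code`, `year`, proxy column, target column.
#' @export
simulate_bridge_data <- function(target = c("lifexp", "lgnic"),
                                 n_countries = 150, years = 1990:2017,
                                 params = NULL, seed = 1L) {
  target <- match.arg(target)
  set.seed(seed)
  n_y <- length(years)
  t0 <- years - years[1]
  if (target == "lifexp") {
    params <- params %||% default_bridge_params()$u5m
    start <- runif(n_countries, 30, 250)
    rate <- runif(n_countries, 0.005, 0.04)
    proxy <- as.vector(vapply(
      seq_len(n_countries),
      function(i) start[i] * exp(-rate[i] * t0), numeric(n_y)
    ))
    yy <- rep(years, n_countries)
    value <- params$intercept + params$linear * proxy +
      params$quad * proxy^2 + params$year_coef * (yy - 2000) +
      rnorm(length(proxy), 0, params$noise_sd)
    tibble(
      iso_code = rep(sprintf("C%03d", seq_len(n_countries)), each = n_y),
      year = yy, u5m = proxy, lifexp = value
    )
  } else {
    params <- params %||% default_bridge_params()$iwi
    start <- runif(n_countries, 5, 60)
    rate <- runif(n_countries, 0.2, 1.5)
    proxy <- as.vector(vapply(
      seq_len(n_countries),
      function(i) clip_range(start[i] + rate[i] * t0, c(0, 100)),
      numeric(n_y)
    ))
    yy <- rep(years, n_countries)
    value <- params$intercept + params$slope * proxy +
      params$year_coef * (yy - 2000) +
      rnorm(length(proxy), 0, params$noise_sd)
    tibble(
      iso_code = rep(sprintf("C%03d", seq_len(n_countries)), each = n_y),
      year = yy, iwi = proxy, lgnic = value
    )
  }
}
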