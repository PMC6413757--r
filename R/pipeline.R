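#' Pipeline configuration
#'
#' Collects the knobs of an end-to-end database build: the year window, the
#' goalposts, the income scaling space, the bridge-model forms, the
#' education-dimension quality rule and the country-year classification
#' rule, plus the seed recorded in the run manifest.
#'
#' @param years Analysis year window.
#' @param goalposts Goalpost table, see [default_goalposts()].
#' @param income_space `"log"` or `"level"`, see [anchor_to_national()].
#' @param bridge_formulas Proxy forms for the two bridges (defaults: life
#'   expectancy quadratic in under-five mortality, log income linear in the
#'   wealth index).
#' @param education_rule For quality summaries, the education dimension is
#'   high-quality if `"both"` schooling indicators are (conservative
#'   default) or if `"either"` is.
#' @param classification `"best"` (default) or `"worst"` status across the
#'   four indicators when classifying a country-year.
#' @param seed Integer seed recorded in the manifest.
#' @return A `shdikit_config` list.
#' @export
pipeline_config <- function(years = 1990:2017,
                            goalposts = default_goalposts(),
                            income_space = c("log", "level"),
                            bridge_formulas = c(lifexp = "quadratic",
                                                lgnic = "linear"),
                            education_rule = c("both", "either"),
                            classification = c("best", "worst"),
                            seed = 1L) {
  if (length(years) == 0) stop_value("empty year window")
  structure(
    list(
      years = as.integer(years),
      goalposts = goalposts,
      income_space = match.arg(income_space),
      bridge_formulas = bridge_formulas,
      education_rule = match.arg(education_rule),
      classification = match.arg(classification),
      seed = as.integer(seed)
    ),
    class = "shdikit_config"
  )
}

BRIDGE_PROXY <- c(lifexp = "u5m", lgnic = "iwi")

#' Build a complete subnational human development database
#'
#' Runs the full construction sequence on a starting panel: (1) for
#' countries without direct life-expectancy or income observations,
#' estimate them from the proxy covariates through national-level
#' regression bridges; (2) impute expected years of schooling from mean
#' years of schooling where needed; (3–4) anchor observed cross-sections to
#' the national series and fill all remaining years by the two-step
#' interpolation/extrapolation procedure, emitting quality flags; (5)
#' compute the dimension indices and the SHDI. The run is deterministic:
#' identical inputs and configuration give identical outputs.
#'
#' @param panel Long starting panel (observed indicator cells; may include
#'   `u5m`/`iwi` proxy rows).
#' @param national Complete national reference series.
#' @param regions Region metadata with populations.
#' @param config A [pipeline_config()].
#' @return List with `panel` (complete, anchored), `indices`, `flags`,
#'   `coefficients` (scaling diagnostics), `bridges` (fitted bridge models,
#'   possibly empty) and `manifest`.
#' @export
build_shdi <- function(panel, national, regions,
                       config = pipeline_config()) {
  if (!inherits(config, "shdikit_config")) {
    stop_value("config must be a pipeline_config()")
  }
  validate_panel(panel)
  validate_regions(regions)
  sub_regions <- regions |>
    dplyr::filter(.data$level == "subnational")
  iso_of <- setNames(sub_regions$iso_code, sub_regions$gdlcode)
  panel <- panel |>
    dplyr::filter(.data$year %in% config$years)

  has_data <- function(p, iso, ind) {
    any(p$indicator == ind & !is.na(p$value) & p$observed &
          iso_of[p$gdlcode] == iso, na.rm = TRUE)
  }

  # stage 1: proxy bridges for countries lacking direct lifexp / lgnic
  bridges <- list()
  for (target in names(BRIDGE_PROXY)) {
    proxy <- BRIDGE_PROXY[[target]]
    need <- Filter(
      function(iso) !has_data(panel, iso, target) &&
        has_data(panel, iso, proxy),
      unique(sub_regions$iso_code)
    )
    if (length(need) == 0) next
    model <- fit_national_bridge(panel, national, regions, target, proxy,
                                 config$bridge_formulas[[target]])
    bridges[[target]] <- model
    proxy_rows <- panel |>
      dplyr::filter(.data$indicator == proxy,
                    iso_of[.data$gdlcode] %in% need)
    est <- predict_subnational(model, proxy_rows)
    panel <- dplyr::bind_rows(panel, est)
  }

  # stage 2: expected years of schooling from mean years where absent
  for (iso in unique(sub_regions$iso_code)) {
    if (has_data(panel, iso, "esch") || !has_data(panel, iso, "msch")) next
    mys <- panel |>
      dplyr::filter(.data$indicator == "msch", .data$observed,
                    !is.na(.data$value),
                    iso_of[.data$gdlcode] == iso)
    nat_m <- national_anchor(national, iso, "msch")
    nat_e <- national_anchor(national, iso, "esch")
    est <- mys |>
      dplyr::mutate(
        indicator = "esch",
        value = impute_eys(
          .data$value,
          nat_m$national[match(.data$year, nat_m$year)],
          nat_e$national[match(.data$year, nat_e$year)]
        )
      )
    panel <- dplyr::bind_rows(panel, est)
  }

  # stages 3-4: anchoring plus gap filling with quality flags
  filled <- fill_panel(panel, national, regions,
                       indicators = SHDI_INDICATORS,
                       income_space = config$income_space)

  # stage 5: dimension indices and SHDI
  indices <- compute_indices(filled$panel, goalposts = config$goalposts)

  manifest <- list(
    package = "shdikit",
    version = as.character(utils::packageVersion("shdikit")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_countries = length(unique(sub_regions$iso_code)),
    n_regions = nrow(sub_regions),
    years = range(config$years),
    bridges_fitted = names(bridges)
  )
  list(
    panel = filled$panel, indices = indices, flags = filled$flags,
    coefficients = filled$coefficients, bridges = bridges,
    manifest = manifest
  )
}

# National-level bridge fit: the national proxy series is the
# population-weighted mean of the regional proxy values; the target comes
# from the national reference series.
fit_national_bridge <- function(panel, national, regions, target, proxy,
                                formula) {
  sub_regions <- regions |>
    dplyr::filter(.data$level == "subnational") |>
    dplyr::select("gdlcode", "iso_code", "population")
  nat_proxy <- panel |>
    dplyr::filter(.data$indicator == proxy, .data$observed,
                  !is.na(.data$value)) |>
    dplyr::inner_join(sub_regions, by = "gdlcode") |>
    dplyr::group_by(.data$iso_code, .data$year) |>
    dplyr::summarise(
      proxy_value = weighted_mean(.data$value, .data$population),
      .groups = "drop"
    )
  nat_target <- national_long(national, target) |>
    dplyr::select("iso_code", "year", target_value = "national")
  data <- dplyr::inner_join(nat_proxy, nat_target,
                            by = c("iso_code", "year"))
  names(data)[names(data) == "proxy_value"] <- proxy
  names(data)[names(data) == "target_value"] <- target
  fit_bridge(data, target, proxy, formula = formula, year = TRUE)
}

#' Run the pipeline from files on disk
#'
#' Thin orchestration over [build_shdi()]: reads the starting-data,
#' national-series and regions CSVs, builds the database, and writes the
#' database, quality and scaling-coefficient files plus a run manifest to
#' `output_dir`.
#'
#' @param starting_path,national_path,regions_path Input CSV paths.
#' @param output_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return The [build_shdi()] result, invisibly, with an added
#'   `paths` element.
#' @export
run_pipeline <- function(starting_path, national_path, regions_path,
                         output_dir, config = pipeline_config()) {
  for (p in c(starting_path, national_path, regions_path)) {
    if (!file.exists(p)) {
      stop_schema(paste0("input file not found: ", p))
    }
  }
  start <- read_starting_data(starting_path)
  national <- read_national(national_path)
  regions <- read_regions(regions_path)
  result <- build_shdi(start$panel, national, regions, config)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    database = file.path(output_dir, "shdi-database.csv"),
    quality = file.path(output_dir, "shdi-data-quality.csv"),
    coefficients = file.path(output_dir, "scaling-coefficients.csv"),
    manifest = file.path(output_dir, "run-manifest.txt")
  )
  write_database(result$panel, result$indices, regions, paths$database,
                 goalposts = config$goalposts)
  write_quality(result$flags, regions, paths$quality)
  readr::write_csv(result$coefficients, paths$coefficients,
                   progress = FALSE)
  writeLines(
    paste(names(result$manifest),
          vapply(result$manifest, function(x) paste(x, collapse = " "),
                 character(1)),
      sep = ": "
    ),
    paths$manifest
  )
  result$paths <- paths
  invisible(result)
}

#' Summarize data quality across countries and years
#'
#' Two complementary summaries of the quality-flag file. The first
#' classifies every country-year by the status of its four indicators —
#' `real` (at least one real value, under the default best-status rule),
#' else `interpolated`, else `short-extrapolated` (five years or less),
#' else `long-extrapolated`, else `national` — and reports percentages
#' overall and split at `split_year`. The second counts, per country-year,
#' how many of the three dimensions (health, income, education) rest on
#' high-quality data (real or interpolated), and reports the share of
#' country-years with at least one, at least two, and all three
#' high-quality dimensions.
#'
#' @param flags Long quality flags (`gdlcode`, `year`, `indicator`,
#'   `polated`, `polyears`).
#' @param regions Region metadata (maps region codes to countries).
#' @param split_year First year of the later period (default 2000).
#' @param education_rule `"both"` (both schooling indicators must be
#'   high-quality, conservative default) or `"either"`.
#' @param classification `"best"` or `"worst"` status aggregation across
#'   indicators.
#' @return List of tibbles `classification` (`period`, `class`, `n`, `pct`)
#'   and `high_quality` (`period`, `measure`, `n`, `pct`).
#' @export
quality_report <- function(flags, regions, split_year = 2000,
                           education_rule = c("both", "either"),
                           classification = c("best", "worst")) {
  education_rule <- match.arg(education_rule)
  classification <- match.arg(classification)
  validate_flags(flags)
  iso_of <- regions |>
    dplyr::distinct(.data$gdlcode, .data$iso_code)

  status_levels <- c("real", "interpolated", "short-extrapolated",
                     "long-extrapolated", "national")
  cy <- flags |>
    dplyr::inner_join(iso_of, by = "gdlcode") |>
    dplyr::distinct(.data$iso_code, .data$year, .data$indicator,
                    .data$polated, .data$polyears) |>
    dplyr::mutate(
      rank = dplyr::case_when(
        .data$polated == 0 ~ 1L,
        .data$polated == 1 ~ 2L,
        .data$polated %in% c(2L, 3L) & .data$polyears <= 5 ~ 3L,
        .data$polated %in% c(2L, 3L) ~ 4L,
        TRUE ~ 5L
      ),
      high_quality = .data$polated %in% c(0L, 1L)
    )

  agg <- if (classification == "best") min else max
  classes <- cy |>
    dplyr::group_by(.data$iso_code, .data$year) |>
    dplyr::summarise(class = status_levels[agg(.data$rank)],
                     .groups = "drop")

  dims <- cy |>
    tidyr::pivot_wider(
      id_cols = c("iso_code", "year"),
      names_from = "indicator", values_from = "high_quality"
    ) |>
    dplyr::mutate(
      health_hq = .data$lifexp,
      income_hq = .data$lgnic,
      ed_hq = if (education_rule == "both") {
        .data$esch & .data$msch
      } else {
        .data$esch | .data$msch
      },
      n_hq = .data$health_hq + .data$income_hq + .data$ed_hq
    )

  period_of <- function(year) {
    ifelse(year < split_year,
           paste0("pre-", split_year), paste0(split_year, "-on"))
  }
  summarize_classes <- function(df, label) {
    df |>
      dplyr::count(.data$class) |>
      dplyr::mutate(period = label, pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::select("period", "class", "n", "pct")
  }
  summarize_hq <- function(df, label) {
    tibble(
      period = label,
      measure = c("at_least_one", "at_least_two", "all_three"),
      n = c(sum(df$n_hq >= 1), sum(df$n_hq >= 2), sum(df$n_hq == 3)),
      pct = 100 * c(sum(df$n_hq >= 1), sum(df$n_hq >= 2),
                    sum(df$n_hq == 3)) / nrow(df)
    )
  }
  class_tab <- dplyr::bind_rows(
    summarize_classes(classes, "all"),
    classes |>
      dplyr::group_by(period = period_of(.data$year)) |>
      dplyr::group_modify(~ summarize_classes(.x, .y$period) |>
                            dplyr::select(-"period")) |>
      dplyr::ungroup()
  )
  hq_tab <- dplyr::bind_rows(
    summarize_hq(dims, "all"),
    dims |>
      dplyr::group_by(period = period_of(.data$year)) |>
      dplyr::group_modify(~ summarize_hq(.x, .y$period) |>
                            dplyr::select(-"period")) |>
      dplyr::ungroup()
  )
  list(classification = class_tab, high_quality = hq_tab)
}
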