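#' File schemas for subnational human development databases
#'
#' The pipeline reads and writes four comma-separated schemas mirroring the
#' deposited database layouts: the *starting data* (one row per region-year
#' with the raw indicator columns), the *national reference series* (one row
#' per country-year with national indicator values and the national HDI), the
#' complete *database* (indicators plus dimension indices and SHDI), and the
#' *data quality* file (per-cell provenance codes and gap lengths). CSV is
#' used as the interchange dialect: UTF-8, header row, missing values as
#' empty fields.
#'
#' Internally indicator observations travel in a long *panel*: one row per
#' `(gdlcode, year, indicator, value, observed)`.
#'
#' @name panel-io
NULL

DATABASE_COLUMNS <- c(
  "iso_code", "country", "year", "gdlcode", "level", "region",
  "shdi", "healthindex", "incindex", "edindex",
  "lifexp", "lgnic", "esch", "msch"
)

STARTING_KEY_COLUMNS <- c("iso_code", "year", "gdlcode")

region_key_frame <- function(regions) {
  regions[, intersect(
    c("iso_code", "country", "gdlcode", "level", "region"),
    names(regions)
  )]
}

#' Read a starting-data file into region metadata and a long indicator panel
#'
#' Rows with an empty indicator cell are skipped (they are missing
#' observations, never zeroes); every retained cell becomes an observed panel
#' entry.
#'
#' @param path Path to a starting-data CSV (region-year rows with columns
#'   among `lifexp`, `lgnic`, `esch`, `msch`, `u5m`, `iwi`; unknown columns
#'   are tolerated and ignored).
#' @return A list with `regions` (one row per region: `iso_code`, `country`,
#'   `gdlcode`, `level`, `region`, and `population` if present) and `panel`
#'   (long tibble `gdlcode`, `year`, `indicator`, `value`, `observed`).
#' @export
read_starting_data <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_keys <- setdiff(STARTING_KEY_COLUMNS, names(raw))
  if (length(missing_keys) > 0) {
    stop_schema(paste0(
      "starting data is missing required column(s): ",
      paste(missing_keys, collapse = ", ")
    ))
  }
  dup <- raw |>
    dplyr::count(.data$gdlcode, .data$year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_integrity(paste0(
      "duplicate (gdlcode, year) rows in starting data: ",
      paste(paste0(dup$gdlcode, "/", dup$year), collapse = ", ")
    ))
  }
  ind_cols <- intersect(c(SHDI_INDICATORS, PROXY_INDICATORS), names(raw))
  panel <- raw |>
    dplyr::select(dplyr::all_of(c("gdlcode", "year", ind_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(ind_cols),
      names_to = "indicator", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(observed = TRUE) |>
    dplyr::arrange(.data$gdlcode, .data$indicator, .data$year)
  validate_panel(panel)

  meta_cols <- intersect(
    c("iso_code", "country", "gdlcode", "level", "region", "population"),
    names(raw)
  )
  regions <- raw |>
    dplyr::distinct(dplyr::across(dplyr::all_of(meta_cols)))
  list(regions = regions, panel = panel)
}

#' Write a long indicator panel as a starting-data file
#'
#' The inverse of [read_starting_data()]: unobserved cells are written as
#' empty fields and dropped again on read.
#'
#' @param panel Long indicator panel.
#' @param regions Region metadata (`iso_code`, `country`, `gdlcode`, `level`,
#'   `region`; `source1`/`source2` provenance columns are passed through when
#'   present).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_starting_data <- function(panel, regions, path) {
  validate_panel(panel)
  wide <- panel |>
    dplyr::filter(.data$observed, !is.na(.data$value)) |>
    dplyr::select("gdlcode", "year", "indicator", "value") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "value")
  meta_cols <- intersect(
    c("iso_code", "country", "gdlcode", "level", "region",
      "source1", "source2"),
    names(regions)
  )
  out <- dplyr::inner_join(regions[, meta_cols], wide, by = "gdlcode") |>
    dplyr::arrange(.data$gdlcode, .data$year)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write the national reference series
#'
#' One row per country-year with the national values of the four indicators
#' (`lifexpun`, `gnicun` as a level in PPP dollars, `expschun`, `yrschun`),
#' the national HDI (`hdiun`) and the national population. The gap-filling
#' stage presumes this series is complete over the analysis window.
#'
#' @param path CSV path.
#' @return A tibble with the national series.
#' @export
read_national <- function(path) {
  national <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("iso_code", "year", "hdiun", "lifexpun", "gnicun",
                "expschun", "yrschun")
  missing_cols <- setdiff(required, names(national))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "national series is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(!is.na(national$gnicun) & national$gnicun <= 0)) {
    stop_domain("national gnicun must be strictly positive")
  }
  national
}

#' @rdname read_national
#' @param national National series tibble.
#' @export
write_national <- function(national, path) {
  readr::write_csv(national, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read and write region metadata
#'
#' @param regions Tibble with one row per region (`iso_code`, `country`,
#'   `gdlcode`, `level`, `region`, `population`).
#' @param path CSV path.
#' @export
write_regions <- function(regions, path) {
  validate_regions(regions)
  readr::write_csv(regions, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  regions <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_regions(regions)
  regions
}

#' Write the complete subnational database file
#'
#' Emits one row per region-year with the four indicators, the three
#' dimension indices and the SHDI, in the published column order, plus one
#' national row per country-year holding the population-weighted national
#' aggregate. Values are serialized at six decimals.
#'
#' @param panel Complete long panel (every region-year-indicator cell present
#'   for the four index indicators).
#' @param indices Tibble of per region-year index values (`gdlcode`, `year`,
#'   `healthindex`, `incindex`, `edindex`, `shdi`), as returned by
#'   [compute_indices()].
#' @param regions Region metadata including `population` (used to aggregate
#'   the national rows).
#' @param path Output CSV path.
#' @param goalposts Goalposts used for the national rows' indices.
#' @return `path`, invisibly.
#' @export
write_database <- function(panel, indices, regions, path,
                           goalposts = default_goalposts()) {
  validate_regions(regions)
  sub <- panel |>
    dplyr::filter(.data$indicator %in% SHDI_INDICATORS)
  missing <- sub |> dplyr::filter(is.na(.data$value))
  # completeness also requires all four indicators for every region-year
  cells <- sub |>
    dplyr::count(.data$gdlcode, .data$year) |>
    dplyr::filter(.data$n < length(SHDI_INDICATORS))
  if (nrow(missing) > 0 || nrow(cells) > 0) {
    bad <- unique(c(
      paste0(missing$gdlcode, "/", missing$year, "/", missing$indicator),
      paste0(cells$gdlcode, "/", cells$year)
    ))
    stop_completeness(paste0(
      "panel is incomplete; missing cells: ",
      paste(utils::head(bad, 20), collapse = ", "),
      if (length(bad) > 20) " ..."
    ))
  }

  wide <- sub |>
    dplyr::select("gdlcode", "year", "indicator", "value") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "value")
  sub_rows <- wide |>
    dplyr::inner_join(indices, by = c("gdlcode", "year")) |>
    dplyr::inner_join(region_key_frame(regions), by = "gdlcode")

  nat_rows <- national_aggregate_rows(sub, regions, goalposts)

  out <- dplyr::bind_rows(nat_rows, sub_rows) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c("shdi", "healthindex", "incindex", "edindex",
                      SHDI_INDICATORS)),
      ~ round(.x, 6)
    )) |>
    dplyr::select(dplyr::all_of(DATABASE_COLUMNS)) |>
    dplyr::arrange(.data$iso_code, .data$year, .data$level, .data$gdlcode)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# Population-weighted national aggregates of the four indicators, with their
# indices recomputed from the aggregated indicators.
national_aggregate_rows <- function(sub, regions, goalposts) {
  weights <- regions[, c("gdlcode", "iso_code", "population")]
  nat <- sub |>
    dplyr::inner_join(weights, by = "gdlcode") |>
    dplyr::group_by(.data$iso_code, .data$year, .data$indicator) |>
    dplyr::summarise(
      value = weighted_mean(.data$value, .data$population),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "value")
  idx <- compute_indices(
    nat |>
      tidyr::pivot_longer(dplyr::all_of(SHDI_INDICATORS),
        names_to = "indicator", values_to = "value"
      ) |>
      dplyr::rename(gdlcode = "iso_code"),
    goalposts = goalposts
  ) |>
    dplyr::rename(iso_code = "gdlcode")
  countries <- regions |>
    dplyr::distinct(.data$iso_code, .data$country)
  nat |>
    dplyr::inner_join(idx, by = c("iso_code", "year")) |>
    dplyr::inner_join(countries, by = "iso_code") |>
    dplyr::mutate(
      gdlcode = paste0(.data$iso_code, "t"),
      level = "national",
      region = "Total"
    )
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read the data-quality file
#'
#' One row per region-year; for each indicator a `<indicator>_polated`
#' provenance code (0 real, 1 interpolated, 2 extrapolated with a past
#' value, 3 extrapolated with a future value, 4 national value used) and a
#' `<indicator>_polyears` gap length in years.
#'
#' @param flags Long tibble of quality flags (`gdlcode`, `year`, `indicator`,
#'   `polated`, `polyears`).
#' @param regions Region metadata.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_quality <- function(flags, regions, path) {
  validate_flags(flags)
  wide <- flags |>
    dplyr::select("gdlcode", "year", "indicator", "polated", "polyears") |>
    tidyr::pivot_wider(
      names_from = "indicator",
      values_from = c("polated", "polyears"),
      names_glue = "{indicator}_{.value}"
    )
  flag_cols <- as.vector(t(outer(
    c("lgnic", "lifexp", "esch", "msch"),
    c("polated", "polyears"), paste,
    sep = "_"
  )))
  out <- wide |>
    dplyr::inner_join(region_key_frame(regions), by = "gdlcode") |>
    dplyr::select(dplyr::all_of(c(
      "iso_code", "country", "year", "gdlcode", "level", "region", flag_cols
    ))) |>
    dplyr::arrange(.data$iso_code, .data$gdlcode, .data$year)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_quality
#' @export
read_quality <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  flags <- wide |>
    tidyr::pivot_longer(
      dplyr::matches("_(polated|polyears)$"),
      names_to = c("indicator", ".value"),
      names_pattern = "^(.*)_(polated|polyears)$"
    ) |>
    dplyr::select("gdlcode", "year", "indicator", "polated", "polyears") |>
    dplyr::arrange(.data$gdlcode, .data$indicator, .data$year)
  validate_flags(flags)
  flags
}

validate_panel <- function(panel) {
  required <- c("gdlcode", "year", "indicator", "value", "observed")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "panel is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  dup <- panel |>
    dplyr::count(.data$gdlcode, .data$year, .data$indicator) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_integrity(paste0(
      "more than one value per (gdlcode, year, indicator): ",
      paste(utils::head(
        paste0(dup$gdlcode, "/", dup$year, "/", dup$indicator), 10
      ), collapse = ", ")
    ))
  }
  ok <- panel$value
  bad <- (panel$indicator == "lifexp" & !is.na(ok) & (ok <= 0 | ok >= 120)) |
    (panel$indicator %in% c("esch", "msch") & !is.na(ok) & ok < 0) |
    (panel$indicator == "iwi" & !is.na(ok) & (ok < 0 | ok > 100)) |
    (panel$indicator == "u5m" & !is.na(ok) & (ok < 0 | ok > 1000))
  if (any(bad)) {
    offender <- panel[which(bad)[1], ]
    stop_domain(paste0(
      "panel value out of range: ", offender$indicator, " = ",
      offender$value, " at ", offender$gdlcode, "/", offender$year
    ))
  }
  invisible(panel)
}

validate_regions <- function(regions) {
  required <- c("iso_code", "gdlcode", "level")
  missing_cols <- setdiff(required, names(regions))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "regions table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  nat <- regions |>
    dplyr::filter(.data$level == "national") |>
    dplyr::count(.data$iso_code)
  if (any(nat$n > 1)) {
    stop_integrity("more than one national record for a country")
  }
  multi <- regions |>
    dplyr::distinct(.data$gdlcode, .data$iso_code) |>
    dplyr::count(.data$gdlcode) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop_integrity(paste0(
      "gdlcode mapped to more than one country: ",
      paste(multi$gdlcode, collapse = ", ")
    ))
  }
  if ("population" %in% names(regions) &&
      any(!is.na(regions$population) & regions$population <= 0)) {
    stop_domain("region population must be > 0 where present")
  }
  invisible(regions)
}

validate_flags <- function(flags) {
  required <- c("gdlcode", "year", "indicator", "polated", "polyears")
  missing_cols <- setdiff(required, names(flags))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "quality flags missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(!flags$polated %in% 0:4)) {
    stop_value(paste0(
      "unknown polated code: ",
      paste(unique(flags$polated[!flags$polated %in% 0:4]), collapse = ", ")
    ))
  }
  if (any(flags$polated == 0 & flags$polyears != 0)) {
    stop_integrity("real values (polated = 0) must have polyears = 0")
  }
  if (any(flags$polated %in% 1:3 & flags$polyears < 1)) {
    stop_integrity("inter/extrapolated values must have polyears >= 1")
  }
  invisible(flags)
}
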