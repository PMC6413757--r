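#' Population-weighted mean of regional indicator values
#'
#' @param values Numeric vector of regional indicator values (no missing
#'   values allowed; gap filling happens upstream).
#' @param weights Population weights, non-negative with a positive sum.
#' @return The weighted mean \eqn{\sum w_i v_i / \sum w_i}.
#' @export
#' @examples
#' weighted_mean(c(4, 8), c(1, 3)) # 7
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop_domain("values and weights must have equal length")
  }
  if (any(is.na(values))) {
    stop_completeness("weighted_mean requires complete values")
  }
  if (any(is.na(weights)) || any(weights < 0) || sum(weights) <= 0) {
    stop_domain("weights must be non-negative with a positive sum")
  }
  stats::weighted.mean(values, weights)
}

#' Multiplicative coefficient anchoring regional values to a national target
#'
#' The coefficient `c = national_target / weighted_mean(values, weights)`
#' inflates or deflates all regional values of a country-year so that their
#' population-weighted average coincides with the national reference value;
#' it equals one when no re-scaling is necessary. Both the weighted mean and
#' the target must be strictly positive: the anchoring is multiplicative, so
#' the indicator must live on a positive scale (log income is anchored on its
#' positive log values).
#'
#' @inheritParams weighted_mean
#' @param national_target National reference value for the same country-year.
#' @return The scaling coefficient (a positive scalar).
#' @export
scaling_coefficient <- function(values, weights, national_target) {
  m <- weighted_mean(values, weights)
  if (is.na(m) || m <= 0 || is.na(national_target) || national_target <= 0) {
    stop_domain(paste0(
      "scaling requires a positive weighted mean and national target ",
      "(got mean = ", format(m), ", target = ", format(national_target), ")"
    ))
  }
  national_target / m
}

#' Apply a scaling coefficient to a slice of regional values
#'
#' A positive multiplier: region rankings and ratios between regions are
#' preserved, and after scaling the population-weighted mean equals the
#' national target that produced the coefficient.
#'
#' @param values Regional values.
#' @param coefficient Scaling coefficient from [scaling_coefficient()].
#' @return Scaled values.
#' @export
apply_scaling <- function(values, coefficient) {
  if (is.na(coefficient) || coefficient <= 0) {
    stop_domain("scaling coefficient must be positive")
  }
  values * coefficient
}

#' Anchor every country-year-indicator slice of a panel to the national series
#'
#' For each country, year and indicator, computes the population-weighted
#' mean over the country's subnational regions, derives the multiplicative
#' scaling coefficient against the national reference value, and rescales
#' the regional values. Regions with zero population are excluded from the
#' mean but still rescaled.
#'
#' Income is anchored on the log scale by default (`lgnic` values against the
#' log of the national income level); set `income_space = "level"` to scale
#' income levels instead and return their logs.
#'
#' @param panel Long indicator panel (complete in `value` for the cells to
#'   be scaled).
#' @param national National reference series (see [read_national()]).
#' @param regions Region metadata with `population`.
#' @param income_space `"log"` (default) or `"level"`.
#' @return A list with `panel` (scaled values) and `coefficients` (tibble
#'   `iso_code`, `year`, `indicator`, `coefficient`), the latter exportable
#'   for scaling-diagnostic density plots.
#' @export
anchor_to_national <- function(panel, national, regions,
                               income_space = c("log", "level")) {
  income_space <- match.arg(income_space)
  weights <- regions |>
    dplyr::filter(.data$level == "subnational") |>
    dplyr::select("gdlcode", "iso_code", "population")

  joined <- panel |>
    dplyr::inner_join(weights, by = "gdlcode")
  nat_long <- national_long(national, unique(joined$indicator))
  joined <- joined |>
    dplyr::inner_join(nat_long, by = c("iso_code", "year", "indicator"))

  scaled <- joined |>
    dplyr::group_by(.data$iso_code, .data$year, .data$indicator) |>
    dplyr::group_modify(function(df, key) {
      scale_slice(df, key$indicator, income_space)
    }) |>
    dplyr::ungroup()

  coefficients <- scaled |>
    dplyr::distinct(.data$iso_code, .data$year, .data$indicator,
                    .data$coefficient)
  out <- scaled |>
    dplyr::select("gdlcode", "year", "indicator", "value", "observed") |>
    dplyr::arrange(.data$gdlcode, .data$indicator, .data$year)
  list(panel = out, coefficients = coefficients)
}

scale_slice <- function(df, indicator, income_space) {
  in_mean <- df$population > 0
  if (!any(in_mean)) stop_domain("no positive-population region in slice")
  if (indicator == "lgnic" && income_space == "level") {
    lev <- exp(df$value)
    cc <- scaling_coefficient(
      lev[in_mean], df$population[in_mean], exp(df$national[1])
    )
    df$value <- log(apply_scaling(lev, cc))
  } else {
    cc <- scaling_coefficient(
      df$value[in_mean], df$population[in_mean], df$national[1]
    )
    df$value <- apply_scaling(df$value, cc)
  }
  df$coefficient <- cc
  df
}

# National series in long form on the panel's indicator scale (income as
# natural log).
national_long <- function(national, indicators) {
  indicators <- intersect(indicators, SHDI_INDICATORS)
  dplyr::bind_rows(lapply(indicators, function(ind) {
    cols <- national[, c("iso_code", "year", national_column(ind))]
    names(cols) <- c("iso_code", "year", "national")
    if (ind == "lgnic") cols$national <- log(cols$national)
    cols$indicator <- ind
    cols
  }))
}
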