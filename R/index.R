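#' UNDP goalposts for the four index indicators
#'
#' Fixed minimum and maximum bounds used to normalize each indicator onto
#' \[0, 1\]: life expectancy 20–85 years, gross national income per capita
#' 100–75,000 (2011 PPP dollars, normalized on the log scale), expected
#' years of schooling 0–18, mean years of schooling 0–15.
#'
#' @return Tibble with columns `indicator`, `min`, `max`.
#' @export
default_goalposts <- function() {
  tibble(
    indicator = c("lifexp", "gnic", "esch", "msch"),
    min = c(20, 100, 0, 0),
    max = c(85, 75000, 18, 15)
  )
}

goalpost_for <- function(goalposts, indicator) {
  row <- goalposts[goalposts$indicator == indicator, ]
  if (nrow(row) != 1 || row$min >= row$max) {
    stop_value(paste0("invalid goalposts for ", indicator))
  }
  c(row$min, row$max)
}

#' Goalpost-normalized dimension index
#'
#' `(value - min) / (max - min)`, with the raw value capped into
#' `[min, max]` first so the index is always in \[0, 1\].
#'
#' @param value Raw indicator value(s).
#' @param min,max Goalposts, `min < max`.
#' @return Index value(s) in \[0, 1\].
#' @export
#' @examples
#' dimension_index(52.5, 20, 85) # 0.5
dimension_index <- function(value, min, max) {
  if (any(min >= max)) stop_value("goalposts must satisfy min < max")
  (clip_range(value, c(min, max)) - min) / (max - min)
}

#' Income dimension index from GNI per capita
#'
#' Normalized on the natural-log scale between the income goalposts:
#' `(ln(gnic) - ln(100)) / (ln(75000) - ln(100))`, capped into \[0, 1\].
#'
#' @param gnic_pc GNI per capita level (2011 PPP dollars), strictly positive.
#' @param goalposts Goalpost table, see [default_goalposts()].
#' @return Index in \[0, 1\].
#' @export
income_index <- function(gnic_pc, goalposts = default_goalposts()) {
  if (any(is.na(gnic_pc)) || any(gnic_pc <= 0)) {
    stop_domain("GNI per capita must be strictly positive")
  }
  gp <- goalpost_for(goalposts, "gnic")
  dimension_index(log(gnic_pc), log(gp[1]), log(gp[2]))
}

#' Education index from the two schooling indices
#'
#' Expected and mean years of schooling are weighted equally: the education
#' dimension is the geometric mean of their two goalposted indices.
#'
#' @param eys_index,mys_index Indices in \[0, 1\].
#' @return `sqrt(eys_index * mys_index)`.
#' @export
education_index <- function(eys_index, mys_index) {
  if (any(eys_index < 0 | eys_index > 1 | mys_index < 0 | mys_index > 1,
          na.rm = TRUE)) {
    stop_domain("education sub-indices must lie in [0, 1]")
  }
  sqrt(eys_index * mys_index)
}

#' Subnational Human Development Index
#'
#' Geometric mean of the education, health and income dimension indices.
#'
#' @param ed,health,inc Dimension indices in \[0, 1\].
#' @return `(ed * health * inc)^(1/3)`.
#' @export
#' @examples
#' shdi(0.4, 0.5, 0.625) # 0.5
shdi <- function(ed, health, inc) {
  if (any(c(ed, health, inc) < 0 | c(ed, health, inc) > 1, na.rm = TRUE)) {
    stop_domain("dimension indices must lie in [0, 1]")
  }
  (ed * health * inc)^(1 / 3)
}

#' Compute dimension indices and the SHDI for every region-year of a panel
#'
#' @param panel Complete long panel holding the four indicators (`lifexp`,
#'   `lgnic`, `esch`, `msch`; income as natural log of GNI per capita).
#' @param goalposts Goalpost table, see [default_goalposts()].
#' @return Tibble `gdlcode`, `year`, `healthindex`, `incindex`, `edindex`,
#'   `shdi`.
#' @export
compute_indices <- function(panel, goalposts = default_goalposts()) {
  wide <- panel |>
    dplyr::filter(.data$indicator %in% SHDI_INDICATORS) |>
    dplyr::select("gdlcode", "year", "indicator", "value") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "value")
  missing_cols <- setdiff(SHDI_INDICATORS, names(wide))
  if (length(missing_cols) > 0 || any(is.na(wide[SHDI_INDICATORS]))) {
    stop_completeness("panel must hold all four indicators for every cell")
  }
  gp_h <- goalpost_for(goalposts, "lifexp")
  gp_e <- goalpost_for(goalposts, "esch")
  gp_m <- goalpost_for(goalposts, "msch")
  wide |>
    dplyr::mutate(
      healthindex = dimension_index(.data$lifexp, gp_h[1], gp_h[2]),
      incindex = income_index(exp(.data$lgnic), goalposts),
      edindex = education_index(
        dimension_index(.data$esch, gp_e[1], gp_e[2]),
        dimension_index(.data$msch, gp_m[1], gp_m[2])
      ),
      shdi = shdi(.data$edindex, .data$healthindex, .data$incindex)
    ) |>
    dplyr::select("gdlcode", "year", "healthindex", "incindex",
                  "edindex", "shdi")
}
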