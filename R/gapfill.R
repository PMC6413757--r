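#' Plan how each year of a country-indicator series will be filled
#'
#' For every year of the window: years with real observations are kept;
#' interior missing years are linearly interpolated between the nearest
#' bracketing observed years; exterior missing years are filled by carrying
#' the nearest observed year (code 3 when the anchor lies in the future,
#' code 2 when it lies in the past); with no observations at all the
#' national value is used. Gap length is the distance to the anchor for
#' extrapolation and the larger of the two anchor distances for
#' interpolation.
#'
#' @param observed_years Integer years with real observations (possibly
#'   empty).
#' @param window Integer vector of years to cover.
#' @return Tibble `year`, `method` (`"real"`, `"interpolate"`,
#'   `"extrapolate-past"`, `"extrapolate-future"`, `"national"`),
#'   `anchor1`, `anchor2` (NA where unused), `gap_length`.
#' @export
plan_gaps <- function(observed_years, window) {
  if (length(window) == 0) stop_value("empty year window")
  window <- sort(as.integer(window))
  obs <- sort(as.integer(observed_years))
  plan_one <- function(t) {
    if (t %in% obs) {
      c(method = "real", anchor1 = t, anchor2 = NA, gap = 0)
    } else if (length(obs) == 0) {
      c(method = "national", anchor1 = NA, anchor2 = NA, gap = 0)
    } else if (t < min(obs)) {
      a <- min(obs)
      c(method = "extrapolate-future", anchor1 = a, anchor2 = NA,
        gap = a - t)
    } else if (t > max(obs)) {
      a <- max(obs)
      c(method = "extrapolate-past", anchor1 = a, anchor2 = NA,
        gap = t - a)
    } else {
      a <- max(obs[obs < t])
      b <- min(obs[obs > t])
      c(method = "interpolate", anchor1 = a, anchor2 = b,
        gap = max(t - a, b - t))
    }
  }
  rows <- t(vapply(window, plan_one, c(method = "", anchor1 = "",
                                       anchor2 = "", gap = "")))
  tibble(
    year = window,
    method = unname(rows[, "method"]),
    anchor1 = suppressWarnings(as.integer(rows[, "anchor1"])),
    anchor2 = suppressWarnings(as.integer(rows[, "anchor2"])),
    gap_length = as.integer(rows[, "gap"])
  )
}

#' Linear interpolation of a region's value between two anchor years
#'
#' @param value_a,value_b Values at the bracketing anchor years.
#' @param year_a,year_b Anchor years with `year_a < year_t < year_b`.
#' @param year_t Target year.
#' @return The linear blend; always within `[min(a, b), max(a, b)]`.
#' @export
interpolate_region <- function(value_a, value_b, year_a, year_b, year_t) {
  if (!(year_a < year_t && year_t < year_b)) {
    stop_value("anchors must strictly bracket the target year")
  }
  value_a + (value_b - value_a) * (year_t - year_a) / (year_b - year_a)
}

#' Carry a region's value from the nearest observed year
#'
#' The first step of the extrapolation procedure is a plain carry: the
#' regional value of the nearest observed year is used unchanged. The
#' temporal trend is supplied by the second step (rescaling to the target
#' year's national value), which preserves the regional ratios of the
#' nearest observed year.
#'
#' @param nearest_value Regional value(s) at the nearest observed year.
#' @return The same value(s).
#' @export
extrapolate_region <- function(nearest_value) nearest_value

#' Complete a gappy panel over the full year window
#'
#' The two-step fill: per country and indicator, missing years are first
#' estimated by linear interpolation between the nearest bracketing
#' observed years (interior gaps) or by carrying the nearest observed year
#' (exterior gaps); countries with no observations at all receive the
#' national value. Every country-year-indicator slice — filled or real — is
#' then rescaled so its population-weighted mean equals the national
#' reference value. Quality flags record the provenance of every cell.
#'
#' A year counts as observed for a country-indicator only when every
#' subnational region reports a value (the rescale needs the complete
#' cross-section); survey-driven gaps are country-wide so this is the
#' natural unit.
#'
#' @param panel Long panel with `observed` flags (masked cells hold `NA`).
#' @param national Complete national reference series over the window.
#' @param regions Region metadata with populations.
#' @param indicators Indicators to fill (default: the four index
#'   indicators).
#' @param income_space Scaling space for income, see [anchor_to_national()].
#' @return List with `panel` (complete, anchored), `flags` (long quality
#'   flags) and `coefficients` (scaling diagnostics).
#' @export
fill_panel <- function(panel, national, regions,
                       indicators = SHDI_INDICATORS,
                       income_space = c("log", "level")) {
  income_space <- match.arg(income_space)
  validate_regions(regions)
  sub_regions <- regions |>
    dplyr::filter(.data$level == "subnational")

  pieces <- list()
  flag_pieces <- list()
  for (iso in unique(sub_regions$iso_code)) {
    window <- as.integer(sort(national$year[national$iso_code == iso]))
    if (length(window) == 0 || anyDuplicated(window) > 0 ||
        any(diff(window) != 1L)) {
      stop_domain(paste0(
        "national series must be complete over the window for ", iso
      ))
    }
    gdl <- sub_regions$gdlcode[sub_regions$iso_code == iso]
    for (ind in indicators) {
      anchor <- national_anchor(national, iso, ind)
      if (any(is.na(anchor$national))) {
        stop_domain(paste0(
          "national series has a gap for ", iso, "/", ind
        ))
      }
      filled <- fill_country_indicator(
        panel, iso, ind, gdl, window, anchor
      )
      pieces[[paste(iso, ind)]] <- filled$panel
      flag_pieces[[paste(iso, ind)]] <- filled$flags
    }
  }
  unscaled <- dplyr::bind_rows(pieces)
  flags <- dplyr::bind_rows(flag_pieces) |>
    dplyr::arrange(.data$gdlcode, .data$indicator, .data$year)
  anchored <- anchor_to_national(unscaled, national, regions,
                                 income_space = income_space)
  list(
    panel = anchored$panel,
    flags = flags,
    coefficients = anchored$coefficients
  )
}

fill_country_indicator <- function(panel, iso, ind, gdl, window, anchor) {
  slice <- panel |>
    dplyr::filter(.data$gdlcode %in% gdl, .data$indicator == ind)
  # regions x years value matrix over the full window
  vals <- matrix(NA_real_, length(gdl), length(window),
                 dimnames = list(gdl, window))
  obs <- matrix(FALSE, length(gdl), length(window),
                dimnames = list(gdl, window))
  if (nrow(slice) > 0) {
    in_window <- slice$year %in% window
    idx <- cbind(
      match(slice$gdlcode[in_window], gdl),
      match(slice$year[in_window], window)
    )
    vals[idx] <- slice$value[in_window]
    obs[idx] <- slice$observed[in_window] & !is.na(slice$value[in_window])
  }
  observed_years <- window[colSums(obs) == length(gdl)]
  plan <- plan_gaps(observed_years, window)

  nat_val <- anchor$national[match(window, anchor$year)]
  out_vals <- vals
  for (k in seq_along(window)) {
    m <- plan$method[k]
    if (m == "real") next
    if (m == "national") {
      out_vals[, k] <- nat_val[k]
    } else if (m == "interpolate") {
      a <- match(plan$anchor1[k], window)
      b <- match(plan$anchor2[k], window)
      out_vals[, k] <- interpolate_region(
        vals[, a], vals[, b], window[a], window[b], window[k]
      )
    } else {
      a <- match(plan$anchor1[k], window)
      out_vals[, k] <- extrapolate_region(vals[, a])
    }
  }
  method_code <- c(
    "real" = 0L, "interpolate" = 1L, "extrapolate-past" = 2L,
    "extrapolate-future" = 3L, "national" = 4L
  )
  list(
    panel = tibble(
      gdlcode = rep(gdl, times = length(window)),
      year = rep(window, each = length(gdl)),
      indicator = ind,
      value = as.vector(out_vals),
      observed = rep(plan$method == "real", each = length(gdl))
    ),
    flags = tibble(
      gdlcode = rep(gdl, times = length(window)),
      year = rep(window, each = length(gdl)),
      indicator = ind,
      polated = rep(unname(method_code[plan$method]),
                    each = length(gdl)),
      polyears = rep(ifelse(plan$method %in% c("real", "national"),
                            0L, plan$gap_length),
                     each = length(gdl))
    )
  )
}
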