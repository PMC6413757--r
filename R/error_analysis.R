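#' Enumerate all inter/extrapolation simulations a set of observed years allows
#'
#' With observations in years `t1 < t2 < ... < tk`, every ordered pair
#' `(source, target)` yields an extrapolation simulation (forward and
#' backward), and every triple `a < t < b` of observed years yields an
#' interpolation simulation of the bracketed middle year. Gaps are bounded
#' (extrapolation 15 years, interpolation 10 — the interpolation gap is the
#' larger of the two anchor distances) because beyond those bounds the
#' number of simulations real data allows is too small to be informative.
#'
#' @param observed_years Integer vector of observed years.
#' @param max_extrap,max_interp Gap bounds in years.
#' @return Tibble `method`, `anchor1`, `anchor2` (NA for extrapolation),
#'   `target`, `gap`. Empty when fewer than two years are observed.
#' @export
enumerate_simulations <- function(observed_years, max_extrap = 15,
                                  max_interp = 10) {
  obs <- sort(unique(as.integer(observed_years)))
  empty <- tibble(
    method = character(), anchor1 = integer(), anchor2 = integer(),
    target = integer(), gap = integer()
  )
  if (length(obs) < 2) {
    return(empty)
  }
  pairs <- expand.grid(anchor1 = obs, target = obs)
  pairs <- pairs[pairs$anchor1 != pairs$target, ]
  pairs$gap <- abs(pairs$target - pairs$anchor1)
  pairs <- pairs[pairs$gap <= max_extrap, ]
  ext <- tibble(
    method = rep("extrapolation", nrow(pairs)),
    anchor1 = as.integer(pairs$anchor1), anchor2 = NA_integer_,
    target = as.integer(pairs$target), gap = as.integer(pairs$gap)
  )
  trip <- expand.grid(anchor1 = obs, target = obs, anchor2 = obs)
  trip <- trip[trip$anchor1 < trip$target & trip$target < trip$anchor2, ]
  trip$gap <- pmax(trip$target - trip$anchor1, trip$anchor2 - trip$target)
  trip <- trip[trip$gap <= max_interp, ]
  int <- tibble(
    method = rep("interpolation", nrow(trip)),
    anchor1 = as.integer(trip$anchor1),
    anchor2 = as.integer(trip$anchor2),
    target = as.integer(trip$target), gap = as.integer(trip$gap)
  )
  out <- dplyr::bind_rows(ext, int)
  if (nrow(out) == 0) empty else out
}

#' Relative error of a simulated value against the observed one
#'
#' `100 * |sim - obs| / obs`, in percent.
#'
#' @param simulated,observed Numeric vectors; `observed` must be nonzero.
#' @return Relative error in percent.
#' @export
#' @examples
#' relative_error(93, 100) # 7
relative_error <- function(simulated, observed) {
  if (any(is.na(observed)) || any(observed == 0)) {
    stop_domain("relative error is undefined for observed = 0")
  }
  100 * abs(simulated - observed) / observed
}

#' Simulated inter/extrapolation error study
#'
#' Quantifies the error introduced by the gap-filling procedures. Starting
#' from the really observed country-year cross-sections (anchored to the
#' national series, as in production), every feasible simulation is
#' enumerated per country and indicator: each observed year is re-estimated
#' from other observed years by the same two-step procedure used to fill
#' real gaps (carry or linear interpolation of the regional values, then
#' rescaling to the target year's national value). Each simulated regional
#' value is compared with the observed one via the relative-error formula,
#' and the pooled distributions are summarized per indicator, method and gap
#' length by their ventiles (centiles 5, 10, ..., 95; linear interpolation
#' between order statistics). Forward and backward extrapolations are
#' pooled. The study is pure enumeration: identical inputs give identical
#' tables.
#'
#' @param panel Long panel with `observed` flags (only observed cells are
#'   used).
#' @param national Complete national reference series.
#' @param regions Region metadata with populations.
#' @param indicators Indicators to study.
#' @param max_extrap,max_interp Gap bounds, see [enumerate_simulations()].
#' @param centiles Centiles to report (default ventiles 5–95).
#' @param income_space Scaling space for income, see [anchor_to_national()].
#' @return Long tibble `indicator`, `method`, `gap`, `centile`, `value`,
#'   `n` (number of pooled region-level errors behind each ventile row).
#'   Cells with an observed value of zero are excluded with a counted
#'   warning.
#' @export
error_study <- function(panel, national, regions,
                        indicators = SHDI_INDICATORS,
                        max_extrap = 15, max_interp = 10,
                        centiles = seq(5, 95, by = 5),
                        income_space = c("log", "level")) {
  income_space <- match.arg(income_space)
  sub_regions <- regions |>
    dplyr::filter(.data$level == "subnational")
  obs_panel <- panel |>
    dplyr::filter(.data$observed, !is.na(.data$value),
                  .data$indicator %in% indicators)

  errors <- list()
  n_zero <- 0L
  for (iso in unique(sub_regions$iso_code)) {
    gdl <- sub_regions$gdlcode[sub_regions$iso_code == iso]
    pop <- sub_regions$population[sub_regions$iso_code == iso]
    for (ind in indicators) {
      slice <- obs_panel |>
        dplyr::filter(.data$gdlcode %in% gdl, .data$indicator == ind)
      if (nrow(slice) == 0) next
      counts <- table(slice$year)
      years_ok <- as.integer(names(counts)[counts == length(gdl)])
      if (length(years_ok) < 2) next
      anchor <- national_anchor(national, iso, ind)
      nat <- setNames(anchor$national, anchor$year)
      vals <- matrix(NA_real_, length(gdl), length(years_ok),
                     dimnames = list(gdl, years_ok))
      vals[cbind(match(slice$gdlcode, gdl),
                 match(slice$year, years_ok))] <- slice$value
      vals <- vals[, !is.na(nat[as.character(years_ok)]), drop = FALSE]
      years_ok <- as.integer(colnames(vals))
      if (length(years_ok) < 2) next
      # anchor the observed cross-sections to the national series
      for (k in seq_along(years_ok)) {
        cc <- scaling_coefficient(vals[, k], pop,
                                  nat[[as.character(years_ok[k])]])
        vals[, k] <- apply_scaling(vals[, k], cc)
      }
      sims <- enumerate_simulations(years_ok, max_extrap, max_interp)
      if (nrow(sims) == 0) next
      res <- lapply(seq_len(nrow(sims)), function(j) {
        s <- sims[j, ]
        raw <- if (s$method == "extrapolation") {
          extrapolate_region(vals[, as.character(s$anchor1)])
        } else {
          interpolate_region(
            vals[, as.character(s$anchor1)],
            vals[, as.character(s$anchor2)],
            s$anchor1, s$anchor2, s$target
          )
        }
        target_nat <- nat[[as.character(s$target)]]
        sim <- apply_scaling(raw, scaling_coefficient(raw, pop, target_nat))
        obs <- vals[, as.character(s$target)]
        keep <- obs != 0
        n_zero <<- n_zero + sum(!keep)
        tibble(
          indicator = ind, method = s$method, gap = s$gap,
          error = relative_error(sim[keep], obs[keep])
        )
      })
      errors[[paste(iso, ind)]] <- dplyr::bind_rows(res)
    }
  }
  if (n_zero > 0) {
    warn(paste0(n_zero, " cell(s) with observed value 0 excluded from the",
                " relative-error study"))
  }
  all_err <- dplyr::bind_rows(errors)
  if (nrow(all_err) == 0) {
    return(tibble(
      indicator = character(), method = character(), gap = integer(),
      centile = numeric(), value = numeric(), n = integer()
    ))
  }
  all_err |>
    dplyr::group_by(.data$indicator, .data$method, .data$gap) |>
    dplyr::reframe(
      centile = centiles,
      value = unname(quantile(.data$error, probs = centiles / 100,
                              type = 7)),
      n = length(.data$error)
    ) |>
    dplyr::arrange(.data$indicator, .data$method, .data$gap, .data$centile)
}
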