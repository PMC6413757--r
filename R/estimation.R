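#' Impute expected years of schooling from mean years of schooling
#'
#' Where expected years of schooling is unavailable subnationally, the
#' regional variation of mean years of schooling is applied to the national
#' expected-years value: `E_i = E_n * M_i / M_n` for region `i` with
#' national anchors `E_n`, `M_n`. The result is capped at the EYS goalpost
#' downstream, not here. The formula is scale-equivariant in the mean-years
#' unit: multiplying all MYS values by a constant leaves it unchanged.
#'
#' @param mys_region Regional mean years of schooling (vectorized).
#' @param mys_national National mean years of schooling (> 0).
#' @param eys_national National expected years of schooling.
#' @return Imputed regional expected years of schooling.
#' @export
#' @examples
#' impute_eys(10, 8, 12) # 15
impute_eys <- function(mys_region, mys_national, eys_national) {
  if (any(is.na(mys_national)) || any(mys_national <= 0)) {
    stop_domain("national mean years of schooling must be > 0")
  }
  eys_national * mys_region / mys_national
}

#' Expected years of schooling from age-specific attendance shares
#'
#' The sum over single ages 6–24 of the share of children of that age
#' attending school: the number of schooling years a child entering at age 6
#' can expect if prevailing enrolment patterns persist. Nineteen shares,
#' each in \[0, 1\], so the raw value is at most 19 (goalpost capping is a
#' separate, downstream step).
#'
#' @param shares Numeric vector of 19 attendance shares for ages 6–24.
#' @return Expected years of schooling.
#' @export
eys_from_enrolment <- function(shares) {
  if (length(shares) != 19) {
    stop_value("need 19 attendance shares, one per age 6-24")
  }
  if (any(is.na(shares)) || any(shares < 0 | shares > 1)) {
    stop_domain("attendance shares must lie in [0, 1]")
  }
  sum(shares)
}

#' Convert highest-attainment categories to years of schooling
#'
#' Lookup used when education is recorded as completed levels rather than
#' years: by default primary counts 6 years, lower secondary 9, upper
#' secondary 12, a bachelor degree 15 and a master degree 16 (none 0). The
#' schedule is configurable per country.
#'
#' @param levels Character vector of attainment categories.
#' @param schedule Named numeric vector mapping category to years.
#' @return Years of schooling.
#' @export
attainment_to_years <- function(levels,
                                schedule = c(none = 0, primary = 6,
                                             lower_secondary = 9,
                                             upper_secondary = 12,
                                             bachelor = 15, master = 16)) {
  unknown <- setdiff(unique(levels), names(schedule))
  if (length(unknown) > 0) {
    stop_value(paste0(
      "unknown attainment level(s): ", paste(unknown, collapse = ", ")
    ))
  }
  unname(schedule[levels])
}

#' Fit a national-level proxy bridge model
#'
#' Ordinary least squares explaining a national indicator (life expectancy
#' or log income per capita) from a proxy covariate (under-five mortality or
#' the wealth index), with a linear year control and optional global-region
#' and special-case indicator terms. The proxy enters linearly or with an
#' added quadratic term.
#'
#' @param data Tibble with the target and proxy columns, a `year` column,
#'   and any group/flag columns named below.
#' @param target,proxy Column names of the response and proxy.
#' @param formula `"linear"` or `"quadratic"` in the proxy.
#' @param year Include a linear year covariate (default `TRUE`).
#' @param group_col Optional column name holding a global-region grouping
#'   (entered as a factor).
#' @param flag_cols Optional character vector of 0/1 indicator columns
#'   (special cases such as oil exporters).
#' @return A `shdikit_bridge` object: the `lm` fit plus `coefficients`,
#'   `r2`, `adj_r2`, `n`, and the model description.
#' @export
fit_bridge <- function(data, target, proxy,
                       formula = c("linear", "quadratic"),
                       year = TRUE, group_col = NULL, flag_cols = NULL) {
  formula <- match.arg(formula)
  used <- c(target, proxy, if (year) "year", group_col, flag_cols)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    stop_schema(paste0(
      "bridge data is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- data[stats::complete.cases(data[used]), ]
  terms <- c(
    proxy,
    if (formula == "quadratic") paste0("I(", proxy, "^2)"),
    if (year) "year",
    if (!is.null(group_col)) paste0("factor(", group_col, ")"),
    flag_cols
  )
  fml <- stats::as.formula(paste(target, "~", paste(terms, collapse = " + ")))
  n_par <- length(terms) + 1
  if (nrow(data) < n_par + 2) {
    stop_domain("need at least two more observations than parameters")
  }
  fit <- lm(fml, data = data)
  cf <- coef(fit)
  if (any(is.na(cf))) {
    stop_domain(paste0(
      "rank-deficient bridge design; collinear term(s): ",
      paste(names(cf)[is.na(cf)], collapse = ", ")
    ))
  }
  sm <- summary(fit)
  structure(
    list(
      target = target, proxy = proxy, formula = formula,
      year = year, group_col = group_col, flag_cols = flag_cols,
      fit = fit, coefficients = cf,
      se = sm$coefficients[, "Std. Error"],
      r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
      n = nrow(data)
    ),
    class = "shdikit_bridge"
  )
}

#' @export
print.shdikit_bridge <- function(x, ...) {
  cat("Bridge model: ", x$target, " ~ ", x$proxy,
      if (x$formula == "quadratic") paste0(" + ", x$proxy, "^2"),
      if (x$year) " + year",
      if (!is.null(x$group_col)) " + region group",
      "\n", sep = "")
  cat(sprintf("n = %d, R2 = %.4f, adjusted R2 = %.4f\n",
              x$n, x$r2, x$adj_r2))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Select between a linear and a quadratic bridge by adjusted R-squared
#'
#' Fits both proxy forms on the same data and keeps the one with the higher
#' adjusted R-squared.
#'
#' @inheritParams fit_bridge
#' @return The selected `shdikit_bridge`, with a `comparison` attribute
#'   holding both adjusted R-squared values.
#' @export
select_bridge <- function(data, target, proxy, year = TRUE,
                          group_col = NULL, flag_cols = NULL) {
  lin <- fit_bridge(data, target, proxy, "linear", year, group_col,
                    flag_cols)
  quad <- fit_bridge(data, target, proxy, "quadratic", year, group_col,
                     flag_cols)
  pick <- if (quad$adj_r2 > lin$adj_r2) quad else lin
  attr(pick, "comparison") <- tibble(
    formula = c("linear", "quadratic"),
    adj_r2 = c(lin$adj_r2, quad$adj_r2)
  )
  pick
}

#' Predict a subnational indicator from a fitted bridge model
#'
#' Applies the national-level bridge to regional proxy values. Raw
#' predictions are clipped to the indicator's validity range; national
#' anchoring (the scaling module) is the caller's next step and supplies the
#' final consistency with the national series. Cells whose proxy value is
#' missing are not silently dropped: they are returned in the `gaps`
#' attribute.
#'
#' @param model A `shdikit_bridge`.
#' @param proxy_panel Long panel rows of the model's proxy indicator,
#'   carrying any group/flag columns the model was fitted with.
#' @return Panel rows for the target indicator (same `gdlcode`/`year`,
#'   `observed` inherited from the proxy), with attribute `gaps`.
#' @export
predict_subnational <- function(model, proxy_panel) {
  rows <- proxy_panel[proxy_panel$indicator == model$proxy, ]
  if (nrow(rows) == 0) {
    stop_value(paste0("no rows of proxy indicator ", model$proxy))
  }
  gaps <- rows[is.na(rows$value), c("gdlcode", "year", "indicator")]
  rows <- rows[!is.na(rows$value), ]
  newdata <- rows
  names(newdata)[names(newdata) == "value"] <- model$proxy
  pred <- predict(model$fit, newdata = newdata)
  out <- rows
  out$indicator <- model$target
  out$value <- clip_range(as.numeric(pred), indicator_range(model$target))
  attr(out, "gaps") <- gaps
  out
}

#' Fill an indicator with the national value for every region
#'
#' Last-resort path when a country has no subnational information for an
#' indicator at all: every region receives the national value, flagged with
#' provenance code 4 (national value used, gap length 0).
#'
#' @param national_values National value(s), one per year (recycled if
#'   scalar).
#' @param years Years to fill.
#' @param gdlcodes Region codes of the country's subnational regions.
#' @param indicator Indicator name.
#' @return List with `panel` rows (`observed = FALSE`) and `flags`.
#' @export
fallback_national <- function(national_values, years, gdlcodes, indicator) {
  stopifnot(length(national_values) %in% c(1, length(years)))
  vals <- rep(national_values, length.out = length(years))
  panel <- tibble(
    gdlcode = rep(gdlcodes, each = length(years)),
    year = rep(as.integer(years), times = length(gdlcodes)),
    indicator = indicator,
    value = rep(vals, times = length(gdlcodes)),
    observed = FALSE
  )
  flags <- tibble(
    gdlcode = panel$gdlcode, year = panel$year, indicator = indicator,
    polated = 4L, polyears = 0L
  )
  list(panel = panel, flags = flags)
}
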