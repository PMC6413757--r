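test_that("expected-years imputation follows the ratio formula", {
  expect_equal(impute_eys(8, 8, 12), 12) # equal MYS -> national EYS
  expect_equal(impute_eys(10, 8, 12), 15) # 12 * 10 / 8
  expect_equal(impute_eys(0, 8, 12), 0)
  expect_error(impute_eys(10, 0, 12), class = "shdikit_domain_error")
  # scale equivariance: multiplying all MYS by k changes nothing
  expect_equal(impute_eys(10 * 3, 8 * 3, 12), impute_eys(10, 8, 12))
  # vectorized over regions
  expect_equal(impute_eys(c(4, 8, 12), 8, 12), c(6, 12, 18))
})

test_that("expected years from enrolment is the sum of 19 age shares", {
  shares <- rep(0.8, 19)
  expect_equal(eys_from_enrolment(shares), 15.2)
  expect_equal(eys_from_enrolment(rep(1, 19)), 19) # cap happens downstream
  expect_error(eys_from_enrolment(rep(0.5, 18)),
               class = "shdikit_value_error")
  expect_error(eys_from_enrolment(c(rep(0.5, 18), 1.2)),
               class = "shdikit_domain_error")
})

test_that("attainment categories convert through the schooling schedule", {
  expect_equal(
    attainment_to_years(c("primary", "upper_secondary", "master")),
    c(6, 12, 16)
  )
  expect_error(attainment_to_years("doctorate"),
               class = "shdikit_value_error")
})

test_that("a noise-free linear relation is fitted perfectly", {
  set.seed(2)
  d <- tibble::tibble(
    iwi = runif(50, 10, 90), year = rep(2000:2009, 5)
  )
  d$lgnic <- 4.6 + 0.066 * d$iwi + 0.002 * d$year
  # a perfect fit triggers the summary.lm reliability warning by design
  fit <- suppressWarnings(
    fit_bridge(d, "lgnic", "iwi", formula = "linear", year = TRUE)
  )
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[c("iwi", "year")]),
               c(0.066, 0.002), tolerance = 1e-8)
})

test_that("adjusted R2 selects the quadratic form on quadratic data", {
  d <- simulate_bridge_data("lifexp", n_countries = 36, years = 1990:2017,
                            seed = 8)
  pick <- select_bridge(d, "lifexp", "u5m")
  expect_equal(pick$formula, "quadratic")
  cmp <- attr(pick, "comparison")
  expect_gt(cmp$adj_r2[cmp$formula == "quadratic"],
            cmp$adj_r2[cmp$formula == "linear"])
})

test_that("bridge coefficients are recovered within 3 SE on clean data", {
  p <- default_bridge_params()$u5m
  d <- simulate_bridge_data("lifexp", n_countries = 72, years = 1990:2017,
                            seed = 13)
  fit <- fit_bridge(d, "lifexp", "u5m", formula = "quadratic")
  truth <- c("(Intercept)" = p$intercept + p$year_coef * (-2000),
             u5m = p$linear, "I(u5m^2)" = p$quad, year = p$year_coef)
  for (nm in c("u5m", "I(u5m^2)", "year")) {
    expect_lt(abs(fit$coefficients[[nm]] - truth[[nm]]), 3 * fit$se[[nm]])
  }
})

test_that("coefficient bias shrinks as the sample grows", {
  p <- default_bridge_params()$u5m
  err_at <- function(n) {
    errs <- vapply(1:5, function(s) {
      d <- simulate_bridge_data("lifexp", n_countries = n, seed = 100 + s)
      f <- fit_bridge(d, "lifexp", "u5m", formula = "quadratic")
      abs(f$coefficients[["u5m"]] - p$linear)
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(120), err_at(8))
})

test_that("rank-deficient designs fail loudly naming the collinear term", {
  d <- tibble::tibble(iwi = rep(50, 30), year = rep(2000:2009, 3))
  d$lgnic <- 4.6 + 0.002 * d$year + rnorm(30, 0, 0.01)
  expect_error(fit_bridge(d, "lgnic", "iwi", formula = "linear"),
               "iwi", class = "shdikit_domain_error")
})

test_that("subnational predictions follow the fitted curve", {
  d <- simulate_bridge_data("lifexp", n_countries = 36, seed = 17)
  fit <- fit_bridge(d, "lifexp", "u5m", formula = "quadratic")
  proxy <- tibble::tibble(
    gdlcode = c("Xr01", "Xr02", "Xr03"), year = 2005,
    indicator = "u5m", value = c(50, 50, 120), observed = TRUE
  )
  pred <- predict_subnational(fit, proxy)
  expect_equal(pred$indicator, rep("lifexp", 3))
  # equal proxy values -> identical predictions within the country-year
  expect_equal(pred$value[1], pred$value[2])
  # monotone branch: higher mortality -> lower predicted life expectancy
  expect_lt(pred$value[3], pred$value[1])
})

test_that("missing proxy cells are reported, not dropped silently", {
  d <- simulate_bridge_data("lifexp", n_countries = 36, seed = 17)
  fit <- fit_bridge(d, "lifexp", "u5m", formula = "quadratic")
  proxy <- tibble::tibble(
    gdlcode = c("Xr01", "Xr02"), year = 2005,
    indicator = "u5m", value = c(50, NA), observed = c(TRUE, FALSE)
  )
  pred <- predict_subnational(fit, proxy)
  expect_equal(nrow(pred), 1)
  gaps <- attr(pred, "gaps")
  expect_equal(gaps$gdlcode, "Xr02")
})

test_that("national fallback fills all regions and flags code 4", {
  fb <- fallback_national(72.0, 2000:2001, c("Xr01", "Xr02", "Xr03"),
                          "lifexp")
  expect_equal(nrow(fb$panel), 6)
  expect_true(all(fb$panel$value == 72.0))
  expect_true(all(fb$flags$polated == 4L))
  expect_true(all(fb$flags$polyears == 0L))
  # weighted mean equals the national value exactly, any weights
  expect_equal(
    weighted_mean(fb$panel$value[fb$panel$year == 2000], c(1, 5, 2)), 72.0
  )
})
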