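test_that("prevalent years run from first A10 delivery to death or period end", {
  claims <- dplyr::bind_rows(
    year_claims("alive", 2002, 4),
    year_claims("dead", 1998, 4),
    year_claims("late", 2006, 4)
  )
  persons <- make_persons(c("alive", "dead", "late"),
                          death_date = as.Date(c(NA, "2003-06-15", NA)))
  cy <- case_years(c("alive", "dead", "late"), claims, persons)
  expect_equal(cy$year[cy$patient_id == "alive"], 2002:2006)
  # first delivery 1998: prevalent from the period start, death year inclusive
  expect_equal(cy$year[cy$patient_id == "dead"], 2000:2003)
  expect_equal(cy$year[cy$patient_id == "late"], 2006L)

  # a death before the first delivery is a data inconsistency
  bad_persons <- make_persons("alive", death_date = as.Date("2000-01-01"))
  expect_error(case_years("alive", claims, bad_persons), "death before first delivery")

  # removing a death date never shrinks the prevalent years
  cy2 <- case_years(c("alive", "dead", "late"), claims,
                    make_persons(c("alive", "dead", "late")))
  expect_true(all(cy$year[cy$patient_id == "dead"] %in%
                    cy2$year[cy2$patient_id == "dead"]))
})

test_that("annual prevalence divides prevalent cases by the covered population", {
  cy <- tibble::tibble(patient_id = c("a", "b", "a"), year = c(2000L, 2000L, 2001L))
  den <- tibble::tibble(year = 2000:2001, sex = "all", age_class = "all",
                        population = c(100L, 100L))
  ps <- annual_prevalence(cy, den)
  expect_s3_class(ps, "prevalence_series")
  expect_equal(ps$rate, c(2, 1))
  expect_error(annual_prevalence(cy, den[1, ]), "2001")
  # zero cases in a covered year
  expect_equal(annual_prevalence(cy[0, ], den, years = 2000)$rate, 0)
})

test_that("published national counts give the published rates", {
  ref <- lux_reference_counts()
  ann <- ref[!is.na(ref$year), ]
  ps <- prevalence_series(ann$year, ann$treated_type2, ann$initial_population)
  expect_equal(round_half_up(ps$rate[ps$year == 2000], 2), 3.15)
  expect_equal(round_half_up(ps$rate[ps$year == 2006], 2), 3.79)
  expect_equal(round_half_up(mean_annual_increase(ps), 1), 3.2)
  expect_gte(linear_trend_r2(ps), 0.95)
})

test_that("stratified numerators partition the annual numerator", {
  sim <- simulate_population(simulation_config(n_population = 1500, seed = 21))
  cases <- detect_cases(count_deliveries(sim$claims, "A10", c(1995, 2006)),
                        sim$persons)
  split <- split_by_oha(cases, sim$claims)
  t2 <- classify_type2(split, 66L, sim$claims, sim$persons)
  cy <- case_years(t2, sim$claims, sim$persons)
  den <- denominators_from_persons(sim$persons, 2000:2006)
  strat <- stratified_prevalence(cy, sim$persons, den, 2005)
  expect_equal(sum(strat$cases), sum(cy$year == 2005))
  expect_true(all(strat$rate >= 0 & strat$rate <= 100))
  # simulated onset is concentrated in mid-to-late adulthood
  young <- strat[strat$age_class %in% c("0-9", "10-19", "20-29"), ]
  older <- strat[strat$age_class %in% c("50-59", "60-69", "70-79"), ]
  expect_lt(sum(young$cases), sum(older$cases))
})

test_that("direct age-standardization is a convex combination of class rates", {
  standard <- tibble::tibble(age_class = c("young", "old"), weight = c(0.5, 0.5))
  rates <- tibble::tibble(age_class = c("young", "old"), rate = c(2, 4))
  expect_equal(age_standardize(rates, standard), 3)
  # uniform rates are reproduced whatever the weights
  expect_equal(age_standardize(c(young = 5, old = 5), standard), 5)
  expect_error(age_standardize(c(young = 5), standard), "old")
  expect_warning(age_standardize(c(young = 5), standard, impute_zero = TRUE), "old")

  set.seed(8)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    w <- rdirichlet_flat(k)
    r <- stats::runif(k, 0, 20)
    cls <- paste0("c", 1:k)
    std <- tibble::tibble(age_class = cls, weight = w)
    out <- age_standardize(stats::setNames(r, cls), std)
    expect_gte(out, min(r) - 1e-12)
    expect_lte(out, max(r) + 1e-12)
  }

  # standardizing with the population's own structure recovers the crude rate
  pop <- c(a = 300, b = 500, c = 200)
  cases <- c(a = 3, b = 20, c = 30)
  own_std <- tibble::tibble(age_class = names(pop), weight = pop / sum(pop))
  crude <- 100 * sum(cases) / sum(pop)
  expect_equal(age_standardize(stats::setNames(100 * cases / pop, names(pop)), own_std),
               crude)
})

test_that("mean annual increase summarizes relative year-over-year change", {
  expect_equal(mean_annual_increase(c(1, 1.1, 1.21)), 10)
  expect_equal(mean_annual_increase(rep(2, 5)), 0)
  expect_equal(mean_annual_increase(c(1, 1.1, 1.21), method = "geometric"), 10)
  expect_error(mean_annual_increase(5), "two years")
  expect_error(mean_annual_increase(c(1, 0, 2)), "positive")
})

test_that("linear trend R-squared behaves at the extremes", {
  expect_equal(suppressWarnings(linear_trend_r2(2 + 0.3 * (1:8))), 1)
  expect_warning(r2 <- linear_trend_r2(rep(3, 5)), "constant")
  expect_true(is.na(r2))
  set.seed(14)
  expect_lt(linear_trend_r2(stats::rnorm(200)), 0.1)
})

test_that("double exponential smoothing is exact on linear series", {
  x <- 3 + 0.25 * (0:11)
  fit <- fit_des(x)
  # the in-sample RMSE keeps the initialization transient, but the final
  # state has converged to the line and forecasts continue it
  expect_equal(unname(predict(fit, h = 1:3)), 3 + 0.25 * (12:14), tolerance = 1e-9)
  # constant series forecasts the constant
  fit_c <- fit_des(rep(4, 6))
  expect_equal(unname(predict(fit_c, h = 1:2)), c(4, 4), tolerance = 1e-9)
})

test_that("alpha selection equals the brute-force grid argmin", {
  set.seed(99)
  for (i in 1:10) {
    x <- cumsum(stats::rnorm(12, mean = 0.3)) + 5
    grid <- seq(0.05, 0.95, by = 0.05)
    fit <- fit_des(x, grid)
    rmse <- vapply(grid, function(a) oracle_des_rmse(x, a), numeric(1))
    expect_equal(fit$alpha, grid[which.min(rmse)])
    expect_equal(fit$rmse, min(rmse), tolerance = 1e-12)
  }
  expect_error(fit_des(1:10, numeric(0)), "empty")
})

test_that("forecast error on noisy linear series is bounded by the noise scale", {
  set.seed(4)
  sigma <- 0.05
  errs <- replicate(20, {
    x <- 1 + 0.1 * (1:10) + stats::rnorm(10, sd = sigma)
    truth <- 1 + 0.1 * 12
    abs(predict(fit_des(x), h = 2)[[1]] - truth)
  })
  expect_lt(stats::median(errs), 10 * sigma)
})
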