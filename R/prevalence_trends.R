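#' Prevalent years per classified case
#'
#' A case counts as treated type-2-prevalent in every calendar year from the
#' year of their first A10 delivery (searched over the full claims horizon)
#' until the end of the reporting period or their death, whichever comes
#' first. The death year itself counts: patients treated in the year they
#' die are prevalent that year.
#'
#' @param type2 Tibble from [classify_type2()], or a character vector of
#'   patient ids.
#' @param claims Claims tibble (used to locate each case's first A10
#'   delivery).
#' @param persons Persons tibble (death dates).
#' @param period Two years, the reporting period; default `c(2000, 2006)`.
#' @return A long tibble `(patient_id, year)`, one row per prevalent
#'   patient-year within `period`.
#' @export
case_years <- function(type2, claims, persons, period = c(2000L, 2006L)) {
  ids <- case_ids(type2)
  period <- assert_year_range(period)
  a10 <- claims[atc_matches(claims$atc_code, "A10") & claims$patient_id %in% ids, ,
                drop = FALSE]
  if (!all(ids %in% a10$patient_id)) {
    stop("every case must have at least one A10 delivery", call. = FALSE)
  }
  first <- tapply(claim_year(a10$delivery_date), a10$patient_id, min)
  dy <- death_years(persons)
  res <- lapply(ids, function(id) {
    f <- first[[id]]
    d <- if (id %in% names(dy)) dy[[id]] else NA_integer_
    if (!is.na(d) && d < f) {
      stop("death before first delivery for patient ", id, call. = FALSE)
    }
    last <- min(period[2], if (is.na(d)) period[2] else d)
    first_rep <- max(f, period[1])
    if (first_rep > last) return(NULL)  # e.g. died before the reporting period
    yrs <- seq.int(first_rep, last)
    tibble::tibble(patient_id = id, year = as.integer(yrs))
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) out <- tibble::tibble(patient_id = character(0), year = integer(0))
  out
}

#' Build a prevalence series from counts
#'
#' @param year Integer vector of years.
#' @param cases Numerator counts (prevalent treated patients).
#' @param population Denominator counts (covered population on 31 December).
#' @return A tibble `(year, cases, population, rate)` of class
#'   `prevalence_series`; `rate` is in percent.
#' @examples
#' prevalence_series(2000, 13152, 418182)
#' @export
prevalence_series <- function(year, cases, population) {
  stopifnot(length(year) == length(cases), length(cases) == length(population),
            all(cases >= 0), all(population > 0), all(cases <= population))
  out <- tibble::tibble(
    year = as.integer(year), cases = cases, population = population,
    rate = 100 * cases / population
  )
  class(out) <- c("prevalence_series", class(out))
  out
}

#' Annual treated-prevalence rates
#'
#' Prevalence for year X is the number of cases prevalent in X divided by
#' the covered resident population on 31 December of X (the `"all"` sex and
#' age-class row of the denominator table).
#'
#' @param case_years_tbl Output of [case_years()].
#' @param denominators Denominator tibble (see [read_denominators()]).
#' @param years Years to report; default every year present in
#'   `case_years_tbl`.
#' @return A [prevalence_series()] tibble.
#' @export
annual_prevalence <- function(case_years_tbl, denominators, years = NULL) {
  years <- as.integer(years %||% sort(unique(case_years_tbl$year)))
  den <- denominators[denominators$sex == "all" & denominators$age_class == "all", ]
  missing_years <- setdiff(years, den$year)
  if (length(missing_years)) {
    stop("no denominator for year(s): ", paste(missing_years, collapse = ", "),
         call. = FALSE)
  }
  num <- vapply(years, function(y) sum(case_years_tbl$year == y), numeric(1))
  pop <- den$population[match(years, den$year)]
  prevalence_series(years, num, pop)
}

#' Sex- and/or age-stratified prevalence for one year
#'
#' Ages are computed as `year - birth_year` and assigned to classes with
#' [age_class_label()]. Cases with a missing stratifying variable are
#' excluded with a message.
#'
#' @param case_years_tbl Output of [case_years()].
#' @param persons Persons tibble.
#' @param denominators Denominator tibble with the matching strata.
#' @param year The year to stratify.
#' @param by Character subset of `c("sex", "age_class")`.
#' @param age_breaks Passed to [age_class_label()].
#' @return A tibble with the stratum keys and `(cases, population, rate)`.
#' @export
stratified_prevalence <- function(case_years_tbl, persons, denominators, year,
                                  by = c("sex", "age_class"),
                                  age_breaks = seq(0, 100, by = 10)) {
  by <- match.arg(by, c("sex", "age_class"), several.ok = TRUE)
  year <- as.integer(year)
  ids <- case_years_tbl$patient_id[case_years_tbl$year == year]
  info <- persons[match(ids, persons$patient_id), ]
  info$age_class <- age_class_label(year - info$birth_year, age_breaks)
  drop <- apply(is.na(info[, by, drop = FALSE]), 1, any)
  if (any(drop)) {
    message(sum(drop), " case(s) with missing ", paste(by, collapse = "/"),
            " excluded from stratified prevalence")
    info <- info[!drop, ]
  }
  num <- dplyr::count(info, dplyr::across(dplyr::all_of(by)), name = "cases")
  den <- denominators[denominators$year == year, ]
  if (!"sex" %in% by) den <- den[den$sex == "all", ] else den <- den[den$sex != "all", ]
  if (!"age_class" %in% by) {
    den <- den[den$age_class == "all", ]
  } else {
    den <- den[den$age_class != "all", ]
  }
  out <- dplyr::left_join(num, den[c(by, "population")], by = by)
  if (any(is.na(out$population))) {
    bad <- out[is.na(out$population), by, drop = FALSE]
    stop("no denominator for stratum: ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = "; "),
         call. = FALSE)
  }
  out$year <- year
  out$rate <- 100 * out$cases / out$population
  out[c("year", by, "cases", "population", "rate")]
}

#' Direct age-standardization
#'
#' Weighted average of age-class-specific rates using a fixed reference
#' population's age weights (e.g. the EU15 structure), making rates
#' comparable across populations with different age pyramids.
#'
#' @param stratum_rates Tibble `(age_class, rate)` or a named numeric vector
#'   of rates per age class.
#' @param standard Tibble `(age_class, weight)` (see
#'   [read_standard_population()]).
#' @param impute_zero If `TRUE`, standard classes without a rate contribute
#'   0 with a warning instead of erroring.
#' @return The standardized rate (same units as the input rates).
#' @export
age_standardize <- function(stratum_rates, standard, impute_zero = FALSE) {
  if (is.data.frame(stratum_rates)) {
    rates <- stats::setNames(stratum_rates$rate, stratum_rates$age_class)
  } else {
    rates <- stratum_rates
  }
  missing_cls <- setdiff(standard$age_class, names(rates))
  if (length(missing_cls)) {
    if (!impute_zero) {
      stop("no rate for standard age class(es): ",
           paste(missing_cls, collapse = ", "), call. = FALSE)
    }
    warning("rate imputed as 0 for age class(es): ",
            paste(missing_cls, collapse = ", "), call. = FALSE)
    rates[missing_cls] <- 0
  }
  extra <- setdiff(names(rates), standard$age_class)
  if (length(extra)) {
    stop("rate given for class(es) absent from the standard: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  sum(standard$weight * rates[standard$age_class])
}

#' Mean annual increase of a rate series
#'
#' Arithmetic mean of the year-over-year relative changes,
#' `100 * mean(rate_t / rate_(t-1) - 1)`; the geometric variant is the
#' constant growth rate compounding to the same endpoint.
#'
#' @param series A [prevalence_series()] or numeric rate vector (in year
#'   order, consecutive years).
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return Percent per year.
#' @export
mean_annual_increase <- function(series, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  r <- rate_vector(series)
  n <- length(r)
  if (n < 2) stop("need at least two years", call. = FALSE)
  if (any(r[-n] <= 0)) stop("rates must be positive throughout the series", call. = FALSE)
  if (method == "arithmetic") {
    100 * mean(r[-1] / r[-n] - 1)
  } else {
    100 * ((r[n] / r[1])^(1 / (n - 1)) - 1)
  }
}

#' R-squared of the linear trend
#'
#' Ordinary least-squares fit of rate on year; the R-squared quantifies how
#' linear the observed trend is (a prerequisite for projecting it with a
#' trend-following smoother).
#'
#' @param series A [prevalence_series()] or numeric rate vector.
#' @return R-squared in `[0, 1]`; `NA` with a warning when the rates have
#'   zero variance.
#' @export
linear_trend_r2 <- function(series) {
  r <- rate_vector(series)
  if (length(r) < 3) stop("need at least three years", call. = FALSE)
  if (stats::var(r) == 0) {
    warning("rates are constant; R-squared undefined", call. = FALSE)
    return(NA_real_)
  }
  t <- seq_along(r)
  summary(stats::lm(r ~ t))$r.squared
}

#' Brown's double exponential smoothing with RMSE-minimizing alpha
#'
#' Fits Brown's one-parameter double exponential smoothing (two coupled
#' exponentially-weighted averages, yielding a local level and a local
#' linear trend) for each alpha on a grid, scores each fit by its in-sample
#' one-step-ahead root-mean-square error, and keeps the alpha with the
#' lowest RMSE. Both smoothed statistics are initialized at the first
#' observation. Forecasts are linear in the horizon:
#' `forecast(h) = level + h * trend` from the final state.
#'
#' @param series A [prevalence_series()] or numeric rate vector (>= 3
#'   observations).
#' @param alpha_grid Candidate smoothing constants in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return An object of class `des_fit` with elements `alpha`, `level`,
#'   `trend`, `rmse`, `fitted` (one-step-ahead forecasts aligned with the
#'   input), `alpha_grid`, `rmse_grid`, `data` and `last_year` (when the
#'   input is a series).
#' @seealso [predict.des_fit()]
#' @export
fit_des <- function(series, alpha_grid = seq(0.05, 0.95, by = 0.05)) {
  x <- rate_vector(series)
  if (length(x) < 3) stop("need at least three observations", call. = FALSE)
  if (!length(alpha_grid)) stop("alpha grid is empty", call. = FALSE)
  stopifnot(all(alpha_grid > 0 & alpha_grid < 1))
  passes <- lapply(alpha_grid, des_pass, x = x)
  rmse_grid <- vapply(passes, `[[`, numeric(1), "rmse")
  best <- which.min(rmse_grid)
  fit <- passes[[best]]
  structure(
    list(alpha = alpha_grid[best], level = fit$level, trend = fit$trend,
         rmse = fit$rmse, fitted = fit$fitted,
         alpha_grid = alpha_grid, rmse_grid = rmse_grid, data = x,
         last_year = if (is.data.frame(series)) max(series$year) else NA_integer_),
    class = "des_fit"
  )
}

#' @noRd
des_pass <- function(alpha, x) {
  n <- length(x)
  s1 <- s2 <- numeric(n)
  s1[1] <- s2[1] <- x[1]
  fitted <- rep(NA_real_, n)
  for (t in 2:n) {
    level_prev <- 2 * s1[t - 1] - s2[t - 1]
    trend_prev <- alpha / (1 - alpha) * (s1[t - 1] - s2[t - 1])
    fitted[t] <- level_prev + trend_prev
    s1[t] <- alpha * x[t] + (1 - alpha) * s1[t - 1]
    s2[t] <- alpha * s1[t] + (1 - alpha) * s2[t - 1]
  }
  list(
    rmse = sqrt(mean((x[-1] - fitted[-1])^2)),
    level = 2 * s1[n] - s2[n],
    trend = alpha / (1 - alpha) * (s1[n] - s2[n]),
    fitted = fitted
  )
}

#' Forecast from a double-exponential-smoothing fit
#'
#' @param object A `des_fit`.
#' @param h Forecast horizons (positive integers); default `1:2`.
#' @param ... Unused.
#' @return Numeric forecasts, named by year when the fit knows its last
#'   observed year.
#' @export
predict.des_fit <- function(object, h = 1:2, ...) {
  stopifnot(all(h >= 1))
  out <- object$level + h * object$trend
  if (!is.na(object$last_year)) names(out) <- object$last_year + h
  out
}

#' @export
print.des_fit <- function(x, ...) {
  cat(sprintf("<des_fit> Brown's double exponential smoothing: alpha = %.2f (RMSE %.4g)\n",
              x$alpha, x$rmse))
  cat(sprintf("  final level %.4g, trend %.4g per year\n", x$level, x$trend))
  invisible(x)
}

#' @noRd
rate_vector <- function(series) {
  if (is.data.frame(series)) {
    if (!"rate" %in% names(series)) stop("series must have a `rate` column", call. = FALSE)
    if ("year" %in% names(series)) series <- series[order(series$year), ]
    as.numeric(series$rate)
  } else {
    as.numeric(series)
  }
}

#' National reference counts shipped with the package
#'
#' Published annual totals for Luxembourg, 2000-2006: the covered initial
#' population, patients treated for diabetes, and patients treated for type
#' 2 diabetes, together with the period-wide totals (`year = NA`). These
#' support the arithmetic cross-checks of the prevalence and summary
#' operations without access to the underlying claims database.
#'
#' @return A tibble `(year, initial_population, treated_diabetes,
#'   treated_type2)`.
#' @export
lux_reference_counts <- function() {
  path <- system.file("extdata", "luxembourg_reference_counts.csv",
                      package = "diabrx", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    initial_population = readr::col_integer(),
    treated_diabetes = readr::col_integer(),
    treated_type2 = readr::col_integer()
  ))
}
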