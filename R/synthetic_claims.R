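#' Configuration for the synthetic claims generator
#'
#' Defines a ground-truth-labelled population whose A10 delivery
#' trajectories exercise every stage of the phenotyping pipeline:
#' oral-agent-treated type-2 patients (a configurable subset of whom later
#' switch to insulin-only treatment at ages centred on `switch_age_mean`),
#' young-onset insulin-only type-1 patients, non-diabetic "noise" users
#' with one or two isolated A10 deliveries (prescription or dispensing
#' errors — the reason the case definition demands three deliveries a
#' year), and "traveller" diabetics who fill only two prescriptions a year
#' at home. Deaths follow an age-dependent annual hazard and truncate
#' trajectories.
#'
#' @param n_population Number of simulated persons.
#' @param frac_type2_treated Fraction with treated type-2 diabetes.
#' @param frac_type1_treated Fraction with treated type-1 diabetes.
#' @param frac_noise_users Fraction of non-diabetics with sporadic A10
#'   claims.
#' @param deliveries_per_year_mean Mean yearly deliveries for adherent
#'   patients (adherent oral-agent years are floored at 3).
#' @param insulin_deliveries_per_year_mean Mean yearly deliveries for
#'   insulin-treated years (insulin is dispensed more often).
#' @param adherent_fraction Fraction of diabetic patients refilling
#'   regularly (at least 3 deliveries every full treated year).
#' @param traveller_fraction Fraction of type-2 patients with exactly 2
#'   deliveries per year (the rest bought abroad).
#' @param switch_fraction Fraction of type-2 patients who switch from oral
#'   agents to insulin-only treatment within the horizon.
#' @param switch_age_mean,switch_age_sd Age (years) at the switch to
#'   insulin-only treatment.
#' @param onset_span Years over which treatment onset is drawn; the first
#'   year carries extra mass, standing in for cases already prevalent when
#'   the horizon opens.
#' @param onset_start_weight Relative weight of the first onset year.
#' @param death_hazard Function age -> annual death probability.
#' @param horizon Two years, the claims horizon.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `simulation_config` (a named list).
#' @seealso [simulate_population()], [scenario_presets()]
#' @export
simulation_config <- function(n_population = 5000L,
                              frac_type2_treated = 0.035,
                              frac_type1_treated = 0.002,
                              frac_noise_users = 0.02,
                              deliveries_per_year_mean = 5,
                              insulin_deliveries_per_year_mean = 6,
                              adherent_fraction = 0.9,
                              traveller_fraction = 0.05,
                              switch_fraction = 0.25,
                              switch_age_mean = 66.3,
                              switch_age_sd = 4,
                              onset_span = c(1995L, 2005L),
                              onset_start_weight = 6,
                              death_hazard = function(age) pmin(0.4, 2e-05 * exp(0.1 * age)),
                              horizon = c(1995L, 2006L),
                              seed = 1L) {
  fr <- c(frac_type2_treated, frac_type1_treated, frac_noise_users)
  if (any(fr < 0) || any(fr > 1) || frac_type2_treated + frac_type1_treated > 1 ||
      sum(fr) > 1) {
    stop("population fractions must lie in [0, 1] and sum to at most 1", call. = FALSE)
  }
  stopifnot(n_population > 0, deliveries_per_year_mean > 0,
            adherent_fraction >= 0, adherent_fraction <= 1,
            switch_fraction >= 0, switch_fraction <= 1,
            switch_age_sd >= 0)
  horizon <- assert_year_range(horizon)
  onset_span <- assert_year_range(onset_span)
  structure(
    list(n_population = as.integer(n_population),
         frac_type2_treated = frac_type2_treated,
         frac_type1_treated = frac_type1_treated,
         frac_noise_users = frac_noise_users,
         deliveries_per_year_mean = deliveries_per_year_mean,
         insulin_deliveries_per_year_mean = insulin_deliveries_per_year_mean,
         adherent_fraction = adherent_fraction,
         traveller_fraction = traveller_fraction,
         switch_fraction = switch_fraction,
         switch_age_mean = switch_age_mean,
         switch_age_sd = switch_age_sd,
         onset_span = onset_span,
         onset_start_weight = onset_start_weight,
         death_hazard = death_hazard,
         horizon = horizon,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Named scenario presets
#'
#' `tiny` (400 persons) keeps unit tests fast; `luxembourg_like` emulates a
#' population with ~3.5% treated type-2 prevalence and an insulin-switch
#' age centred on 66.3 years; `high_noise` stresses the false-positive
#' defences with 8% sporadic users.
#'
#' @param name Optional preset name; with no argument all presets are
#'   returned as a named list. An unknown name errors, listing the presets.
#' @return A `simulation_config`, or a named list of them.
#' @export
scenario_presets <- function(name = NULL) {
  presets <- list(
    tiny = simulation_config(n_population = 400L, seed = 1L),
    luxembourg_like = simulation_config(
      n_population = 5000L, frac_type2_treated = 0.035,
      frac_type1_treated = 0.002, frac_noise_users = 0.02,
      deliveries_per_year_mean = 5, switch_age_mean = 66.3, seed = 1L
    ),
    high_noise = simulation_config(n_population = 2000L, frac_noise_users = 0.08,
                                   seed = 1L)
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Simulate a labelled population with pharmacy claims
#'
#' Draws persons, their A10 delivery trajectories and a truth table from a
#' [simulation_config()]. Identical configurations (including the seed)
#' produce identical output.
#'
#' Trajectory rules: type-2 patients receive oral agents (A10B) from their
#' onset year; switchers receive only insulin (A10A) from their switch year
#' on; type-1 patients receive only insulin from a young onset age; noise
#' users get 1-2 deliveries in a single year; travellers get exactly 2
#' deliveries every treated year. The onset year itself is treated as a
#' partial year (1-3 deliveries); deaths truncate all claims at the death
#' date.
#'
#' @param config A [simulation_config()].
#' @return A list with `persons`, `claims` and `truth` tibbles. `truth` has
#'   columns `patient_id`, `label` (`type1`/`type2`/`none`), `onset_year`,
#'   `switch_year`, `adherent`, `traveller`.
#' @export
simulate_population <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_population
  h0 <- cfg$horizon[1]
  h1 <- cfg$horizon[2]

  labels <- sample(
    c("type2", "type1", "noise", "none"), n, replace = TRUE,
    prob = c(cfg$frac_type2_treated, cfg$frac_type1_treated,
             cfg$frac_noise_users,
             1 - cfg$frac_type2_treated - cfg$frac_type1_treated - cfg$frac_noise_users)
  )
  ids <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("male", "female"), n, replace = TRUE)

  onset_years <- function(k) {
    yrs <- seq(cfg$onset_span[1], cfg$onset_span[2])
    w <- c(cfg$onset_start_weight, rep(1, length(yrs) - 1L))
    yrs[sample.int(length(yrs), k, replace = TRUE, prob = w)]
  }

  birth_v <- integer(n)
  death_v <- rep(NA_real_, n)          # numeric days since epoch; Date at the end
  onset_v <- rep(NA_integer_, n)
  switch_v <- rep(NA_integer_, n)
  adherent_v <- rep(NA, n)
  traveller_v <- logical(n)
  cl_id <- list(); cl_date <- list(); cl_atc <- list()

  oha_codes <- c("A10BA02", "A10BB01", "A10BB12", "A10BG03")
  ins_codes <- c("A10AB01", "A10AC01", "A10AD01", "A10AE04")

  push_claims <- function(id, dates, codes) {
    k <- length(cl_id) + 1L
    cl_id[[k]] <<- rep(id, length(dates))
    cl_date[[k]] <<- as.numeric(dates)
    cl_atc[[k]] <<- codes
  }

  for (i in seq_len(n)) {
    lab <- labels[i]
    onset <- NA_integer_
    switch_year <- NA_integer_
    adherent <- NA
    traveller <- FALSE

    if (lab == "type2") {
      switcher <- stats::runif(1) < cfg$switch_fraction
      if (switcher) {
        # draw the switch age first; the birth year follows from it
        switch_age <- round(stats::rnorm(1, cfg$switch_age_mean, cfg$switch_age_sd))
        switch_year <- sample(seq(h0 + 2L, h1), 1)
        onset <- max(h0, switch_year - sample(2:8, 1))
        birth <- switch_year - switch_age
        adherent <- TRUE  # insulin initiation implies close follow-up
      } else {
        onset <- onset_years(1)
        onset_age <- pmin(95, pmax(30, round(stats::rnorm(1, 62, 12))))
        birth <- onset - onset_age
        traveller <- stats::runif(1) < cfg$traveller_fraction
        if (traveller) {
          onset <- min(onset, h1 - 3L)  # travellers need >= 3 treated years
          birth <- onset - onset_age
          adherent <- FALSE
        } else {
          adherent <- stats::runif(1) < cfg$adherent_fraction
        }
      }
    } else if (lab == "type1") {
      onset <- onset_years(1)
      onset_age <- pmin(40, pmax(1, round(stats::rnorm(1, 18, 8))))
      birth <- onset - onset_age
      adherent <- stats::runif(1) < cfg$adherent_fraction
    } else {
      birth <- 2000L - sample(10:90, 1)
    }

    # age-dependent death, simulated year by year over the horizon
    death_year <- NA_integer_
    for (y in h0:h1) {
      age <- y - birth
      if (age >= 0 && stats::runif(1) < cfg$death_hazard(age)) {
        death_year <- y
        break
      }
    }
    death_date <- if (is.na(death_year)) as.Date(NA) else {
      as.Date(sprintf("%d-01-01", death_year)) + sample.int(365, 1) - 1L
    }
    if (!is.na(death_year) && format(death_date, "%Y") != as.character(death_year)) {
      death_date <- as.Date(sprintf("%d-12-31", death_year))
    }

    # claims
    if (lab %in% c("type2", "type1") &&
        (is.na(death_year) || death_year >= onset)) {
      last_year <- min(h1, if (is.na(death_year)) h1 else death_year)
      if (!is.na(switch_year) && switch_year > last_year) switch_year <- NA_integer_
      yrs <- seq.int(onset, last_year)
      k <- vapply(yrs, function(y) {
        if (traveller) return(2L)
        if (y == onset) return(sample(1:3, 1))
        on_insulin <- lab == "type1" || (!is.na(switch_year) && y >= switch_year)
        mu <- if (on_insulin) cfg$insulin_deliveries_per_year_mean else cfg$deliveries_per_year_mean
        if (isTRUE(adherent)) max(3L, stats::rpois(1, mu)) else min(2L, stats::rpois(1, 1.2))
      }, integer(1))
      for (j in seq_along(yrs)) {
        if (k[j] == 0L) next
        y <- yrs[j]
        on_insulin <- lab == "type1" || (!is.na(switch_year) && y >= switch_year)
        pool <- if (on_insulin) ins_codes else oha_codes
        dates <- spaced_days(y, k[j])
        if (!is.na(death_year) && y == death_year) dates <- dates[dates <= death_date]
        if (!length(dates)) next
        push_claims(ids[i], dates, sample(pool, length(dates), replace = TRUE))
      }
    } else if (lab == "noise") {
      y <- sample(h0:h1, 1)
      if (is.na(death_year) || y <= death_year) {
        dates <- spaced_days(y, sample(1:2, 1))
        if (!is.na(death_year) && y == death_year) dates <- dates[dates <= death_date]
        if (length(dates)) {
          push_claims(ids[i], dates,
                      sample(c(oha_codes, ins_codes), length(dates), replace = TRUE))
        }
      }
    }

    birth_v[i] <- as.integer(birth)
    death_v[i] <- as.numeric(death_date)
    onset_v[i] <- as.integer(onset)
    switch_v[i] <- as.integer(switch_year)
    adherent_v[i] <- adherent
    traveller_v[i] <- traveller
  }

  claims <- tibble::tibble(
    patient_id = as.character(unlist(cl_id) %||% character(0)),
    delivery_date = as.Date(unlist(cl_date) %||% numeric(0), origin = "1970-01-01"),
    atc_code = as.character(unlist(cl_atc) %||% character(0))
  )
  claims <- dplyr::arrange(claims, .data$patient_id, .data$delivery_date, .data$atc_code)
  persons <- tibble::tibble(
    patient_id = ids, sex = sex, birth_year = birth_v,
    death_date = as.Date(death_v, origin = "1970-01-01")
  )
  truth <- tibble::tibble(
    patient_id = ids,
    label = ifelse(labels == "noise", "none", labels),
    onset_year = onset_v, switch_year = switch_v,
    adherent = adherent_v, traveller = traveller_v
  )
  list(persons = persons, claims = claims, truth = truth)
}

#' Refill-like delivery dates within one year
#'
#' Anchors `k` dates evenly over the year and jitters each within its slot,
#' mimicking regular refills: dates are distinct and, for realistic yearly
#' counts, about a month or more apart.
#'
#' @noRd
spaced_days <- function(year, k) {
  start <- as.Date(sprintf("%d-01-01", year))
  if (k <= 0) return(as.Date(character(0)))
  if (k == 1L) return(start + sample.int(365, 1) - 1L)
  anchors <- round(seq(15, 350, length.out = k))
  gap <- (350 - 15) / (k - 1)
  jit <- round(stats::runif(k, -1, 1) * max(0, min(13, gap / 2 - 1)))
  days <- pmin(364, pmax(0, anchors + jit))
  unique(start + sort(days))
}

#' Covered-population denominators from simulated persons
#'
#' Counts persons alive on 31 December of each year (death year excluded),
#' by sex and ten-year age class, plus the `"all"` marginal rows, in the
#' layout expected by [read_denominators()].
#'
#' @param persons Persons tibble.
#' @param years Years to tabulate.
#' @param age_breaks Passed to [age_class_label()].
#' @return A tibble `(year, sex, age_class, population)`.
#' @export
denominators_from_persons <- function(persons, years,
                                      age_breaks = seq(0, 100, by = 10)) {
  dy <- death_years(persons)
  out <- lapply(as.integer(years), function(y) {
    alive <- is.na(dy) | dy > y
    p <- persons[alive & !is.na(persons$birth_year) & persons$birth_year <= y, ]
    p$age_class <- age_class_label(y - p$birth_year, age_breaks)
    p <- p[!is.na(p$age_class) & !is.na(p$sex), ]
    strat <- dplyr::count(p, .data$sex, .data$age_class, name = "population")
    by_sex <- dplyr::count(p, .data$sex, name = "population")
    by_sex$age_class <- "all"
    strat_age <- dplyr::count(p, .data$age_class, name = "population")
    strat_age$sex <- "all"
    all_row <- tibble::tibble(sex = "all", age_class = "all", population = nrow(p))
    res <- dplyr::bind_rows(strat, by_sex, strat_age, all_row)
    res$year <- y
    res[c("year", "sex", "age_class", "population")]
  })
  dplyr::bind_rows(out)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_config> n = %d, horizon %d-%d, seed %d\n",
    "  type2 %.3f (switchers %.2f, travellers %.2f), type1 %.3f, noise %.3f\n",
    "  adherent %.2f at %.1f deliveries/year; switch age %.1f (sd %.1f)\n"),
    x$n_population, x$horizon[1], x$horizon[2], x$seed,
    x$frac_type2_treated, x$switch_fraction, x$traveller_fraction,
    x$frac_type1_treated, x$frac_noise_users,
    x$adherent_fraction, x$deliveries_per_year_mean,
    x$switch_age_mean, x$switch_age_sd))
  invisible(x)
}

#' Write the simulated tables as CSVs
#'
#' @param sim Output of [simulate_population()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_claims(sim$claims, file.path(dir, "claims.csv"))
  write_persons(sim$persons, file.path(dir, "persons.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}
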