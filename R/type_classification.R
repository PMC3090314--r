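#' Split detected cases by oral-agent exposure (step 2)
#'
#' Among detected treated-diabetes cases, patients with at least one
#' delivery of an oral hypoglycemic agent (ATC A10B) over the horizon form
#' the OHA-exposed set; the remainder received only insulin (A10A). The two
#' sets partition the case set.
#'
#' @param cases Case tibble from [detect_cases()], or a character vector of
#'   patient ids.
#' @param claims Claims tibble covering the same horizon.
#' @param horizon Two years bounding the claims considered; default
#'   `c(1995, 2006)`.
#' @return A list with character vectors `oha_set` and `insulin_only_set`.
#' @export
split_by_oha <- function(cases, claims, horizon = c(1995L, 2006L)) {
  ids <- case_ids(cases)
  horizon <- assert_year_range(horizon)
  yr <- claim_year(claims$delivery_date)
  in_h <- yr >= horizon[1] & yr <= horizon[2]
  a10 <- claims[in_h & atc_matches(claims$atc_code, "A10"), , drop = FALSE]
  no_a10 <- setdiff(ids, unique(a10$patient_id))
  if (length(no_a10)) {
    stop("case(s) without any A10 claim in the horizon (e.g. ", no_a10[1],
         "); detection and classification must use the same claims",
         call. = FALSE)
  }
  oha <- intersect(ids, unique(a10$patient_id[atc_matches(a10$atc_code, "A10B")]))
  list(oha_set = oha, insulin_only_set = setdiff(ids, oha))
}

#' Estimate the type-1/type-2 switch-age threshold
#'
#' The age separating late-onset (type 2) from early-onset (type 1)
#' insulin-only patients is estimated from the data rather than fixed: among
#' OHA-exposed cases, those whose treatment ends in an insulin-only segment
#' (at least one A10A delivery strictly after their last A10B year, and no
#' A10B thereafter within the horizon) define the switch cohort. The
#' threshold is the floor of their mean age in the first insulin-only year,
#' reflecting local prescribing practice.
#'
#' @param cases Case tibble or id vector (see [split_by_oha()]).
#' @param claims Claims tibble.
#' @param persons Persons tibble (birth years). Switchers with a missing
#'   birth year are excluded with a message.
#' @param horizon Two years; default `c(1995, 2006)`.
#' @param default Threshold returned when no qualifying switcher exists.
#' @param rounding `"floor"` (default) or `"nearest"`.
#' @return A list with `threshold` (integer years) and `cohort`, a tibble
#'   `(patient_id, switch_year, age_at_switch)`.
#' @export
estimate_switch_threshold <- function(cases, claims, persons,
                                      horizon = c(1995L, 2006L),
                                      default = 66L,
                                      rounding = c("floor", "nearest")) {
  rounding <- match.arg(rounding)
  split <- split_by_oha(cases, claims, horizon)
  horizon <- assert_year_range(horizon)
  yr <- claim_year(claims$delivery_date)
  in_h <- yr >= horizon[1] & yr <= horizon[2]
  sub <- claims[in_h & claims$patient_id %in% split$oha_set, , drop = FALSE]
  sub$year <- claim_year(sub$delivery_date)
  is_b <- atc_matches(sub$atc_code, "A10B")
  is_a <- atc_matches(sub$atc_code, "A10A")
  last_b <- tapply(sub$year[is_b], sub$patient_id[is_b], max)
  cohort <- lapply(names(last_b), function(id) {
    a_years <- sub$year[is_a & sub$patient_id == id]
    a_after <- a_years[a_years > last_b[[id]]]
    if (!length(a_after)) return(NULL)
    tibble::tibble(patient_id = id, switch_year = min(a_after))
  })
  cohort <- dplyr::bind_rows(cohort)
  if (!nrow(cohort)) {
    message("no OHA-to-insulin switchers found; using default threshold ", default)
    return(list(threshold = as.integer(default),
                cohort = tibble::tibble(patient_id = character(0),
                                        switch_year = integer(0),
                                        age_at_switch = integer(0))))
  }
  birth <- stats::setNames(persons$birth_year, persons$patient_id)
  cohort$age_at_switch <- cohort$switch_year - as.integer(birth[cohort$patient_id])
  n_miss <- sum(is.na(cohort$age_at_switch))
  if (n_miss) {
    message(n_miss, " switcher(s) without birth year excluded from the threshold estimate")
    cohort <- cohort[!is.na(cohort$age_at_switch), ]
  }
  if (!nrow(cohort)) {
    message("no switcher with a known birth year; using default threshold ", default)
    return(list(threshold = as.integer(default), cohort = cohort))
  }
  m <- mean(cohort$age_at_switch)
  threshold <- if (rounding == "floor") floor(m) else round_half_up(m)
  list(threshold = as.integer(threshold), cohort = cohort)
}

#' Classify detected cases as type 2 (steps 2 and 3)
#'
#' Step 2 takes every OHA-exposed case (oral agents are not used for type 1
#' diabetes). Step 3 adds insulin-only cases who were older than the switch
#' threshold in the year of their first insulin delivery: late insulin
#' initiation at those ages reflects type-2 progression, not type-1 onset.
#' Remaining insulin-only cases are labelled type 1 and are not in the
#' returned set. Insulin-only cases with a missing birth year cannot be
#' age-assessed and stay out of step 3 (a message reports the count).
#'
#' @param split Output of [split_by_oha()].
#' @param threshold Integer switch-age threshold (years), e.g. from
#'   [estimate_switch_threshold()].
#' @param claims Claims tibble.
#' @param persons Persons tibble.
#' @param horizon Two years; default `c(1995, 2006)`.
#' @param inclusive If `TRUE`, step 3 uses `age >= threshold` instead of the
#'   default strict `age > threshold` ("older than").
#' @return A tibble `(patient_id, step)` with `step` in `c(2, 3)` and
#'   attribute `threshold_used`.
#' @export
classify_type2 <- function(split, threshold, claims, persons,
                           horizon = c(1995L, 2006L), inclusive = FALSE) {
  stopifnot(is.list(split), all(c("oha_set", "insulin_only_set") %in% names(split)),
            threshold >= 0)
  horizon <- assert_year_range(horizon)
  yr <- claim_year(claims$delivery_date)
  in_h <- yr >= horizon[1] & yr <= horizon[2]
  ins <- claims[in_h & atc_matches(claims$atc_code, "A10A"), , drop = FALSE]
  first_ins <- tapply(claim_year(ins$delivery_date), ins$patient_id, min)
  missing_ins <- setdiff(split$insulin_only_set, names(first_ins))
  if (length(missing_ins)) {
    stop("insulin-only case(s) without any A10A claim (e.g. ", missing_ins[1],
         "): inconsistent split", call. = FALSE)
  }
  birth <- stats::setNames(persons$birth_year, persons$patient_id)
  ids <- split$insulin_only_set
  age_first_ins <- as.integer(first_ins[ids]) - as.integer(birth[ids])
  n_miss <- sum(is.na(age_first_ins))
  if (n_miss) {
    message(n_miss, " insulin-only case(s) without birth year excluded from step 3")
  }
  keep <- !is.na(age_first_ins) &
    (if (inclusive) age_first_ins >= threshold else age_first_ins > threshold)
  step3 <- ids[keep]
  out <- dplyr::bind_rows(
    tibble::tibble(patient_id = split$oha_set, step = 2L),
    tibble::tibble(patient_id = step3, step = 3L)
  )
  attr(out, "threshold_used") <- as.integer(threshold)
  out
}

#' Counts summary of the detection and classification funnel
#'
#' @param cases Case tibble or id vector from [detect_cases()].
#' @param type2 Tibble from [classify_type2()].
#' @return A tibble with one row of counts: cases, step-2 and step-3
#'   members, type-2 total and the type-2 share of all treated-diabetes
#'   cases (percent, 1 decimal).
#' @export
classification_summary <- function(cases, type2) {
  ids <- case_ids(cases)
  if (!all(type2$patient_id %in% ids)) {
    stop("type-2 set must be a subset of the case set", call. = FALSE)
  }
  n_cases <- length(ids)
  n2 <- sum(type2$step == 2L)
  n3 <- sum(type2$step == 3L)
  tibble::tibble(
    n_cases = n_cases,
    n_step2 = n2,
    n_step3 = n3,
    n_type2 = n2 + n3,
    type2_share_pct = if (n_cases) round_half_up(100 * (n2 + n3) / n_cases, 1) else NA_real_
  )
}

#' @noRd
case_ids <- function(cases) {
  if (is.data.frame(cases)) unique(cases$patient_id) else unique(as.character(cases))
}
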