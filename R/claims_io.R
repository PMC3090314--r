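#' Read a pharmacy-claims table
#'
#' Reads a CSV of reimbursed drug deliveries with columns `patient_id`,
#' `delivery_date` (ISO-8601 `YYYY-MM-DD`) and `atc_code`. Rows dated outside
#' the study horizon are dropped with a message giving their count; a
#' malformed date or a missing column is a hard error naming the offending
#' row.
#'
#' @param path Path to the claims CSV.
#' @param horizon Two years `c(first, last)` delimiting the study window;
#'   default `c(1995, 2006)`.
#' @return A tibble with columns `patient_id` (character), `delivery_date`
#'   (`Date`) and `atc_code` (uppercase character).
#' @seealso [count_deliveries()], [write_claims()]
#' @export
read_claims <- function(path, horizon = c(1995L, 2006L)) {
  horizon <- assert_year_range(horizon)
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "delivery_date", "atc_code")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("claims file is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dates <- as.Date(raw$delivery_date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) {
    stop(sprintf("malformed delivery_date %s at row %d",
                 raw$delivery_date[bad[1]] %||% "<missing>", bad[1]),
         call. = FALSE)
  }
  atc <- toupper(trimws(raw$atc_code))
  bad_atc <- which(is.na(atc) | !grepl("^[A-Z0-9]+$", atc))
  if (length(bad_atc)) {
    stop(sprintf("invalid atc_code at row %d", bad_atc[1]), call. = FALSE)
  }
  claims <- tibble::tibble(
    patient_id = raw$patient_id,
    delivery_date = dates,
    atc_code = atc
  )
  yrs <- claim_year(claims$delivery_date)
  outside <- yrs < horizon[1] | yrs > horizon[2]
  if (any(outside)) {
    message(sum(outside), " claim row(s) outside horizon ",
            horizon[1], "-", horizon[2], " dropped")
    claims <- claims[!outside, ]
  }
  claims
}

#' Read a person registry
#'
#' Expects columns `patient_id`, `sex` (`male`/`female`, `m`/`f` accepted),
#' `birth_year` and `death_date` (empty means alive). Persons with a missing
#' birth year are retained (they still count for detection) but a message
#' reports how many there are, since they are excluded from age-dependent
#' steps.
#'
#' @param path Path to the persons CSV.
#' @return A tibble with columns `patient_id`, `sex`, `birth_year`
#'   (integer, possibly `NA`) and `death_date` (`Date`, `NA` if alive).
#' @export
read_persons <- function(path) {
  if (!file.exists(path)) stop("persons file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "sex", "birth_year", "death_date")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("persons file is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sex <- tolower(trimws(raw$sex))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  sex[!sex %in% c("male", "female")] <- NA_character_
  birth <- suppressWarnings(as.integer(raw$birth_year))
  if (anyNA(birth)) {
    message(sum(is.na(birth)), " person(s) with missing birth_year ",
            "(kept for detection, excluded from age-dependent steps)")
  }
  dd <- raw$death_date
  dd[!is.na(dd) & !nzchar(trimws(dd))] <- NA_character_
  death <- as.Date(dd, format = "%Y-%m-%d")
  bad <- which(!is.na(dd) & is.na(death))
  if (length(bad)) {
    stop(sprintf("malformed death_date at row %d", bad[1]), call. = FALSE)
  }
  bad_death <- which(!is.na(death) & !is.na(birth) & claim_year(death) < birth)
  if (length(bad_death)) {
    stop(sprintf("death before birth for patient %s", raw$patient_id[bad_death[1]]),
         call. = FALSE)
  }
  tibble::tibble(
    patient_id = raw$patient_id,
    sex = sex,
    birth_year = birth,
    death_date = death
  )
}

#' Read covered-population denominators
#'
#' One row per `(year, sex, age_class)` stratum with the covered resident
#' population on 31 December; `sex` and/or `age_class` may be `"all"` for
#' marginal rows.
#'
#' @param path Path to the denominators CSV
#'   (`year,sex,age_class,population`).
#' @return A tibble with those four columns, `population` integer.
#' @export
read_denominators <- function(path) {
  if (!file.exists(path)) stop("denominators file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(),
    sex = readr::col_character(),
    age_class = readr::col_character(),
    population = readr::col_double()
  ))
  if (any(is.na(raw$population) | raw$population <= 0)) {
    stop("denominator populations must be positive", call. = FALSE)
  }
  raw
}

#' Read a standard-population weight table
#'
#' @param path Path to a CSV with columns `age_class,weight`; weights must be
#'   non-negative and sum to 1 (within 1e-6; near-misses are renormalized
#'   with a message).
#' @return A tibble with columns `age_class` and `weight`.
#' @export
read_standard_population <- function(path) {
  if (!file.exists(path)) stop("standard-population file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    age_class = readr::col_character(),
    weight = readr::col_double()
  ))
  if (any(is.na(raw$weight) | raw$weight < 0)) {
    stop("standard-population weights must be non-negative", call. = FALSE)
  }
  s <- sum(raw$weight)
  if (abs(s - 1) > 0.01) {
    stop("standard-population weights sum to ", format(s), ", not 1", call. = FALSE)
  }
  if (abs(s - 1) > 1e-6) {
    message("standard-population weights renormalized (sum was ", format(s), ")")
    raw$weight <- raw$weight / s
  }
  raw
}

#' Write claims / persons tables
#'
#' Inverse of [read_claims()] and [read_persons()]: dates are written
#' ISO-8601 and a missing death date becomes an empty field, so a write
#' followed by a read reproduces the table exactly.
#'
#' @param claims,persons Tibbles as returned by the readers.
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_claims <- function(claims, path) {
  readr::write_csv(claims[c("patient_id", "delivery_date", "atc_code")], path, na = "")
  invisible(claims)
}

#' @rdname write_claims
#' @export
write_persons <- function(persons, path) {
  readr::write_csv(persons[c("patient_id", "sex", "birth_year", "death_date")], path, na = "")
  invisible(persons)
}

#' Per-patient, per-year distinct-delivery counts for an ATC prefix
#'
#' Tallies, for every patient and calendar year, the number of deliveries of
#' drugs whose ATC code starts with `atc_prefix` (case-insensitive). By
#' default a "delivery" is a distinct `(patient, date)` pair, so several
#' claim lines from one pharmacy visit count once; set
#' `distinct_dates = FALSE` for raw line counting. Patient-years with no
#' matching claim are simply absent (an absent pair means a count of 0).
#'
#' @param claims Claims tibble (see [read_claims()]).
#' @param atc_prefix ATC prefix, e.g. `"A10"` (all hypoglycemic agents),
#'   `"A10A"` (insulins) or `"A10B"` (oral agents).
#' @param year_range Optional two years restricting the tally; defaults to
#'   the range of years present in `claims`.
#' @param distinct_dates Count distinct delivery dates (default) rather than
#'   raw claim lines.
#' @return An object of class `delivery_matrix`: a list with `atc_prefix`,
#'   `year_range`, and `counts`, a tibble `(patient_id, year, n)`.
#' @examples
#' claims <- tibble::tibble(
#'   patient_id = "p1",
#'   delivery_date = as.Date(c("2003-01-10", "2003-05-02", "2003-09-30")),
#'   atc_code = "A10BA02"
#' )
#' count_deliveries(claims, "A10")
#' @export
count_deliveries <- function(claims, atc_prefix, year_range = NULL,
                             distinct_dates = TRUE) {
  stopifnot(is.character(atc_prefix), length(atc_prefix) == 1L, nzchar(atc_prefix))
  m <- claims[atc_matches(claims$atc_code, atc_prefix), , drop = FALSE]
  if (nrow(m)) {
    m$year <- claim_year(m$delivery_date)
  } else {
    m$year <- integer(0)
  }
  if (is.null(year_range)) {
    year_range <- if (nrow(m)) range(m$year) else c(NA_integer_, NA_integer_)
  } else {
    year_range <- assert_year_range(year_range)
    m <- m[m$year >= year_range[1] & m$year <= year_range[2], , drop = FALSE]
  }
  if (distinct_dates) {
    m <- dplyr::distinct(m, .data$patient_id, .data$year, .data$delivery_date)
  }
  counts <- dplyr::count(m, .data$patient_id, .data$year, name = "n")
  structure(
    list(atc_prefix = toupper(atc_prefix), year_range = year_range,
         counts = counts, distinct_dates = distinct_dates),
    class = "delivery_matrix"
  )
}

#' @export
print.delivery_matrix <- function(x, ...) {
  cat(sprintf("<delivery_matrix> ATC prefix %s, years %s-%s: %d patients, %d patient-years\n",
              x$atc_prefix, x$year_range[1], x$year_range[2],
              dplyr::n_distinct(x$counts$patient_id), nrow(x$counts)))
  invisible(x)
}

#' Yearly counts for one patient as a named vector
#'
#' @param matrix A `delivery_matrix`.
#' @param patient_id One patient identifier.
#' @param years Years to report (zeros filled in); default the matrix range.
#' @return Named integer vector, names = years.
#' @export
patient_counts <- function(matrix, patient_id, years = NULL) {
  stopifnot(inherits(matrix, "delivery_matrix"))
  if (is.null(years)) years <- seq(matrix$year_range[1], matrix$year_range[2])
  rows <- matrix$counts[matrix$counts$patient_id == patient_id, ]
  out <- stats::setNames(integer(length(years)), years)
  hit <- match(rows$year, years)
  out[hit[!is.na(hit)]] <- rows$n[!is.na(hit)]
  out
}

#' Missing-data report
#'
#' One proportion of missing values per required field of the claims and
#' persons tables (a clean extract reports 0 everywhere). An empty table
#' yields `NA` proportions with `flagged = TRUE`.
#'
#' @param claims Claims tibble, or `NULL` to skip.
#' @param persons Persons tibble, or `NULL` to skip.
#' @return Tibble `(table, field, n, n_missing, prop_missing, flagged)`.
#' @export
completeness_report <- function(claims = NULL, persons = NULL) {
  one <- function(tbl, name, fields) {
    miss <- vapply(fields, function(f) {
      v <- tbl[[f]]
      sum(is.na(v) | (is.character(v) & !is.na(v) & !nzchar(v)))
    }, integer(1), USE.NAMES = FALSE)
    tibble::tibble(
      table = name, field = fields, n = nrow(tbl), n_missing = miss,
      prop_missing = if (nrow(tbl)) miss / nrow(tbl) else NA_real_,
      flagged = nrow(tbl) == 0L
    )
  }
  out <- list()
  if (!is.null(claims)) {
    out <- c(out, list(one(claims, "claims", c("patient_id", "delivery_date", "atc_code"))))
  }
  if (!is.null(persons)) {
    # death_date is excluded: an absent death date means alive, not missing
    out <- c(out, list(one(persons, "persons", c("patient_id", "sex", "birth_year"))))
  }
  dplyr::bind_rows(out)
}
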