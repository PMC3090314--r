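# In-code fixtures: tiny claims/persons builders used across test files.

make_claims <- function(patient_id, dates, atc_code) {
  tibble::tibble(
    patient_id = patient_id,
    delivery_date = as.Date(dates),
    atc_code = atc_code
  )
}

# n deliveries for one patient in one year, evenly spread, given ATC code
year_claims <- function(id, year, n, atc = "A10BA02") {
  if (n == 0) {
    return(make_claims(character(0), as.Date(character(0)), character(0)))
  }
  days <- round(seq(20, 340, length.out = n))
  make_claims(rep(id, n), as.Date(sprintf("%d-01-01", year)) + days, rep(atc, n))
}

# counts: named list id -> named vector year -> count
claims_from_counts <- function(counts, atc = "A10BA02") {
  rows <- list()
  for (id in names(counts)) {
    v <- counts[[id]]
    for (y in names(v)) {
      rows[[length(rows) + 1L]] <- year_claims(id, as.integer(y), v[[y]], atc)
    }
  }
  dplyr::bind_rows(rows)
}

death_year_of <- function(persons) {
  stats::setNames(as.integer(format(persons$death_date, "%Y")), persons$patient_id)
}

# flat Dirichlet draw (normalized exponentials)
rdirichlet_flat <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}

make_persons <- function(patient_id, sex = "male", birth_year = 1940L,
                         death_date = as.Date(NA)) {
  tibble::tibble(
    patient_id = patient_id,
    sex = rep_len(sex, length(patient_id)),
    birth_year = as.integer(rep_len(birth_year, length(patient_id))),
    death_date = rep_len(as.Date(death_date), length(patient_id))
  )
}
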