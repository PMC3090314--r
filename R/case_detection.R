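#' Detection window for the delivery-count criteria
#'
#' The detection step runs in two phases: phase 1 over the reporting window
#' (default 2000-2006) and, for patients not selected there (typically
#' because they died early), phase 2 over the full treatment-history window
#' (default 1995-2006). The right-truncation criterion (criterion 4) also
#' accepts a single well-treated year among the last two years of phase 1,
#' since treatment continuation beyond the window cannot be observed.
#'
#' @param phase1 Two years, the phase-1 window.
#' @param phase2 Two years, the phase-2 window; must contain `phase1`.
#' @param last_two_years The two years used by criterion 4's truncation arm;
#'   default the last two years of `phase1`.
#' @return An object of class `detection_window`.
#' @export
detection_window <- function(phase1 = c(2000L, 2006L), phase2 = c(1995L, 2006L),
                             last_two_years = NULL) {
  phase1 <- assert_year_range(phase1)
  phase2 <- assert_year_range(phase2)
  if (phase2[1] > phase1[1] || phase2[2] < phase1[2]) {
    stop("phase2 window must contain phase1", call. = FALSE)
  }
  last_two_years <- as.integer(last_two_years %||% c(phase1[2] - 1L, phase1[2]))
  if (!all(last_two_years >= phase1[1] & last_two_years <= phase1[2])) {
    stop("last_two_years must lie within phase1", call. = FALSE)
  }
  structure(list(phase1 = phase1, phase2 = phase2,
                 last_two_years = last_two_years),
            class = "detection_window")
}

#' Evaluate the four treated-diabetes criteria for one patient
#'
#' A patient is considered treated for diabetes when at least one of four
#' criteria on yearly ATC-A10 delivery counts holds:
#'
#' 1. at least 3 deliveries per year in 2 or more years;
#' 2. at least 3 deliveries in 1 year and at least 2 deliveries per year in
#'    2 or more *other* years (see `overlap_criterion2`);
#' 3. at least 2 deliveries per year in 3 or more years (patients often
#'    abroad fill part of their prescriptions elsewhere);
#' 4. at least 3 deliveries in the year of death, the year before death, or
#'    either of the window's last two years (right truncation: incident
#'    cases of the final years and decedents cannot accumulate 2 treated
#'    years).
#'
#' Years need not be consecutive. Criterion 2's qualifying 3-delivery year
#' does not by default double-count toward its two 2-delivery years;
#' `overlap_criterion2 = TRUE` switches to the overlapping reading.
#'
#' @param counts Named integer vector of yearly A10 delivery counts, names
#'   are calendar years. Years outside the evaluated window are ignored.
#' @param window A [detection_window()].
#' @param death_year Calendar year of death, or `NA` if alive.
#' @param phase Which phase's year window to evaluate over (1 or 2).
#' @param overlap_criterion2 Allow the 3-delivery year to also count toward
#'   criterion 2's 2-delivery years.
#' @return Integer vector, the sorted subset of `c(1, 2, 3, 4)` satisfied
#'   (possibly empty).
#' @examples
#' w <- detection_window()
#' evaluate_criteria(c("2000" = 3, "2003" = 4), w)        # criterion 1
#' evaluate_criteria(c("2000" = 2, "2001" = 2, "2002" = 2), w)  # criterion 3
#' evaluate_criteria(c("2005" = 3), w)                    # criterion 4 only
#' @export
evaluate_criteria <- function(counts, window = detection_window(),
                              death_year = NA, phase = 1L,
                              overlap_criterion2 = FALSE) {
  stopifnot(inherits(window, "detection_window"), phase %in% c(1L, 2L))
  if (length(counts) && any(counts < 0)) {
    stop("delivery counts must be non-negative", call. = FALSE)
  }
  rng <- if (phase == 1L) window$phase1 else window$phase2
  if (length(counts)) {
    yrs <- as.integer(names(counts))
    if (anyNA(yrs)) stop("`counts` must be named by calendar year", call. = FALSE)
    counts <- counts[yrs >= rng[1] & yrs <= rng[2]]
    yrs <- as.integer(names(counts))
  } else {
    yrs <- integer(0)
  }
  n3 <- sum(counts >= 3)
  n2 <- sum(counts >= 2)
  c1 <- n3 >= 2
  c2 <- if (overlap_criterion2) n3 >= 1 && n2 >= 2 else n3 >= 1 && (n2 - 1) >= 2
  c3 <- n2 >= 3
  c4_years <- window$last_two_years
  if (!is.na(death_year)) c4_years <- c(c4_years, death_year, death_year - 1L)
  c4 <- any(counts[yrs %in% c4_years] >= 3)
  which(c(c1, c2, c3, c4))
}

#' Primary criterion attribution
#'
#' For reporting the criterion mix of a detected population, each patient is
#' attributed one criterion: the lowest-numbered of criteria 1-3 that
#' matched, and criterion 4 only when no other matched (its role is to
#' rescue truncated trajectories, not to relabel well-observed ones).
#'
#' @param criteria Integer vector of matched criteria (non-empty).
#' @return A single integer in 1..4.
#' @export
primary_criterion <- function(criteria) {
  stopifnot(length(criteria) >= 1L)
  main <- setdiff(criteria, 4L)
  if (length(main)) min(main) else 4L
}

#' Patients with at least one A10 claim
#'
#' The preliminary selection: any patient reimbursed at least one
#' hypoglycemic agent (ATC prefix A10) during the horizon. Every detected
#' case is necessarily in this set.
#'
#' @param claims Claims tibble.
#' @param horizon Two years bounding the selection; default all years present.
#' @return Character vector of patient ids.
#' @export
preselect_a10 <- function(claims, horizon = NULL) {
  m <- claims[atc_matches(claims$atc_code, "A10"), , drop = FALSE]
  if (!is.null(horizon)) {
    horizon <- assert_year_range(horizon)
    yr <- claim_year(m$delivery_date)
    m <- m[yr >= horizon[1] & yr <= horizon[2], , drop = FALSE]
  }
  unique(m$patient_id)
}

#' Detect treated-diabetes patients (step 1, two phases)
#'
#' Applies [evaluate_criteria()] to every patient in the A10 delivery
#' matrix. Phase 1 restricts counts to the phase-1 years; patients not
#' selected there are re-evaluated over the phase-2 years (all four criteria
#' again) and, if selected, annotated `phase = 2`. All matched criteria are
#' recorded, along with the [primary_criterion()].
#'
#' @param matrix A `delivery_matrix` for ATC prefix `"A10"` covering the
#'   phase-2 window (see [count_deliveries()]).
#' @param persons Persons tibble; supplies death years for criterion 4.
#'   Patients present in the matrix but absent from `persons` are processed
#'   with unknown death year, with a warning.
#' @param window A [detection_window()].
#' @param overlap_criterion2 Passed to [evaluate_criteria()].
#' @return A tibble `(patient_id, phase, criteria, primary_criterion)` with
#'   `criteria` a comma-separated string such as `"1,4"`.
#' @export
detect_cases <- function(matrix, persons, window = detection_window(),
                         overlap_criterion2 = FALSE) {
  stopifnot(inherits(matrix, "delivery_matrix"))
  if (matrix$year_range[1] > window$phase2[1] || matrix$year_range[2] < window$phase2[2]) {
    stop("delivery matrix must cover the phase-2 window", call. = FALSE)
  }
  counts <- matrix$counts
  dy <- death_years(persons)
  ids <- unique(counts$patient_id)
  unknown <- setdiff(ids, persons$patient_id)
  if (length(unknown)) {
    warning(length(unknown), " patient(s) in the delivery matrix are absent ",
            "from the person registry; processed with unknown death year",
            call. = FALSE)
  }
  by_patient <- split(
    stats::setNames(counts$n, counts$year),
    counts$patient_id
  )
  res <- lapply(ids, function(id) {
    v <- by_patient[[id]]
    d <- if (id %in% names(dy)) dy[[id]] else NA_integer_
    crit <- evaluate_criteria(v, window, death_year = d, phase = 1L,
                              overlap_criterion2 = overlap_criterion2)
    phase <- 1L
    if (!length(crit)) {
      crit <- evaluate_criteria(v, window, death_year = d, phase = 2L,
                                overlap_criterion2 = overlap_criterion2)
      phase <- 2L
    }
    if (!length(crit)) return(NULL)
    tibble::tibble(
      patient_id = id, phase = phase,
      criteria = paste(crit, collapse = ","),
      primary_criterion = primary_criterion(crit)
    )
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    out <- tibble::tibble(patient_id = character(0), phase = integer(0),
                          criteria = character(0), primary_criterion = integer(0))
  }
  out
}
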