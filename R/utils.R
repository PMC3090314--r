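#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used when
#' reporting percentages at fixed precision), unlike [base::round()] which
#' rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(97.65, 1) # 97.7
#' round(97.65, 1)         # 97.6 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_year_range <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2]) {
    stop(sprintf("`%s` must be two years c(first, last) with first <= last", arg),
         call. = FALSE)
  }
  as.integer(x)
}

#' @noRd
claim_year <- function(date) as.integer(format(date, "%Y"))

#' @noRd
atc_matches <- function(atc, prefix) {
  startsWith(toupper(atc), toupper(prefix))
}

#' @noRd
death_years <- function(persons) {
  yr <- rep(NA_integer_, nrow(persons))
  has <- !is.na(persons$death_date)
  yr[has] <- claim_year(persons$death_date[has])
  stats::setNames(yr, persons$patient_id)
}

#' Ten-year age-class labels
#'
#' Assigns ages to the default ten-year age classes `0-9`, `10-19`, ...,
#' `90-100`; the final class is closed on both ends so centenarians are kept.
#'
#' @param age Integer vector of ages in years.
#' @param breaks Increasing integer vector of left endpoints plus the final
#'   (inclusive) upper bound; default `seq(0, 100, 10)`.
#' @return Character vector of class labels; `NA` outside the break range.
#' @examples
#' age_class_label(c(4, 66, 100))
#' @export
age_class_label <- function(age, breaks = seq(0, 100, by = 10)) {
  breaks <- as.integer(breaks)
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  k <- length(breaks) - 1L
  labs <- paste0(breaks[-length(breaks)], "-", breaks[-1] - 1L)
  labs[k] <- paste0(breaks[k], "-", breaks[k + 1L])
  idx <- findInterval(age, breaks, rightmost.closed = TRUE)
  out <- rep(NA_character_, length(age))
  ok <- !is.na(idx) & idx >= 1L & idx <= k
  out[ok] <- labs[idx[ok]]
  out
}
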