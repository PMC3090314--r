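#' Inputs for gold-standard-free validity bounds
#'
#' When no gold standard exists, classifier validity can still be bracketed:
#' given the total treated-diabetes population, the number classified type 2
#' (positives) and type 1 (negatives), and a plausible range for the true
#' type-2 proportion (T2P), every confusion-matrix cell is constrained to an
#' interval. The default misclassification caps encode the extreme
#' assignments at the T2P range limits: at most
#' `positives - t2p_min * pop_total` type-1 patients hide among the
#' positives, and at most `t2p_max * pop_total - positives` type-2 patients
#' hide among the negatives.
#'
#' @param pop_total Total treated-diabetes cases.
#' @param positives Cases classified type 2.
#' @param t2p_min,t2p_max Bounds on the true type-2 proportion, in (0, 1).
#' @param fp_cap,fn_cap Optional overrides of the default caps.
#' @return An object of class `validity_inputs`.
#' @export
validity_inputs <- function(pop_total, positives, t2p_min, t2p_max,
                            fp_cap = NULL, fn_cap = NULL) {
  stopifnot(pop_total > 0, positives >= 0, positives <= pop_total,
            t2p_min > 0, t2p_max < 1, t2p_min <= t2p_max)
  negatives <- pop_total - positives
  fp_cap <- fp_cap %||% max(0, positives - t2p_min * pop_total)
  fn_cap <- fn_cap %||% max(0, t2p_max * pop_total - positives)
  structure(
    list(pop_total = pop_total, positives = positives, negatives = negatives,
         t2p_min = t2p_min, t2p_max = t2p_max,
         fp_cap = fp_cap, fn_cap = fn_cap),
    class = "validity_inputs"
  )
}

#' Confusion-matrix cell intervals at a given true type-2 proportion
#'
#' With `D2 = t2p * pop_total` true type-2 patients (kept real-valued; see
#' Details) and `D1 = pop_total - D2` true type-1 patients, the false
#' negatives satisfy `FN >= max(0, D2 - positives)` and
#' `FN <= min(negatives, D2, fn_cap, min(D1, fp_cap) + D2 - positives)` —
#' the last term propagating the false-positive cap through
#' `FP = positives - D2 + FN`. The other cells follow by the margins
#' `TP + FN = D2`, `FP + TN = D1`, `TP + FP = positives`,
#' `FN + TN = negatives`, so all four intervals are mutually consistent at
#' each endpoint.
#'
#' `D2` is generally non-integer; it is used exactly in all ratios and only
#' rounded when counts are displayed.
#'
#' @param inputs A [validity_inputs()].
#' @param t2p True type-2 proportion; must lie in
#'   `[inputs$t2p_min, inputs$t2p_max]`.
#' @return A one-row tibble with `t2p`, `d2`, `d1` and `_lo`/`_hi` columns
#'   for `tp`, `fp`, `tn`, `fn` (real-valued).
#' @examples
#' vi <- validity_inputs(22178, 21068, t2p_min = 0.928, t2p_max = 0.967)
#' confusion_bounds(vi, 0.928)  # forces FN = 0: all negatives are true
#' @export
confusion_bounds <- function(inputs, t2p) {
  stopifnot(inherits(inputs, "validity_inputs"))
  if (t2p < inputs$t2p_min - 1e-12 || t2p > inputs$t2p_max + 1e-12) {
    stop(sprintf("t2p = %g outside the configured range [%g, %g]",
                 t2p, inputs$t2p_min, inputs$t2p_max), call. = FALSE)
  }
  pos <- inputs$positives
  neg <- inputs$negatives
  d2 <- t2p * inputs$pop_total
  d1 <- inputs$pop_total - d2
  fn_lo <- max(0, d2 - pos)
  fn_hi <- min(neg, d2, inputs$fn_cap, min(d1, inputs$fp_cap) + d2 - pos)
  if (fn_hi < fn_lo - 1e-9) {
    stop("no confusion matrix is consistent with these inputs at t2p = ", t2p,
         call. = FALSE)
  }
  fn_hi <- max(fn_hi, fn_lo)
  tibble::tibble(
    t2p = t2p, d2 = d2, d1 = d1,
    tp_lo = d2 - fn_hi, tp_hi = d2 - fn_lo,
    fp_lo = pos - (d2 - fn_lo), fp_hi = pos - (d2 - fn_hi),
    tn_lo = neg - fn_hi, tn_hi = neg - fn_lo,
    fn_lo = fn_lo, fn_hi = fn_hi
  )
}

#' Validity-metric intervals over a grid of true type-2 proportions
#'
#' For each grid value the confusion-cell intervals are converted to
#' sensitivity `SE = TP / D2`, specificity `SPE = TN / D1`, positive
#' predictive value `PPV = TP / positives` and negative predictive value
#' `NPV = TN / negatives`, reported in percent rounded half-up at one
#' decimal. The attribute `"minima"` holds the grid-wide minima of the
#' lower bounds — the "always higher than" guarantees of the classifier.
#'
#' @param inputs A [validity_inputs()].
#' @param t2p_grid Proportions within `[t2p_min, t2p_max]`; defaults to the
#'   two range limits.
#' @return A tibble with one row per grid value (cell intervals plus
#'   `se_lo`, `se_hi`, `spe_lo`, `spe_hi`, `ppv_lo`, `ppv_hi`, `npv_lo`,
#'   `npv_hi` in percent) and attribute `minima`, a named numeric vector.
#' @examples
#' vi <- validity_inputs(22178, 21068, t2p_min = 0.928, t2p_max = 0.967)
#' mi <- metric_intervals(vi, c(0.928, 0.94, 0.967))
#' attr(mi, "minima")
#' @export
metric_intervals <- function(inputs, t2p_grid = NULL) {
  stopifnot(inherits(inputs, "validity_inputs"))
  t2p_grid <- t2p_grid %||% c(inputs$t2p_min, inputs$t2p_max)
  rows <- dplyr::bind_rows(lapply(t2p_grid, confusion_bounds, inputs = inputs))
  pct <- function(x) round_half_up(100 * x, 1)
  rows <- dplyr::mutate(
    rows,
    se_lo  = pct(.data$tp_lo / .data$d2),  se_hi  = pct(.data$tp_hi / .data$d2),
    spe_lo = pct(.data$tn_lo / .data$d1),  spe_hi = pct(.data$tn_hi / .data$d1),
    ppv_lo = pct(.data$tp_lo / inputs$positives),
    ppv_hi = pct(.data$tp_hi / inputs$positives),
    npv_lo = pct(.data$tn_lo / inputs$negatives),
    npv_hi = pct(.data$tn_hi / inputs$negatives)
  )
  attr(rows, "minima") <- c(
    se = min(rows$se_lo), spe = min(rows$spe_lo),
    ppv = min(rows$ppv_lo), npv = min(rows$npv_lo)
  )
  rows
}

#' Pool per-age-class bounds on the true type-2 proportion
#'
#' The true type-2 proportion is not homogeneous across ages (virtually all
#' childhood-onset diabetes is type 1; nearly all late-onset is type 2), so
#' its plausible range is built per age class and pooled by population
#' shares: the pooled bounds are the share-weighted sums of the class lower
#' and upper bounds.
#'
#' @param class_shares Named numeric vector of population shares per age
#'   class; must sum to 1 (tolerance 1e-6).
#' @param class_t2p_bounds Named list (same names) of `c(lo, hi)` bounds in
#'   `[0, 1]`.
#' @return Numeric `c(t2p_min, t2p_max)`.
#' @examples
#' t2p_range_from_classes(
#'   c(young = 0.5, old = 0.5),
#'   list(young = c(0.8, 0.9), old = c(1, 1))
#' )
#' @export
t2p_range_from_classes <- function(class_shares, class_t2p_bounds) {
  if (abs(sum(class_shares) - 1) > 1e-6) {
    stop("age-class shares must sum to 1", call. = FALSE)
  }
  if (!setequal(names(class_shares), names(class_t2p_bounds))) {
    stop("age-class names of shares and bounds must match", call. = FALSE)
  }
  b <- class_t2p_bounds[names(class_shares)]
  lo <- vapply(b, `[`, numeric(1), 1)
  hi <- vapply(b, `[`, numeric(1), 2)
  stopifnot(all(lo >= 0 & hi <= 1 & lo <= hi))
  c(t2p_min = sum(class_shares * lo), t2p_max = sum(class_shares * hi))
}

#' Cross-check rejected patients against hospital-discharge diabetes codes
#'
#' Patients rejected by the detection step should rarely carry a diabetes
#' discharge diagnosis (ICD-10 E10-E14); this counts those who do. Codes
#' are matched on their three-character root, so `"E11.9"` matches.
#'
#' @param rejected Character vector of rejected patient ids.
#' @param discharge_records Tibble `(patient_id, icd10_code)`; a patient may
#'   have several rows. Malformed codes are skipped with a warning.
#' @return A list with `n_rejected`, `n_with_diabetes_code` and
#'   `prop_of_rejected` (the caller may prefer another denominator; the raw
#'   count is authoritative).
#' @export
discharge_crosscheck <- function(rejected, discharge_records) {
  rejected <- unique(as.character(rejected))
  codes <- toupper(trimws(discharge_records$icd10_code))
  ok <- grepl("^[A-Z][0-9]{2}", codes)
  if (any(!ok)) {
    warning(sum(!ok), " malformed ICD-10 code(s) skipped", call. = FALSE)
  }
  root <- substr(codes[ok], 1, 3)
  hit_ids <- unique(discharge_records$patient_id[ok][root %in% paste0("E1", 0:4)])
  n_hit <- sum(rejected %in% hit_ids)
  list(
    n_rejected = length(rejected),
    n_with_diabetes_code = n_hit,
    prop_of_rejected = if (length(rejected)) n_hit / length(rejected) else NA_real_
  )
}
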