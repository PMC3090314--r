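# Independent brute-force oracles. These deliberately use exhaustive
# enumeration (combn over year subsets, enumeration over label assignments,
# literal smoothing recursions) rather than the counting shortcuts used by
# the implementation.

# The four treated-diabetes criteria by explicit subset enumeration.
oracle_criteria <- function(counts, last_two, death_year = NA) {
  yrs <- as.integer(names(counts))
  yrs_ge <- function(th) yrs[counts >= th]
  has_subset <- function(pool, k) {
    length(pool) >= k && (k == 0 || ncol(utils::combn(pool, k)) >= 1)
  }
  c1 <- has_subset(yrs_ge(3), 2)
  c2 <- FALSE
  for (y3 in yrs_ge(3)) {
    if (has_subset(setdiff(yrs_ge(2), y3), 2)) c2 <- TRUE
  }
  c3 <- has_subset(yrs_ge(2), 3)
  special <- last_two
  if (!is.na(death_year)) special <- c(special, death_year, death_year - 1L)
  c4 <- any(counts[yrs %in% special] >= 3)
  which(c(c1, c2, c3, c4))
}

# All integer confusion matrices consistent with the totals, the true
# type-2 count d2, and the misclassification caps. Returns a matrix with
# one row per feasible assignment (possibly zero rows).
oracle_confusion_cells <- function(pop, pos, d2, fp_cap, fn_cap) {
  neg <- pop - pos
  d1 <- pop - d2
  rows <- list()
  for (fn in 0:neg) {
    tp <- d2 - fn
    fp <- pos - tp
    tn <- neg - fn
    if (tp < 0 || fp < 0 || tn < 0) next
    if (fp > d1 || fp > fp_cap || fn > fn_cap) next
    rows[[length(rows) + 1L]] <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  }
  do.call(rbind, rows)
}

# One-step-ahead RMSE of Brown's smoothing, written as the literal
# textbook recursion.
oracle_des_rmse <- function(x, alpha) {
  s1 <- x[1]
  s2 <- x[1]
  se <- 0
  for (t in 2:length(x)) {
    pred <- (2 * s1 - s2) + alpha / (1 - alpha) * (s1 - s2)
    se <- se + (x[t] - pred)^2
    s1 <- alpha * x[t] + (1 - alpha) * s1
    s2 <- alpha * s1 + (1 - alpha) * s2
  }
  sqrt(se / (length(x) - 1))
}
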