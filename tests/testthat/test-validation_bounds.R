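lux_inputs <- function() validity_inputs(22178, 21068, t2p_min = 0.928, t2p_max = 0.967)

test_that("the T2P range limits force the extreme assignments", {
  vi <- lux_inputs()
  lo <- confusion_bounds(vi, 0.928)
  # at the lower limit every classifier negative is a true negative
  expect_equal(lo$fn_lo, 0)
  expect_equal(lo$fn_hi, 0)
  expect_equal(round(lo$tp_lo), 20581)
  expect_equal(lo$tn_lo, 1110)

  hi <- confusion_bounds(vi, 0.967)
  # at the upper limit every classifier positive is a true positive
  expect_equal(hi$tp_lo, 21068)
  expect_equal(hi$tp_hi, 21068)
  expect_lt(hi$fp_hi, 1)
  expect_equal(round(hi$tn_hi), 732)

  expect_error(confusion_bounds(vi, 0.90), "outside")
})

test_that("degenerate all-positive classifier yields a point confusion matrix", {
  vi <- validity_inputs(100, 100, t2p_min = 0.999, t2p_max = 0.999)
  b <- confusion_bounds(vi, 0.999)
  expect_equal(b$tp_lo, 99.9)
  expect_equal(b$fn_hi, 0)
  expect_equal(b$tn_hi, 0)
})

test_that("cell intervals match exhaustive enumeration of label assignments", {
  set.seed(202)
  n_checked <- 0
  for (i in 1:250) {
    pop <- sample(5:30, 1)
    pos <- sample(1:(pop - 1), 1)
    d2 <- sample(1:(pop - 1), 1)
    fp_cap <- sample(0:pop, 1)
    fn_cap <- sample(0:pop, 1)
    t2p <- d2 / pop
    vi <- validity_inputs(pop, pos, t2p_min = t2p, t2p_max = t2p,
                          fp_cap = fp_cap, fn_cap = fn_cap)
    cells <- oracle_confusion_cells(pop, pos, d2, fp_cap, fn_cap)
    info <- sprintf("pop=%d pos=%d d2=%d fp_cap=%d fn_cap=%d", pop, pos, d2, fp_cap, fn_cap)
    if (is.null(cells)) {
      expect_error(confusion_bounds(vi, t2p), "consistent", info = info)
      next
    }
    b <- confusion_bounds(vi, t2p)
    expect_equal(c(b$tp_lo, b$tp_hi), range(cells[, "tp"]), info = info)
    expect_equal(c(b$fp_lo, b$fp_hi), range(cells[, "fp"]), info = info)
    expect_equal(c(b$tn_lo, b$tn_hi), range(cells[, "tn"]), info = info)
    expect_equal(c(b$fn_lo, b$fn_hi), range(cells[, "fn"]), info = info)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 150)
})

test_that("metric intervals reproduce the published extreme rows", {
  mi <- metric_intervals(lux_inputs(), c(0.928, 0.967))
  lo <- mi[1, ]
  expect_equal(lo$se_lo, 100.0)
  expect_equal(lo$spe_lo, 69.5)
  expect_equal(lo$ppv_lo, 97.7)
  expect_equal(lo$npv_lo, 100.0)
  hi <- mi[2, ]
  expect_equal(hi$se_lo, 98.2)
  expect_equal(hi$npv_lo, 65.9)
})

test_that("a perfect classifier with zero caps scores 100 everywhere", {
  vi <- validity_inputs(100, 95, t2p_min = 0.95, t2p_max = 0.95,
                        fp_cap = 0, fn_cap = 0)
  mi <- metric_intervals(vi, 0.95)
  expect_equal(unname(attr(mi, "minima")), rep(100, 4))
})

test_that("metric minima land where the margins bind", {
  mi <- metric_intervals(lux_inputs(), c(0.928, 0.93, 0.94, 0.95, 0.96, 0.967))
  # SE and PPV floors are set at/near the upper T2P limit, NPV at the upper,
  # SPE at an interior row; all intervals are ordered and within [0, 100]
  expect_true(all(mi$se_lo <= mi$se_hi))
  expect_true(all(mi$npv_lo <= mi$npv_hi))
  expect_true(all(mi$spe_lo >= 0 & mi$spe_hi <= 100))
  m <- attr(mi, "minima")
  expect_equal(mi$se_lo[mi$t2p == 0.967], m[["se"]])
  expect_equal(mi$npv_lo[mi$t2p == 0.967], m[["npv"]])
  expect_equal(mi$ppv_lo[mi$t2p == 0.928], m[["ppv"]])
})

test_that("age-class T2P bounds pool by population shares", {
  expect_equal(
    unname(t2p_range_from_classes(c(all = 1), list(all = c(0.9, 0.95)))),
    c(0.9, 0.95)
  )
  expect_equal(
    unname(t2p_range_from_classes(c(a = 0.5, b = 0.5),
                                  list(a = c(0.8, 0.9), b = c(1, 1)))),
    c(0.9, 0.95)
  )
  expect_error(t2p_range_from_classes(c(a = 0.6, b = 0.6),
                                      list(a = c(0, 1), b = c(0, 1))),
               "sum to 1")

  # any share-weighted point with class values inside their bounds lies
  # inside the pooled interval
  set.seed(33)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    shares <- stats::setNames(as.numeric(rdirichlet_flat(k)), letters[1:k])
    lo <- stats::runif(k, 0, 0.5)
    hi <- lo + stats::runif(k, 0, 0.5)
    bounds <- stats::setNames(Map(c, lo, hi), letters[1:k])
    pooled <- t2p_range_from_classes(shares, bounds)
    point <- sum(shares * stats::runif(k, lo, hi))
    expect_gte(point, pooled[["t2p_min"]] - 1e-12)
    expect_lte(point, pooled[["t2p_max"]] + 1e-12)
  }
})

test_that("discharge cross-check matches ICD-10 roots E10-E14", {
  discharges <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    icd10_code = c("E11.9", "E66.0", "bad-code")
  )
  expect_warning(
    res <- discharge_crosscheck(c("p1", "p2", "p3", "p4"), discharges),
    "malformed"
  )
  expect_equal(res$n_with_diabetes_code, 1L)
  expect_equal(res$prop_of_rejected, 0.25)

  empty <- discharge_crosscheck(c("p1"), tibble::tibble(patient_id = character(0),
                                                        icd10_code = character(0)))
  expect_equal(empty$n_with_diabetes_code, 0L)
})
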