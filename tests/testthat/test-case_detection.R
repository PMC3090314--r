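test_that("each criterion fires on its canonical pattern", {
  w <- detection_window()
  expect_true(1 %in% evaluate_criteria(c("2000" = 3, "2003" = 4), w))
  # three 2-delivery years: criterion 3 alone (no 3-delivery year for criterion 2)
  expect_equal(evaluate_criteria(c("2000" = 2, "2001" = 2, "2002" = 2), w), 3L)
  # a single well-treated year among the window's last two: truncation rescue
  expect_equal(evaluate_criteria(c("2005" = 3), w), 4L)
  # one 3-delivery year plus two other 2-delivery years: criterion 2 (and
  # necessarily 3, since the non-overlapping reading needs three 2+ years)
  expect_equal(evaluate_criteria(c("2001" = 3, "2002" = 2, "2004" = 2), w),
               c(2L, 3L))
  expect_equal(evaluate_criteria(stats::setNames(integer(0), character(0)), w),
               integer(0))
  # death-year arm of criterion 4
  expect_equal(evaluate_criteria(c("2002" = 3), w, death_year = 2003), 4L)
  expect_error(evaluate_criteria(c("2002" = -1), w), "non-negative")
})

test_that("criterion 2 readings differ only on overlapping year sets", {
  w <- detection_window()
  counts <- c("2001" = 3, "2002" = 2) # the 3-year would need to double-count
  expect_false(2 %in% evaluate_criteria(counts, w))
  expect_true(2 %in% evaluate_criteria(counts, w, overlap_criterion2 = TRUE))
})

test_that("criteria agree with the subset-enumeration oracle on small instances", {
  w <- detection_window(phase1 = c(2003, 2006))
  yrs <- 2003:2006
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3)
  set.seed(11)
  grid <- grid[sample.int(nrow(grid), 60), ]
  for (i in seq_len(nrow(grid))) {
    counts <- stats::setNames(as.numeric(grid[i, ]), yrs)
    for (dy in c(NA, 2004, 2006)) {
      expect_equal(
        evaluate_criteria(counts, w, death_year = dy),
        oracle_criteria(counts, w$last_two_years, dy),
        info = paste(paste(counts, collapse = ","), "death", dy)
      )
    }
  }
})

test_that("primary criterion attributes 4 only as a last resort", {
  expect_equal(primary_criterion(c(1L, 2L, 4L)), 1L)
  expect_equal(primary_criterion(c(2L, 3L)), 2L)
  expect_equal(primary_criterion(4L), 4L)
})

test_that("detection runs in two phases and flags late-phase rescues", {
  # dead in 1998 with two well-treated years before: invisible to phase 1
  claims <- claims_from_counts(list(
    early_death = c("1996" = 3, "1997" = 3),
    ordinary    = c("2001" = 4, "2002" = 4),
    one_off     = c("2001" = 1)
  ))
  persons <- make_persons(c("early_death", "ordinary", "one_off"),
                          death_date = as.Date(c("1998-03-01", NA, NA)))
  m <- count_deliveries(claims, "A10", c(1995, 2006))
  cases <- detect_cases(m, persons)
  expect_setequal(cases$patient_id, c("early_death", "ordinary"))
  expect_equal(cases$phase[cases$patient_id == "early_death"], 2L)
  expect_equal(cases$phase[cases$patient_id == "ordinary"], 1L)
})

test_that("detection is monotone in deliveries and ignores out-of-phase-1 claims", {
  base_counts <- list(p = c("2001" = 2, "2002" = 2, "2003" = 2))
  persons <- make_persons("p")
  m <- count_deliveries(claims_from_counts(base_counts), "A10", c(1995, 2006))
  base_case <- detect_cases(m, persons)
  expect_equal(base_case$patient_id, "p")

  # adding deliveries anywhere never removes a selected patient
  set.seed(5)
  for (rep in 1:10) {
    extra <- base_counts
    y <- sample(1995:2006, 1)
    extra$p[as.character(y)] <- sum(extra$p[as.character(y)], sample(1:3, 1), na.rm = TRUE)
    m2 <- count_deliveries(claims_from_counts(extra), "A10", c(1995, 2006))
    expect_true("p" %in% detect_cases(m2, persons)$patient_id)
  }

  # phase-1 membership is untouched by pre-2000 claims
  with_history <- claims_from_counts(list(p = c("1995" = 4, "1996" = 4,
                                                "2001" = 2, "2002" = 2, "2003" = 2)))
  m3 <- count_deliveries(with_history, "A10", c(1995, 2006))
  cases3 <- detect_cases(m3, persons)
  expect_equal(cases3$phase[cases3$patient_id == "p"], 1L)
  expect_equal(cases3$criteria[cases3$patient_id == "p"],
               base_case$criteria[base_case$patient_id == "p"])
})

test_that("the A10 preselection always contains the detected cases", {
  claims <- dplyr::bind_rows(
    claims_from_counts(list(p1 = c("2001" = 4, "2002" = 4))),
    make_claims("p2", "2003-02-01", "A10AB01"),
    make_claims("p3", "2003-02-01", "C10AA05")
  )
  pre <- preselect_a10(claims, c(1995, 2006))
  expect_setequal(pre, c("p1", "p2"))
  m <- count_deliveries(claims, "A10", c(1995, 2006))
  cases <- detect_cases(m, make_persons(c("p1", "p2", "p3")))
  expect_true(all(cases$patient_id %in% pre))

  sim <- simulate_population(simulation_config(n_population = 600, seed = 3))
  pre_s <- preselect_a10(sim$claims, c(1995, 2006))
  cases_s <- detect_cases(count_deliveries(sim$claims, "A10", c(1995, 2006)),
                          sim$persons)
  expect_true(all(cases_s$patient_id %in% pre_s))
})

test_that("matrix patients missing from the registry are processed with a warning", {
  claims <- claims_from_counts(list(ghost = c("2001" = 4, "2002" = 4)))
  m <- count_deliveries(claims, "A10", c(1995, 2006))
  expect_warning(cases <- detect_cases(m, make_persons("someone_else")),
                 "absent")
  expect_equal(cases$patient_id, "ghost")
})
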