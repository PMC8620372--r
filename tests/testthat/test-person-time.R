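test_that("follow-up spanning a band boundary splits symmetrically", {
  # follow-up exactly ages 55 to 65 on the 365.25 d/y scale
  birth <- as.Date("1940-01-15")
  start <- birth + ceiling(55 * 365.25)
  end <- birth + ceiling(65 * 365.25)
  subjects <- make_subjects(birth_date = birth, followup_start = start,
                            followup_end = end)
  pt <- compute_person_time(subjects, NULL)
  tol <- 1 / 365.25
  expect_equal(pt$person_years[pt$gender == "F" & pt$age_band == "50-59"],
               5, tolerance = tol)
  expect_equal(pt$person_years[pt$gender == "F" & pt$age_band == "60-69"],
               5, tolerance = tol)
  expect_equal(pt$person_years[pt$gender == "ALL"], 10, tolerance = tol)
})

test_that("person-time stops at the first event", {
  subjects <- make_subjects()  # born 1930, follow-up 1977-2014
  fe <- tibble::tibble(
    subject_id = "T001", outcome = "VT",
    event_date = as.Date("1990-06-01"), matched_code = "415.1",
    age_at_event = 60L
  )
  pt_event <- compute_person_time(subjects, fe)
  pt_full <- compute_person_time(subjects, NULL)
  total_event <- pt_event$person_years[pt_event$gender == "ALL"]
  total_full <- pt_full$person_years[pt_full$gender == "ALL"]
  expect_lt(total_event, total_full)
  # accrual runs from the 50th birthday (born 1930-01-15, in-band from 1980)
  # to the event date
  start_at_50 <- as.numeric(subjects$birth_date) + 50 * 365.25
  expect_equal(
    total_event,
    (as.numeric(as.Date("1990-06-01")) - start_at_50) / 365.25,
    tolerance = 1e-9
  )
  expect_equal(pt_event$events[pt_event$gender == "ALL"], 1L)
  expect_equal(pt_event$events[pt_event$age_band == "60-69" &
                                 pt_event$gender == "F"], 1L)
})

test_that("stratum person-time and events sum exactly to the overall row", {
  cohort <- simulate_cohort(sim_config(n_subjects = 400, seed = 21))
  fe <- identify_first_events(cohort$subjects, cohort$episodes, vt_code_set())
  pt <- compute_person_time(cohort$subjects, fe)
  strat <- pt[pt$gender != "ALL", ]
  overall <- pt[pt$gender == "ALL", ]
  expect_equal(sum(strat$person_years), overall$person_years, tolerance = 1e-9)
  expect_equal(sum(strat$events), overall$events)
})

test_that("subjects younger than the first band contribute nothing until 50", {
  # aged 40 at entry: no person-time for the first ten years
  birth <- as.Date("1937-06-01")
  subjects <- make_subjects(
    birth_date = birth,
    followup_start = as.Date("1977-06-01"),
    followup_end = as.Date("1992-06-01")
  )
  pt <- compute_person_time(subjects, NULL)
  total <- pt$person_years[pt$gender == "ALL"]
  expect_equal(total, 5, tolerance = 2 / 365.25)
  expect_equal(pt$person_years[pt$age_band == "50-59" & pt$gender == "F"],
               total, tolerance = 1e-9)
})

test_that("Lexis split matches the day-by-day brute-force oracle per subject", {
  # day-granularity rounding is below one day per subject and band; the
  # comparison is per subject so rounding cannot accumulate across people
  for (s in c(2, 13)) {
    cohort <- simulate_cohort(sim_config(n_subjects = 8, seed = s))
    fe <- identify_first_events(cohort$subjects, cohort$episodes, vt_code_set())
    expect_person_time_matches_day_loop(cohort$subjects, fe)
  }
})

test_that("degenerate follow-up intervals are hard errors", {
  bad <- make_subjects()
  bad$followup_end <- bad$followup_start - 1
  expect_error(compute_person_time(bad, NULL), "followup_end")
  born_late <- make_subjects(birth_date = as.Date("1980-01-01"))
  expect_error(compute_person_time(born_late, NULL), "born")
  two_events <- tibble::tibble(
    subject_id = c("T001", "T001"),
    event_date = as.Date(c("1990-01-01", "1991-01-01")),
    age_at_event = c(59L, 60L)
  )
  expect_error(compute_person_time(make_subjects(), two_events),
               "at most one event")
})
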