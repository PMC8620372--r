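test_that("earliest qualifying episode wins and later ones are dropped", {
  subjects <- make_subjects()
  episodes <- make_episodes(
    rep("T001", 2), c("2005-07-01", "2001-03-02"),
    list("415.1", "451.2")
  )
  fe <- identify_first_events(subjects, episodes, vt_code_set())
  expect_equal(nrow(fe), 1)
  expect_equal(fe$event_date, as.Date("2001-03-02"))
  expect_equal(fe$matched_code, "451.2")
  expect_equal(fe$outcome, "VT")
  # age at event: born 1930-01-15, event 2001-03-02 -> 71 completed years
  expect_equal(fe$age_at_event, 71L)
})

test_that("a code matches at any diagnosis position, invariant to permutation", {
  subjects <- make_subjects()
  perms <- list(
    c("451.2", "428.0", "486"),
    c("428.0", "451.2", "486"),
    c("486", "428.0", "451.2")
  )
  dates <- lapply(perms, function(p) {
    episodes <- make_episodes("T001", "2001-03-02", list(p))
    identify_first_events(subjects, episodes, vt_code_set())
  })
  for (d in dates) {
    expect_equal(d$event_date, as.Date("2001-03-02"))
    expect_equal(d$matched_code, "451.2")
  }
})

test_that("pre-2007-only dialect code does not match after the switch", {
  subjects <- make_subjects()
  post <- make_episodes("T001", "2010-05-01", "287.3")
  expect_equal(nrow(identify_first_events(subjects, post, itp_code_set())), 0)
  pre <- make_episodes("T001", "2003-05-01", "287.3")
  fe <- identify_first_events(subjects, pre, itp_code_set())
  expect_equal(fe$matched_code, "287.3")
  # the post-update code matches on both sides of the switch
  post31 <- make_episodes("T001", "2010-05-01", "287.31")
  expect_equal(nrow(identify_first_events(subjects, post31, itp_code_set())), 1)
})

test_that("distractor-only histories yield no events", {
  subjects <- make_subjects(3)
  episodes <- make_episodes(
    c("T001", "T002", "T003"),
    c("1990-01-01", "2000-06-15", "2010-11-30"),
    distractor_codes()[1:3]
  )
  expect_equal(nrow(identify_first_events(subjects, episodes, vt_code_set())), 0)
  expect_equal(nrow(identify_first_events(subjects, episodes, itp_code_set())), 0)
})

test_that("unknown subject aborts; out-of-follow-up episodes warn and drop", {
  subjects <- make_subjects()
  orphan <- make_episodes("GHOST", "2000-01-01", "415.1")
  expect_error(identify_first_events(subjects, orphan, vt_code_set()),
               "absent from the cohort")
  outside <- make_episodes(
    rep("T001", 2), c("1975-01-01", "2001-03-02"), c("415.1", "415.1")
  )
  expect_warning(
    fe <- identify_first_events(subjects, outside, vt_code_set()),
    "outside"
  )
  expect_equal(fe$event_date, as.Date("2001-03-02"))
})

test_that("same-day ties break by diagnosis position then code order", {
  subjects <- make_subjects()
  episodes <- make_episodes(
    rep("T001", 2), rep("2001-03-02", 2),
    list(c("428.0", "453.8"), c("415.1", "486"))
  )
  fe <- identify_first_events(subjects, episodes, vt_code_set())
  # 415.1 sits at position 1, beating 453.8 at position 2
  expect_equal(fe$matched_code, "415.1")
})

test_that("identification is idempotent on an already-reduced dataset", {
  cohort <- simulate_cohort(sim_config(n_subjects = 300, seed = 11))
  fe <- identify_first_events(cohort$subjects, cohort$episodes, vt_code_set())
  reduced <- make_episodes(fe$subject_id, fe$event_date,
                           as.list(fe$matched_code))
  fe2 <- identify_first_events(cohort$subjects, reduced, vt_code_set())
  expect_equal(
    fe2[order(fe2$subject_id), ],
    fe[order(fe$subject_id), ]
  )
})

test_that("first events agree with the generator's ground-truth log", {
  cohort <- simulate_cohort(sim_config(n_subjects = 800, seed = 5))
  for (oc in c("VT", "ITP")) {
    set <- if (oc == "VT") vt_code_set() else itp_code_set()
    fe <- identify_first_events(cohort$subjects, cohort$episodes, set)
    truth <- cohort$truth[cohort$truth$outcome == oc, ]
    expect_equal(nrow(fe), nrow(truth))
    m <- merge(fe, truth, by = "subject_id")
    expect_equal(m$event_date, m$first_event_date)
  }
})

test_that("wide dx1..dxK episode tables are accepted", {
  subjects <- make_subjects()
  wide <- tibble::tibble(
    subject_id = "T001", admission_date = as.Date("2001-03-02"),
    dx1 = "428.0", dx2 = "451.2", dx3 = NA_character_
  )
  fe <- identify_first_events(subjects, wide, vt_code_set())
  expect_equal(fe$matched_code, "451.2")
})
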