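test_that("zero hazards and zero distractor rate yield an empty episode list", {
  cfg <- sim_config(
    n_subjects = 50, seed = 1,
    stratum_hazards = dplyr::mutate(default_stratum_hazards(), hazard = 0),
    distractor_code_rate = 0
  )
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$episodes), 0)
  expect_equal(nrow(cohort$truth), 0)
  expect_equal(nrow(cohort$subjects), 50)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 150, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  other <- simulate_cohort(sim_config(n_subjects = 150, seed = 100))
  expect_false(identical(simulate_cohort(cfg)$episodes, other$episodes))
})

test_that("no outcome code leaks into distractors; dialect respects the switch", {
  # ITP hazard inflated so both coding dialects appear in one cohort
  hz <- dplyr::mutate(default_stratum_hazards(),
                      hazard = ifelse(outcome == "ITP", 0.01, hazard))
  cohort <- simulate_cohort(sim_config(n_subjects = 600, seed = 3,
                                       stratum_hazards = hz))
  outcome_codes <- c(vt_code_set()$codes, itp_code_set()$codes)
  ep <- cohort$episodes
  has_outcome <- vapply(
    ep$diagnoses, function(d) any(d %in% outcome_codes), logical(1)
  )
  # every episode in the truth log carries an outcome code; the rest are
  # distractor-only
  truth_keys <- paste(cohort$truth$subject_id, cohort$truth$first_event_date)
  ep_keys <- paste(ep$subject_id, ep$admission_date)
  expect_true(all(truth_keys %in% ep_keys[has_outcome]))
  # pre-2007-only dialect code never appears on or after the switch date
  has_old_itp <- vapply(ep$diagnoses, function(d) "287.3" %in% d, logical(1))
  expect_true(all(ep$admission_date[has_old_itp] < as.Date("2007-01-01")))
  # post-switch ITP admissions use the post-update code
  has_new_itp <- vapply(ep$diagnoses, function(d) "287.31" %in% d, logical(1))
  expect_true(any(has_old_itp))
  expect_true(any(has_new_itp))
  expect_true(all(ep$admission_date[has_new_itp] >= as.Date("2007-01-01")))
})

test_that("event counts concentrate around hazard x person-time across seeds", {
  # Poisson concentration: |d - hT| <= 4*sqrt(hT) in >= 99% of seeds
  h <- 0.02
  hz <- dplyr::mutate(default_stratum_hazards(),
                      hazard = ifelse(outcome == "VT", h, 0))
  hits <- vapply(1:30, function(s) {
    cfg <- sim_config(n_subjects = 150, seed = s, stratum_hazards = hz,
                      distractor_code_rate = 0)
    cohort <- simulate_cohort(cfg)
    pt <- compute_person_time(cohort$subjects, NULL)
    T_all <- pt$person_years[pt$gender == "ALL"]
    d <- sum(cohort$truth$n_events[cohort$truth$outcome == "VT"])
    abs(d - h * T_all) <= 4 * sqrt(h * T_all)
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("dose tables are returned verbatim and validated", {
  spec <- tibble::tibble(
    gender = c("F", "M"), age_band = c("50-59", "50-59"), doses = c(10L, 20L)
  )
  expect_equal(dose_table(spec), spec)
  expect_equal(nrow(dose_table(spec[0, ])), 0)
  dup <- dplyr::bind_rows(spec, spec[1, ])
  expect_error(dose_table(dup), "Duplicate")
  bad <- dplyr::mutate(spec, doses = c(-1L, 5L))
  expect_error(dose_table(bad), ">= 0")
})

test_that("the packaged dose fixture carries the published totals", {
  doses <- italy_doses_2021()
  over50 <- doses[doses$age_band != "<50", ]
  expect_equal(sum(over50$doses), 1767281L)
  expect_equal(sum(doses$doses), 2702730L)
  expect_equal(
    doses$doses[doses$gender == "F" & doses$age_band == "50-59"], 350064L
  )
})
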