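#' Default ground-truth stratum hazards for simulation
#'
#' Hazards (events per person-year) by outcome, gender and attained-age band,
#' at the magnitudes seen in population-based over-50 cohorts: venous
#' thromboembolism of order 0.3-1.7 per 1000 person-years rising with age, and
#' immune thrombocytopenia of order 2.7 per 100,000 person-years, rare enough
#' that it is analysed unstratified downstream.
#'
#' @param scheme Age-band scheme from [age_bands()].
#' @return Tibble with columns `outcome`, `gender`, `age_band`, `hazard`.
#' @export
default_stratum_hazards <- function(scheme = age_bands()) {
  bands <- scheme$age_band
  vt_f <- c(0.312, 0.743, 1.718, 1.594)[seq_along(bands)] / 1000
  vt_m <- c(0.779, 1.049, 1.440, 1.457)[seq_along(bands)] / 1000
  dplyr::bind_rows(
    tibble(outcome = "VT", gender = "F", age_band = bands, hazard = vt_f),
    tibble(outcome = "VT", gender = "M", age_band = bands, hazard = vt_m),
    tidyr::expand_grid(outcome = "ITP", gender = c("F", "M"), age_band = bands) %>%
      mutate(hazard = 2.77e-05)
  )
}

#' Simulation configuration for a synthetic claims cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults emulate a middle-aged community cohort enrolled mid-1977 and
#' followed administratively to the end of 2014, with hospital-episode
#' outcome hazards at the magnitudes of [default_stratum_hazards()].
#'
#' @param n_subjects Number of subjects (default 3066).
#' @param entry_date Follow-up start for every subject (default `"1977-06-01"`).
#' @param admin_end_date Administrative end of follow-up (default
#'   `"2014-12-31"`).
#' @param gender_split Proportion female in `[0, 1]` (default 0.5).
#' @param age_at_entry_range Two-element numeric, uniform age-at-entry range in
#'   years (default `c(40, 59)`).
#' @param stratum_hazards Tibble `(outcome, gender, age_band, hazard)` of
#'   events per person-year; ages outside the scheme have hazard zero.
#' @param distractor_code_rate Expected non-outcome hospitalizations per
#'   person-year (default 0.05).
#' @param dialect_switch_date Date the post-update ICD-9-CM dialect takes over
#'   (default `"2007-01-01"`); earlier outcome admissions are coded in the
#'   pre-update dialect where the code set defines one.
#' @param scheme Age-band scheme the hazards are keyed by.
#' @param seed Integer seed; regeneration with the same seed is bit-identical.
#' @return A validated list of class `oevax_sim_config`.
#' @export
sim_config <- function(n_subjects = 3066,
                       entry_date = as.Date("1977-06-01"),
                       admin_end_date = as.Date("2014-12-31"),
                       gender_split = 0.5,
                       age_at_entry_range = c(40, 59),
                       stratum_hazards = default_stratum_hazards(scheme),
                       distractor_code_rate = 0.05,
                       dialect_switch_date = as.Date("2007-01-01"),
                       scheme = age_bands(),
                       seed = 1L) {
  entry_date <- as.Date(entry_date)
  admin_end_date <- as.Date(admin_end_date)
  if (!isTRUE(n_subjects >= 1)) abort("`n_subjects` must be a positive count.")
  if (!isTRUE(entry_date < admin_end_date)) {
    abort("`entry_date` must precede `admin_end_date`.")
  }
  if (!isTRUE(gender_split >= 0 && gender_split <= 1)) {
    abort("`gender_split` must lie in [0, 1].")
  }
  if (length(age_at_entry_range) != 2 || diff(age_at_entry_range) < 0) {
    abort("`age_at_entry_range` must be c(lower, upper) with lower <= upper.")
  }
  stratum_hazards <- as_tibble(stratum_hazards)
  needed <- c("outcome", "gender", "age_band", "hazard")
  if (nrow(stratum_hazards) == 0 || !all(needed %in% names(stratum_hazards))) {
    abort("`stratum_hazards` must have columns outcome, gender, age_band, hazard.")
  }
  if (any(stratum_hazards$hazard < 0)) abort("Hazards must be >= 0.")
  check_gender(stratum_hazards$gender)
  if (!all(stratum_hazards$age_band %in% scheme$age_band)) {
    abort("`stratum_hazards$age_band` must use labels from `scheme`.")
  }
  if (distractor_code_rate < 0) abort("`distractor_code_rate` must be >= 0.")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      entry_date = entry_date,
      admin_end_date = admin_end_date,
      gender_split = gender_split,
      age_at_entry_range = as.numeric(age_at_entry_range),
      stratum_hazards = stratum_hazards,
      distractor_code_rate = distractor_code_rate,
      dialect_switch_date = as.Date(dialect_switch_date),
      scheme = scheme,
      seed = as.integer(seed)
    ),
    class = "oevax_sim_config"
  )
}

#' Generate a synthetic person-level cohort with hospital episodes
#'
#' Draws a cohort of subjects and their hospital episodes under known
#' ground-truth hazards, so every downstream stage (event identification,
#' person-time, rates, projection) can be tested against the truth. Within
#' each attained-age band a subject's outcome events follow a
#' time-homogeneous Poisson process at the configured hazard; every outcome
#' occurrence is emitted as an episode (not just the first), exercising the
#' first-occurrence filter. Outcome episodes are coded in the dialect valid at
#' the admission date; background (distractor) episodes carry codes from
#' [distractor_codes()], disjoint from all outcome definitions.
#'
#' @param config A [sim_config()].
#' @param code_sets Named list of [code_set()]s keyed by outcome label
#'   (defaults to the packaged VT and ITP definitions, with the ITP dialect
#'   switch taken from `config`).
#' @return A list of class `oevax_cohort` with tibbles:
#'   * `subjects`: `subject_id`, `gender`, `birth_date`, `followup_start`,
#'     `followup_end`;
#'   * `episodes`: `subject_id`, `admission_date`, `diagnoses` (list column,
#'     position 1 = primary);
#'   * `truth`: per subject and outcome, the ground-truth first outcome
#'     episode date and total outcome episode count.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 200, seed = 42))
#' cohort$subjects
#' @export
simulate_cohort <- function(config, code_sets = NULL) {
  stopifnot(inherits(config, "oevax_sim_config"))
  if (is.null(code_sets)) {
    code_sets <- list(
      VT = vt_code_set(),
      ITP = itp_code_set(config$dialect_switch_date)
    )
  }
  outcomes <- unique(config$stratum_hazards$outcome)
  missing_sets <- setdiff(outcomes, names(code_sets))
  if (length(missing_sets) > 0) {
    abort(paste0("No code set supplied for outcome(s): ",
                 paste(missing_sets, collapse = ", ")))
  }

  withr::with_seed(config$seed, {
    subjects <- draw_subjects(config)
    ep <- draw_outcome_episodes(config, subjects, code_sets)
    distract <- draw_distractor_episodes(config, subjects)
    episodes <- bind_rows(ep$episodes, distract) %>%
      arrange(.data$subject_id, .data$admission_date) %>%
      select("subject_id", "admission_date", "diagnoses")
    list_out <- structure(
      list(subjects = subjects, episodes = episodes, truth = ep$truth),
      class = "oevax_cohort"
    )
    list_out
  })
}

#' @export
print.oevax_cohort <- function(x, ...) {
  cat("<synthetic cohort>", nrow(x$subjects), "subjects,",
      nrow(x$episodes), "episodes,",
      sum(x$truth$n_events), "ground-truth outcome events\n")
  invisible(x)
}

draw_subjects <- function(config) {
  n <- config$n_subjects
  gender <- ifelse(runif(n) < config$gender_split, "F", "M")
  age0 <- runif(n, config$age_at_entry_range[1], config$age_at_entry_range[2])
  tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    gender = gender,
    birth_date = config$entry_date - round(age0 * DAYS_PER_YEAR),
    followup_start = config$entry_date,
    followup_end = config$admin_end_date
  )
}

# exposure segments: one row per subject x band overlapping follow-up
band_segments <- function(subjects, scheme) {
  tidyr::expand_grid(subjects, scheme) %>%
    mutate(
      seg_start = pmax(
        .data$followup_start,
        .data$birth_date + ceiling(.data$lower * DAYS_PER_YEAR)
      ),
      seg_end = if_else(
        is.finite(.data$upper),
        pmin(.data$followup_end,
             .data$birth_date + ceiling(pmin(.data$upper, 1e4) * DAYS_PER_YEAR)),
        .data$followup_end
      ),
      seg_days = pmax(0, as.numeric(.data$seg_end - .data$seg_start))
    ) %>%
    filter(.data$seg_days > 0)
}

draw_outcome_episodes <- function(config, subjects, code_sets) {
  segs <- band_segments(subjects, config$scheme)
  events <- tidyr::expand_grid(
    segs,
    outcome = unique(config$stratum_hazards$outcome)
  ) %>%
    inner_join(
      config$stratum_hazards,
      by = c("outcome", "gender", "age_band")
    ) %>%
    mutate(n_ev = rpois(n(), .data$hazard * .data$seg_days / DAYS_PER_YEAR)) %>%
    filter(.data$n_ev > 0) %>%
    tidyr::uncount(.data$n_ev) %>%
    mutate(
      admission_date = .data$seg_start +
        floor(runif(n()) * .data$seg_days)
    ) %>%
    select("subject_id", "outcome", "admission_date")

  if (nrow(events) == 0) {
    return(list(
      episodes = tibble(
        subject_id = character(), admission_date = as.Date(character()),
        diagnoses = list()
      ),
      truth = tibble(
        subject_id = character(), outcome = character(),
        first_event_date = as.Date(character()), n_events = integer()
      )
    ))
  }

  events <- events %>%
    mutate(
      matched_code = purrr::map2_chr(
        .data$outcome, .data$admission_date,
        function(o, d) sample_outcome_code(code_sets[[o]], d, config)
      ),
      diagnoses = purrr::map(.data$matched_code, pad_with_distractors)
    )

  truth <- events %>%
    group_by(.data$subject_id, .data$outcome) %>%
    summarise(
      first_event_date = min(.data$admission_date),
      n_events = dplyr::n(),
      .groups = "drop"
    )

  list(
    episodes = events %>% select("subject_id", "admission_date", "diagnoses"),
    truth = truth
  )
}

# pre-switch admissions use the old-dialect (date-restricted) codes when the
# definition has any; otherwise draw uniformly from the codes valid that day
sample_outcome_code <- function(set, date, config) {
  old <- names(set$valid_before)
  if (length(old) > 0 && date < config$dialect_switch_date) {
    pool <- old
  } else {
    pool <- codes_valid_at(set, date)
  }
  pool[sample.int(length(pool), 1L)]
}

# outcome code at a random diagnosis position among 1-3, rest distractors
pad_with_distractors <- function(code) {
  k <- sample.int(3L, 1L)
  pos <- sample.int(k, 1L)
  dx <- distractor_codes()[sample.int(length(distractor_codes()), k)]
  dx[pos] <- code
  dx
}

draw_distractor_episodes <- function(config, subjects) {
  if (config$distractor_code_rate == 0) {
    return(tibble(
      subject_id = character(), admission_date = as.Date(character()),
      diagnoses = list()
    ))
  }
  fu_days <- as.numeric(subjects$followup_end - subjects$followup_start)
  n_ep <- rpois(nrow(subjects), config$distractor_code_rate * fu_days / DAYS_PER_YEAR)
  subjects %>%
    mutate(n_ep = n_ep) %>%
    filter(.data$n_ep > 0) %>%
    tidyr::uncount(.data$n_ep) %>%
    mutate(
      admission_date = .data$followup_start +
        floor(runif(n()) * as.numeric(.data$followup_end - .data$followup_start)),
      diagnoses = purrr::map(
        sample.int(length(distractor_codes()), n(), replace = TRUE),
        function(i) distractor_codes()[i]
      )
    ) %>%
    select("subject_id", "admission_date", "diagnoses")
}

#' Build a dose table
#'
#' A dose table counts first vaccine doses by gender and age band; in a
#' first-dose-only administration window the dose count equals the number of
#' vaccinated subjects. The table is returned verbatim after validation.
#'
#' @param strata A data frame with columns `gender` (`"F"`, `"M"`, or `"ALL"`
#'   for strata not broken down by gender), `age_band`, `doses`.
#' @return Tibble with the same columns, doses as integer.
#' @examples
#' dose_table(data.frame(gender = "F", age_band = "50-59", doses = 1000))
#' @export
dose_table <- function(strata) {
  strata <- as_tibble(strata)
  if (nrow(strata) == 0) {
    return(tibble(gender = character(), age_band = character(), doses = integer()))
  }
  needed <- c("gender", "age_band", "doses")
  if (!all(needed %in% names(strata))) {
    abort("Dose table needs columns gender, age_band, doses.")
  }
  check_gender(strata$gender, allow_all = TRUE)
  if (any(strata$doses < 0)) abort("`doses` must be >= 0.")
  dup <- strata %>% dplyr::count(.data$gender, .data$age_band) %>% filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "Duplicate (gender, age_band) strata: ",
      paste(paste(dup$gender, dup$age_band), collapse = "; ")
    ))
  }
  strata %>%
    mutate(doses = as.integer(.data$doses)) %>%
    select("gender", "age_band", "doses")
}

#' First doses administered in Italy, 22 Jan - 12 Apr 2021
#'
#' ChAdOx1-S (Vaxzevria) first-dose counts by gender and 10-year age band from
#' the open Italian COVID-19 vaccine-administration repository, restricted to
#' a window in which essentially all administrations were first doses. Doses
#' to under-50s (935,449 of the 2,702,730 total) are carried as a single
#' `ALL`-gender `<50` stratum, since the over-50 projection does not use their
#' breakdown.
#'
#' @return A [dose_table()] tibble.
#' @export
italy_doses_2021 <- function() {
  path <- system.file("extdata", "italy_first_doses_2021.csv", package = "oevax")
  dose_table(readr::read_csv(path, show_col_types = FALSE))
}
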