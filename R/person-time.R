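#' Stratified person-time with Lexis expansion across age bands
#'
#' Accrues each subject's at-risk follow-up time — from `followup_start` until
#' the first outcome event or the end of follow-up, whichever comes first —
#' and splits it across attained-age bands: the time lived while aged within a
#' band accrues to that band (Lexis expansion). Subjects younger than the
#' first band contribute nothing until they age into it. Each stratum's event
#' count is the number of first events whose age at event falls in the band.
#' Person-years are day counts divided by 365.25.
#'
#' @param subjects Cohort tibble (`subject_id`, `gender`, `birth_date`,
#'   `followup_start`, `followup_end`).
#' @param first_events First events for a single outcome, from
#'   [identify_first_events()]; may have zero rows.
#' @param scheme Age-band scheme from [age_bands()].
#' @return Tibble with one row per (gender, age band) stratum plus an
#'   `ALL`/`ALL` overall row: `gender`, `age_band`, `events`, `person_years`.
#'   Stratum rows sum exactly to the overall row.
#' @export
compute_person_time <- function(subjects, first_events = NULL,
                                scheme = age_bands()) {
  subjects <- as_tibble(subjects)
  check_gender(subjects$gender)
  if (any(subjects$followup_end < subjects$followup_start)) {
    abort("Found subject(s) with followup_end before followup_start.")
  }
  if (any(subjects$birth_date >= subjects$followup_start)) {
    abort("Found subject(s) born on or after followup_start.")
  }
  if (is.null(first_events) || nrow(first_events) == 0) {
    first_events <- tibble(
      subject_id = character(), event_date = as.Date(character()),
      age_at_event = integer()
    )
  }
  if (length(unique(first_events$subject_id)) < nrow(first_events)) {
    abort("`first_events` must hold at most one event per subject.")
  }

  censored <- subjects %>%
    left_join(
      first_events %>% select("subject_id", "event_date", "age_at_event"),
      by = "subject_id"
    ) %>%
    mutate(
      risk_end = pmin(
        .data$followup_end,
        dplyr::coalesce(.data$event_date, .data$followup_end)
      )
    )

  # continuous overlap of [followup_start, risk_end) with each band's
  # attained-age window [birth + lower*365.25, birth + upper*365.25) in days
  strata <- tidyr::expand_grid(censored, scheme) %>%
    mutate(
      band_open = as.numeric(.data$birth_date) + .data$lower * DAYS_PER_YEAR,
      band_close = as.numeric(.data$birth_date) + .data$upper * DAYS_PER_YEAR,
      ov_start = pmax(as.numeric(.data$followup_start), .data$band_open),
      ov_end = pmin(as.numeric(.data$risk_end), .data$band_close),
      days = pmax(0, .data$ov_end - .data$ov_start)
    ) %>%
    group_by(.data$gender, .data$age_band) %>%
    summarise(person_years = sum(.data$days) / DAYS_PER_YEAR, .groups = "drop")

  ev_counts <- first_events %>%
    left_join(subjects %>% select("subject_id", "gender"), by = "subject_id") %>%
    mutate(age_band = assign_age_band(.data$age_at_event, scheme)) %>%
    filter(!is.na(.data$age_band)) %>%
    dplyr::count(.data$gender, .data$age_band, name = "events")

  out <- tidyr::expand_grid(
    gender = c("F", "M"), age_band = scheme$age_band
  ) %>%
    left_join(strata, by = c("gender", "age_band")) %>%
    left_join(ev_counts, by = c("gender", "age_band")) %>%
    mutate(
      person_years = dplyr::coalesce(.data$person_years, 0),
      events = as.integer(dplyr::coalesce(.data$events, 0L))
    )

  overall <- tibble(
    gender = "ALL", age_band = "ALL",
    events = sum(out$events),
    person_years = sum(out$person_years)
  )
  bind_rows(out, overall)
}
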