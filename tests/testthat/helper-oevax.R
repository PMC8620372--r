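# shared fixtures built in code

make_subjects <- function(n = 1,
                          gender = "F",
                          birth_date = as.Date("1930-01-15"),
                          followup_start = as.Date("1977-06-01"),
                          followup_end = as.Date("2014-12-31")) {
  tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)),
    gender = rep_len(gender, n),
    birth_date = rep_len(birth_date, n),
    followup_start = rep_len(followup_start, n),
    followup_end = rep_len(followup_end, n)
  )
}

make_episodes <- function(subject_id, admission_date, codes) {
  tibble::tibble(
    subject_id = subject_id,
    admission_date = as.Date(admission_date),
    diagnoses = if (is.list(codes)) codes else as.list(codes)
  )
}

# printed cells of the published stratified VT table, frozen as test oracle
published_vt_table <- function() {
  tibble::tribble(
    ~gender, ~age_band, ~events, ~person_years, ~rate, ~ci_low, ~ci_high, ~doses, ~expected,
    "F", "50-59",  2L,  6405, 0.312, 0.078, 1.248, 350064L,  4.49,
    "F", "60-69", 10L, 13460, 0.743, 0.400, 1.381, 215887L,  6.59,
    "F", "70-79", 22L, 12802, 1.718, 1.131, 2.610, 404790L, 28.58,
    "F", "80+",   10L,  6275, 1.594, 0.857, 2.962,  36940L,  2.42,
    "M", "50-59",  5L,  6422, 0.779, 0.324, 1.871, 228011L,  7.30,
    "M", "60-69", 13L, 12393, 1.049, 0.609, 1.807, 148207L,  6.39,
    "M", "70-79", 15L, 10418, 1.440, 0.868, 2.388, 358223L, 21.20,
    "M", "80+",    6L,  4117, 1.458, 0.655, 3.244,  25159L,  1.51,
    "ALL", "ALL", 83L, 72293, 1.148, 0.926, 1.424, 1767281L, 83.38
  )
}

# day-by-day person-time accumulation, the brute-force oracle for the
# continuous Lexis split; returns person-years per (gender, age_band)
brute_person_time <- function(subjects, first_events = NULL,
                              scheme = age_bands()) {
  if (is.null(first_events) || nrow(first_events) == 0) {
    first_events <- tibble::tibble(
      subject_id = character(), event_date = as.Date(character())
    )
  }
  acc <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    ev <- first_events$event_date[first_events$subject_id == s$subject_id]
    risk_end <- min(c(s$followup_end, ev))
    if (risk_end <= s$followup_start) next
    days <- seq(s$followup_start, risk_end - 1, by = "day")
    band <- assign_age_band(age_years(days, s$birth_date), scheme)
    tab <- table(band[!is.na(band)])
    for (b in names(tab)) {
      key <- paste(s$gender, b, sep = "|")
      acc[[key]] <- (acc[[key]] %||% 0) + tab[[b]] / 365.25
    }
  }
  if (length(acc) == 0) {
    return(tibble::tibble(gender = character(), age_band = character(),
                          person_years = numeric()))
  }
  keys <- strsplit(names(acc), "|", fixed = TRUE)
  tibble::tibble(
    gender = vapply(keys, `[`, "", 1),
    age_band = vapply(keys, `[`, "", 2),
    person_years = unlist(acc)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assert the continuous Lexis split agrees with the day loop for every
# subject and band to within one day of person-time
expect_person_time_matches_day_loop <- function(subjects, first_events,
                                                scheme = age_bands()) {
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, , drop = FALSE]
    fe_i <- first_events[first_events$subject_id == s$subject_id, , drop = FALSE]
    pt <- compute_person_time(s, fe_i, scheme)
    oracle <- brute_person_time(s, fe_i, scheme)
    joined <- merge(pt[pt$gender != "ALL", ], oracle,
                    by = c("gender", "age_band"), all.x = TRUE)
    joined$person_years.y[is.na(joined$person_years.y)] <- 0
    testthat::expect_true(
      all(abs(joined$person_years.x - joined$person_years.y) <= 1 / 365.25),
      label = paste("subject", s$subject_id, "day-loop agreement")
    )
  }
}
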