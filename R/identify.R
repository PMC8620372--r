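#' Identify first qualifying outcome events
#'
#' Applies a claims-based case definition to a cohort: an event is the first
#' hospital episode in a subject's follow-up carrying a code of the outcome
#' definition at any diagnosis position (primary or secondary). Codes with a
#' dialect restriction match only when valid at the admission date. At most
#' one event is returned per subject; ties on the same day are broken
#' deterministically by lowest diagnosis position, then code string order.
#'
#' Episodes dated outside a subject's follow-up interval are ignored with a
#' warning (they cannot qualify); an episode referencing a subject absent from
#' `subjects` is a data-integrity error and aborts.
#'
#' @param subjects Tibble with `subject_id`, `gender`, `birth_date`,
#'   `followup_start`, `followup_end`.
#' @param episodes Tibble with `subject_id`, `admission_date` and `diagnoses`
#'   (a list column of code vectors, position 1 = primary) or wide `dx1`,
#'   `dx2`, ... columns.
#' @param set An outcome [code_set()].
#' @return Tibble of first events: `subject_id`, `outcome`, `event_date`,
#'   `matched_code`, `age_at_event` (completed years on the 365.25 d/y scale),
#'   one row per subject with any qualifying episode.
#' @examples
#' subjects <- tibble::tibble(
#'   subject_id = "A", gender = "F",
#'   birth_date = as.Date("1940-01-15"),
#'   followup_start = as.Date("1977-06-01"),
#'   followup_end = as.Date("2014-12-31")
#' )
#' episodes <- tibble::tibble(
#'   subject_id = "A", admission_date = as.Date("2001-03-02"),
#'   diagnoses = list(c("428.0", "451.2"))
#' )
#' identify_first_events(subjects, episodes, vt_code_set())
#' @export
identify_first_events <- function(subjects, episodes, set) {
  stopifnot(inherits(set, "oevax_code_set"))
  subjects <- as_tibble(subjects)
  episodes <- normalize_episode_table(episodes)

  empty <- tibble(
    subject_id = character(), outcome = character(),
    event_date = as.Date(character()), matched_code = character(),
    age_at_event = integer()
  )
  if (nrow(episodes) == 0) return(empty)

  unknown <- setdiff(unique(episodes$subject_id), subjects$subject_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "Episodes reference subject(s) absent from the cohort: ",
      paste(head(unknown, 5), collapse = ", "),
      if (length(unknown) > 5) ", ..."
    ))
  }

  long <- episodes %>%
    mutate(.episode = row_number()) %>%
    tidyr::unnest_longer(
      "diagnoses", values_to = "code", indices_to = "position"
    ) %>%
    mutate(code = normalize_icd9(.data$code)) %>%
    left_join(
      subjects %>%
        select("subject_id", "birth_date", "followup_start", "followup_end"),
      by = "subject_id"
    )

  out_of_window <- long %>%
    distinct(.data$.episode, .data$admission_date,
             .data$followup_start, .data$followup_end) %>%
    filter(.data$admission_date < .data$followup_start |
             .data$admission_date > .data$followup_end)
  if (nrow(out_of_window) > 0) {
    warn(paste0(
      nrow(out_of_window),
      " episode(s) dated outside the subject's follow-up were ignored."
    ))
  }

  hits <- long %>%
    filter(
      .data$admission_date >= .data$followup_start,
      .data$admission_date <= .data$followup_end,
      .data$code %in% set$codes
    )
  if (length(set$valid_before) > 0) {
    vb <- tibble(
      code = names(set$valid_before),
      .valid_before = unname(set$valid_before)
    )
    hits <- hits %>%
      left_join(vb, by = "code") %>%
      filter(is.na(.data$.valid_before) |
               .data$admission_date < .data$.valid_before)
  }
  if (nrow(hits) == 0) return(empty)

  hits %>%
    arrange(.data$subject_id, .data$admission_date, .data$position, .data$code) %>%
    group_by(.data$subject_id) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    mutate(
      outcome = set$outcome,
      age_at_event = as.integer(floor(
        age_years(.data$admission_date, .data$birth_date)
      ))
    ) %>%
    select(
      "subject_id", "outcome",
      event_date = "admission_date", matched_code = "code", "age_at_event"
    )
}

# accept either a `diagnoses` list column or wide dx1..dxK columns
normalize_episode_table <- function(episodes) {
  episodes <- as_tibble(episodes)
  if (!"subject_id" %in% names(episodes) ||
      !"admission_date" %in% names(episodes)) {
    abort("Episode table needs `subject_id` and `admission_date` columns.")
  }
  episodes$admission_date <- as.Date(episodes$admission_date)
  if ("diagnoses" %in% names(episodes)) {
    if (nrow(episodes) > 0 &&
        any(lengths(episodes$diagnoses) == 0)) {
      abort("Every episode must carry at least one diagnosis code.")
    }
    return(episodes)
  }
  dx_cols <- grep("^dx[0-9]+$", names(episodes), value = TRUE)
  if (length(dx_cols) == 0) {
    abort("Episode table needs a `diagnoses` list column or dx1..dxK columns.")
  }
  dx_cols <- dx_cols[order(as.integer(sub("dx", "", dx_cols)))]
  episodes$diagnoses <- purrr::pmap(
    episodes[dx_cols],
    function(...) {
      v <- as.character(c(...))
      v[!is.na(v) & v != ""]
    }
  )
  if (nrow(episodes) > 0 && any(lengths(episodes$diagnoses) == 0)) {
    abort("Every episode must carry at least one diagnosis code.")
  }
  episodes[c("subject_id", "admission_date", "diagnoses")]
}
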