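#' Read and write pipeline tables as headered CSV
#'
#' All tabular interchange is plain CSV with ISO-8601 dates. The cohort table
#' has columns `subject_id, gender, birth_date, followup_start, followup_end`;
#' the episode table is wide, `subject_id, admission_date, dx1..dxK` (empty
#' trailing codes blank); the dose table is `gender, age_band, doses`.
#' Malformed dates abort naming the offending row numbers.
#'
#' @param path File path.
#' @param subjects,episodes,doses Tibbles as produced by this package.
#' @return Readers return tibbles; writers return the input invisibly.
#' @name oevax-io
NULL

#' @rdname oevax-io
#' @export
read_cohort_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  needed <- c("subject_id", "gender", "birth_date", "followup_start",
              "followup_end")
  if (!all(needed %in% names(raw))) {
    abort(paste0("Cohort CSV must have columns: ", paste(needed, collapse = ", ")))
  }
  for (col in c("birth_date", "followup_start", "followup_end")) {
    parsed <- as.Date(raw[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0 || anyNA(raw[[col]])) {
      bad <- union(bad, which(is.na(raw[[col]])))
      abort(paste0(
        "Malformed ", col, " in cohort CSV at data row(s): ",
        paste(head(sort(bad), 5), collapse = ", ")
      ))
    }
    raw[[col]] <- parsed
  }
  as_tibble(raw[needed])
}

#' @rdname oevax-io
#' @export
write_cohort_csv <- function(subjects, path) {
  readr::write_csv(subjects, path)
  invisible(subjects)
}

#' @rdname oevax-io
#' @export
read_episodes_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  parsed <- as.Date(raw$admission_date, format = "%Y-%m-%d")
  bad <- which(is.na(parsed))
  if (length(bad) > 0) {
    abort(paste0(
      "Malformed admission_date in episode CSV at data row(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  raw$admission_date <- parsed
  normalize_episode_table(raw)
}

#' @rdname oevax-io
#' @export
write_episodes_csv <- function(episodes, path) {
  episodes <- normalize_episode_table(episodes)
  k <- max(1L, max(lengths(episodes$diagnoses), 0L))
  wide <- episodes %>%
    mutate(.episode = row_number()) %>%
    tidyr::unnest_longer("diagnoses", values_to = "code",
                         indices_to = "position") %>%
    mutate(position = paste0("dx", .data$position)) %>%
    tidyr::pivot_wider(names_from = "position", values_from = "code") %>%
    select(-".episode")
  # stable column order dx1..dxK
  dx_cols <- paste0("dx", seq_len(k))
  wide <- wide[c("subject_id", "admission_date", intersect(dx_cols, names(wide)))]
  readr::write_csv(wide, path, na = "")
  invisible(episodes)
}

#' @rdname oevax-io
#' @export
read_dose_csv <- function(path) {
  dose_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname oevax-io
#' @export
write_dose_csv <- function(doses, path) {
  readr::write_csv(dose_table(doses), path)
  invisible(doses)
}
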