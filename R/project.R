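#' Define a post-vaccination risk window
#'
#' The risk window is the fixed interval after (first-dose) vaccination over
#' which background events are projected. Its exposure fraction is
#' `days / 365` — a flat calendar fraction by construction (365 exactly, the
#' convention of the projection formula, not the 365.25 used for person-time
#' accrual).
#'
#' @param days Window length in days (default 15).
#' @return List of class `oevax_risk_window` with `days` and
#'   `fraction_of_year`.
#' @export
risk_window <- function(days = 15) {
  if (!isTRUE(days > 0)) abort("`days` must be > 0.")
  structure(
    list(days = days, fraction_of_year = days / 365),
    class = "oevax_risk_window"
  )
}

#' Project expected event counts onto a vaccinated population
#'
#' For each dose stratum, the expected number of background events in the
#' risk window is
#' `E = N * (rate / scale) * days / 365`,
#' i.e. vaccinated subjects times the annual background rate times the
#' fraction of a year they are observed. The overall row applies the
#' *overall* rate to the total doses (the published convention), rather than
#' summing the stratum expectations; the two differ only through rounding and
#' are reported side by side.
#'
#' In `table_faithful` mode the stratum rates are first rounded to 3 decimals
#' on their reporting scale, reproducing projections computed from a printed
#' rate table; full precision is the default for new analyses.
#'
#' @param rates Rate tibble from [estimate_rates()] (needs `gender`,
#'   `age_band`, `rate`, `scale`; an `ALL`/`ALL` row supplies the overall
#'   rate).
#' @param doses Dose table from [dose_table()]. Strata whose age band is not
#'   present in `rates` and that fall below the rate table's bands (e.g. a
#'   `<50` stratum in an over-50 analysis) must be removed by the caller;
#'   every dose stratum except `ALL`-gender rows must match a rate stratum.
#' @param window A [risk_window()].
#' @param table_faithful Round stratum rates to 3 decimals before projecting
#'   (default `FALSE`).
#' @return Tibble with `gender`, `age_band`, `doses`, `rate_used`, `expected`,
#'   one row per dose stratum plus an `ALL`/`ALL` overall row.
#' @examples
#' rates <- estimate_rates(reference_vt_counts(), scale = 1000)
#' doses <- dplyr::filter(italy_doses_2021(), gender != "ALL")
#' project_expected(rates, doses, table_faithful = TRUE)
#' @export
project_expected <- function(rates, doses, window = risk_window(),
                             table_faithful = FALSE) {
  stopifnot(inherits(window, "oevax_risk_window"))
  rates <- as_tibble(rates)
  doses <- dose_table(doses)
  if (!all(c("gender", "age_band", "rate", "scale") %in% names(rates))) {
    abort("`rates` needs gender, age_band, rate, scale columns.")
  }

  strat_rates <- rates %>% filter(.data$gender != "ALL")
  overall_rate <- rates %>%
    filter(.data$gender == "ALL", .data$age_band == "ALL")

  strat <- doses %>%
    left_join(
      strat_rates %>% select("gender", "age_band", "rate", "scale"),
      by = c("gender", "age_band")
    )
  unmatched <- strat %>% filter(is.na(.data$rate))
  if (nrow(unmatched) > 0) {
    abort(paste0(
      "No rate for dose stratum/strata: ",
      paste(paste(unmatched$gender, unmatched$age_band), collapse = "; ")
    ))
  }

  strat <- strat %>%
    mutate(
      rate_used = if (table_faithful) round(.data$rate, 3) else .data$rate,
      expected = .data$doses * (.data$rate_used / .data$scale) *
        window$fraction_of_year
    ) %>%
    select("gender", "age_band", "doses", "rate_used", "expected")

  if (nrow(overall_rate) == 1) {
    r_all <- if (table_faithful) round(overall_rate$rate, 3) else overall_rate$rate
    total <- tibble(
      gender = "ALL", age_band = "ALL",
      doses = sum(strat$doses),
      rate_used = r_all,
      expected = sum(strat$doses) * (r_all / overall_rate$scale) *
        window$fraction_of_year
    )
    strat <- bind_rows(strat, total)
  }
  strat
}
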