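#' Share of doses delivered at or above an age threshold
#'
#' @param doses A [dose_table()]; age bands must not straddle the threshold.
#' @param age_threshold Age in years (default 50).
#' @return Percentage of all doses in bands at/above the threshold.
#' @examples
#' summarize_doses(italy_doses_2021())
#' @export
summarize_doses <- function(doses, age_threshold = 50) {
  doses <- dose_table(doses)
  bounds <- parse_band_label(doses$age_band)
  straddle <- bounds$lower < age_threshold & bounds$upper > age_threshold
  if (any(straddle)) {
    abort(paste0(
      "Age band(s) straddle the ", age_threshold, "-year threshold: ",
      paste(unique(doses$age_band[straddle]), collapse = ", ")
    ))
  }
  total <- sum(doses$doses)
  if (total == 0) abort("Dose table holds zero doses.")
  100 * sum(doses$doses[bounds$lower >= age_threshold]) / total
}

# band label -> [lower, upper) bounds; understands "50-59", "80+", "<50", "ALL"
parse_band_label <- function(label) {
  lower <- rep(NA_real_, length(label))
  upper <- rep(NA_real_, length(label))
  plus <- grepl("^[0-9]+\\+$", label)
  range <- grepl("^[0-9]+-[0-9]+$", label)
  under <- grepl("^<[0-9]+$", label)
  lower[plus] <- as.numeric(sub("\\+$", "", label[plus]))
  upper[plus] <- Inf
  lower[range] <- as.numeric(sub("-.*$", "", label[range]))
  upper[range] <- as.numeric(sub("^.*-", "", label[range])) + 1
  lower[under] <- 0
  upper[under] <- as.numeric(sub("^<", "", label[under]))
  lower[label == "ALL"] <- 0
  upper[label == "ALL"] <- Inf
  if (anyNA(lower)) {
    abort(paste0("Unparseable age band label(s): ",
                 paste(unique(label[is.na(lower)]), collapse = ", ")))
  }
  list(lower = lower, upper = upper)
}

#' Run the full observed-versus-expected pipeline
#'
#' Orchestrates identification, person-time, rate estimation, projection and
#' prediction intervals for one or more outcomes, and returns an `oe_report`
#' object with [tidy()], [glance()], [autoplot()] and `print()` methods.
#'
#' Stratified outcomes (e.g. VT) are rated per (gender, age band) stratum and
#' projected stratum by stratum, with the overall row using the overall rate
#' on the total doses; rare outcomes flagged unstratified (e.g. ITP) are rated
#' overall only and projected onto the total doses of the bands the scheme
#' covers. Dose strata outside the scheme (e.g. an under-50 stratum in an
#' over-50 analysis) are excluded from projection but kept for dose
#' summaries.
#'
#' @param subjects Cohort tibble or path to a cohort CSV.
#' @param episodes Episode tibble or path to an episode CSV.
#' @param doses Dose tibble or path to a dose CSV.
#' @param code_sets Named list of [code_set()]s, one per outcome.
#' @param scales Named numeric, reporting scale per outcome (per `scale`
#'   person-years).
#' @param stratified Named logical, whether each outcome is rated and
#'   projected by stratum.
#' @param scheme Age-band scheme, default [age_bands()].
#' @param window A [risk_window()].
#' @param settings A [boot_settings()]; one seeded stream drives all
#'   bootstrap resampling, strata in fixed table order.
#' @param table_faithful Use 3-decimal rounded rates in the projection
#'   (reproduction mode); default `FALSE` (full precision).
#' @param out_dir Optional directory; when given, writes `results.csv` (tidy
#'   table), one rendered `table_<outcome>.csv` per outcome and
#'   `manifest.yaml`. Two runs with identical inputs and seed write
#'   byte-identical files.
#' @return An `oe_report` object.
#' @export
run_pipeline <- function(subjects, episodes, doses,
                         code_sets = list(VT = vt_code_set(),
                                          ITP = itp_code_set()),
                         scales = c(VT = 1000, ITP = 1e5),
                         stratified = c(VT = TRUE, ITP = FALSE),
                         scheme = age_bands(),
                         window = risk_window(),
                         settings = boot_settings(),
                         table_faithful = FALSE,
                         out_dir = NULL) {
  if (is.character(subjects)) subjects <- read_cohort_csv(subjects)
  if (is.character(episodes)) episodes <- read_episodes_csv(episodes)
  if (is.character(doses)) doses <- read_dose_csv(doses)
  doses <- dose_table(doses)
  outcomes <- names(code_sets)
  if (is.null(outcomes) || !all(outcomes %in% names(scales)) ||
      !all(outcomes %in% names(stratified))) {
    abort("`code_sets`, `scales` and `stratified` must share outcome names.")
  }

  inform(paste0("Read ", nrow(subjects), " subjects, ", nrow(episodes),
                " episodes, ", nrow(doses), " dose strata."))
  doses_in_scheme <- doses %>% filter(.data$age_band %in% scheme$age_band)

  results <- purrr::map(outcomes, function(oc) {
    fe <- identify_first_events(subjects, episodes, code_sets[[oc]])
    inform(paste0(oc, ": ", nrow(fe), " first event(s) identified."))
    pt <- compute_person_time(subjects, fe, scheme)
    if (nrow(fe) == 0) {
      warn(paste0(oc, ": no qualifying events; rates and expected counts are 0."))
    }
    if (!isTRUE(stratified[[oc]])) {
      # rare outcome: rate reported overall only
      pt <- pt %>% filter(.data$gender == "ALL")
    }
    empty_strata <- pt %>% filter(.data$person_years <= 0)
    if (nrow(empty_strata) > 0) {
      warn(paste0(oc, ": dropping ", nrow(empty_strata),
                  " stratum/strata with no person-time."))
      pt <- pt %>% filter(.data$person_years > 0)
    }
    rates <- estimate_rates(pt, scale = scales[[oc]])
    expected <- if (isTRUE(stratified[[oc]])) {
      project_expected(rates, doses_in_scheme %>% filter(.data$gender != "ALL"),
                       window, table_faithful)
    } else {
      project_overall(rates, doses_in_scheme, window, table_faithful)
    }
    expected <- add_prediction_intervals(expected, settings)
    list(first_events = fe, person_time = pt, rates = rates,
         expected = expected)
  })
  names(results) <- outcomes

  report <- structure(
    list(
      outcomes = results,
      doses = doses,
      manifest = list(
        package = "oevax",
        version = as.character(utils::packageVersion("oevax")),
        seed = settings$seed,
        n_reps = settings$n_reps,
        window_days = window$days,
        table_faithful = table_faithful,
        n_subjects = nrow(subjects),
        n_episodes = nrow(episodes),
        config_hash = rlang::hash(list(
          scheme, window$days, settings$n_reps, settings$seed,
          table_faithful, scales, stratified,
          purrr::map(code_sets, function(s) s[c("outcome", "codes")])
        ))
      )
    ),
    class = "oe_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# overall-only projection for rare, unstratified outcomes
project_overall <- function(rates, doses, window, table_faithful) {
  overall <- rates %>% filter(.data$gender == "ALL", .data$age_band == "ALL")
  if (nrow(overall) != 1) abort("Need exactly one ALL/ALL rate row.")
  total_doses <- sum(doses$doses[doses$gender != "ALL"])
  r <- if (table_faithful) round(overall$rate, 3) else overall$rate
  tibble(
    gender = "ALL", age_band = "ALL",
    doses = total_doses,
    rate_used = r,
    expected = total_doses * (r / overall$scale) * window$fraction_of_year
  )
}

#' @export
print.oe_report <- function(x, ...) {
  cat("Observed-versus-expected report (seed", x$manifest$seed, ")\n")
  for (oc in names(x$outcomes)) {
    res <- x$outcomes[[oc]]
    cat("\n==", oc, "(per", format(res$rates$scale[1], big.mark = ","),
        "person-years; risk window", x$manifest$window_days, "days) ==\n")
    print(as.data.frame(render_report_table(x, oc)), row.names = FALSE)
  }
  invisible(x)
}

#' Render one outcome of a report at publication precision
#'
#' Rates and confidence bounds are shown to 3 decimals, expected counts to 2,
#' person-years to the nearest integer; full precision is preserved in
#' [tidy()] output. Rounding happens only here, at the reporting layer.
#'
#' @param report An `oe_report`.
#' @param outcome Outcome name, e.g. `"VT"`.
#' @return Tibble of formatted character/numeric columns.
#' @export
render_report_table <- function(report, outcome) {
  stopifnot(inherits(report, "oe_report"))
  res <- report$outcomes[[outcome]]
  if (is.null(res)) abort(paste0("No outcome `", outcome, "` in report."))
  res$rates %>%
    left_join(
      res$expected %>%
        select("gender", "age_band", "doses", "expected",
               "pi_low", "pi_high"),
      by = c("gender", "age_band")
    ) %>%
    mutate(
      person_years = round(.data$person_years),
      rate_fmt = sprintf("%.3f", .data$rate),
      ci_fmt = if_else(
        is.na(.data$ci_low), "-",
        sprintf("(%.3f-%.3f)", .data$ci_low, .data$ci_high)
      ),
      expected_fmt = if_else(
        is.na(.data$expected), "-", sprintf("%.2f", .data$expected)
      ),
      pi_fmt = if_else(
        is.na(.data$pi_low), "-",
        sprintf("(%.0f-%.0f)", .data$pi_low, .data$pi_high)
      )
    ) %>%
    select(
      "gender", "age_band", "events", "person_years",
      rate = "rate_fmt", ci95 = "ci_fmt", "doses",
      expected = "expected_fmt", pi95 = "pi_fmt"
    )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(report), file.path(out_dir, "results.csv"))
  for (oc in names(report$outcomes)) {
    readr::write_csv(
      render_report_table(report, oc),
      file.path(out_dir, paste0("table_", oc, ".csv"))
    )
  }
  yaml::write_yaml(report$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(report)
}

#' @method tidy oe_report
#' @export
tidy.oe_report <- function(x, ...) {
  purrr::imap(x$outcomes, function(res, oc) {
    res$rates %>%
      left_join(
        res$expected %>%
          select("gender", "age_band", "doses", "rate_used", "expected",
                 "pi_low", "pi_high"),
        by = c("gender", "age_band")
      ) %>%
      mutate(outcome = oc, .before = 1)
  }) %>%
    bind_rows()
}

#' @method glance oe_report
#' @export
glance.oe_report <- function(x, ...) {
  overall <- purrr::imap(x$outcomes, function(res, oc) {
    r <- res$rates %>% filter(.data$gender == "ALL")
    e <- res$expected %>% filter(.data$gender == "ALL")
    tibble(
      outcome = oc, events = r$events, person_years = r$person_years,
      rate = r$rate, scale = r$scale, expected = e$expected
    )
  }) %>% bind_rows()
  tibble(
    n_subjects = x$manifest$n_subjects,
    n_episodes = x$manifest$n_episodes,
    total_doses = sum(x$doses$doses),
    window_days = x$manifest$window_days,
    n_outcomes = length(x$outcomes),
    total_person_years = overall$person_years[1],
    total_expected = sum(overall$expected),
    seed = x$manifest$seed
  )
}

#' Plot a report's rates or expected counts
#'
#' `type = "rates"` shows stratum incidence rates with 95% confidence
#' intervals on a log scale; `type = "expected"` shows projected event counts
#' with 95% prediction intervals.
#'
#' @param object An `oe_report`.
#' @param type `"rates"` or `"expected"`.
#' @param outcome Outcome to plot (default first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oe_report
#' @export
autoplot.oe_report <- function(object, type = c("rates", "expected"),
                               outcome = names(object$outcomes)[1], ...) {
  type <- match.arg(type)
  res <- object$outcomes[[outcome]]
  if (is.null(res)) abort(paste0("No outcome `", outcome, "` in report."))
  if (type == "rates") {
    dat <- res$rates %>% filter(.data$gender != "ALL", .data$events > 0)
    ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$age_band, y = .data$rate, colour = .data$gender
    )) +
      ggplot2::geom_pointrange(
        ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
        position = ggplot2::position_dodge(width = 0.4)
      ) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(
        x = "Age band (years)",
        y = paste0(outcome, " rate per ", format(res$rates$scale[1],
                                                 big.mark = ","), " PY"),
        colour = "Gender",
        title = paste0("Background ", outcome,
                       " incidence with 95% confidence intervals")
      ) +
      ggplot2::theme_minimal()
  } else {
    dat <- res$expected %>% filter(.data$gender != "ALL")
    if (nrow(dat) == 0) dat <- res$expected
    ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$age_band, y = .data$expected, fill = .data$gender
    )) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$pi_low, ymax = .data$pi_high),
        position = ggplot2::position_dodge(width = 0.9), width = 0.3
      ) +
      ggplot2::labs(
        x = "Age band (years)", y = "Expected events in risk window",
        fill = "Gender",
        title = paste0("Expected ", outcome,
                       " events with 95% prediction intervals")
      ) +
      ggplot2::theme_minimal()
  }
}

#' Reproduce the published reference analysis
#'
#' Runs the rate, projection and prediction-interval stages from the packaged
#' printed stratum counts ([reference_vt_counts()], [reference_itp_counts()])
#' and the packaged dose table, in table-faithful mode (rates rounded to 3
#' decimals before projection, risk-window fraction `15/365`), mirroring how
#' the published table was computed from its own printed cells.
#'
#' Note the prediction intervals are those of the stated Poisson-resampling
#' procedure; the reference publication prints far narrower, non-integer
#' bounds that the stated procedure does not produce (see the methods
#' vignette).
#'
#' @param settings A [boot_settings()].
#' @return An `oe_report` object.
#' @examples
#' rep <- reproduce_reference_analysis()
#' render_report_table(rep, "VT")
#' @export
reproduce_reference_analysis <- function(settings = boot_settings()) {
  doses <- italy_doses_2021()
  scheme <- age_bands()
  window <- risk_window(15)
  doses_over50 <- doses %>% filter(.data$age_band %in% scheme$age_band)

  vt_rates <- estimate_rates(reference_vt_counts(), scale = 1000)
  vt_expected <- project_expected(
    vt_rates, doses_over50 %>% filter(.data$gender != "ALL"),
    window, table_faithful = TRUE
  ) %>%
    add_prediction_intervals(settings)

  itp_rates <- estimate_rates(reference_itp_counts(), scale = 1e5)
  itp_expected <- project_overall(
    itp_rates, doses_over50, window, table_faithful = FALSE
  ) %>%
    add_prediction_intervals(settings)

  structure(
    list(
      outcomes = list(
        VT = list(first_events = NULL, person_time = reference_vt_counts(),
                  rates = vt_rates, expected = vt_expected),
        ITP = list(first_events = NULL, person_time = reference_itp_counts(),
                   rates = itp_rates, expected = itp_expected)
      ),
      doses = doses,
      manifest = list(
        package = "oevax",
        version = as.character(utils::packageVersion("oevax")),
        seed = settings$seed, n_reps = settings$n_reps,
        window_days = window$days, table_faithful = TRUE,
        n_subjects = NA_integer_, n_episodes = NA_integer_,
        config_hash = rlang::hash("reference-analysis")
      )
    ),
    class = "oe_report"
  )
}
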