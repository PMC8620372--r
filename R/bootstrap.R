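#' Bootstrap settings for prediction intervals
#'
#' @param n_reps Number of Poisson resamples (default 10000; at least 1000).
#' @param lower_q,upper_q Quantiles bounding the prediction interval
#'   (defaults 0.025 and 0.975).
#' @param seed Integer seed for the resampling stream.
#' @return List of class `oevax_boot_settings`.
#' @export
boot_settings <- function(n_reps = 10000, lower_q = 0.025, upper_q = 0.975,
                          seed = 1L) {
  if (!isTRUE(n_reps >= 1000)) abort("`n_reps` must be >= 1000.")
  if (!(lower_q > 0 && lower_q < upper_q && upper_q < 1)) {
    abort("Quantiles must satisfy 0 < lower_q < upper_q < 1.")
  }
  structure(
    list(n_reps = as.integer(n_reps), lower_q = lower_q, upper_q = upper_q,
         seed = as.integer(seed)),
    class = "oevax_boot_settings"
  )
}

#' Poisson-bootstrap prediction interval for one expected count
#'
#' Resamples a future event count from `Poisson(E)` `n_reps` times and
#' returns the empirical (`lower_q`, `upper_q`) quantiles (inverse-ECDF,
#' `type = 1`), which converge to the exact Poisson quantiles
#' `qpois(q, E)` as `n_reps` grows. This is a prediction interval for a
#' future count, not a confidence interval for the rate: it conditions on the
#' point estimate `E` and carries no rate-estimation uncertainty.
#'
#' @param expected Non-negative expected count `E`.
#' @param settings A [boot_settings()]; its `seed` is used unless the call is
#'   already inside a managed RNG stream (`use_seed = FALSE`).
#' @param use_seed Seed the RNG from `settings$seed` (default `TRUE`). Set to
#'   `FALSE` when the caller manages one seeded stream across strata.
#' @return Named numeric `c(pi_low, pi_high)`.
#' @examples
#' poisson_bootstrap_pi(4.49, boot_settings(seed = 7))
#' @export
poisson_bootstrap_pi <- function(expected, settings = boot_settings(),
                                 use_seed = TRUE) {
  stopifnot(inherits(settings, "oevax_boot_settings"))
  if (!isTRUE(expected >= 0)) abort("`expected` must be >= 0.")
  draw <- function() {
    reps <- rpois(settings$n_reps, expected)
    stats::quantile(reps, c(settings$lower_q, settings$upper_q),
                    type = 1, names = FALSE)
  }
  q <- if (use_seed) withr::with_seed(settings$seed, draw()) else draw()
  c(pi_low = q[1], pi_high = q[2])
}

#' Attach prediction intervals to a projection table
#'
#' Runs the Poisson bootstrap for every row of a [project_expected()] result.
#' A single seeded stream is used and strata are processed in the table's
#' row order (gender, then age band, overall last), so results are
#' reproducible and independent of any parallel setting.
#'
#' @param expected Projection tibble from [project_expected()].
#' @param settings A [boot_settings()].
#' @return `expected` with `pi_low`, `pi_high` columns appended.
#' @export
add_prediction_intervals <- function(expected, settings = boot_settings()) {
  stopifnot(inherits(settings, "oevax_boot_settings"))
  expected <- as_tibble(expected)
  if (!"expected" %in% names(expected)) {
    abort("`expected` must come from project_expected().")
  }
  withr::with_seed(settings$seed, {
    pis <- purrr::map(
      expected$expected,
      function(e) poisson_bootstrap_pi(e, settings, use_seed = FALSE)
    )
  })
  expected %>%
    mutate(
      pi_low = purrr::map_dbl(pis, "pi_low"),
      pi_high = purrr::map_dbl(pis, "pi_high")
    )
}
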