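#' Define an attained-age band scheme
#'
#' Builds the ordered set of contiguous 10-year (or custom) attained-age bands
#' used to stratify person-time, events, rates and doses. The default scheme is
#' the one used for over-50 adverse-event surveillance: 50-59, 60-69, 70-79 and
#' an open-ended 80+ band. Ages below the first break fall outside the scheme
#' and contribute neither events nor person-time.
#'
#' @param breaks Integer vector of band lower bounds in whole years, strictly
#'   increasing (default `c(50, 60, 70, 80)`).
#' @param open_end If `TRUE` (default) the last band is open-ended (`80+`);
#'   otherwise the last break closes the previous band and is dropped.
#' @return A tibble with columns `age_band` (label), `lower`, `upper` (years;
#'   `upper = Inf` for the open band), one row per band, ordered by age.
#' @examples
#' age_bands()
#' age_bands(breaks = c(18, 50, 65))
#' @export
age_bands <- function(breaks = c(50, 60, 70, 80), open_end = TRUE) {
  if (length(breaks) < 1 || any(diff(breaks) <= 0)) {
    abort("`breaks` must be a strictly increasing vector of ages.")
  }
  if (any(breaks < 0)) abort("`breaks` must be non-negative ages.")
  lower <- breaks
  upper <- c(breaks[-1], Inf)
  if (!open_end) {
    lower <- breaks[-length(breaks)]
    upper <- breaks[-1]
  }
  label <- ifelse(
    is.infinite(upper),
    paste0(lower, "+"),
    paste0(lower, "-", upper - 1)
  )
  tibble(age_band = label, lower = lower, upper = upper)
}

#' Assign ages to bands of a scheme
#'
#' @param age Numeric ages in years (fractional allowed; band membership uses
#'   completed years, i.e. `floor(age)`).
#' @param scheme A band scheme from [age_bands()].
#' @return Character vector of band labels, `NA` for ages outside the scheme.
#' @export
assign_age_band <- function(age, scheme = age_bands()) {
  idx <- findInterval(floor(age), scheme$lower)
  out <- ifelse(idx >= 1, scheme$age_band[pmax(idx, 1)], NA_character_)
  # findInterval maps ages past the last closed band into it; reject those
  if (any(is.finite(scheme$upper))) {
    too_old <- floor(age) >= scheme$upper[match(out, scheme$age_band)]
    out[!is.na(too_old) & too_old] <- NA_character_
  }
  out
}

check_gender <- function(gender, allow_all = FALSE) {
  ok <- c("F", "M", if (allow_all) "ALL")
  bad <- setdiff(unique(gender), ok)
  if (length(bad) > 0) {
    abort(paste0(
      "`gender` must be one of ", paste(ok, collapse = ", "),
      "; found: ", paste(bad, collapse = ", ")
    ))
  }
  invisible(gender)
}
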