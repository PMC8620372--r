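#' Normalize an ICD-9-CM code to dotted canonical form
#'
#' Claims extracts carry diagnosis codes in two dialects: dotted (`"451.11"`)
#' and undotted (`"45111"`). This helper strips whitespace, validates the shape
#' (numeric `ddd[.dd]`, `Vdd[.dd]` or `Eddd[.d]`) and returns the dotted
#' canonical form. It is idempotent, so already-canonical codes pass through.
#'
#' @param raw Character vector of raw code strings.
#' @return Character vector of canonical dotted codes.
#' @examples
#' normalize_icd9(c("45111", " 415.1 ", "287.31"))
#' @export
normalize_icd9 <- function(raw) {
  if (length(raw) == 0) return(character())
  x <- trimws(as.character(raw))
  bad <- is.na(x) | x == ""
  if (any(bad)) abort("ICD-9-CM codes must be non-empty strings.")

  undotted <- gsub(".", "", x, fixed = TRUE)
  ok_num <- grepl("^[0-9]{3}[0-9]{0,2}$", undotted)
  ok_v <- grepl("^V[0-9]{2}[0-9]{0,2}$", undotted, ignore.case = TRUE)
  ok_e <- grepl("^E[0-9]{3}[0-9]{0,1}$", undotted, ignore.case = TRUE)
  # dotted input must have the dot in the canonical position
  has_dot <- grepl(".", x, fixed = TRUE)
  root_len <- ifelse(ok_v, 3L, ifelse(ok_e, 4L, 3L))
  dot_ok <- !has_dot | regexpr(".", x, fixed = TRUE) == root_len + 1L
  valid <- (ok_num | ok_v | ok_e) & dot_ok
  if (!all(valid)) {
    abort(paste0(
      "Not ICD-9-CM-shaped code(s): ",
      paste(unique(x[!valid]), collapse = ", ")
    ))
  }

  undotted <- toupper(undotted)
  root <- substr(undotted, 1L, root_len)
  ext <- substr(undotted, root_len + 1L, nchar(undotted))
  ifelse(nchar(ext) > 0, paste0(root, ".", ext), root)
}

#' Construct an outcome code set
#'
#' A code set is the claims-based case definition of one outcome: the ICD-9-CM
#' codes whose appearance at any diagnosis position of a hospital episode
#' qualifies the episode, plus optional date restrictions for codes that are
#' only valid under an older coding dialect (e.g. a code retired by the 2007
#' ICD-9-CM update matches only admissions before the switch date).
#'
#' @param outcome Outcome label, e.g. `"VT"` or `"ITP"`.
#' @param codes Character vector of ICD-9-CM codes (dotted or undotted).
#' @param valid_before Optional named `Date` (or date string) vector: for each
#'   named code, the admission date before which the code is a valid match.
#'   Names must be a subset of `codes`.
#' @return A list of class `oevax_code_set` with canonicalized elements
#'   `outcome`, `codes`, `valid_before`.
#' @examples
#' code_set("ITP", c("287.31", "287.3"), valid_before = c("287.3" = "2007-01-01"))
#' @export
code_set <- function(outcome, codes, valid_before = NULL) {
  if (length(codes) == 0) abort("`codes` must be non-empty.")
  codes <- normalize_icd9(codes)
  if (anyDuplicated(codes)) abort("`codes` contains duplicates after normalization.")
  vb <- as.Date(character())
  if (!is.null(valid_before) && length(valid_before) > 0) {
    nm <- normalize_icd9(names(valid_before))
    vb <- as.Date(unname(unlist(lapply(valid_before, as.character))))
    names(vb) <- nm
    if (!all(nm %in% codes)) {
      abort("Restricted codes must be a subset of `codes`.")
    }
    if (anyNA(vb)) abort("`valid_before` dates could not be parsed.")
  }
  structure(
    list(outcome = as.character(outcome)[1], codes = codes, valid_before = vb),
    class = "oevax_code_set"
  )
}

#' @export
print.oevax_code_set <- function(x, ...) {
  cat("<code set> outcome:", x$outcome, "\n")
  cat("  codes:", paste(x$codes, collapse = ", "), "\n")
  if (length(x$valid_before) > 0) {
    cat("  restricted:", paste0(
      names(x$valid_before), " (before ", format(x$valid_before), ")",
      collapse = ", "
    ), "\n")
  }
  invisible(x)
}

#' Default venous-thromboembolism (VT) case definition
#'
#' Pulmonary embolism (415.1) or deep vein thrombosis (451.11, 451.19, 451.2,
#' 451.81, 453.8) at any diagnosis position of a hospital episode.
#'
#' @return An [code_set()] object.
#' @export
vt_code_set <- function() {
  code_set("VT", c("415.1", "451.11", "451.19", "451.2", "451.81", "453.8"))
}

#' Default immune-thrombocytopenia (ITP) case definition
#'
#' Immune thrombocytopenic purpura (287.31) or primary thrombocytopenia
#' (287.3); 287.3 is the pre-update dialect code and matches only admissions
#' before the ICD-9-CM 2007 coding switch.
#'
#' @param dialect_switch_date Date the newer coding dialect takes over
#'   (default `"2007-01-01"`).
#' @return An [code_set()] object.
#' @export
itp_code_set <- function(dialect_switch_date = as.Date("2007-01-01")) {
  code_set(
    "ITP", c("287.31", "287.3"),
    valid_before = stats::setNames(as.Date(dialect_switch_date), "287.3")
  )
}

#' Codes valid as a match at a given admission date
#' @noRd
codes_valid_at <- function(set, date) {
  vb <- set$valid_before
  if (length(vb) == 0) return(set$codes)
  restricted <- names(vb)
  keep <- vapply(
    set$codes,
    function(cd) !(cd %in% restricted) || date < vb[[cd]],
    logical(1)
  )
  set$codes[keep]
}

#' Plausible non-outcome (distractor) diagnosis codes
#'
#' A fixed list of common hospital-discharge ICD-9-CM codes disjoint from the
#' packaged VT and ITP case definitions, used by the synthetic-cohort
#' generator for background hospitalizations.
#'
#' @return Character vector of canonical ICD-9-CM codes.
#' @export
distractor_codes <- function() {
  c(
    "250.00", "401.9", "410.91", "414.01", "427.31", "428.0", "434.91",
    "486", "491.21", "518.81", "530.81", "540.9", "560.9", "574.20",
    "584.9", "599.0", "715.90", "780.2", "786.50", "820.8"
  )
}
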