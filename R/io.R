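## Cohort CSV interchange: header `subject_id,age,value`, one observation
## per row, UTF-8, LF written (CRLF accepted on read).

#' Read and write cohort CSV files
#'
#' The single interchange format for cohort data is a plain CSV with header
#' exactly `subject_id,age,value` and one observation per row. On read, the
#' design is inferred from subject multiplicity: if any subject appears more
#' than once the file is taken as longitudinal (and every subject must then
#' appear at two or more distinct ages), otherwise as cross-sectional.
#' Malformed input — missing or extra columns, non-numeric or negative ages,
#' non-numeric values, duplicate (subject, age) pairs, or a header with no
#' rows — raises a parse error naming the offending line.
#'
#' `write_cohort()` writes values as decimal text at full double precision
#' (15 significant digits), so write-then-read round-trips records exactly.
#'
#' @param path File path.
#' @param cohort A `cohort_sample`.
#' @return `read_cohort()` returns a `cohort_sample`; `write_cohort()`
#'   returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cross_sectional(scenario_spec("S1"), 20, seed = 3), path)
#' read_cohort(path)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("No such file: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  header <- sub("\r$", "", header)
  if (!identical(header, "subject_id,age,value")) {
    abort_parse(sprintf(
      "Line 1: expected header 'subject_id,age,value', found '%s'.", header
    ))
  }
  # readr's own parse warning is superseded by the classed error below
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      age = readr::col_double(),
      value = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    abort_parse(sprintf(
      "Line %d: could not parse column '%s' (expected %s, got '%s').",
      probs$row[1L] + 1L, names(raw)[probs$col[1L]], probs$expected[1L],
      probs$actual[1L]
    ))
  }
  if (nrow(raw) == 0L) abort_parse("Empty cohort: file has a header but no observations.")
  # +1 converts data-frame row numbers to file line numbers (header is line 1)
  validate_cohort(raw, line_offset = 1L)

  multiplicity <- table(raw$subject_id)
  if (any(multiplicity > 1L)) {
    if (any(multiplicity < 2L)) {
      abort_parse(
        "Mixed design: some subjects observed once, others repeatedly; expected purely cross-sectional or purely longitudinal data."
      )
    }
    design <- "longitudinal"
  } else {
    design <- "cross_sectional"
  }
  new_cohort(raw, design = design, provenance = sprintf("file %s", path))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  df <- tibble::tibble(
    subject_id = as.character(cohort$subject_id),
    age = format(cohort$age, digits = 15, scientific = FALSE, trim = TRUE),
    value = format(cohort$value, digits = 15, scientific = FALSE, trim = TRUE)
  )
  readr::write_csv(df, path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Serialise a dispersion curve as a JSON report block
#'
#' Plain-list form of a [bin_cohort()] result (source plus one record per
#' bin), suitable for `jsonlite::write_json(..., auto_unbox = TRUE)`.
#'
#' @param curve A `dispersion_curve` tibble.
#' @return A named list with elements `source` and `bins`.
#' @export
dispersion_report <- function(curve) {
  cols <- c("bin_lo", "bin_hi", "midpoint", "n", "mean", "sd", "covar")
  if (!all(cols %in% names(curve))) {
    abort_contract("`curve` must be a dispersion curve (see bin_cohort()).")
  }
  list(
    source = attr(curve, "source") %||% "unknown",
    bins = purrr::pmap(as.data.frame(curve)[cols], list)
  )
}

#' Write a dispersion curve as CSV
#'
#' Serialises a [bin_cohort()] result with header
#' `bin_lo,bin_hi,midpoint,n,mean,sd,covar`.
#'
#' @param curve A `dispersion_curve` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dispersion <- function(curve, path) {
  cols <- c("bin_lo", "bin_hi", "midpoint", "n", "mean", "sd", "covar")
  if (!all(cols %in% names(curve))) {
    abort_contract("`curve` must be a dispersion curve (see bin_cohort()).")
  }
  readr::write_csv(curve[cols], path, eol = "\n", progress = FALSE)
  invisible(path)
}
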