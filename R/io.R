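## CSV dialects. Assay tables are long format (strain,lot,lab,analyte,value)
## with an empty value field meaning not-tested, distinct from "0.0"
## (measured zero). Survey tables are one row per respondent with
## semicolon-delimited multi-select fields.

#' Read a long-format assay table
#'
#' Expects the header `strain,lot,lab,analyte,value`. Empty value fields are
#' recorded as not-tested (`NA`); `"0"` / `"0.0"` are measured zeros.
#' Analyte names are canonicalized against the packaged panel. Negative
#' values, unknown analytes and duplicate (strain, lot, analyte) cells are
#' parse errors reported with their line number.
#'
#' @param path CSV file path.
#' @return An `assay_tbl` (see [generate_lot_assays()]).
#' @export
read_assay_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  expected <- c("strain", "lot", "lab", "analyte", "value")
  if (!identical(names(raw), expected)) {
    stop("assay table header must be ", paste(expected, collapse = ","),
         " (got ", paste(names(raw), collapse = ","), ")", call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L
  canon <- canonical_analyte(raw$analyte, error_on_unknown = FALSE)
  if (anyNA(canon)) {
    i <- which(is.na(canon))[1]
    stop("line ", line[i], ": unknown analyte ", sQuote(raw$analyte[i]),
         call. = FALSE)
  }
  vchr <- trimws(raw$value)
  value <- suppressWarnings(as.numeric(vchr))
  value[vchr == ""] <- NA_real_
  bad_num <- vchr != "" & is.na(value)
  if (any(bad_num)) {
    i <- which(bad_num)[1]
    stop("line ", line[i], ": unparseable value ", sQuote(raw$value[i]),
         call. = FALSE)
  }
  if (any(value < 0, na.rm = TRUE)) {
    i <- which(value < 0)[1]
    stop("line ", line[i], ": negative concentration ", value[i],
         call. = FALSE)
  }
  key <- paste(trimws(raw$strain), trimws(raw$lot), canon, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop("line ", line[i], ": duplicate cell for (",
         raw$strain[i], ", ", raw$lot[i], ", ", canon[i], ")",
         call. = FALSE)
  }
  out <- tibble::tibble(
    strain = trimws(raw$strain), lot = trimws(raw$lot),
    lab = trimws(raw$lab), analyte = canon, value = value
  )
  class(out) <- c("assay_tbl", class(out))
  out
}

#' Write a long-format assay table
#'
#' Inverse of [read_assay_table()]: not-tested cells become empty fields,
#' measured zeros are written as `0`.
#'
#' @param assays An assay table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(assays, path) {
  readr::write_csv(assays, path, na = "")
  invisible(path)
}

split_multi <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    unique(v[v != ""])
  })
}

join_multi <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

#' Read a survey-response table
#'
#' Expects the header `respondent_id,likert_rating,most_effective,
#' least_effective,side_effects,symptoms` with semicolon-delimited
#' multi-select fields. A blank rating is absent; out-of-range ratings and
#' duplicate respondent ids are errors.
#'
#' @param path CSV file path.
#' @return A `survey_tbl` (see [generate_survey()]).
#' @export
read_survey_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  expected <- c("respondent_id", "likert_rating", "most_effective",
                "least_effective", "side_effects", "symptoms")
  if (!identical(names(raw), expected)) {
    stop("survey table header must be ", paste(expected, collapse = ","),
         call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L
  if (anyDuplicated(raw$respondent_id)) {
    i <- which(duplicated(raw$respondent_id))[1]
    stop("line ", line[i], ": duplicate respondent id ",
         sQuote(raw$respondent_id[i]), call. = FALSE)
  }
  rchr <- trimws(raw$likert_rating)
  rating <- suppressWarnings(as.numeric(rchr))
  rating[rchr == ""] <- NA_real_
  bad <- rchr != "" & (is.na(rating) | rating %% 1 != 0 |
                         rating < 0 | rating > 10)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("line ", line[i], ": Likert rating must be an integer in 0..10, ",
         "got ", sQuote(raw$likert_rating[i]), call. = FALSE)
  }
  out <- tibble::tibble(
    respondent_id = raw$respondent_id,
    likert_rating = as.integer(rating),
    most_effective = split_multi(raw$most_effective),
    least_effective = split_multi(raw$least_effective),
    side_effects = split_multi(raw$side_effects),
    symptoms = split_multi(raw$symptoms)
  )
  class(out) <- c("survey_tbl", class(out))
  out
}

#' Write a survey-response table
#'
#' Inverse of [read_survey_table()]; multi-select sets are joined with
#' semicolons, an absent rating becomes an empty field.
#'
#' @param responses A survey table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(responses, path) {
  flat <- tibble::tibble(
    respondent_id = responses$respondent_id,
    likert_rating = responses$likert_rating,
    most_effective = join_multi(responses$most_effective),
    least_effective = join_multi(responses$least_effective),
    side_effects = join_multi(responses$side_effects),
    symptoms = join_multi(responses$symptoms)
  )
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' Published reference weighted averages
#'
#' The packaged copy of the published per-analyte group weighted averages
#' (% w/w), coefficients and p-values from the seven-strain patient
#' preference study that this package's defaults emulate. Used for
#' reproduction checks of the difference-over-sum coefficient from the
#' printed operands.
#'
#' @return Tibble with columns `analyte`, `wa_me`, `wa_le`, `cc_printed`,
#'   `p_printed` (`NA` for the not-applicable rows).
#' @export
reference_weighted_averages <- function() {
  path <- system.file("extdata", "reference_weighted_averages.csv",
                      package = "chemovote", mustWork = TRUE)
  raw <- utils::read.csv(path, colClasses = c("character", rep("numeric", 4)),
                         check.names = FALSE, fileEncoding = "UTF-8")
  out <- tibble::as_tibble(raw)
  out$analyte <- canonical_analyte(out$analyte)
  out
}
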