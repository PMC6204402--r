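# Fixture builders and independent oracles shared across the suite.

# Plain population mean/SD of the vote-expanded sample: each value
# replicated `w` times (integer weights). Independent oracle for the
# weighted statistics.
expanded_mean <- function(values, weights) {
  mean(rep(values, times = weights))
}
expanded_sd <- function(values, weights) {
  x <- rep(values, times = weights)
  sqrt(mean((x - mean(x))^2))
}

# Survey table from plain lists (everything optional).
make_survey <- function(most = list(), least = list(), ratings = NULL,
                        side_effects = list(), symptoms = list()) {
  n <- max(length(most), length(least), length(ratings),
           length(side_effects), length(symptoms), 1L)
  pad <- function(x) {
    x <- c(x, rep(list(character(0)), n - length(x)))
    lapply(x, as.character)
  }
  out <- tibble::tibble(
    respondent_id = sprintf("R%04d", seq_len(n)),
    likert_rating = if (is.null(ratings)) rep(NA_integer_, n) else
      as.integer(c(ratings, rep(NA, n - length(ratings)))),
    most_effective = pad(most),
    least_effective = pad(least),
    side_effects = pad(side_effects),
    symptoms = pad(symptoms)
  )
  class(out) <- c("survey_tbl", class(out))
  out
}

# Long assay table from a strains x analytes value list:
# values[[strain]][[analyte]] is a numeric vector with one entry per lot
# (NA = not tested).
make_assays <- function(values, lab = "Lab A") {
  rows <- list()
  for (s in names(values)) {
    n_lot <- length(values[[s]][[1]])
    for (li in seq_len(n_lot)) {
      for (a in names(values[[s]])) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strain = s, lot = paste0(s, "-L", li), lab = lab,
          analyte = a, value = values[[s]][[a]][li]
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$analyte <- canonical_analyte(out$analyte)
  class(out) <- c("assay_tbl", class(out))
  out
}

# Vote tally built directly (bypassing a survey).
make_tally <- function(votes, n_respondents,
                       category = "most_effective") {
  out <- tibble::tibble(strain = names(votes),
                        votes = as.integer(unname(votes)))
  out <- out[order(-out$votes, out$strain), ]
  structure(out, category = category, n_respondents = n_respondents,
            class = c("vote_tally", class(out)))
}
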