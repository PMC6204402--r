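## Survey descriptives: strain vote tallies and rankings, Likert
## effectiveness summary, side-effect tabulation.

#' Tally strain votes for one category
#'
#' Counts, for every strain, the number of respondents whose selection set
#' for the category contains it (multi-select: a respondent contributes at
#' most one vote per strain but may vote several strains). The category
#' respondent total is the number of respondents with a non-empty selection.
#'
#' @param responses A survey table (see [generate_survey()] /
#'   [read_survey_table()]).
#' @param category `"most_effective"` or `"least_effective"`.
#' @return A `vote_tally`: tibble with columns `strain`, `votes`, plus
#'   attributes `category` and `n_respondents`.
#' @export
tally_strain_votes <- function(responses,
                               category = c("most_effective",
                                            "least_effective")) {
  category <- match.arg(category)
  sets <- lapply(responses[[category]], unique)
  n_cat <- sum(lengths(sets) > 0L)
  counts <- table(unlist(sets))
  out <- tibble::tibble(
    strain = if (is.null(names(counts))) character(0) else names(counts),
    votes = as.integer(counts)
  )
  out <- out[order(-out$votes, out$strain), ]
  structure(out, category = category, n_respondents = n_cat,
            class = c("vote_tally", class(out)))
}

#' @export
print.vote_tally <- function(x, ...) {
  cat("<vote_tally> ", attr(x, "category"), ": ",
      attr(x, "n_respondents"), " respondents, ",
      nrow(x), " strains\n", sep = "")
  NextMethod()
}

#' Rank strains by votes
#'
#' Sorts by votes descending with alphabetical tie-break and reports each
#' strain's share of category respondents (to one decimal). A catch-all
#' label (default `"Others"`) can be excluded from the ranking while still
#' counting toward the respondent total.
#'
#' @param tally A [tally_strain_votes()] result.
#' @param k Maximum number of strains returned (those with at least one
#'   vote).
#' @param exclude Strain labels dropped from the ranking (case-insensitive);
#'   `NULL` keeps everything.
#' @return Tibble with columns `rank`, `strain`, `votes`, `percentage`.
#' @export
rank_strains <- function(tally, k = 4L, exclude = "Others") {
  stopifnot(k >= 1L)
  n <- attr(tally, "n_respondents")
  if (is.null(n) || n == 0L) {
    stop("cannot rank strains: no respondents answered this category",
         call. = FALSE)
  }
  x <- tally[tally$votes >= 1L, ]
  if (!is.null(exclude)) {
    x <- x[!(tolower(trimws(x$strain)) %in% tolower(trimws(exclude))), ]
  }
  x <- x[order(-x$votes, x$strain), ]
  x <- utils::head(x, k)
  tibble::tibble(
    rank = seq_len(nrow(x)),
    strain = x$strain,
    votes = x$votes,
    percentage = round(100 * x$votes / n, 1)
  )
}

#' Summarize Likert effectiveness ratings
#'
#' Sample statistics over rated respondents only: mean, standard deviation
#' (n - 1 denominator), median (mean of central pair for even n), a Student-t
#' 95% confidence interval for the mean, the full 0--10 histogram, and the
#' fraction of ratings at or above `high_cutoff`.
#'
#' @param responses A survey table.
#' @param high_cutoff Rating threshold for the reported high-rating fraction.
#' @return A `likert_summary` list: `n`, `mean`, `sd`, `median`, `ci95`
#'   (length-2), `histogram` (tibble `rating`, `count`), `prop_high`,
#'   `high_cutoff`.
#' @export
summarize_likert <- function(responses, high_cutoff = 7L) {
  r <- responses$likert_rating
  r <- r[!is.na(r)]
  if (!length(r)) stop("no respondents provided a Likert rating",
                       call. = FALSE)
  if (any(r < 0L | r > 10L)) stop("Likert ratings must lie in 0..10",
                                  call. = FALSE)
  n <- length(r)
  m <- mean(r)
  s <- stats::sd(r)
  half <- if (n > 1L) stats::qt(0.975, n - 1L) * s / sqrt(n) else 0
  structure(list(
    n = n, mean = m, sd = if (n > 1L) s else 0,
    median = stats::median(r),
    ci95 = c(m - half, m + half),
    histogram = tibble::tibble(
      rating = 0:10,
      count = as.integer(tabulate(r + 1L, nbins = 11L))
    ),
    prop_high = mean(r >= high_cutoff),
    high_cutoff = high_cutoff
  ), class = "likert_summary")
}

#' @export
print.likert_summary <- function(x, ...) {
  cat(sprintf(
    "<likert_summary> n = %d, mean %.2f (95%% CI %.2f-%.2f), sd %.2f, median %s\n",
    x$n, x$mean, x$ci95[1], x$ci95[2], x$sd, format(x$median)
  ))
  cat(sprintf("  ratings >= %d: %.0f%%\n", x$high_cutoff, 100 * x$prop_high))
  invisible(x)
}

#' Tabulate reported side effects
#'
#' Counts respondents reporting each side effect, with percentages over a
#' configurable denominator: `"responders"` (respondents reporting at least
#' one side effect; the default), `"all"` (every respondent), or an explicit
#' number.
#'
#' @param responses A survey table.
#' @param denominator `"responders"`, `"all"`, or a positive number.
#' @return Tibble with columns `side_effect`, `count`, `percentage`
#'   (one decimal), sorted by count descending.
#' @export
tabulate_side_effects <- function(responses, denominator = "responders") {
  sets <- lapply(responses$side_effects, unique)
  d <- if (is.numeric(denominator)) {
    denominator
  } else {
    switch(match.arg(denominator, c("responders", "all")),
           responders = sum(lengths(sets) > 0L),
           all = length(sets))
  }
  counts <- table(unlist(sets))
  if (!length(counts)) {
    return(tibble::tibble(side_effect = character(0), count = integer(0),
                          percentage = numeric(0)))
  }
  out <- tibble::tibble(
    side_effect = names(counts),
    count = as.integer(counts),
    percentage = round(100 * as.integer(counts) / d, 1)
  )
  out[order(-out$count, out$side_effect), ]
}
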