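## Vote-weighted constituent averaging: each production-lot measurement
## carries its strain's survey vote count as a frequency-style preference
## weight.

check_weight_args <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (!length(values)) stop("no values supplied", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) == 0) stop("at least one weight must be positive",
                              call. = FALSE)
}

#' Vote-weighted mean
#'
#' `sum(w * x) / sum(w)`. With integer vote weights this equals the plain
#' mean of the sample in which each lot value is replicated `w` times.
#'
#' @param values Numeric vector of lot concentrations (% w/w).
#' @param weights Non-negative weights (vote counts), at least one positive.
#' @return The weighted mean.
#' @export
#' @examples
#' weighted_mean(c(16.6, 19.4, 21.0), c(44, 44, 44)) # plain mean, 19.0
#' weighted_mean(c(2, 4), c(1, 3))                   # mean of (2,4,4,4), 3.5
weighted_mean <- function(values, weights) {
  check_weight_args(values, weights)
  sum(weights * values) / sum(weights)
}

#' Vote-weighted standard deviation
#'
#' Frequency-weight interpretation with the population (`sum(w)`)
#' denominator: `sqrt(sum(w * (x - m)^2) / sum(w))`, which equals the
#' population SD of the vote-expanded sample exactly.
#'
#' @inheritParams weighted_mean
#' @return The weighted standard deviation.
#' @export
#' @examples
#' weighted_sd(c(2, 4), c(1, 3)) # population SD of (2,4,4,4) = sqrt(3)/2
weighted_sd <- function(values, weights) {
  check_weight_args(values, weights)
  m <- sum(weights * values) / sum(weights)
  sqrt(sum(weights * (values - m)^2) / sum(weights))
}

#' Build a vote-weighted constituent profile for a strain group
#'
#' Restricts the assay table to the top `top_k` strains of the tally and,
#' for each panel analyte, pools all measured lot values across those
#' strains, each value weighted by its strain's vote count. Not-tested cells
#' (`NA`) are excluded and their weight leaves the denominator for that
#' analyte only (`missing = "exclude"`, the default); `missing = "as_zero"`
#' instead counts them as measured zeros (sensitivity mode). The standard
#' error is the weighted SD divided by the square root of the number of
#' contributing lot measurements.
#'
#' Alongside `n_measurements` the profile records the Kish effective sample
#' size `n_eff = sum(w)^2 / sum(w^2)` of each analyte's weight vector, which
#' the association stage uses for variance estimation (equal weights give
#' `n_eff = n_measurements`).
#'
#' An analyte not tested in every contributing lot is flagged absent
#' (`n_measurements = 0`, `NA` statistics) rather than zero.
#'
#' @param assays Assay table (`strain`, `lot`, `lab`, `analyte`, `value`).
#' @param tally A [tally_strain_votes()] result for the group's category.
#' @param top_k Number of top strains forming the group (default 4).
#' @param missing Not-tested handling: `"exclude"` or `"as_zero"`.
#' @param exclude Labels excluded from the ranking (see [rank_strains()]).
#' @return A `weighted_profile`: tibble with columns `analyte`,
#'   `weighted_mean`, `weighted_sd`, `weighted_se`, `n_measurements`,
#'   `n_eff`, in panel order; attributes `group` (the tally's category),
#'   `strains`, `votes`.
#' @export
build_group_profile <- function(assays, tally, top_k = 4L,
                                missing = c("exclude", "as_zero"),
                                exclude = "Others") {
  missing <- match.arg(missing)
  ranked <- rank_strains(tally, k = top_k, exclude = exclude)
  if (nrow(ranked) < top_k) {
    stop("only ", nrow(ranked), " strains received votes; cannot form a ",
         "top-", top_k, " group", call. = FALSE)
  }
  votes <- stats::setNames(ranked$votes, ranked$strain)
  sub <- assays[assays$strain %in% ranked$strain, ]
  if (!nrow(sub)) stop("no assays available for the top-", top_k,
                       " strains", call. = FALSE)
  no_assay <- setdiff(ranked$strain, unique(sub$strain))
  if (length(no_assay)) {
    stop("no assays for group strain(s): ",
         paste(sQuote(no_assay), collapse = ", "), call. = FALSE)
  }
  panel <- panel_analytes()
  w_all <- unname(votes[sub$strain])
  v_all <- sub$value
  if (missing == "as_zero") v_all[is.na(v_all)] <- 0
  res <- lapply(panel, function(a) {
    idx <- sub$analyte == a & !is.na(v_all)
    x <- v_all[idx]
    w <- w_all[idx]
    n <- length(x)
    if (n == 0L) {
      return(list(weighted_mean = NA_real_, weighted_sd = NA_real_,
                  weighted_se = NA_real_, n_measurements = 0L,
                  n_eff = NA_real_))
    }
    m <- weighted_mean(x, w)
    s <- weighted_sd(x, w)
    list(weighted_mean = m, weighted_sd = s,
         weighted_se = s / sqrt(n), n_measurements = n,
         n_eff = sum(w)^2 / sum(w^2))
  })
  out <- tibble::tibble(
    analyte = panel,
    weighted_mean = vapply(res, `[[`, numeric(1), "weighted_mean"),
    weighted_sd = vapply(res, `[[`, numeric(1), "weighted_sd"),
    weighted_se = vapply(res, `[[`, numeric(1), "weighted_se"),
    n_measurements = vapply(res, `[[`, integer(1), "n_measurements"),
    n_eff = vapply(res, `[[`, numeric(1), "n_eff")
  )
  structure(out, group = attr(tally, "category"),
            strains = ranked$strain, votes = unname(votes),
            class = c("weighted_profile", class(out)))
}

#' @export
print.weighted_profile <- function(x, ...) {
  cat("<weighted_profile> ", attr(x, "group"), ": strains ",
      paste(attr(x, "strains"), collapse = ", "), "\n", sep = "")
  NextMethod()
}
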