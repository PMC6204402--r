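## The bounded difference-over-sum association coefficient, the
## summary-level two-sample significance test, the Table-style association
## assembly, and the major/minor terpene partition.

#' Difference-over-sum association coefficient
#'
#' `(wa_me - wa_le) / (wa_me + wa_le)` for a pair of non-negative group
#' weighted averages. Bounded in `[-1, 1]`: `+1` exactly when the
#' constituent is absent from the least-effective group (and present in the
#' most-effective), `-1` in the opposite case, `NA` when absent from both.
#' Positive values indicate association with increased anxiolytic
#' effectiveness, negative with decreased.
#'
#' @param wa_me,wa_le Non-negative group weighted averages (% w/w);
#'   vectorized.
#' @return Numeric vector in `[-1, 1]`, `NA` where both inputs are zero.
#' @export
#' @examples
#' correlation_coefficient(18.01, 13.67) # 0.137 at 3 decimals
#' correlation_coefficient(0, 0.069)     # -1
correlation_coefficient <- function(wa_me, wa_le) {
  if (any(wa_me < 0, na.rm = TRUE) || any(wa_le < 0, na.rm = TRUE)) {
    stop("weighted averages must be non-negative", call. = FALSE)
  }
  out <- (wa_me - wa_le) / (wa_me + wa_le)
  out[!is.na(wa_me) & !is.na(wa_le) & wa_me == 0 & wa_le == 0] <- NA_real_
  out
}

#' Summary-level two-sample difference-of-means test
#'
#' Welch's unequal-variance t statistic from group summaries:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Satterthwaite degrees of
#' freedom and a two-sided p-value. Degenerate inputs (both SDs zero) give
#' `t = 0, p = 1` for equal means, and `p = 0` with `degenerate = TRUE` for
#' unequal means.
#'
#' @param mean1,sd1,n1 First group mean, SD and sample size (`n1 >= 2`).
#' @param mean2,sd2,n2 Second group summaries (`n2 >= 2`).
#' @return Tibble with columns `t_stat`, `df`, `p_value`, `degenerate`;
#'   vectorized over the inputs.
#' @export
#' @examples
#' difference_of_means_test(5, 1, 12, 4, 1, 12) # t = 2.449, df = 22
difference_of_means_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (any(c(sd1, sd2) < 0, na.rm = TRUE)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (any(c(n1, n2) < 2, na.rm = TRUE)) {
    stop("each group needs at least 2 measurements", call. = FALSE)
  }
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  denom <- sqrt(se1 + se2)
  diff <- mean1 - mean2
  t_stat <- ifelse(denom > 0, diff / denom,
                   ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(denom > 0,
               (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              0)
  tibble::tibble(
    t_stat = t_stat, df = df, p_value = p,
    degenerate = denom == 0 & diff != 0
  )
}

#' Assemble the per-analyte association table
#'
#' Joins the most- and least-effective group profiles in panel order and,
#' per analyte, computes the difference-over-sum coefficient, its
#' delta-method standard error, and a summary-level Welch test on the group
#' weighted means. Rows where the constituent is absent from both groups
#' carry their weighted averages but no coefficient or test
#' (`status = "NA_zero_both"`); rows with fewer than two measurements in
#' either group are `status = "insufficient_data"`.
#'
#' The variance entering the test accounts for the preference weighting:
#' each group's SD is Bessel-corrected for reliability weights
#' (`sd / sqrt(1 - sum(w^2)/sum(w)^2)`), the standard error uses the Kish
#' effective sample size `n_eff = sum(w)^2 / sum(w^2)`, and the
#' Satterthwaite degrees of freedom use the actual measurement counts.
#' With equal weights this is exactly the classic Welch test on the lot
#' measurements.
#'
#' Significance flags mirror the reporting convention `*` (`p < alpha`) and
#' `#` (`alpha <= p < marginal_band`); a Benjamini-Hochberg adjusted column
#' (`p_adjusted`) is appended as a supplementary extension -- the flags
#' themselves are unadjusted.
#'
#' @param profile_me,profile_le [build_group_profile()] results for the
#'   most- and least-effective groups; panels must match.
#' @param alpha Significance level for the `significant` flag.
#' @param marginal_band Upper bound of the marginal band.
#' @return An `association_tbl`: tibble in panel order with columns
#'   `analyte`, `wa_me`, `wa_le`, `cc`, `se_cc`, `t_stat`, `df`, `p_value`,
#'   `status`, `significant`, `marginal`, `p_adjusted`.
#' @export
build_association_table <- function(profile_me, profile_le, alpha = 0.05,
                                    marginal_band = 0.10) {
  stopifnot(alpha >= 0, marginal_band >= alpha)
  if (!identical(profile_me$analyte, profile_le$analyte)) {
    bad <- union(setdiff(profile_me$analyte, profile_le$analyte),
                 setdiff(profile_le$analyte, profile_me$analyte))
    stop("profiles disagree on the analyte panel: ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  n_an <- nrow(profile_me)
  wa_me <- profile_me$weighted_mean
  wa_le <- profile_le$weighted_mean
  insufficient <- profile_me$n_measurements < 2L |
    profile_le$n_measurements < 2L |
    ## extreme weight concentration can leave an effective size below 2,
    ## in which case the variance of the weighted mean is not estimable
    (!is.na(profile_me$n_eff) & profile_me$n_eff < 2) |
    (!is.na(profile_le$n_eff) & profile_le$n_eff < 2)
  zero_both <- !insufficient & wa_me == 0 & wa_le == 0
  valid <- !insufficient & !zero_both

  cc <- rep(NA_real_, n_an)
  cc[valid] <- correlation_coefficient(wa_me[valid], wa_le[valid])

  ## delta-method SE of (a-b)/(a+b) from the group SEs of a and b
  se_cc <- rep(NA_real_, n_an)
  a <- wa_me[valid]; b <- wa_le[valid]
  se_a <- profile_me$weighted_se[valid]
  se_b <- profile_le$weighted_se[valid]
  se_cc[valid] <- 2 * sqrt(b^2 * se_a^2 + a^2 * se_b^2) / (a + b)^2

  t_stat <- df <- p <- rep(NA_real_, n_an)
  degenerate <- rep(FALSE, n_an)
  if (any(valid)) {
    ## Reliability-weight Bessel correction, Kish effective size for the SE,
    ## and degrees of freedom from the actual measurement counts. Passed as
    ## equivalent summaries: sd' = s_rel * sqrt(n_meas / n_eff) with n_meas
    ## gives sd'^2/n_meas = s_rel^2/n_eff while Satterthwaite sees n_meas-1.
    q_me <- 1 / profile_me$n_eff[valid]
    q_le <- 1 / profile_le$n_eff[valid]
    n_me <- profile_me$n_measurements[valid]
    n_le <- profile_le$n_measurements[valid]
    sd_me <- profile_me$weighted_sd[valid] / sqrt(1 - q_me) *
      sqrt(n_me * q_me)
    sd_le <- profile_le$weighted_sd[valid] / sqrt(1 - q_le) *
      sqrt(n_le * q_le)
    test <- difference_of_means_test(
      wa_me[valid], sd_me, n_me,
      wa_le[valid], sd_le, n_le
    )
    t_stat[valid] <- test$t_stat
    df[valid] <- test$df
    p[valid] <- test$p_value
    degenerate[valid] <- test$degenerate
  }
  status <- dplyr::case_when(
    insufficient ~ "insufficient_data",
    zero_both ~ "NA_zero_both",
    .default = "valid"
  )
  out <- tibble::tibble(
    analyte = profile_me$analyte,
    wa_me = wa_me, wa_le = wa_le,
    cc = cc, se_cc = se_cc,
    t_stat = t_stat, df = df, p_value = p,
    status = status,
    significant = !is.na(p) & p < alpha,
    marginal = !is.na(p) & p >= alpha & p < marginal_band,
    p_adjusted = {
      padj <- rep(NA_real_, n_an)
      padj[valid] <- stats::p.adjust(p[valid], method = "BH")
      padj
    }
  )
  if (any(degenerate)) {
    attr(out, "degenerate_variance") <- out$analyte[degenerate]
  }
  structure(out, alpha = alpha, marginal_band = marginal_band,
            class = c("association_tbl", class(out)))
}

#' Partition terpenes into major and minor
#'
#' Terpene analytes only (cannabinoids and the total-terpenes aggregate are
#' excluded): a terpene is major when its larger group weighted average
#' exceeds the threshold, the level above which terpenes are conventionally
#' of pharmacological interest.
#'
#' @param table An [build_association_table()] result.
#' @param threshold Concentration threshold in % w/w (default 0.05).
#' @return A `terpene_partition` list with character vectors `major` and
#'   `minor` and the `threshold`.
#' @export
partition_terpenes <- function(table, threshold = 0.05) {
  stopifnot(threshold > 0)
  terps <- panel_analytes("terpene")
  x <- table[table$analyte %in% terps, ]
  hi <- pmax(x$wa_me, x$wa_le)
  structure(list(
    major = x$analyte[!is.na(hi) & hi > threshold],
    minor = x$analyte[is.na(hi) | hi <= threshold],
    threshold = threshold
  ), class = "terpene_partition")
}

#' @export
print.terpene_partition <- function(x, ...) {
  cat("<terpene_partition> threshold ", x$threshold, " %w/w\n",
      "  major (", length(x$major), "): ",
      paste(x$major, collapse = ", "), "\n",
      "  minor (", length(x$minor), ")\n", sep = "")
  invisible(x)
}
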