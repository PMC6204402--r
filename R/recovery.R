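## Parameter-recovery and null-calibration experiments: run the full
## tally -> profile -> association pipeline on replicated synthetic data
## with known planted effects and score what comes back.

#' Run a replicated recovery experiment
#'
#' For each replicate, generates lot assays and survey responses under the
#' configuration (with a per-replicate seed derived from the configured
#' seed), tallies both vote categories, builds the two top-`top_k` group
#' profiles and the association table, and records each analyte's
#' coefficient and significance call. Replicates are scored only when the
#' downstream two-sample comparison is well-posed; a replicate is excluded
#' (and counted, with its reason) when a category has no respondents, when
#' fewer than `top_k` strains received votes in a category, or when the two
#' strain groups overlap -- overlapping groups share lot measurements, so
#' the two-sample test's independence assumption fails and neither
#' calibration nor recovery is interpretable there.
#'
#' Reported rates: `sign_recovery_rate` is the fraction of
#' (replicate x planted analyte) coefficients whose sign matches the
#' planted weight's sign; `false_positive_rate` is the fraction of
#' significance calls at `alpha` among analytes with zero planted weight
#' (valid rows only), with a Monte-Carlo standard error computed from the
#' spread of per-replicate false-positive fractions.
#'
#' @param config A [sim_config()]; its `effect_weights` are the planted
#'   ground truth.
#' @param n_replicates Number of replicates (`>= 1`).
#' @param alpha Significance level for false-positive scoring.
#' @param top_k Group size (default 4).
#' @return A `recovery_report` list: `per_analyte` (tibble with
#'   `planted_weight`, `mean_cc`, `sign_match_rate`, `significant_rate`,
#'   `n_estimates`), `sign_recovery_rate`, `false_positive_rate`,
#'   `fp_mc_se`, `alpha`, `n_replicates`, `n_valid`, `n_excluded`,
#'   `exclusions` (named counts by reason).
#' @export
run_recovery_experiment <- function(config, n_replicates, alpha = 0.05,
                                    top_k = 4L) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1L)
  if (config$seed + 2 * n_replicates >= 2^31) {
    stop("seed too large for the per-replicate seed schedule", call. = FALSE)
  }
  planted <- names(config$effect_weights)[config$effect_weights != 0]
  panel <- panel_analytes()
  cc_mat <- matrix(NA_real_, n_replicates, length(panel),
                   dimnames = list(NULL, panel))
  sig_mat <- matrix(NA, n_replicates, length(panel),
                    dimnames = list(NULL, panel))
  valid_rep <- logical(n_replicates)
  reason <- character(n_replicates)
  for (i in seq_len(n_replicates)) {
    res <- tryCatch(
      recovery_replicate(config, config$seed + 2L * i, alpha, top_k),
      error = function(e) {
        stop("replicate ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    if (is.character(res)) {
      reason[i] <- res
      next
    }
    valid_rep[i] <- TRUE
    cc_mat[i, res$analyte] <- res$cc
    sig_mat[i, res$analyte] <- ifelse(res$status == "valid",
                                      res$significant, NA)
  }
  n_valid <- sum(valid_rep)
  cc_v <- cc_mat[valid_rep, , drop = FALSE]
  sig_v <- sig_mat[valid_rep, , drop = FALSE]
  null_analytes <- setdiff(panel, planted)

  per_analyte <- tibble::tibble(
    analyte = panel,
    planted_weight = vapply(panel, function(a) {
      w <- config$effect_weights[a]
      if (is.na(w)) 0 else unname(w)
    }, numeric(1), USE.NAMES = FALSE),
    n_estimates = unname(colSums(!is.na(cc_v))),
    mean_cc = unname(colMeans(cc_v, na.rm = TRUE)),
    sign_match_rate = vapply(panel, function(a) {
      w <- config$effect_weights[a]
      if (is.na(w) || w == 0) return(NA_real_)
      x <- cc_v[, a]
      mean(sign(x[!is.na(x)]) == sign(w))
    }, numeric(1), USE.NAMES = FALSE),
    significant_rate = unname(colMeans(sig_v, na.rm = TRUE))
  )
  per_analyte$mean_cc[is.nan(per_analyte$mean_cc)] <- NA_real_
  per_analyte$significant_rate[is.nan(per_analyte$significant_rate)] <-
    NA_real_

  sign_recovery <- if (length(planted) && n_valid) {
    x <- cc_v[, planted, drop = FALSE]
    w <- rep(config$effect_weights[planted], each = nrow(x))
    mean(sign(x[!is.na(x)]) == sign(w[!is.na(x)]))
  } else NA_real_

  fp_by_rep <- if (n_valid) {
    apply(sig_v[, null_analytes, drop = FALSE], 1,
          function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE))
  } else numeric(0)
  fp_by_rep <- fp_by_rep[!is.na(fp_by_rep)]
  fp <- if (length(fp_by_rep)) mean(fp_by_rep) else NA_real_
  fp_se <- if (length(fp_by_rep) > 1) {
    stats::sd(fp_by_rep) / sqrt(length(fp_by_rep))
  } else NA_real_

  excl <- table(reason[reason != ""])
  structure(list(
    per_analyte = per_analyte,
    sign_recovery_rate = sign_recovery,
    false_positive_rate = fp,
    fp_mc_se = fp_se,
    alpha = alpha,
    n_replicates = n_replicates,
    n_valid = n_valid,
    n_excluded = n_replicates - n_valid,
    exclusions = stats::setNames(as.integer(excl), names(excl))
  ), class = "recovery_report")
}

## One replicate; returns the association tibble, or a string naming the
## exclusion reason when the replicate is not scoreable.
recovery_replicate <- function(config, seed, alpha, top_k) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  assays <- generate_lot_assays(cfg)
  survey <- generate_survey(cfg, assays)
  tally_me <- tally_strain_votes(survey, "most_effective")
  tally_le <- tally_strain_votes(survey, "least_effective")
  if (attr(tally_me, "n_respondents") == 0L) return("empty_most")
  if (attr(tally_le, "n_respondents") == 0L) return("empty_least")
  rme <- rank_strains(tally_me, k = top_k)
  rle <- rank_strains(tally_le, k = top_k)
  if (nrow(rme) < top_k || nrow(rle) < top_k) return("too_few_strains")
  if (length(intersect(rme$strain, rle$strain))) {
    return("overlapping_groups")
  }
  prof_me <- build_group_profile(assays, tally_me, top_k = top_k)
  prof_le <- build_group_profile(assays, tally_le, top_k = top_k)
  build_association_table(prof_me, prof_le, alpha = alpha)
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$n_valid, "/", x$n_replicates,
      " valid replicates (", x$n_excluded, " excluded)\n", sep = "")
  if (length(x$exclusions)) {
    cat("  exclusions:",
        paste(names(x$exclusions), x$exclusions, sep = "=",
              collapse = ", "), "\n")
  }
  cat(sprintf("  sign recovery rate: %s\n",
              ifelse(is.na(x$sign_recovery_rate), "n/a (no planted effects)",
                     sprintf("%.3f", x$sign_recovery_rate))))
  cat(sprintf("  false positive rate at alpha=%.2f: %.4f (MC se %.4f)\n",
              x$alpha, x$false_positive_rate, x$fp_mc_se))
  invisible(x)
}
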