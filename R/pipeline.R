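## End-to-end orchestration: read (or simulate) inputs, tally -> rank ->
## profile -> associate -> partition, and write a reproducible report
## bundle.

#' Pipeline configuration
#'
#' Either file inputs (`assay_path` + `survey_path`) or a [sim_config()]
#' for a fully synthetic run.
#'
#' @param assay_path,survey_path Input CSV paths (see [read_assay_table()],
#'   [read_survey_table()]); ignored when `sim` is given.
#' @param sim Optional [sim_config()] for a synthetic run.
#' @param top_k Strains per preference group.
#' @param alpha Significance level.
#' @param marginal_band Upper bound of the marginal significance band
#'   (must exceed `alpha`).
#' @param terpene_threshold Major/minor terpene partition threshold
#'   (% w/w, `> 0`).
#' @param side_effect_denominator See [tabulate_side_effects()].
#' @param missing Not-tested handling in profiles (`"exclude"` or
#'   `"as_zero"`).
#' @param exclude_from_ranking Labels excluded from rankings.
#' @param out_dir Optional output directory for the report bundle.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(assay_path = NULL, survey_path = NULL,
                            sim = NULL, top_k = 4L, alpha = 0.05,
                            marginal_band = 0.10, terpene_threshold = 0.05,
                            side_effect_denominator = "responders",
                            missing = c("exclude", "as_zero"),
                            exclude_from_ranking = "Others",
                            out_dir = NULL) {
  missing <- match.arg(missing)
  stopifnot(top_k >= 1L, alpha < marginal_band, terpene_threshold > 0)
  if (is.null(sim) && (is.null(assay_path) || is.null(survey_path))) {
    stop("provide either both input paths or a sim_config", call. = FALSE)
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(
    assay_path = assay_path, survey_path = survey_path, sim = sim,
    top_k = as.integer(top_k), alpha = alpha,
    marginal_band = marginal_band,
    terpene_threshold = terpene_threshold,
    side_effect_denominator = side_effect_denominator,
    missing = missing, exclude_from_ranking = exclude_from_ranking,
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes tally -> rank -> Likert/side-effect descriptives -> group
#' profiles (both categories) -> association table -> terpene partition,
#' and (if `out_dir` is configured) writes the report bundle. With
#' `verbose = TRUE` every excluded datum class (not-tested assay cells,
#' unrated respondents, non-responding category members) is logged with a
#' count; logging never changes any table.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log exclusion counts as messages.
#' @return A `report_bundle` list with elements `assays`, `survey`,
#'   `tally_most`, `tally_least`, `ranking_most`, `ranking_least`,
#'   `likert`, `side_effects`, `profile_most`, `profile_least`,
#'   `association`, `partition`, and `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)
  if (!is.null(config$sim)) {
    assays <- generate_lot_assays(config$sim)
    survey <- generate_survey(config$sim, assays)
    say("simulated ", length(unique(assays$lot)), " lots and ",
        nrow(survey), " respondents (seed ", config$sim$seed, ")")
  } else {
    assays <- read_assay_table(config$assay_path)
    survey <- read_survey_table(config$survey_path)
  }
  say("not-tested assay cells excluded: ", sum(is.na(assays$value)))
  say("respondents without a Likert rating: ",
      sum(is.na(survey$likert_rating)))

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage ", sQuote(name), ": ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tally_most <- step("tally", tally_strain_votes(survey, "most_effective"))
  tally_least <- step("tally",
                      tally_strain_votes(survey, "least_effective"))
  say("category respondents: most=", attr(tally_most, "n_respondents"),
      ", least=", attr(tally_least, "n_respondents"))
  ranking_most <- step("rank", rank_strains(
    tally_most, k = config$top_k, exclude = config$exclude_from_ranking))
  ranking_least <- step("rank", rank_strains(
    tally_least, k = config$top_k, exclude = config$exclude_from_ranking))
  likert <- step("likert", summarize_likert(survey))
  side_effects <- step("side_effects", tabulate_side_effects(
    survey, denominator = config$side_effect_denominator))
  profile_most <- step("profile", build_group_profile(
    assays, tally_most, top_k = config$top_k, missing = config$missing,
    exclude = config$exclude_from_ranking))
  profile_least <- step("profile", build_group_profile(
    assays, tally_least, top_k = config$top_k, missing = config$missing,
    exclude = config$exclude_from_ranking))
  association <- step("associate", build_association_table(
    profile_most, profile_least, alpha = config$alpha,
    marginal_band = config$marginal_band))
  partition <- step("partition", partition_terpenes(
    association, threshold = config$terpene_threshold))

  bundle <- structure(list(
    assays = assays, survey = survey,
    tally_most = tally_most, tally_least = tally_least,
    ranking_most = ranking_most, ranking_least = ranking_least,
    likert = likert, side_effects = side_effects,
    profile_most = profile_most, profile_least = profile_least,
    association = association, partition = partition,
    config = config
  ), class = "report_bundle")
  if (!is.null(config$out_dir)) {
    write_report_bundle(bundle, config$out_dir)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  lots: ", length(unique(x$assays$lot)),
      ", respondents: ", nrow(x$survey), "\n", sep = "")
  cat("  most effective group: ",
      paste(x$ranking_most$strain, collapse = ", "), "\n", sep = "")
  cat("  least effective group: ",
      paste(x$ranking_least$strain, collapse = ", "), "\n", sep = "")
  sig <- x$association$analyte[x$association$significant]
  cat("  significant analytes (p < ", attr(x$association, "alpha"), "): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

fmt3 <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))

#' Write a report bundle to disk
#'
#' Writes tidy CSV tables (vote tallies and rankings, Likert histogram and
#' summary, side effects, both group profiles, the association table in
#' fixed 3-decimal display form plus a full-precision companion, and the
#' terpene partition), echoes the input tables, and writes a JSON run
#' manifest (file list, config hash, package version). Output is
#' byte-stable: rerunning an identical configuration reproduces identical
#' files.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_assay_table(bundle$assays, p("assays.csv"))
  write_survey_table(bundle$survey, p("survey.csv"))
  readr::write_csv(tibble::as_tibble(bundle$tally_most), p("votes_most.csv"))
  readr::write_csv(tibble::as_tibble(bundle$tally_least),
                   p("votes_least.csv"))
  readr::write_csv(bundle$ranking_most, p("ranking_most.csv"))
  readr::write_csv(bundle$ranking_least, p("ranking_least.csv"))
  readr::write_csv(bundle$likert$histogram, p("likert_histogram.csv"))
  readr::write_csv(tibble::tibble(
    n = bundle$likert$n, mean = bundle$likert$mean, sd = bundle$likert$sd,
    median = bundle$likert$median, ci_low = bundle$likert$ci95[1],
    ci_high = bundle$likert$ci95[2], prop_high = bundle$likert$prop_high,
    high_cutoff = bundle$likert$high_cutoff
  ), p("likert_summary.csv"))
  readr::write_csv(bundle$side_effects, p("side_effects.csv"))
  readr::write_csv(tibble::as_tibble(bundle$profile_most),
                   p("profile_most.csv"))
  readr::write_csv(tibble::as_tibble(bundle$profile_least),
                   p("profile_least.csv"))
  assoc <- bundle$association
  readr::write_csv(tibble::tibble(
    analyte = assoc$analyte,
    wa_most_effective = fmt3(assoc$wa_me),
    wa_least_effective = fmt3(assoc$wa_le),
    correlation_coefficient = fmt3(assoc$cc),
    p_value = fmt3(assoc$p_value),
    flag = ifelse(assoc$significant, "*",
                  ifelse(assoc$marginal, "#", "")),
    status = assoc$status
  ), p("association.csv"))
  readr::write_csv(tibble::as_tibble(assoc), p("association_full.csv"))
  readr::write_csv(tibble::tibble(
    analyte = c(bundle$partition$major, bundle$partition$minor),
    group = c(rep("major", length(bundle$partition$major)),
              rep("minor", length(bundle$partition$minor)))
  ), p("partition.csv"))
  cfg_path <- p("config.yaml")
  yaml::write_yaml(config_as_list(bundle$config), cfg_path)
  files <- c("assays.csv", "survey.csv", "votes_most.csv",
             "votes_least.csv", "ranking_most.csv", "ranking_least.csv",
             "likert_histogram.csv", "likert_summary.csv",
             "side_effects.csv", "profile_most.csv", "profile_least.csv",
             "association.csv", "association_full.csv", "partition.csv",
             "config.yaml")
  manifest <- list(
    package = "chemovote",
    version = as.character(utils::packageVersion("chemovote")),
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = if (!is.null(bundle$config$sim)) bundle$config$sim$seed else NULL,
    files = files
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

## Plain-list view of configs for YAML serialization. The output directory
## is incidental to the analysis and omitted, so identical analyses yield
## identical serialized configs wherever they are written.
config_as_list <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  if (!is.null(x$sim)) x$sim <- sim_config_as_list(x$sim)
  x[!vapply(x, is.null, logical(1))]
}

sim_config_as_list <- function(sim) {
  x <- unclass(sim)
  x$archetypes <- lapply(x$archetypes, function(a) {
    prof <- a$mean_profile[a$mean_profile > 0]
    list(name = a$name, mean_profile = as.list(prof), lot_cv = a$lot_cv)
  })
  x$strains <- as.list(x$strains)
  x$effect_weights <- as.list(x$effect_weights)
  x$strain_popularity <- as.list(x$strain_popularity)
  x$response_rates <- as.list(x$response_rates)
  x$side_effect_probs <- as.list(x$side_effect_probs)
  x$symptom_probs <- as.list(x$symptom_probs)
  x
}

#' Write / read a simulation configuration as YAML
#'
#' Serializes a [sim_config()] (including archetype profiles and the planted
#' `effect_weights` ground truth, so recovery scoring can be reproduced from
#' the file alone) and reads it back.
#'
#' @param sim A `sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(sim, path) {
  stopifnot(inherits(sim, "sim_config"))
  yaml::write_yaml(sim_config_as_list(sim), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  archetypes <- lapply(x$archetypes, function(a) {
    chemotype_archetype(a$name, unlist(a$mean_profile), a$lot_cv)
  })
  sim_config(
    strains = unlist(x$strains),
    archetypes = archetypes,
    effect_weights = unlist(x$effect_weights),
    n_lots_per_strain = x$n_lots_per_strain,
    n_respondents = x$n_respondents,
    strains_tried = x$strains_tried,
    respondent_noise_sd = x$respondent_noise_sd,
    vote_margin = x$vote_margin,
    strain_popularity = unlist(x$strain_popularity),
    lab_masks = x$lab_masks,
    lab_names = x$lab_names,
    response_rates = unlist(x$response_rates),
    likert_intercept = x$likert_intercept,
    likert_slope = x$likert_slope,
    side_effect_probs = unlist(x$side_effect_probs),
    symptom_probs = unlist(x$symptom_probs),
    seed = x$seed
  )
}
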