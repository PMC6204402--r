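## Synthetic strain chemotypes, lot assays and survey responses with planted
## ground truth, so the whole pipeline can be exercised and its operating
## characteristics (null calibration, parameter recovery) measured without
## any external data.

#' Define a chemotype archetype
#'
#' An archetype is a mean constituent profile (% w/w) plus a lot-to-lot
#' coefficient of variation. Strains assigned to the same archetype share a
#' ground-truth chemotype; production lots scatter around it.
#'
#' @param name Archetype label.
#' @param mean_profile Named numeric vector of mean concentrations (% w/w),
#'   names drawn from the measured panel (see [analyte_panel()]; the
#'   total-terpenes aggregate is computed, not specified). Analytes omitted
#'   are absent (0).
#' @param lot_cv Coefficient of variation of multiplicative lot-level noise
#'   (unitless, `>= 0`).
#' @return A `chemotype_archetype` object.
#' @export
chemotype_archetype <- function(name, mean_profile, lot_cv = 0.12) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(mean_profile), length(mean_profile) >= 1L,
            !is.null(names(mean_profile)),
            is.numeric(lot_cv), length(lot_cv) == 1L, lot_cv >= 0)
  if (any(mean_profile < 0)) {
    stop("archetype ", sQuote(name), ": negative mean concentration",
         call. = FALSE)
  }
  measured <- setdiff(panel_analytes(), "Total terpenes")
  nm <- canonical_analyte(names(mean_profile))
  if ("Total terpenes" %in% nm) {
    stop("archetype ", sQuote(name),
         ": 'Total terpenes' is an aggregate and cannot be specified",
         call. = FALSE)
  }
  full <- stats::setNames(numeric(length(measured)), measured)
  full[nm] <- as.numeric(mean_profile)
  structure(list(name = name, mean_profile = full, lot_cv = lot_cv),
            class = "chemotype_archetype")
}

#' @export
print.chemotype_archetype <- function(x, ...) {
  nz <- x$mean_profile[x$mean_profile > 0]
  cat("<chemotype_archetype> ", x$name,
      " (", length(nz), " non-zero analytes, lot CV ", x$lot_cv, ")\n",
      sep = "")
  invisible(x)
}

profile_from <- function(...) {
  v <- c(...)
  stats::setNames(as.numeric(v), names(v))
}

#' Built-in chemotype archetypes
#'
#' Four archetypes spanning the chemotype space the package's defaults
#' emulate: a nerolidol-rich THC-dominant "kush" profile, a myrcene-dominant
#' profile, a terpinolene-dominant profile (carrying the co-occurring minor
#' terpenes alpha-phellandrene, 3-carene, alpha-/gamma-terpinene), and a
#' mixed THC:CBD (type II) profile. Cannabinoids sit at 0--19 % w/w and
#' individual terpenes at 0--0.5 % w/w.
#'
#' @param lot_cv Lot-to-lot coefficient of variation shared by all
#'   archetypes; the default 0.12 is the empirical CV of the three published
#'   THC production-lot values (16.6, 19.4, 21.0 % w/w) in the worked
#'   weighted-average example the generator emulates.
#' @return Named list of [chemotype_archetype()] objects.
#' @export
default_archetypes <- function(lot_cv = 0.12) {
  list(
    kush = chemotype_archetype("kush", profile_from(
      "delta9-Tetrahydrocannabinol" = 19, "Cannabidiol" = 0.07,
      "Cannabigerol" = 0.70, "Cannabichromene" = 0.13,
      "alpha-Pinene" = 0.17, "Camphene" = 0.012, "Sabinene" = 0.05,
      "beta-Pinene" = 0.07, "Myrcene" = 0.27, "D-Limonene" = 0.23,
      "Eucalyptol" = 0.004, "beta-Ocimene" = 0.006, "Terpinolene" = 0.010,
      "Fenchone" = 0.013, "Linalool" = 0.11, "Fenchol" = 0.034,
      "Borneol" = 0.020, "alpha-Terpineol" = 0.062, "Geraniol" = 0.001,
      "gamma-Terpineol" = 0.014, "beta-Caryophyllene" = 0.31,
      "Caryophyllene oxide" = 0.010, "Humulene" = 0.10, "Valencene" = 0.003,
      "trans-Nerolidol" = 0.50, "alpha-Bisabolol" = 0.08
    ), lot_cv),
    myrcene_dominant = chemotype_archetype("myrcene_dominant", profile_from(
      "delta9-Tetrahydrocannabinol" = 15, "Cannabidiol" = 0.10,
      "Cannabigerol" = 0.80, "Cannabichromene" = 0.20,
      "alpha-Pinene" = 0.09, "Camphene" = 0.009, "Sabinene" = 0.012,
      "beta-Pinene" = 0.05, "Myrcene" = 0.50, "D-Limonene" = 0.15,
      "Eucalyptol" = 0.004, "beta-Ocimene" = 0.030, "Terpinolene" = 0.012,
      "Sabinene hydrate" = 0.003, "Fenchone" = 0.013, "Linalool" = 0.11,
      "Fenchol" = 0.025, "Borneol" = 0.024, "alpha-Terpineol" = 0.060,
      "beta-Caryophyllene" = 0.20, "Caryophyllene oxide" = 0.006,
      "Humulene" = 0.08, "trans-Nerolidol" = 0.15, "Guaiol" = 0.09,
      "alpha-Bisabolol" = 0.04
    ), lot_cv),
    terpinolene_dominant = chemotype_archetype("terpinolene_dominant",
      profile_from(
      "delta9-Tetrahydrocannabinol" = 14, "Cannabidiol" = 0.10,
      "Cannabigerol" = 0.70, "Cannabichromene" = 0.20,
      "alpha-Pinene" = 0.10, "Camphene" = 0.008, "Sabinene" = 0.010,
      "beta-Pinene" = 0.05, "Myrcene" = 0.25, "alpha-Phellandrene" = 0.025,
      "3-Carene" = 0.018, "D-Limonene" = 0.14, "Eucalyptol" = 0.013,
      "beta-Ocimene" = 0.10, "Terpinolene" = 0.45,
      "alpha-Terpinene" = 0.017, "gamma-Terpinene" = 0.014,
      "Sabinene hydrate" = 0.013, "Fenchone" = 0.012, "Linalool" = 0.10,
      "Fenchol" = 0.022, "Borneol" = 0.022, "alpha-Terpineol" = 0.055,
      "beta-Caryophyllene" = 0.17, "Caryophyllene oxide" = 0.005,
      "Humulene" = 0.07, "Guaiol" = 0.06, "alpha-Bisabolol" = 0.035
    ), lot_cv),
    type_ii = chemotype_archetype("type_ii", profile_from(
      "delta9-Tetrahydrocannabinol" = 6, "Cannabidiol" = 8,
      "Cannabigerol" = 0.90, "Cannabichromene" = 0.25,
      "alpha-Pinene" = 0.08, "Camphene" = 0.008, "Sabinene" = 0.010,
      "beta-Pinene" = 0.05, "Myrcene" = 0.35, "D-Limonene" = 0.10,
      "beta-Ocimene" = 0.020, "Terpinolene" = 0.008, "Fenchone" = 0.010,
      "Linalool" = 0.09, "Fenchol" = 0.020, "Borneol" = 0.020,
      "alpha-Terpineol" = 0.050, "beta-Caryophyllene" = 0.18,
      "Caryophyllene oxide" = 0.006, "Humulene" = 0.07,
      "trans-Nerolidol" = 0.05, "Guaiol" = 0.07, "alpha-Bisabolol" = 0.03
    ), lot_cv)
  )
}

#' Simulation configuration
#'
#' Bundles everything the generators need: the strain-to-archetype map, the
#' planted analyte effect weights (the recoverable ground truth), the voting
#' and Likert response model, lab coverage masks, and the seed.
#'
#' The latent anxiolytic utility of strain `s` for respondent `r` is
#' `popularity_s + sum_a weight_a * mean_concentration_{s,a} + noise_{r,s}`
#' with Gaussian noise. Respondents vote every tried strain within
#' `vote_margin` utility of their best (worst) tried strain as most (least)
#' effective. `strain_popularity` (default all zero) models preference
#' heterogeneity unrelated to chemotype.
#'
#' @param strains Named character vector: strain label -> archetype name.
#' @param archetypes Named list of [chemotype_archetype()] objects covering
#'   every archetype used in `strains`.
#' @param effect_weights Named numeric vector of signed utility weights per
#'   analyte (utility units per % w/w); analytes omitted have weight 0.
#' @param n_lots_per_strain Production lots assayed per strain.
#' @param n_respondents Number of survey respondents.
#' @param strains_tried Integer vector of possible tried-set sizes, sampled
#'   uniformly per respondent; all values must be `>= 2` (a respondent must
#'   be able to vote both categories).
#' @param respondent_noise_sd Standard deviation of respondent-by-strain
#'   utility noise.
#' @param vote_margin Utility margin for multi-select voting.
#' @param strain_popularity Named numeric vector of chemotype-independent
#'   utility offsets per strain (default 0).
#' @param lab_masks Named list: lot id -> character vector of analytes that
#'   lot's lab does not test (recorded not-tested, distinct from measured 0).
#' @param lab_names Length-2 character vector: default lab, masked-lot lab.
#' @param response_rates Named numeric vector with elements `most`, `least`,
#'   `likert`: probability a respondent answers each item.
#' @param likert_intercept,likert_slope Affine map from a respondent's best
#'   tried utility to the 0--10 Likert rating (rounded, clamped).
#' @param side_effect_probs,symptom_probs Named probability vectors for the
#'   independent side-effect and symptom flags.
#' @param seed Integer seed; fixed seed implies bit-reproducible output.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(strains,
                       archetypes = default_archetypes(),
                       effect_weights = numeric(0),
                       n_lots_per_strain = 3L,
                       n_respondents = 442L,
                       strains_tried = 3:7,
                       respondent_noise_sd = 1.5,
                       vote_margin = 0.25,
                       strain_popularity = NULL,
                       lab_masks = list(),
                       lab_names = c("Lab A", "Lab B"),
                       response_rates = c(most = 219 / 442,
                                          least = 189 / 442,
                                          likert = 260 / 442),
                       likert_intercept = 4.5,
                       likert_slope = 0.8,
                       side_effect_probs = c("Dry mouth" = 0.649,
                                             "Short-term memory" = 0.341,
                                             "Anxiety" = 0.142,
                                             "Paranoia" = 0.133,
                                             "Respiratory problems" = 0.059,
                                             "Others" = 0.121),
                       symptom_probs = c("Anxiety" = 0.60, "Pain" = 0.35,
                                         "Insomnia" = 0.30,
                                         "Depression" = 0.25),
                       seed = 1L) {
  stopifnot(is.character(strains), !is.null(names(strains)),
            length(strains) >= 1L,
            n_lots_per_strain >= 1L, n_respondents >= 1L,
            respondent_noise_sd >= 0, vote_margin >= 0,
            all(c("most", "least", "likert") %in% names(response_rates)))
  missing_arch <- setdiff(unique(unname(strains)), names(archetypes))
  if (length(missing_arch)) {
    stop("no archetype defined for: ",
         paste(sQuote(missing_arch), collapse = ", "), call. = FALSE)
  }
  if (any(strains_tried < 2L)) {
    stop("strains_tried must be >= 2: a respondent must be able to vote ",
         "both a most- and a least-effective strain", call. = FALSE)
  }
  if (any(strains_tried > length(strains))) {
    stop("strains_tried cannot exceed the number of strains", call. = FALSE)
  }
  if (length(effect_weights)) {
    names(effect_weights) <- canonical_analyte(names(effect_weights))
  }
  if (is.null(strain_popularity)) {
    strain_popularity <- stats::setNames(numeric(length(strains)),
                                         names(strains))
  }
  stopifnot(all(names(strains) %in% names(strain_popularity)))
  measured <- setdiff(panel_analytes(), "Total terpenes")
  for (lot in names(lab_masks)) {
    lab_masks[[lot]] <- canonical_analyte(unlist(lab_masks[[lot]]))
    bad <- setdiff(lab_masks[[lot]], measured)
    if (length(bad)) {
      stop("lab mask for lot ", sQuote(lot), " names non-measured analyte: ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
  }
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  structure(list(
    strains = strains, archetypes = archetypes,
    effect_weights = effect_weights,
    n_lots_per_strain = as.integer(n_lots_per_strain),
    n_respondents = as.integer(n_respondents),
    strains_tried = as.integer(strains_tried),
    respondent_noise_sd = respondent_noise_sd,
    vote_margin = vote_margin,
    strain_popularity = strain_popularity,
    lab_masks = lab_masks, lab_names = lab_names,
    response_rates = response_rates,
    likert_intercept = likert_intercept, likert_slope = likert_slope,
    side_effect_probs = side_effect_probs, symptom_probs = symptom_probs,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", length(x$strains), " strains x ",
      x$n_lots_per_strain, " lots, ", x$n_respondents, " respondents\n",
      "  planted non-zero weights: ",
      sum(x$effect_weights != 0), "; noise sd ", x$respondent_noise_sd,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Study-emulating simulation configuration
#'
#' Seven strains in three production lots each (21 lots), with lab masks on
#' two lots for the four terpenes one laboratory does not assay
#' (trans-nerolidol, eucalyptol, gamma-terpinene, alpha-terpinene), 442
#' respondents with category response rates matching the survey the package
#' emulates, and planted weights that make the kush archetype the preferred
#' chemotype.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
study_sim_config <- function(seed = 1L, ...) {
  strains <- c(
    "Bubba Kush"           = "kush",
    "Skywalker OG Kush"    = "kush",
    "Kosher Kush"          = "kush",
    "Blueberry Lambsbread" = "myrcene_dominant",
    "Tangerine Dream"      = "myrcene_dominant",
    "Chocolope"            = "terpinolene_dominant",
    "CBD Shark"            = "type_ii"
  )
  mask4 <- c("trans-Nerolidol", "Eucalyptol", "gamma-Terpinene",
             "alpha-Terpinene")
  ## lots are labelled P001..P0xx in strain order; mask one Kosher Kush lot
  ## and one Chocolope lot (strains 3 and 6 -> lots 9 and 17)
  args <- utils::modifyList(list(
    strains = strains,
    effect_weights = c("delta9-Tetrahydrocannabinol" = 0.1,
                       "trans-Nerolidol" = 2, "Terpinolene" = -3.5,
                       "Guaiol" = -4, "Cannabidiol" = -0.05),
    respondent_noise_sd = 3,
    vote_margin = 0.15,
    likert_intercept = 3.2,
    likert_slope = 1.0,
    lab_masks = list(P009 = mask4, P017 = mask4),
    lab_names = c("Anandia", "MB Labs"),
    seed = seed
  ), list(...))
  do.call(sim_config, args)
}

#' Null-calibration simulation configuration
#'
#' Every strain shares one archetype and every planted effect weight is zero,
#' so the no-chemotype-association null holds exactly. Strains differ only in
#' chemotype-independent popularity offsets, which keeps the most- and
#' least-effective groups stable and (almost always) disjoint -- the regime
#' in which the two-sample test's independence assumption holds and its size
#' can be measured. Eight strains are used so that two disjoint groups of
#' four exist.
#'
#' @param seed Integer seed.
#' @param n_strains Number of strains (`>= 2 * top_k` for disjoint groups).
#' @param popularity_spread Half-range of the popularity offsets.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
null_sim_config <- function(seed = 1L, n_strains = 8L,
                            popularity_spread = 1.6, ...) {
  labels <- sprintf("Strain %02d", seq_len(n_strains))
  strains <- stats::setNames(rep("kush", n_strains), labels)
  pop <- stats::setNames(
    seq(popularity_spread, -popularity_spread, length.out = n_strains),
    labels
  )
  args <- utils::modifyList(list(
    strains = strains, effect_weights = numeric(0),
    strain_popularity = pop, respondent_noise_sd = 1, seed = seed
  ), list(...))
  do.call(sim_config, args)
}

#' Planted-signal simulation configuration
#'
#' Eight strains sharing one base archetype except for a gradient in a single
#' planted analyte, which carries a signed utility weight. All other analytes
#' are identical across strains (null). Used for parameter-recovery
#' experiments: with a strong weight and low respondent noise the preference
#' ranking follows the gradient and the planted analyte's coefficient sign is
#' always recovered.
#'
#' @param analyte Planted analyte (canonicalized).
#' @param weight Planted signed utility weight (utility per % w/w).
#' @param noise_sd Respondent noise standard deviation.
#' @param gradient Concentration range (% w/w) of the planted analyte across
#'   strains.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
signal_sim_config <- function(analyte = "trans-Nerolidol", weight = 12,
                              noise_sd = 0.25,
                              gradient = seq(0.05, 0.75, length.out = 8L),
                              seed = 1L, ...) {
  analyte <- canonical_analyte(analyte)
  n_strains <- length(gradient)
  labels <- sprintf("Strain %02d", seq_len(n_strains))
  base <- default_archetypes()$kush
  archetypes <- lapply(seq_len(n_strains), function(i) {
    prof <- base$mean_profile
    prof[analyte] <- gradient[i]
    chemotype_archetype(sprintf("grad_%02d", i), prof[prof > 0],
                        lot_cv = base$lot_cv)
  })
  names(archetypes) <- sprintf("grad_%02d", seq_len(n_strains))
  args <- utils::modifyList(list(
    strains = stats::setNames(names(archetypes), labels),
    archetypes = archetypes,
    effect_weights = stats::setNames(weight, analyte),
    respondent_noise_sd = noise_sd,
    seed = seed
  ), list(...))
  do.call(sim_config, args)
}

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Ground-truth strain-by-analyte mean concentration matrix.
strain_mean_matrix <- function(config) {
  measured <- setdiff(panel_analytes(), "Total terpenes")
  t(vapply(names(config$strains), function(s) {
    config$archetypes[[config$strains[[s]]]]$mean_profile[measured]
  }, numeric(length(measured))))
}

lot_ids <- function(config) {
  n <- length(config$strains) * config$n_lots_per_strain
  sprintf("P%03d", seq_len(n))
}

#' Generate synthetic production-lot assays
#'
#' Draws each lot's concentration for each measured analyte as the archetype
#' mean times unit-mean multiplicative lognormal noise with the archetype's
#' lot CV (exactly the mean when `lot_cv = 0`), appends the total-terpenes
#' aggregate as the sum of that lot's measured terpenes, and applies the
#' configured lab coverage masks (masked cells are not-tested `NA`, distinct
#' from a measured 0).
#'
#' @param config A [sim_config()].
#' @return An assay table: tibble with columns `strain`, `lot`, `lab`,
#'   `analyte`, `value` (% w/w; `NA` = not tested), one row per lot x panel
#'   analyte, with class `assay_tbl`.
#' @export
generate_lot_assays <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  measured <- setdiff(panel_analytes(), "Total terpenes")
  terpenes <- panel_analytes("terpene")
  strains <- names(config$strains)
  n_lot <- config$n_lots_per_strain
  ids <- lot_ids(config)
  unknown_lots <- setdiff(names(config$lab_masks), ids)
  if (length(unknown_lots)) {
    stop("lab mask names unknown lot(s): ",
         paste(sQuote(unknown_lots), collapse = ", "), call. = FALSE)
  }
  M <- strain_mean_matrix(config)
  with_seed(config$seed, {
    rows <- vector("list", length(ids))
    k <- 0L
    for (si in seq_along(strains)) {
      s <- strains[si]
      cv <- config$archetypes[[config$strains[[s]]]]$lot_cv
      sdlog <- sqrt(log(1 + cv^2))
      for (li in seq_len(n_lot)) {
        k <- k + 1L
        lot <- ids[k]
        noise <- if (cv > 0) {
          stats::rlnorm(length(measured), meanlog = -sdlog^2 / 2,
                        sdlog = sdlog)
        } else rep(1, length(measured))
        value <- unname(M[s, measured]) * noise
        names(value) <- measured
        masked <- config$lab_masks[[lot]]
        lab <- if (is.null(masked)) config$lab_names[1] else
          config$lab_names[2]
        if (!is.null(masked)) value[masked] <- NA_real_
        total <- sum(value[terpenes], na.rm = TRUE)
        rows[[k]] <- tibble::tibble(
          strain = s, lot = lot, lab = lab,
          analyte = c(measured, "Total terpenes"),
          value = c(unname(value), total)
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("assay_tbl", class(out))
    out
  })
}

## Repair one respondent's vote sets after margin voting. A strain within the
## margin of both extremes is dropped from both sets (a respondent never
## votes the same strain in both categories); if a set is thereby emptied it
## falls back to a deterministic alphabetical tie-break (first tried strain
## for most effective, last for least), always keeping the sets disjoint.
repair_vote_sets <- function(tried_strains, most, least) {
  if (!length(most) && !length(least)) {
    s <- sort(tried_strains)
    return(list(most = s[1L], least = s[length(s)]))
  }
  if (!length(most)) {
    pool <- setdiff(sort(tried_strains), least)
    if (length(pool)) most <- pool[1L] else {
      most <- sort(least)[1L]
      least <- setdiff(least, most)
    }
  }
  if (!length(least)) {
    pool <- setdiff(sort(tried_strains), most)
    if (length(pool)) least <- pool[length(pool)] else {
      least <- sort(most)[length(most)]
      most <- setdiff(most, least)
    }
  }
  list(most = most, least = least)
}

#' Generate synthetic survey responses
#'
#' Each respondent tries a random subset of strains, assigns each tried
#' strain a latent utility (see [sim_config()]), votes every tried strain
#' within `vote_margin` of the extremes as most/least effective (with a
#' deterministic alphabetical tie-break when all tried strains are within the
#' margin; a respondent never votes the same strain in both categories), and
#' rates overall effectiveness on a 0--10 Likert scale as an affine function
#' of their best tried utility. Category and rating non-response follow
#' `response_rates`.
#'
#' @param config A [sim_config()].
#' @param assays Assay table from [generate_lot_assays()]; every assayed
#'   strain must be present in the configuration.
#' @return A survey table: tibble with columns `respondent_id`,
#'   `likert_rating` (integer or `NA`), and list-columns `most_effective`,
#'   `least_effective`, `side_effects`, `symptoms`; class `survey_tbl`.
#' @export
generate_survey <- function(config, assays = NULL) {
  stopifnot(inherits(config, "sim_config"))
  strains <- sort(names(config$strains))
  if (!is.null(assays)) {
    extra <- setdiff(unique(assays$strain), names(config$strains))
    if (length(extra)) {
      stop("assays contain strain(s) absent from the configuration: ",
           paste(sQuote(extra), collapse = ", "), call. = FALSE)
    }
  }
  M <- strain_mean_matrix(config)[strains, , drop = FALSE]
  w <- stats::setNames(numeric(ncol(M)), colnames(M))
  if (length(config$effect_weights)) {
    w[names(config$effect_weights)] <- config$effect_weights
  }
  base_util <- drop(M %*% w) + config$strain_popularity[strains]
  n <- config$n_respondents
  S <- length(strains)
  eps <- config$vote_margin
  with_seed(config$seed + 1L, {
    ## length-1 strains_tried means every respondent tried that many
    k <- if (length(config$strains_tried) == 1L) {
      rep(config$strains_tried, n)
    } else {
      sample(config$strains_tried, n, replace = TRUE)
    }
    ## tried mask: the k[i] lowest random keys per row
    key <- matrix(stats::runif(n * S), n, S)
    thresh <- vapply(seq_len(n), function(i) sort(key[i, ])[k[i]],
                     numeric(1))
    tried <- key <= thresh
    U <- matrix(rep(base_util, each = n), n, S,
                dimnames = list(NULL, strains))
    if (config$respondent_noise_sd > 0) {
      U <- U + matrix(stats::rnorm(n * S, sd = config$respondent_noise_sd),
                      n, S)
    }
    U[!tried] <- NA_real_
    umax <- do.call(pmax, c(as.data.frame(U), na.rm = TRUE))
    umin <- do.call(pmin, c(as.data.frame(U), na.rm = TRUE))
    most_m <- !is.na(U) & U >= umax - eps
    least_m <- !is.na(U) & U <= umin + eps
    clash <- most_m & least_m
    most_m[clash] <- FALSE
    least_m[clash] <- FALSE
    ans_most <- stats::runif(n) < config$response_rates[["most"]]
    ans_least <- stats::runif(n) < config$response_rates[["least"]]
    ans_likert <- stats::runif(n) < config$response_rates[["likert"]]
    most <- vector("list", n)
    least <- vector("list", n)
    for (i in seq_len(n)) {
      if (ans_most[i] || ans_least[i]) {
        v <- repair_vote_sets(strains[tried[i, ]],
                              strains[most_m[i, ]],
                              strains[least_m[i, ]])
        most[[i]] <- if (ans_most[i]) v$most else character(0)
        least[[i]] <- if (ans_least[i]) v$least else character(0)
      } else {
        most[[i]] <- character(0)
        least[[i]] <- character(0)
      }
    }
    rating <- as.integer(pmin(10, pmax(0, round(
      config$likert_intercept + config$likert_slope * umax
    ))))
    rating[!ans_likert] <- NA_integer_
    draw_sets <- function(probs) {
      flags <- matrix(stats::runif(n * length(probs)), n) <
        matrix(rep(probs, each = n), n)
      lapply(seq_len(n), function(i) names(probs)[flags[i, ]])
    }
    out <- tibble::tibble(
      respondent_id = sprintf("R%04d", seq_len(n)),
      likert_rating = rating,
      most_effective = most,
      least_effective = least,
      side_effects = draw_sets(config$side_effect_probs),
      symptoms = draw_sets(config$symptom_probs)
    )
    class(out) <- c("survey_tbl", class(out))
    out
  })
}
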