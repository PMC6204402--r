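#' The canonical analyte panel
#'
#' The packaged analytical panel: four cannabinoids reported as total
#' potential (acid + neutral forms), thirty terpenes quantified by GC-MS,
#' and a total-terpenes aggregate. All concentrations throughout the package
#' are percent of dry weight (% w/w).
#'
#' @return A tibble with columns `analyte` (canonical name) and `class`
#'   (`"cannabinoid"`, `"terpene"` or `"aggregate"`), in panel (report) order.
#' @export
#' @examples
#' analyte_panel()
analyte_panel <- function() {
  tibble::tibble(
    analyte = c(
      "delta9-Tetrahydrocannabinol", "Cannabidiol", "Cannabigerol",
      "Cannabichromene", "Total terpenes",
      "alpha-Pinene", "Camphene", "Sabinene", "beta-Pinene", "Myrcene",
      "alpha-Phellandrene", "3-Carene", "D-Limonene", "Eucalyptol",
      "beta-Ocimene", "Terpinolene", "alpha-Terpinene", "gamma-Terpinene",
      "Sabinene hydrate", "Fenchone", "Linalool", "Fenchol", "Borneol",
      "alpha-Terpineol", "Geraniol", "gamma-Terpineol", "Nerol",
      "beta-Caryophyllene", "Caryophyllene oxide", "Humulene", "Valencene",
      "trans-Nerolidol", "Cedrol", "Guaiol", "alpha-Bisabolol"
    ),
    class = c(
      rep("cannabinoid", 4L), "aggregate", rep("terpene", 30L)
    )
  )
}

#' @keywords internal
panel_analytes <- function(class = NULL) {
  p <- analyte_panel()
  if (!is.null(class)) p <- p[p$class %in% class, ]
  p$analyte
}

## Lower-cased, punctuation-normalised key used for alias lookup.
normalize_analyte_key <- function(x) {
  x <- trimws(x)
  ## Greek letters and typographic dashes as they appear in lab reports
  x <- gsub("\u03b1", "alpha-", x)
  x <- gsub("\u03b2", "beta-", x)
  x <- gsub("\u03b3", "gamma-", x)
  x <- gsub("[\u0394\u03b4]", "delta", x)
  x <- gsub("[\u2010\u2011\u2012\u2013\u2014]", "-", x)
  x <- tolower(x)
  x <- gsub("-+", "-", gsub("\\s+", " ", x))
  x <- gsub(" ?- ?", "-", x)
  ## single-letter Greek abbreviations ("a-Terpinene" style)
  x <- sub("^a-", "alpha-", x)
  x <- sub("^b-", "beta-", x)
  x <- sub("^y-", "gamma-", x)
  x
}

analyte_alias_table <- function() {
  canon <- panel_analytes()
  key <- normalize_analyte_key(canon)
  extra <- c(
    "thc"                  = "delta9-Tetrahydrocannabinol",
    "delta9-thc"           = "delta9-Tetrahydrocannabinol",
    "delta-9-thc"          = "delta9-Tetrahydrocannabinol",
    "delta-9-tetrahydrocannabinol" = "delta9-Tetrahydrocannabinol",
    "d9-thc"               = "delta9-Tetrahydrocannabinol",
    "cbd"                  = "Cannabidiol",
    "cbg"                  = "Cannabigerol",
    "cbc"                  = "Cannabichromene",
    "total terpene"        = "Total terpenes",
    "limonene"             = "D-Limonene",
    "d-limonene"           = "D-Limonene",
    "alpha-humulene"       = "Humulene",
    "beta-myrcene"         = "Myrcene",
    "cis-sabinene hydrate" = "Sabinene hydrate",
    "1,8-cineole"          = "Eucalyptol",
    "nerolidol"            = "trans-Nerolidol"
  )
  stats::setNames(c(canon, unname(extra)), c(key, names(extra)))
}

#' Canonicalize analyte names against the packaged panel
#'
#' Maps spelling variants (Greek letters vs. single-letter abbreviations,
#' dash variants, common synonyms, case) onto the canonical panel names.
#'
#' @param x Character vector of analyte names.
#' @param error_on_unknown Error (default) or return `NA` for names that do
#'   not resolve to a panel analyte.
#' @return Character vector of canonical analyte names.
#' @export
#' @examples
#' canonical_analyte(c("THC", "a-Terpinene", "b-Caryophyllene"))
canonical_analyte <- function(x, error_on_unknown = TRUE) {
  tab <- analyte_alias_table()
  out <- unname(tab[normalize_analyte_key(x)])
  if (error_on_unknown && anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown analyte name(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}
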