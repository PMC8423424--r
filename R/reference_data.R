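# Published reference values from a large-scale national UK
# heart-failure EHR-to-CDM conversion, used as inputs to the accounting
# checks: the full-scale results themselves depend on licensed source
# data and the licensed standard vocabulary, but the concordance
# accounting identities are exactly recomputable from the printed
# numbers.

#' Published comorbidity concordance reference rows
#'
#' Six comorbidity rows (atrial fibrillation, COPD, type 2 diabetes,
#' acute myocardial infarction, hypertension, cancer) as printed by a
#' published national heart-failure EHR-to-CDM conversion: original and
#' CDM patient counts with their percentage cells, plus unmapped
#' (source-only) and incorrectly mapped (CDM-only) patient counts. The
#' percentage columns are kept as printed strings so their precision is
#' preserved.
#'
#' @return data.frame with count columns (integer) and percentage
#'   columns (character, as printed).
#' @export
reference_concordance <- function() {
  path <- system.file("extdata", "reference_hf_concordance.csv",
                      package = "omopetl", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(
    phenotype = "character", original_n = "integer",
    original_pct = "character", cdm_n = "integer", cdm_pct = "character",
    unmapped_n = "integer", unmapped_pct = "character",
    incorrect_n = "integer", incorrect_pct = "character"))
}

#' Published cohort and visit totals
#'
#' Named vector of the reference conversion's cohort accounting inputs:
#' original cohort size, patients rejected for inconsistent observation
#' periods, resulting CDM cohort size, and the primary-care, hospital
#' and total visit-occurrence counts.
#'
#' @return named numeric vector.
#' @export
reference_cohort_counts <- function() {
  path <- system.file("extdata", "reference_hf_cohort.csv",
                      package = "omopetl", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c("character", "numeric"))
  stats::setNames(df$value, df$quantity)
}
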