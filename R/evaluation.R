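# Source-versus-CDM evaluation: terminology coverage assembly, cohort
# concordance accounting, clinical-covariate comparison, and headline
# difference metrics.

#' Prevalence percentage at a fixed precision
#'
#' `100 * count / denominator`, rounded half-even (banker's rounding) to
#' `digits` decimals. A zero denominator yields `NA` with the
#' `degenerate` attribute set.
#'
#' @param count numerator.
#' @param denominator denominator.
#' @param digits decimals (default 2).
#' @return numeric percentage.
#' @export
prevalence_pct <- function(count, denominator, digits = 2L) {
  if (any(denominator == 0)) {
    out <- rep(NA_real_, length(count))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  round(100 * count / denominator, digits)
}

#' Concordance accounting between source and CDM patient sets
#'
#' Unmapped patients are source-only members (original set minus CDM
#' set); incorrectly mapped patients are CDM-only members (CDM set minus
#' original set), typically created by many-to-one code-to-concept
#' collapse. The accounting identity
#' `cdm = original - unmapped + incorrect` is asserted, never assumed.
#' Membership percentages use the respective cohort denominators; the
#' unmapped and incorrectly-mapped percentages use the phenotype's own
#' original and CDM counts as denominators.
#'
#' @param name phenotype name.
#' @param source_ids patient ids found in the raw representation.
#' @param cdm_ids patient ids found in the CDM representation.
#' @param denom_original original cohort size.
#' @param denom_cdm CDM cohort size.
#' @param digits decimals for the membership percentages.
#' @param diff_digits decimals for the difference percentages.
#' @return one-row data.frame of class `concordance_row`.
#' @export
concordance <- function(name, source_ids, cdm_ids, denom_original,
                        denom_cdm, digits = 2L, diff_digits = 2L) {
  source_ids <- unique(source_ids)
  cdm_ids <- unique(cdm_ids)
  original_n <- length(source_ids)
  cdm_n <- length(cdm_ids)
  unmapped_n <- length(setdiff(source_ids, cdm_ids))
  incorrect_n <- length(setdiff(cdm_ids, source_ids))
  stopifnot(cdm_n == original_n - unmapped_n + incorrect_n)
  degenerate <- denom_original == 0 || denom_cdm == 0
  out <- data.frame(
    phenotype = name,
    original_n = original_n,
    original_pct = prevalence_pct(original_n, denom_original, digits),
    cdm_n = cdm_n,
    cdm_pct = prevalence_pct(cdm_n, denom_cdm, digits),
    unmapped_n = unmapped_n,
    unmapped_pct = if (original_n > 0)
      prevalence_pct(unmapped_n, original_n, diff_digits) else 0,
    incorrect_n = incorrect_n,
    incorrect_pct = if (cdm_n > 0)
      prevalence_pct(incorrect_n, cdm_n, diff_digits) else 0,
    degenerate = degenerate,
    stringsAsFactors = FALSE)
  class(out) <- c("concordance_row", class(out))
  out
}

#' Largest absolute prevalence difference across concordance rows
#'
#' @param rows data.frame with columns `phenotype`, `original_pct`,
#'   `cdm_pct` (e.g. rbind-ed `concordance_row`s).
#' @return list with `value` (max `|cdm_pct - original_pct|`) and
#'   `phenotype`; ties broken alphabetically.
#' @export
max_prevalence_gap <- function(rows) {
  if (!nrow(rows)) stop("no concordance rows", call. = FALSE)
  gap <- abs(rows$cdm_pct - rows$original_pct)
  rows <- rows[order(-gap, rows$phenotype), , drop = FALSE]
  list(value = abs(rows$cdm_pct[1] - rows$original_pct[1]),
       phenotype = rows$phenotype[1])
}

coverage_events_from_run <- function(bundle, cdm, vocabulary) {
  excl <- cdm$exclusions
  excl_key <- paste(excl$source_table, excl$row_id, excl$source_slot,
                    sep = "\r")
  non_mapping <- excl[excl$reason != "unmapped-code", , drop = FALSE]
  nm_key <- paste(non_mapping$source_table, non_mapping$row_id,
                  non_mapping$source_slot, sep = "\r")
  ev <- switch(vocabulary,
    READ = data.frame(code = bundle$clinical$code,
                      key = paste("clinical", bundle$clinical$row_id, 0L,
                                  sep = "\r"), stringsAsFactors = FALSE),
    GEMSCRIPT = data.frame(code = bundle$therapy$drug_code,
                           key = paste("therapy", bundle$therapy$row_id, 0L,
                                       sep = "\r"), stringsAsFactors = FALSE),
    ICD10 = {
      he <- hospital_slot_events(bundle$hospital, 1:20, "diag")
      de <- death_slot_events(bundle$death)
      data.frame(code = c(he$code, de$code),
                 key = c(paste("hospital", he$row_id, he$slot, sep = "\r"),
                         paste("death", de$row_id, de$slot, sep = "\r")),
                 stringsAsFactors = FALSE)
    },
    OPCS4 = {
      pe <- hospital_slot_events(bundle$hospital, 1:4, "proc")
      data.frame(code = pe$code,
                 key = paste("hospital", pe$row_id, pe$slot + 20L,
                             sep = "\r"), stringsAsFactors = FALSE)
    },
    stop("no event extractor for vocabulary ", vocabulary, call. = FALSE))
  ev$excluded <- ev$key %in% nm_key
  ev[, c("code", "excluded")]
}

#' Assemble terminology coverage rows for an ETL run
#'
#' One [coverage()] row per source terminology, with events classified
#' as excluded when they were dropped for non-mapping reasons (missing
#' dates, rejected patients, value-not-entered).
#'
#' @param bundle the `source_bundle`.
#' @param cdm the `cdm_bundle` produced from it.
#' @param vocab the [vocabulary_store].
#' @return data.frame, one coverage row per terminology.
#' @export
coverage_report <- function(bundle, cdm, vocab) {
  rows <- list(
    coverage(coverage_events_from_run(bundle, cdm, "READ"), vocab, "READ"),
    coverage(coverage_events_from_run(bundle, cdm, "ICD10"), vocab, "ICD10"),
    coverage(coverage_events_from_run(bundle, cdm, "OPCS4"), vocab, "OPCS4"),
    coverage(coverage_events_from_run(bundle, cdm, "GEMSCRIPT"), vocab,
             "GEMSCRIPT", resolver = "drug-chain"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pct1 <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)

#' Compare the raw and CDM representations end to end
#'
#' Builds the full comparison report: cohort sizes under both
#' representations, demographic rows (% female, % majority ethnic group,
#' % most-deprived fifth), lifestyle rows, paired biomarker summaries,
#' medication exposure rows, per-phenotype concordance rows, terminology
#' coverage, and the headline maximum absolute prevalence difference.
#'
#' @param bundle the `source_bundle`.
#' @param cdm the `cdm_bundle`.
#' @param vocab the [vocabulary_store].
#' @param definitions named list of [phenotype_definition]s (will be
#'   translated as needed).
#' @param rules [cohort_rules] for the disease cohort.
#' @param cohort_phenotype name of the cohort-defining phenotype
#'   (default `"hf"`).
#' @return list of class `comparison_report`.
#' @export
assemble_reports <- function(bundle, cdm, vocab, definitions,
                             rules = cohort_rules(),
                             cohort_phenotype = "hf") {
  definitions <- lapply(definitions, function(d) {
    if (is.null(d$concept_set)) translate_codelist(d, vocab) else d
  })
  study_end <- cdm$meta$study_end
  op_src <- build_observation_period(bundle, study_end)
  periods_src <- op_src$periods
  periods_cdm <- data.frame(
    patient_id = cdm$observation_period$person_id,
    start = cdm$observation_period$observation_period_start_date,
    end = cdm$observation_period$observation_period_end_date,
    stringsAsFactors = FALSE)
  yob_src <- data.frame(patient_id = bundle$patient$patient_id,
                        year_of_birth = bundle$patient$year_of_birth)
  yob_cdm <- data.frame(patient_id = cdm$person$person_id,
                        year_of_birth = cdm$person$year_of_birth)

  hf_def <- definitions[[cohort_phenotype]]
  hf_src <- find_patients_source(hf_def, bundle)
  hf_cdm <- find_patients_cdm(hf_def, cdm)
  cohort_src <- build_hf_cohort(hf_src, periods_src, yob_src, rules)
  cohort_cdm <- build_hf_cohort(hf_cdm, periods_cdm, yob_cdm, rules)
  inc_src <- cohort_src[cohort_src$included, , drop = FALSE]
  inc_cdm <- cohort_cdm[cohort_cdm$included, , drop = FALSE]
  n_src <- nrow(inc_src); n_cdm <- nrow(inc_cdm)

  demo <- function(ids, pat, eth_col) {
    sub <- pat[pat[[1L]] %in% ids, , drop = FALSE]
    known <- !is.na(sub[[eth_col]]) & sub[[eth_col]] != ""
    list(female = pct1(sum(sub$sex == "F"), nrow(sub)),
         majority_ethnicity = pct1(sum(known & sub[[eth_col]] == "E1"),
                                   sum(known)))
  }
  pat_src <- bundle$patient[, c("patient_id", "sex", "ethnicity_code")]
  pat_cdm <- data.frame(patient_id = cdm$person$person_id,
                        sex = cdm$person$gender_source_value,
                        ethnicity_code = cdm$person$ethnicity_source_value,
                        stringsAsFactors = FALSE)
  demo_src <- demo(inc_src$patient_id, pat_src, "ethnicity_code")
  demo_cdm <- demo(inc_cdm$patient_id, pat_cdm, "ethnicity_code")
  depr <- function(ids, dth) {
    sub <- dth[dth$patient_id %in% ids, , drop = FALSE]
    pct1(sum(sub$deprivation_quintile == 5L, na.rm = TRUE), nrow(sub))
  }
  dq_cdm_tbl <- bundle$death[bundle$death$patient_id %in%
                               cdm$person$person_id, , drop = FALSE]
  demographics <- data.frame(
    row = c("female_pct", "majority_ethnicity_pct", "most_deprived_fifth_pct"),
    original = c(demo_src$female, demo_src$majority_ethnicity,
                 depr(inc_src$patient_id, bundle$death)),
    cdm = c(demo_cdm$female, demo_cdm$majority_ethnicity,
            depr(inc_cdm$patient_id, dq_cdm_tbl)),
    stringsAsFactors = FALSE)

  lifestyle <- do.call(rbind, lapply(
    intersect(LIFESTYLE_PHENOTYPES, names(definitions)), function(p) {
      d <- definitions[[p]]
      data.frame(row = p,
                 original = lifestyle_flag(d, bundle, cohort_src)$pct,
                 cdm = lifestyle_flag(d, cdm, cohort_cdm, vocab)$pct,
                 stringsAsFactors = FALSE)
    }))

  biomarker_names <- names(Filter(function(d) d$kind == "biomarker",
                                  definitions))
  biomarkers <- do.call(rbind, lapply(biomarker_names, function(p) {
    d <- definitions[[p]]
    s <- summarize_biomarker(find_patients_source(d, bundle), cohort_src)
    c_ <- summarize_biomarker(find_patients_cdm(d, cdm), cohort_cdm)
    data.frame(row = p,
               original_median = s$median, cdm_median = c_$median,
               original_iqr = s$iqr, cdm_iqr = c_$iqr,
               original_mean = s$mean, cdm_mean = c_$mean,
               original_sd = s$sd, cdm_sd = c_$sd,
               original_nvals = s$n, cdm_nvals = c_$n,
               stringsAsFactors = FALSE)
  }))

  med_names <- names(Filter(function(d) d$kind == "medication-class",
                            definitions))
  medications <- do.call(rbind, lapply(med_names, function(p) {
    d <- definitions[[p]]
    data.frame(row = p,
               original = medication_flag(find_patients_source(d, bundle),
                                          cohort_src),
               cdm = medication_flag(find_patients_cdm(d, cdm), cohort_cdm),
               stringsAsFactors = FALSE)
  }))

  cond_names <- setdiff(names(Filter(function(d) d$kind == "condition",
                                     definitions)), cohort_phenotype)
  conc <- do.call(rbind, lapply(cond_names, function(p) {
    d <- definitions[[p]]
    src <- intersect(find_patients_source(d, bundle)$patients,
                     inc_src$patient_id)
    cdm_ids <- intersect(find_patients_cdm(d, cdm)$patients,
                         inc_cdm$patient_id)
    concordance(p, src, cdm_ids, n_src, n_cdm)
  }))
  gap <- if (!is.null(conc) && nrow(conc)) max_prevalence_gap(conc) else
    list(value = NA_real_, phenotype = NA_character_)

  structure(list(
    cohort = list(original_n = n_src, cdm_n = n_cdm,
                  rejected_patients = length(cdm$meta$rejected_patients)),
    demographics = demographics, lifestyle = lifestyle,
    biomarkers = biomarkers, medications = medications,
    concordance = conc, coverage = coverage_report(bundle, cdm, vocab),
    max_prevalence_gap = gap), class = "comparison_report")
}

report_to_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

render_md_table <- function(df) {
  if (is.null(df) || !nrow(df)) return("_(empty)_")
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, format = "g", digits = 6) else
      as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "),
                                              " |"))
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (machine readable) and `report.md` (tables
#' mirroring the coverage / cohort-comparison / concordance layout).
#'
#' @param report a `comparison_report`.
#' @param dir output directory (created if absent).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report_to_json(report, file.path(dir, "report.json"))
  md <- c(
    "# Source vs CDM comparison report", "",
    sprintf("Cohort: original n = %d, CDM n = %d, rejected patients = %d",
            report$cohort$original_n, report$cohort$cdm_n,
            report$cohort$rejected_patients), "",
    "## Terminology coverage", render_md_table(report$coverage), "",
    "## Demographics", render_md_table(report$demographics), "",
    "## Lifestyle", render_md_table(report$lifestyle), "",
    "## Biomarkers", render_md_table(report$biomarkers), "",
    "## Medications", render_md_table(report$medications), "",
    "## Comorbidity concordance", render_md_table(report$concordance), "",
    sprintf("Largest absolute prevalence difference: %.2f (%s)",
            report$max_prevalence_gap$value,
            report$max_prevalence_gap$phenotype), "")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
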