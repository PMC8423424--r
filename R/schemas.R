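SEMANTIC_TYPES <- c("id", "date", "code", "integer", "real", "text", "quintile")

#' Define a table schema
#'
#' A schema names a table and types its columns. Semantic types are
#' `id` (integer identifier), `date` (ISO-8601 calendar date), `code`
#' (terminology code, character), `integer`, `real`, `text`, and
#' `quintile` (integer 1-5, used for deprivation fifths).
#'
#' @param name table name.
#' @param columns data.frame with columns `name`, `type`, `nullable`.
#' @param primary_key optional column name whose values must be unique
#'   and non-missing.
#' @return an object of class `table_schema`.
#' @export
table_schema <- function(name, columns, primary_key = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.data.frame(columns),
            all(c("name", "type", "nullable") %in% names(columns)))
  if (anyDuplicated(columns$name)) {
    stop("schema '", name, "': duplicate column names", call. = FALSE)
  }
  bad <- setdiff(columns$type, SEMANTIC_TYPES)
  if (length(bad)) {
    stop("schema '", name, "': unknown semantic type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!any(columns$type == "id")) {
    stop("schema '", name, "': at least one id column is required",
         call. = FALSE)
  }
  if (!is.null(primary_key) && !primary_key %in% columns$name) {
    stop("schema '", name, "': primary key '", primary_key,
         "' is not a column", call. = FALSE)
  }
  structure(list(name = name, columns = columns, primary_key = primary_key),
            class = "table_schema")
}

col_spec <- function(...) {
  x <- list(...)
  data.frame(name = vapply(x, `[[`, "", 1L),
             type = vapply(x, `[[`, "", 2L),
             nullable = vapply(x, function(ci) isTRUE(ci[[3]]), TRUE),
             stringsAsFactors = FALSE)
}
cl <- function(name, type, nullable = FALSE) list(name, type, nullable)

hospital_diag_cols <- function() {
  lapply(sprintf("diag_%02d", 1:20), function(nm) cl(nm, "code", TRUE))
}
hospital_proc_cols <- function() {
  lapply(sprintf("proc_%02d", 1:4), function(nm) cl(nm, "code", TRUE))
}
entity_value_cols <- function() {
  lapply(sprintf("value_%d", 1:8), function(nm) cl(nm, "text", TRUE))
}
death_cause_cols <- function() {
  lapply(sprintf("cause_%02d", 2:15), function(nm) cl(nm, "code", TRUE))
}

#' Schemas of the source bundle, vocabulary bundle and CDM subset
#'
#' Returns the full named list of [table_schema] objects used by the
#' package: the nine source tables of a linked primary-care /
#' hospitalisation / mortality extract, the four vocabulary files, and
#' the populated CDM-subset tables plus the exclusion and code-mapping
#' ledgers.
#'
#' @return named list of `table_schema` objects.
#' @export
bundle_schemas <- function() {
  s <- list()

  s$patient <- table_schema("patient", do.call(col_spec, list(
    cl("patient_id", "id"), cl("sex", "code"),
    cl("year_of_birth", "integer"), cl("ethnicity_code", "code", TRUE),
    cl("registration_date", "date", TRUE),
    cl("transfer_out_date", "date", TRUE),
    cl("practice_id", "id"), cl("death_date", "date", TRUE))),
    primary_key = "patient_id")

  s$practice <- table_schema("practice", do.call(col_spec, list(
    cl("practice_id", "id"), cl("up_to_standard_date", "date"),
    cl("last_collection_date", "date"))), primary_key = "practice_id")

  s$consultation <- table_schema("consultation", do.call(col_spec, list(
    cl("consultation_id", "id"), cl("patient_id", "id"),
    cl("event_date", "date", TRUE))), primary_key = "consultation_id")

  s$clinical <- table_schema("clinical", do.call(col_spec, list(
    cl("row_id", "id"), cl("patient_id", "id"),
    cl("consultation_id", "id", TRUE), cl("event_date", "date", TRUE),
    cl("code", "code"))), primary_key = "row_id")

  s$therapy <- table_schema("therapy", do.call(col_spec, list(
    cl("row_id", "id"), cl("patient_id", "id"),
    cl("consultation_id", "id", TRUE), cl("event_date", "date", TRUE),
    cl("drug_code", "code"))), primary_key = "row_id")

  entity_cols <- c(list(
    cl("row_id", "id"), cl("patient_id", "id"), cl("event_date", "date", TRUE),
    cl("entity_type_id", "integer")), entity_value_cols(),
    list(cl("unit_code", "code", TRUE)))
  s$test <- table_schema("test", do.call(col_spec, entity_cols),
                         primary_key = "row_id")
  s$additional <- table_schema("additional", do.call(col_spec, entity_cols),
                               primary_key = "row_id")

  s$hospital <- table_schema("hospital", do.call(col_spec, c(list(
    cl("spell_id", "id"), cl("patient_id", "id"),
    cl("admission_date", "date", TRUE)),
    hospital_diag_cols(), hospital_proc_cols(),
    list(cl("ethnicity_code", "code", TRUE)))), primary_key = "spell_id")

  s$death <- table_schema("death", do.call(col_spec, c(list(
    cl("patient_id", "id"), cl("death_date", "date"),
    cl("cause_01", "code")), death_cause_cols(),
    list(cl("deprivation_quintile", "quintile")))),
    primary_key = "patient_id")

  # vocabulary bundle
  s$concept <- table_schema("concept", do.call(col_spec, list(
    cl("concept_id", "id"), cl("code", "code"),
    cl("vocabulary_name", "text"), cl("domain", "text", TRUE),
    cl("standard", "integer"))), primary_key = "concept_id")

  s$mapping_edge <- table_schema("mapping_edge", do.call(col_spec, list(
    cl("edge_id", "id"), cl("source_code", "code"),
    cl("source_vocabulary", "text"), cl("target_concept_id", "integer"),
    cl("relationship", "text"))), primary_key = "edge_id")

  s$entity_field_map <- table_schema("entity_field_map", do.call(col_spec, list(
    cl("map_id", "id"), cl("entity_type_id", "integer"),
    cl("field_index", "integer"), cl("target_concept_id", "integer", TRUE),
    cl("value_semantics", "text"))), primary_key = "map_id")

  s$unit_map <- table_schema("unit_map", do.call(col_spec, list(
    cl("unit_id", "id"), cl("unit_code", "code"),
    cl("target_concept_id", "integer"))), primary_key = "unit_id")

  # CDM subset
  s$person <- table_schema("person", do.call(col_spec, list(
    cl("person_id", "id"), cl("gender_source_value", "code"),
    cl("year_of_birth", "integer"),
    cl("ethnicity_source_value", "code", TRUE))), primary_key = "person_id")

  s$observation_period <- table_schema("observation_period", do.call(col_spec, list(
    cl("person_id", "id"), cl("observation_period_start_date", "date"),
    cl("observation_period_end_date", "date"))), primary_key = "person_id")

  s$visit_occurrence <- table_schema("visit_occurrence", do.call(col_spec, list(
    cl("visit_occurrence_id", "id"), cl("person_id", "id"),
    cl("visit_start_date", "date"), cl("visit_end_date", "date"),
    cl("visit_source", "text"), cl("source_encounter_id", "integer"))),
    primary_key = "visit_occurrence_id")

  event_cols <- function(extra = list()) {
    do.call(col_spec, c(list(
      cl("event_id", "id"), cl("person_id", "id"),
      cl("concept_id", "integer"), cl("event_date", "date"),
      cl("visit_occurrence_id", "integer", TRUE),
      cl("invalid_visit", "integer")), extra, list(
      cl("source_table", "text"), cl("source_row_id", "integer"),
      cl("source_slot", "integer"), cl("source_code", "code"),
      cl("source_vocabulary", "text"))))
  }
  s$condition_occurrence <- table_schema("condition_occurrence", event_cols(),
                                         primary_key = "event_id")
  s$procedure_occurrence <- table_schema("procedure_occurrence", event_cols(),
                                         primary_key = "event_id")
  s$observation <- table_schema("observation", event_cols(),
                                primary_key = "event_id")
  s$drug_exposure <- table_schema("drug_exposure", event_cols(list(
    cl("drug_exposure_end_date", "date"))), primary_key = "event_id")
  s$measurement <- table_schema("measurement", event_cols(list(
    cl("value_as_number", "real", TRUE),
    cl("unit_concept_id", "integer", TRUE))), primary_key = "event_id")

  s$cdm_death <- table_schema("death", event_cols(list(
    cl("cause_rank", "integer"))), primary_key = "event_id")

  s$drug_era <- table_schema("drug_era", do.call(col_spec, list(
    cl("era_id", "id"), cl("person_id", "id"),
    cl("drug_concept_id", "integer"), cl("drug_era_start_date", "date"),
    cl("drug_era_end_date", "date"), cl("drug_exposure_count", "integer"))),
    primary_key = "era_id")

  s$exclusions <- table_schema("exclusions", do.call(col_spec, list(
    cl("exclusion_id", "id"), cl("source_table", "text"),
    cl("row_id", "integer"), cl("source_slot", "integer"),
    cl("reason", "text"))), primary_key = "exclusion_id")

  s$code_mappings <- table_schema("code_mappings", do.call(col_spec, list(
    cl("mapping_id", "id"), cl("source_code", "code"),
    cl("source_vocabulary", "text"),
    cl("target_concept_id", "integer", TRUE))), primary_key = "mapping_id")

  s
}

EXCLUSION_REASONS <- c("missing-date", "rejected-patient",
                       "inconsistent-observation-period", "unmapped-code",
                       "zero-value-entity")
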