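# Code-list phenotyping, executable against BOTH the raw source bundle
# and the transformed CDM bundle. A phenotype is a set of per-terminology
# code lists plus the sources it draws on; translation through the
# vocabulary yields the concept set used on the CDM side (where
# many-to-one code->concept collapse can enlarge the captured
# population).

#' Define a phenotype
#'
#' @param name phenotype name.
#' @param kind one of `condition`, `medication-class`, `biomarker`,
#'   `lifestyle`.
#' @param sources subset of `primary-care`, `hospital`, `death`.
#' @param codelists named list of character code vectors, one per
#'   terminology (e.g. `list(READ = ..., ICD10 = ...)`).
#' @param entity_fields for biomarkers: data.frame of
#'   (entity_type_id, field_index) slots carrying the value.
#' @param status_universe for lifestyle phenotypes: all codes of the
#'   status group, used by the last-known-status rule.
#' @return object of class `phenotype_definition`.
#' @export
phenotype_definition <- function(name, kind, sources, codelists = list(),
                                 entity_fields = NULL,
                                 status_universe = NULL) {
  kind <- match.arg(kind, c("condition", "medication-class", "biomarker",
                            "lifestyle"))
  sources <- match.arg(sources, c("primary-care", "hospital", "death"),
                       several.ok = TRUE)
  if (kind != "biomarker" && !any(lengths(codelists) > 0)) {
    stop("phenotype '", name, "': at least one non-empty code list required",
         call. = FALSE)
  }
  structure(list(name = name, kind = kind, sources = sources,
                 codelists = codelists, entity_fields = entity_fields,
                 status_universe = status_universe,
                 concept_set = NULL, unmapped_codes = NULL),
            class = "phenotype_definition")
}

#' Translate a phenotype's code lists into a concept set
#'
#' Union of [resolve()] (or the two-hop drug chain for medication
#' classes, the entity-field map for biomarkers) over all codes;
#' duplicate targets collapse, which is where a list of k source codes
#' can shrink to fewer unique concepts. Codes with no mapping are
#' reported, and a phenotype whose whole list fails to translate is
#' flagged untranslatable.
#'
#' @param defn a [phenotype_definition].
#' @param vocab a [vocabulary_store].
#' @return the definition with `concept_set` (sorted unique concept ids),
#'   `unmapped_codes` (data.frame code, vocabulary) and `untranslatable`
#'   filled in.
#' @export
translate_codelist <- function(defn, vocab) {
  stopifnot(inherits(defn, "phenotype_definition"))
  concepts <- integer()
  unmapped <- data.frame(code = character(), vocabulary = character(),
                         stringsAsFactors = FALSE)
  if (defn$kind == "biomarker") {
    ef <- defn$entity_fields
    for (r in seq_len(nrow(ef))) {
      m <- vocab$entity_field_map
      hit <- m$target_concept_id[m$entity_type_id == ef$entity_type_id[r] &
                                   m$field_index == ef$field_index[r]]
      hit <- hit[!is.na(hit)]
      if (length(hit)) concepts <- c(concepts, hit) else
        unmapped <- rbind(unmapped, data.frame(
          code = paste0(ef$entity_type_id[r], ":", ef$field_index[r]),
          vocabulary = "ENTITY", stringsAsFactors = FALSE))
    }
  } else if (defn$kind == "medication-class") {
    codes <- defn$codelists$GEMSCRIPT
    res <- resolve_drug(vocab, codes)
    concepts <- c(concepts, res[!is.na(res)])
    if (anyNA(res)) unmapped <- rbind(unmapped, data.frame(
      code = codes[is.na(res)], vocabulary = "GEMSCRIPT",
      stringsAsFactors = FALSE))
  } else {
    for (v in names(defn$codelists)) {
      codes <- defn$codelists[[v]]
      if (!length(codes)) next
      res <- resolve_many(vocab, codes, v)
      concepts <- c(concepts, unlist(res))
      miss <- lengths(res) == 0L
      if (any(miss)) unmapped <- rbind(unmapped, data.frame(
        code = codes[miss], vocabulary = v, stringsAsFactors = FALSE))
    }
  }
  defn$concept_set <- sort(unique(as.integer(concepts)))
  defn$unmapped_codes <- unmapped
  defn$untranslatable <- length(defn$concept_set) == 0L
  defn
}

new_phenotype_result <- function(name, dates, values = NULL) {
  dates <- dates[!is.na(dates$patient_id), , drop = FALSE]
  patients <- sort(unique(dates$patient_id))
  dated <- dates[!is.na(dates$date), , drop = FALSE]
  first_date <- if (nrow(dated)) {
    agg <- stats::aggregate(date ~ patient_id, data = dated, FUN = min)
    agg[order(agg$patient_id), , drop = FALSE]
  } else {
    data.frame(patient_id = integer(),
               date = as.Date(character()), stringsAsFactors = FALSE)
  }
  structure(list(name = name, patients = patients, dates = dates,
                 first_date = first_date, values = values),
            class = "phenotype_result")
}

hospital_slot_events <- function(hospital, slots, prefix) {
  out <- lapply(slots, function(i) {
    col <- hospital[[sprintf("%s_%02d", prefix, i)]]
    keep <- !is.na(col) & col != ""
    data.frame(patient_id = hospital$patient_id[keep],
               date = hospital$admission_date[keep], code = col[keep],
               row_id = hospital$spell_id[keep], slot = rep(i, sum(keep)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

death_slot_events <- function(death) {
  out <- lapply(1:15, function(i) {
    col <- death[[sprintf("cause_%02d", i)]]
    keep <- !is.na(col) & col != ""
    data.frame(patient_id = death$patient_id[keep],
               date = death$death_date[keep], code = col[keep],
               row_id = death$patient_id[keep], slot = rep(i, sum(keep)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

entity_values_source <- function(bundle, entity_fields) {
  out <- list()
  for (tbl in c("test", "additional")) {
    tb <- bundle[[tbl]]
    for (r in seq_len(nrow(entity_fields))) {
      et <- entity_fields$entity_type_id[r]
      fi <- entity_fields$field_index[r]
      rows <- tb[tb$entity_type_id == et, , drop = FALSE]
      val <- rows[[paste0("value_", fi)]]
      keep <- !is.na(val) & val != ""
      out[[length(out) + 1L]] <- data.frame(
        patient_id = rows$patient_id[keep], date = rows$event_date[keep],
        value = suppressWarnings(as.numeric(val[keep])),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Execute a phenotype against the raw source bundle
#'
#' Membership is the union, across the phenotype's sources, of patients
#' carrying at least one listed code; the earliest event date across
#' sources is retained. Rows with null dates contribute membership but
#' not dates.
#'
#' @param defn a [phenotype_definition].
#' @param bundle a `source_bundle`.
#' @return a `phenotype_result`.
#' @export
find_patients_source <- function(defn, bundle) {
  ev <- list()
  if (defn$kind == "biomarker") {
    vals <- entity_values_source(bundle, defn$entity_fields)
    return(new_phenotype_result(defn$name,
                                vals[, c("patient_id", "date")], vals))
  }
  if (defn$kind == "medication-class") {
    codes <- defn$codelists$GEMSCRIPT
    hit <- bundle$therapy$drug_code %in% codes
    ev[[1]] <- data.frame(patient_id = bundle$therapy$patient_id[hit],
                          date = bundle$therapy$event_date[hit],
                          stringsAsFactors = FALSE)
  } else {
    if ("primary-care" %in% defn$sources) {
      codes <- defn$codelists$READ
      hit <- bundle$clinical$code %in% codes
      ev[[length(ev) + 1L]] <- data.frame(
        patient_id = bundle$clinical$patient_id[hit],
        date = bundle$clinical$event_date[hit], stringsAsFactors = FALSE)
    }
    if ("hospital" %in% defn$sources && length(defn$codelists$ICD10)) {
      he <- hospital_slot_events(bundle$hospital, 1:20, "diag")
      hit <- he$code %in% defn$codelists$ICD10
      ev[[length(ev) + 1L]] <- he[hit, c("patient_id", "date")]
    }
    if ("hospital" %in% defn$sources && length(defn$codelists$OPCS4)) {
      pe <- hospital_slot_events(bundle$hospital, 1:4, "proc")
      hit <- pe$code %in% defn$codelists$OPCS4
      ev[[length(ev) + 1L]] <- pe[hit, c("patient_id", "date")]
    }
    if ("death" %in% defn$sources && length(defn$codelists$ICD10)) {
      de <- death_slot_events(bundle$death)
      hit <- de$code %in% defn$codelists$ICD10
      ev[[length(ev) + 1L]] <- de[hit, c("patient_id", "date")]
    }
  }
  dates <- do.call(rbind, ev)
  if (is.null(dates)) dates <- data.frame(patient_id = integer(),
                                          date = as.Date(character()))
  new_phenotype_result(defn$name, dates)
}

#' Execute a phenotype against the CDM bundle
#'
#' Patients with at least one event whose concept lies in the translated
#' concept set, scanned across the tables matching the phenotype kind
#' (conditions also scan observations and death causes; medication
#' classes scan drug exposures; biomarkers scan measurements).
#'
#' @param defn a translated [phenotype_definition].
#' @param cdm a `cdm_bundle`.
#' @return a `phenotype_result`.
#' @export
find_patients_cdm <- function(defn, cdm) {
  if (is.null(defn$concept_set)) {
    stop("phenotype '", defn$name,
         "' has not been translated; run translate_codelist() first",
         call. = FALSE)
  }
  cs <- defn$concept_set
  tables <- switch(defn$kind,
    condition = c("condition_occurrence", "procedure_occurrence",
                  "observation", "death"),
    lifestyle = c("observation", "condition_occurrence"),
    `medication-class` = "drug_exposure",
    biomarker = "measurement")
  ev <- list()
  for (t in tables) {
    tb <- cdm[[t]]
    hit <- tb$concept_id %in% cs
    ev[[length(ev) + 1L]] <- data.frame(patient_id = tb$person_id[hit],
                                        date = tb$event_date[hit],
                                        stringsAsFactors = FALSE)
  }
  dates <- do.call(rbind, ev)
  values <- NULL
  if (defn$kind == "biomarker") {
    m <- cdm$measurement
    hit <- m$concept_id %in% cs
    values <- data.frame(patient_id = m$person_id[hit],
                         date = m$event_date[hit],
                         value = m$value_as_number[hit],
                         stringsAsFactors = FALSE)
  }
  new_phenotype_result(defn$name, dates, values)
}

#' Cohort entry and exclusion rules
#'
#' @param entry_start earliest admissible index date.
#' @param min_age minimum age (years) at index, from year of birth.
#' @param min_prior_days minimum days between observation-period start
#'   and index (inclusive boundary: exactly `min_prior_days` qualifies).
#' @return object of class `cohort_rules`.
#' @export
cohort_rules <- function(entry_start = "1998-01-01", min_age = 18L,
                         min_prior_days = 365L) {
  stopifnot(min_age > 0, min_prior_days > 0)
  structure(list(entry_start = as.Date(entry_start),
                 min_age = as.integer(min_age),
                 min_prior_days = as.integer(min_prior_days)),
            class = "cohort_rules")
}

#' Build the disease cohort from a phenotype result
#'
#' Index date is the earliest phenotype event on/after the entry start.
#' Exclusions: no observation period (rejected patient or no dated
#' event), age at index under the minimum (age = index year minus year
#' of birth), or less than the minimum prior registration between
#' observation-period start and index. Follow-up ends at the observation
#' period end, which is itself the earliest of death, transfer-out, last
#' practice collection and the study end date.
#'
#' @param result a `phenotype_result`.
#' @param periods data.frame (patient_id, start, end) of observation
#'   periods.
#' @param yob data.frame (patient_id, year_of_birth).
#' @param rules a [cohort_rules].
#' @return data.frame (patient_id, index_date, follow_up_end, included,
#'   reason).
#' @export
build_hf_cohort <- function(result, periods, yob, rules = cohort_rules()) {
  dated <- result$dates[!is.na(result$dates$date) &
                          result$dates$date >= rules$entry_start, ,
                        drop = FALSE]
  idx <- if (nrow(dated)) {
    agg <- stats::aggregate(date ~ patient_id, data = dated, FUN = min)
    names(agg)[2] <- "index_date"
    agg
  } else {
    data.frame(patient_id = integer(), index_date = as.Date(character()))
  }
  all_pat <- data.frame(patient_id = result$patients)
  out <- merge(all_pat, idx, by = "patient_id", all.x = TRUE)
  out <- merge(out, stats::setNames(periods[, c("patient_id", "start", "end")],
                                    c("patient_id", "period_start",
                                      "period_end")),
               by = "patient_id", all.x = TRUE)
  out <- merge(out, yob, by = "patient_id", all.x = TRUE)
  out$reason <- "included"
  out$reason[is.na(out$index_date)] <- "no-index-event"
  no_period <- is.na(out$period_start) & out$reason == "included"
  out$reason[no_period] <- "no-observation-period"
  age <- as.integer(format(out$index_date, "%Y")) - out$year_of_birth
  under <- !is.na(age) & age < rules$min_age & out$reason == "included"
  out$reason[under] <- "under-age"
  prior <- as.integer(out$index_date - out$period_start)
  short <- !is.na(prior) & prior < rules$min_prior_days &
    out$reason == "included"
  out$reason[short] <- "insufficient-prior-registration"
  out$included <- out$reason == "included"
  out$follow_up_end <- out$period_end
  out <- out[order(out$patient_id),
             c("patient_id", "index_date", "follow_up_end", "included",
               "reason")]
  rownames(out) <- NULL
  out
}

#' Summarise a biomarker over a cohort
#'
#' Uses each included patient's first value on/after their index date;
#' missing values are omitted. The interquartile range is the
#' type-7 quantile 0.75 minus 0.25.
#'
#' @param result a `phenotype_result` carrying a value series.
#' @param cohort cohort table from [build_hf_cohort()].
#' @return one-row data.frame (median, iqr, mean, sd, n); `n = 0` when
#'   no values qualify.
#' @export
summarize_biomarker <- function(result, cohort) {
  empty <- data.frame(median = NA_real_, iqr = NA_real_, mean = NA_real_,
                      sd = NA_real_, n = 0L)
  vals <- result$values
  if (is.null(vals) || !nrow(vals)) return(empty)
  inc <- cohort[cohort$included, , drop = FALSE]
  v <- merge(vals, inc[, c("patient_id", "index_date")], by = "patient_id")
  v <- v[!is.na(v$value) & !is.na(v$date) & v$date >= v$index_date, ,
         drop = FALSE]
  if (!nrow(v)) return(empty)
  # ties on the first qualifying date break on value, so both
  # representations pick the same measurement
  v <- v[order(v$patient_id, v$date, v$value), , drop = FALSE]
  first <- v[!duplicated(v$patient_id), , drop = FALSE]
  q <- stats::quantile(first$value, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  data.frame(median = q[2], iqr = q[3] - q[1], mean = mean(first$value),
             sd = stats::sd(first$value), n = nrow(first))
}

#' Percentage of the cohort with at least one exposure in a class
#'
#' @param result a `phenotype_result` for a medication class.
#' @param cohort cohort table from [build_hf_cohort()].
#' @return percentage to 1 decimal.
#' @export
medication_flag <- function(result, cohort) {
  inc <- cohort$patient_id[cohort$included]
  if (!length(inc)) return(0)
  round(100 * sum(inc %in% result$patients) / length(inc), 1)
}

#' Percentage of the cohort with a given last-known lifestyle status
#'
#' For status-group phenotypes (e.g. smoking), the patient's status is
#' the latest status-group code on/before the index date; membership
#' requires that status to lie in the phenotype's own code list (on the
#' source side) or concept set (on the CDM side).
#'
#' @param defn a translated lifestyle [phenotype_definition].
#' @param representation a `source_bundle` or `cdm_bundle`.
#' @param cohort cohort table from [build_hf_cohort()].
#' @param vocab the [vocabulary_store] (needed on the CDM side to
#'   translate the status universe).
#' @return list with `pct` (1 decimal) and `n` members.
#' @export
lifestyle_flag <- function(defn, representation, cohort, vocab = NULL) {
  stopifnot(defn$kind == "lifestyle", !is.null(defn$status_universe))
  inc <- cohort[cohort$included, c("patient_id", "index_date")]
  if (inherits(representation, "source_bundle")) {
    cl <- representation$clinical
    rows <- cl[cl$code %in% defn$status_universe & !is.na(cl$event_date),
               c("patient_id", "event_date", "code")]
    target <- rows$code %in% unlist(defn$codelists)
  } else {
    stopifnot(!is.null(vocab))
    uni_concepts <- unlist(resolve_many(vocab, defn$status_universe, "READ"))
    ob <- representation$observation
    rows <- ob[ob$concept_id %in% uni_concepts,
               c("person_id", "event_date", "concept_id")]
    names(rows)[1] <- "patient_id"
    target <- rows$concept_id %in% defn$concept_set
  }
  rows$is_target <- target
  m <- merge(rows, inc, by = "patient_id")
  m <- m[m$event_date <= m$index_date, , drop = FALSE]
  n_members <- 0L
  if (nrow(m)) {
    m <- m[order(m$patient_id, m$event_date), , drop = FALSE]
    last <- m[!duplicated(m$patient_id, fromLast = TRUE), , drop = FALSE]
    n_members <- sum(last$is_target)
  }
  list(pct = if (nrow(inc)) round(100 * n_members / nrow(inc), 1) else 0,
       n = n_members)
}
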