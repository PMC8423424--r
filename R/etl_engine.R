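# ETL engine: source bundle -> CDM-subset bundle. Every source event
# either lands in exactly one CDM table (one-to-many concept fan-out
# emits multiple rows sharing the same provenance pointer) or is written
# to the exclusion ledger with a reason; nothing is dropped silently.

CDM_EVENT_TABLES <- c("condition_occurrence", "procedure_occurrence",
                      "drug_exposure", "measurement", "observation", "death")

domain_table <- c(condition = "condition_occurrence",
                  procedure = "procedure_occurrence",
                  drug = "drug_exposure",
                  measurement = "measurement",
                  observation = "observation",
                  `death-cause` = "death")

#' Assemble the CDM person table
#'
#' One person row per source patient. Sex and year of birth come from
#' primary care; ethnicity comes exclusively from hospital records (null
#' when the patient has none), even when primary care carries a value —
#' the hospital register is treated as the authoritative ethnicity
#' source inside the ETL.
#'
#' @param bundle a `source_bundle`.
#' @return person data.frame.
#' @export
build_person <- function(bundle) {
  pat <- bundle$patient
  if (anyDuplicated(pat$patient_id)) {
    stop("integrity error: duplicate patient_id in patient table",
         call. = FALSE)
  }
  hosp <- bundle$hospital
  hosp <- hosp[!is.na(hosp$ethnicity_code) & hosp$ethnicity_code != "", ,
               drop = FALSE]
  hosp <- hosp[order(hosp$patient_id, hosp$spell_id), , drop = FALSE]
  first_eth <- hosp[!duplicated(hosp$patient_id), c("patient_id",
                                                    "ethnicity_code")]
  data.frame(
    person_id = pat$patient_id,
    gender_source_value = pat$sex,
    year_of_birth = pat$year_of_birth,
    ethnicity_source_value = first_eth$ethnicity_code[
      match(pat$patient_id, first_eth$patient_id)],
    stringsAsFactors = FALSE)
}

#' Derive observation periods and patient rejections
#'
#' Start = max(registration date, practice up-to-standard date); end =
#' min over the non-null of transfer-out, practice last collection,
#' death, study end. A patient whose start exceeds their end (or whose
#' registration date is null) is rejected outright — never clamped — and
#' every one of their rows is later excluded with reason
#' `rejected-patient`.
#'
#' @param bundle a `source_bundle`.
#' @param study_end study end date.
#' @return list with `periods` (patient_id, start, end) and `rejected`
#'   (patient_id, reason).
#' @export
build_observation_period <- function(bundle, study_end) {
  study_end <- as.Date(study_end)
  pat <- bundle$patient
  prac <- bundle$practice[match(pat$practice_id,
                                bundle$practice$practice_id), , drop = FALSE]
  start <- pmax(pat$registration_date, prac$up_to_standard_date)
  end <- pmin(pat$transfer_out_date, prac$last_collection_date,
              pat$death_date, rep(study_end, nrow(pat)), na.rm = TRUE)
  bad <- is.na(pat$registration_date) | is.na(start) | is.na(end) |
    start > end
  list(periods = data.frame(patient_id = pat$patient_id[!bad],
                            start = start[!bad], end = end[!bad],
                            stringsAsFactors = FALSE),
       rejected = data.frame(patient_id = pat$patient_id[bad],
                             reason = rep("inconsistent-observation-period",
                                          sum(bad)),
                             stringsAsFactors = FALSE))
}

#' Build the visit occurrence table
#'
#' One visit per distinct (encounter id, patient id, date) key;
#' primary-care visits from the consultation table, hospital visits from
#' admissions (start = end = admission date). Encounters with null dates
#' are excluded with reason `missing-date`; encounters of rejected
#' patients with reason `rejected-patient`. Visit ids are deterministic
#' surrogate integers assigned in sorted-key order.
#'
#' @param bundle a `source_bundle`.
#' @param rejected_ids patient ids rejected from the ETL.
#' @return list with `visits` data.frame and `exclusions` data.frame.
#' @export
build_visits <- function(bundle, rejected_ids = integer()) {
  excl <- list()
  note <- function(tbl, ids, reason, slot = 0L) {
    if (length(ids)) excl[[length(excl) + 1L]] <<- data.frame(
      source_table = tbl, row_id = ids, source_slot = slot, reason = reason,
      stringsAsFactors = FALSE)
  }
  cons <- bundle$consultation
  rej <- cons$patient_id %in% rejected_ids
  note("consultation", cons$consultation_id[rej], "rejected-patient")
  cons <- cons[!rej, , drop = FALSE]
  nodate <- is.na(cons$event_date)
  note("consultation", cons$consultation_id[nodate], "missing-date")
  cons <- cons[!nodate, , drop = FALSE]

  hosp <- bundle$hospital
  rej <- hosp$patient_id %in% rejected_ids
  note("hospital", hosp$spell_id[rej], "rejected-patient")
  hosp <- hosp[!rej, , drop = FALSE]
  nodate <- is.na(hosp$admission_date)
  note("hospital", hosp$spell_id[nodate], "missing-date")
  hosp <- hosp[!nodate, , drop = FALSE]

  pc <- unique(data.frame(source = "primary-care",
                          encounter_id = cons$consultation_id,
                          person_id = cons$patient_id,
                          date = cons$event_date, stringsAsFactors = FALSE))
  hs <- unique(data.frame(source = "hospital",
                          encounter_id = hosp$spell_id,
                          person_id = hosp$patient_id,
                          date = hosp$admission_date, stringsAsFactors = FALSE))
  keys <- rbind(pc[order(pc$person_id, pc$encounter_id, pc$date), ,
                   drop = FALSE],
                hs[order(hs$person_id, hs$encounter_id, hs$date), ,
                   drop = FALSE])
  visits <- data.frame(
    visit_occurrence_id = seq_len(nrow(keys)),
    person_id = keys$person_id,
    visit_start_date = keys$date,
    visit_end_date = keys$date,
    visit_source = keys$source,
    source_encounter_id = keys$encounter_id,
    stringsAsFactors = FALSE)
  list(visits = visits,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(source_table = character(), row_id = integer(),
                    source_slot = integer(), reason = character(),
                    stringsAsFactors = FALSE))
}

empty_event_table <- function(extra = NULL) {
  base <- data.frame(event_id = integer(), person_id = integer(),
                     concept_id = integer(),
                     event_date = as.Date(character()),
                     visit_occurrence_id = integer(),
                     invalid_visit = integer(), stringsAsFactors = FALSE)
  if (!is.null(extra)) base <- cbind(base, extra)
  cbind(base, data.frame(source_table = character(),
                         source_row_id = integer(), source_slot = integer(),
                         source_code = character(),
                         source_vocabulary = character(),
                         stringsAsFactors = FALSE))
}

# Fan a set of resolved source events out into CDM event rows.
# events: data.frame(person_id, event_date, visit_occurrence_id,
#   invalid_visit, source_row_id, source_slot, source_code); targets is a
# list of integer concept vectors parallel to events rows.
fan_out <- function(events, targets, source_table, source_vocabulary) {
  k <- lengths(targets)
  idx <- rep(seq_len(nrow(events)), k)
  out <- events[idx, , drop = FALSE]
  out$concept_id <- unlist(targets)
  out$source_table <- source_table
  out$source_vocabulary <- source_vocabulary
  rownames(out) <- NULL
  out
}

#' Run the full ETL
#'
#' Transforms a source bundle into a CDM bundle: person assembly,
#' observation periods with rejection, visit construction, domain
#' routing of all clinical events through the vocabulary, drug-era
#' derivation, and a complete exclusion + code-mapping ledger. Events
#' dated outside the observation period are retained (the quality-check
#' module reports them); events referencing an encounter that produced
#' no visit keep a null visit reference and are flagged.
#'
#' @param bundle a `source_bundle`.
#' @param vocab a [vocabulary_store].
#' @param study_end study end date (default 2016-03-08; the bundle's own
#'   study end, when present, is used unless overridden).
#' @param era_gap maximum days between consecutive exposure starts
#'   merged into one drug era (default 30).
#' @param drug_duration assumed prescription duration in days
#'   (default 30).
#' @return object of class `cdm_bundle`.
#' @export
etl_run <- function(bundle, vocab, study_end = NULL, era_gap = 30L,
                    drug_duration = 30L) {
  stopifnot(inherits(bundle, "source_bundle"),
            inherits(vocab, "vocabulary_store"))
  if (is.null(study_end)) {
    study_end <- if (!is.null(bundle$study_end)) bundle$study_end else
      as.Date("2016-03-08")
  }
  study_end <- as.Date(study_end)

  person_all <- build_person(bundle)
  op <- build_observation_period(bundle, study_end)
  rejected_ids <- op$rejected$patient_id
  person <- person_all[!person_all$person_id %in% rejected_ids, ,
                       drop = FALSE]
  excl <- list(data.frame(
    source_table = rep("patient", length(rejected_ids)),
    row_id = rejected_ids, source_slot = rep(0L, length(rejected_ids)),
    reason = rep("inconsistent-observation-period", length(rejected_ids)),
    stringsAsFactors = FALSE))
  note <- function(tbl, ids, slots, reason) {
    if (length(ids)) excl[[length(excl) + 1L]] <<- data.frame(
      source_table = tbl, row_id = ids, source_slot = slots, reason = reason,
      stringsAsFactors = FALSE)
  }

  vb <- build_visits(bundle, rejected_ids)
  visits <- vb$visits
  excl[[length(excl) + 1L]] <- vb$exclusions
  pc_visit <- visits[visits$visit_source == "primary-care", , drop = FALSE]
  visit_of_cons <- stats::setNames(pc_visit$visit_occurrence_id,
                                   pc_visit$source_encounter_id)
  hs_visit <- visits[visits$visit_source == "hospital", , drop = FALSE]
  visit_of_spell <- stats::setNames(hs_visit$visit_occurrence_id,
                                    hs_visit$source_encounter_id)

  events <- stats::setNames(
    lapply(CDM_EVENT_TABLES, function(t) list()), CDM_EVENT_TABLES)
  mapping <- list()
  note_mapping <- function(codes, vocabulary, targets) {
    if (length(codes)) mapping[[length(mapping) + 1L]] <<- data.frame(
      source_code = codes, source_vocabulary = vocabulary,
      target_concept_id = targets, stringsAsFactors = FALSE)
  }
  domain_of <- stats::setNames(vocab$concepts$domain,
                               vocab$concepts$concept_id)
  add_events <- function(ev, targets, source_table, vocabulary,
                         force_table = NULL) {
    rows <- fan_out(ev, targets, source_table, vocabulary)
    if (!nrow(rows)) return(invisible())
    tbl <- if (is.null(force_table)) {
      domain_table[domain_of[as.character(rows$concept_id)]]
    } else rep(force_table, nrow(rows))
    for (t in unique(tbl)) {
      events[[t]][[length(events[[t]]) + 1L]] <<- rows[tbl == t, ,
                                                       drop = FALSE]
    }
  }

  route_coded <- function(tbl_name, tb, code_col, resolver, vocabulary,
                          force_table = NULL) {
    if (!nrow(tb)) return(invisible())
    rej <- tb$patient_id %in% rejected_ids
    note(tbl_name, tb$row_id[rej], 0L, "rejected-patient")
    tb <- tb[!rej, , drop = FALSE]
    nodate <- is.na(tb$event_date)
    note(tbl_name, tb$row_id[nodate], 0L, "missing-date")
    tb <- tb[!nodate, , drop = FALSE]
    if (!nrow(tb)) return(invisible())
    codes <- tb[[code_col]]
    targets <- resolver(codes)
    note_mapping(codes, vocabulary,
                 vapply(targets, function(x) {
                   if (length(x)) x[1L] else NA_integer_
                 }, integer(1L)))
    unm <- lengths(targets) == 0L
    note(tbl_name, tb$row_id[unm], 0L, "unmapped-code")
    tb <- tb[!unm, , drop = FALSE]
    targets <- targets[!unm]
    if (!nrow(tb)) return(invisible())
    vref <- visit_of_cons[as.character(tb$consultation_id)]
    ev <- data.frame(
      person_id = tb$patient_id, event_date = tb$event_date,
      visit_occurrence_id = as.integer(vref),
      invalid_visit = as.integer(!is.na(tb$consultation_id) & is.na(vref)),
      source_row_id = tb$row_id, source_slot = 0L,
      source_code = codes[!unm], stringsAsFactors = FALSE)
    add_events(ev, targets, tbl_name, vocabulary, force_table)
  }

  # primary-care diagnoses / observations, and prescriptions
  tb <- bundle$clinical
  tb$event_date <- tb$event_date
  route_coded("clinical", tb, "code",
              function(codes) resolve_many(vocab, codes, "READ"), "READ")
  route_coded("therapy", bundle$therapy, "drug_code", function(codes) {
    res <- resolve_drug(vocab, codes)
    lapply(res, function(x) if (is.na(x)) integer() else x)
  }, "GEMSCRIPT")

  # wide entity rows -> long measurements
  for (tbl_name in c("test", "additional")) {
    tb <- bundle[[tbl_name]]
    if (!nrow(tb)) next
    rej <- tb$patient_id %in% rejected_ids
    pop_slots <- function(rows) {
      lapply(seq_len(nrow(rows)), function(r) {
        vals <- unlist(rows[r, paste0("value_", 1:8)], use.names = FALSE)
        which(!is.na(vals) & vals != "")
      })
    }
    if (any(rej)) {
      slots <- pop_slots(tb[rej, , drop = FALSE])
      note(tbl_name, rep(tb$row_id[rej], lengths(slots)), unlist(slots),
           "rejected-patient")
    }
    tb <- tb[!rej, , drop = FALSE]
    nodate <- is.na(tb$event_date)
    if (any(nodate)) {
      slots <- pop_slots(tb[nodate, , drop = FALSE])
      note(tbl_name, rep(tb$row_id[nodate], lengths(slots)), unlist(slots),
           "missing-date")
    }
    tb <- tb[!nodate, , drop = FALSE]
    for (r in seq_len(nrow(tb))) {
      vals <- as.character(unlist(tb[r, paste0("value_", 1:8)],
                                  use.names = FALSE))
      res <- resolve_entity_row(vocab, tb$entity_type_id[r], vals,
                                tb$unit_code[r])
      note(tbl_name, rep(tb$row_id[r], length(res$unmapped)), res$unmapped,
           "unmapped-code")
      note(tbl_name, rep(tb$row_id[r], length(res$excluded)), res$excluded,
           "zero-value-entity")
      if (nrow(res$candidates)) {
        cand <- res$candidates
        ev <- data.frame(
          person_id = tb$patient_id[r], event_date = tb$event_date[r],
          visit_occurrence_id = NA_integer_, invalid_visit = 0L,
          value_as_number = cand$value_as_number,
          unit_concept_id = cand$unit_concept_id,
          source_row_id = tb$row_id[r], source_slot = cand$field_index,
          source_code = paste0(tb$entity_type_id[r], ":", cand$field_index),
          stringsAsFactors = FALSE)
        add_events(ev, as.list(cand$concept_id), tbl_name, "ENTITY",
                   force_table = "measurement")
      }
    }
  }

  # hospital discharge diagnoses and procedures
  hosp <- bundle$hospital
  if (nrow(hosp)) {
    rej <- hosp$patient_id %in% rejected_ids
    nodate <- !rej & is.na(hosp$admission_date)
    route_hosp_slots <- function(slots, prefix, vocabulary, force_table) {
      for (i in slots) {
        col <- hosp[[sprintf("%s_%02d", prefix, i)]]
        popul <- !is.na(col) & col != ""
        slot_no <- if (prefix == "proc") 20L + i else i
        note("hospital", hosp$spell_id[popul & rej], slot_no,
             "rejected-patient")
        note("hospital", hosp$spell_id[popul & nodate], slot_no,
             "missing-date")
        keep <- popul & !rej & !nodate
        if (!any(keep)) next
        codes <- col[keep]
        targets <- resolve_many(vocab, codes, vocabulary)
        note_mapping(codes, vocabulary,
                     vapply(targets, function(x) {
                       if (length(x)) x[1L] else NA_integer_
                     }, integer(1L)))
        unm <- lengths(targets) == 0L
        note("hospital", hosp$spell_id[keep][unm], slot_no, "unmapped-code")
        if (all(unm)) next
        sub <- hosp[keep, , drop = FALSE][!unm, , drop = FALSE]
        ev <- data.frame(
          person_id = sub$patient_id, event_date = sub$admission_date,
          visit_occurrence_id = as.integer(
            visit_of_spell[as.character(sub$spell_id)]),
          invalid_visit = 0L,
          source_row_id = sub$spell_id, source_slot = slot_no,
          source_code = codes[!unm], stringsAsFactors = FALSE)
        add_events(ev, targets[!unm], "hospital", vocabulary, force_table)
      }
    }
    route_hosp_slots(1:20, "diag", "ICD10", "condition_occurrence")
    route_hosp_slots(1:4, "proc", "OPCS4", "procedure_occurrence")
  }

  # mortality register: underlying + secondary causes
  dth <- bundle$death
  if (nrow(dth)) {
    rej <- dth$patient_id %in% rejected_ids
    for (i in 1:15) {
      col <- dth[[sprintf("cause_%02d", i)]]
      popul <- !is.na(col) & col != ""
      note("death", dth$patient_id[popul & rej], i, "rejected-patient")
      keep <- popul & !rej
      if (!any(keep)) next
      codes <- col[keep]
      targets <- resolve_many(vocab, codes, "ICD10")
      note_mapping(codes, "ICD10",
                   vapply(targets, function(x) {
                     if (length(x)) x[1L] else NA_integer_
                   }, integer(1L)))
      unm <- lengths(targets) == 0L
      note("death", dth$patient_id[keep][unm], i, "unmapped-code")
      if (all(unm)) next
      sub <- dth[keep, , drop = FALSE][!unm, , drop = FALSE]
      ev <- data.frame(
        person_id = sub$patient_id, event_date = sub$death_date,
        visit_occurrence_id = NA_integer_, invalid_visit = 0L,
        cause_rank = i,
        source_row_id = sub$patient_id, source_slot = i,
        source_code = codes[!unm], stringsAsFactors = FALSE)
      add_events(ev, targets[!unm], "death", "ICD10", force_table = "death")
    }
  }

  bind_events <- function(lst, extra_cols = character()) {
    if (!length(lst)) {
      return(empty_event_table(
        if (length(extra_cols)) {
          stats::setNames(as.data.frame(replicate(length(extra_cols),
                                                  numeric(),
                                                  simplify = FALSE)),
                          extra_cols)
        } else NULL))
    }
    out <- do.call(rbind, lst)
    out <- out[order(out$person_id, out$event_date, out$source_row_id,
                     out$source_slot, out$concept_id), , drop = FALSE]
    out$event_id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  }
  cdm_tables <- lapply(names(events), function(t) bind_events(events[[t]]))
  names(cdm_tables) <- names(events)
  # table-specific columns (present even when a table is empty)
  cdm_tables$drug_exposure$drug_exposure_end_date <-
    cdm_tables$drug_exposure$event_date + drug_duration
  if (!"value_as_number" %in% names(cdm_tables$measurement)) {
    cdm_tables$measurement$value_as_number <- numeric(0)
    cdm_tables$measurement$unit_concept_id <- integer(0)
  }
  if (!"cause_rank" %in% names(cdm_tables$death)) {
    cdm_tables$death$cause_rank <- integer(0)
  }

  drug_era <- derive_drug_eras(cdm_tables$drug_exposure, era_gap,
                               drug_duration)

  exclusions <- do.call(rbind, excl)
  exclusions <- exclusions[order(exclusions$source_table, exclusions$row_id,
                                 exclusions$source_slot), , drop = FALSE]
  exclusions$exclusion_id <- seq_len(nrow(exclusions))
  rownames(exclusions) <- NULL

  map_ledger <- if (length(mapping)) unique(do.call(rbind, mapping)) else
    data.frame(source_code = character(), source_vocabulary = character(),
               target_concept_id = integer(), stringsAsFactors = FALSE)
  map_ledger <- map_ledger[order(map_ledger$source_vocabulary,
                                 map_ledger$source_code), , drop = FALSE]
  map_ledger$mapping_id <- seq_len(nrow(map_ledger))
  rownames(map_ledger) <- NULL

  structure(c(list(person = person,
                   observation_period = data.frame(
                     person_id = op$periods$patient_id,
                     observation_period_start_date = op$periods$start,
                     observation_period_end_date = op$periods$end,
                     stringsAsFactors = FALSE),
                   visit_occurrence = visits),
              cdm_tables,
              list(drug_era = drug_era, exclusions = exclusions,
                   code_mappings = map_ledger,
                   meta = list(study_end = study_end, era_gap = era_gap,
                               drug_duration = drug_duration,
                               rejected_patients = rejected_ids))),
            class = "cdm_bundle")
}

#' @export
print.cdm_bundle <- function(x, ...) {
  cat("<cdm_bundle>\n")
  for (t in setdiff(names(x), "meta")) {
    cat(sprintf("  %-22s %6d rows\n", t, nrow(x[[t]])))
  }
  invisible(x)
}

#' Merge drug exposures into drug eras
#'
#' Per (person, drug concept), exposures sorted by start date are merged
#' into one era while consecutive starts are at most `gap_days` apart;
#' the era runs from the first start to the last start plus the default
#' prescription duration.
#'
#' @param drug_exposure CDM drug exposure table.
#' @param gap_days merge window in days.
#' @param duration_days assumed prescription duration in days.
#' @return drug_era data.frame.
#' @export
derive_drug_eras <- function(drug_exposure, gap_days = 30L,
                             duration_days = 30L) {
  empty <- data.frame(era_id = integer(), person_id = integer(),
                      drug_concept_id = integer(),
                      drug_era_start_date = as.Date(character()),
                      drug_era_end_date = as.Date(character()),
                      drug_exposure_count = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(drug_exposure) || !nrow(drug_exposure)) return(empty)
  de <- drug_exposure[order(drug_exposure$person_id,
                            drug_exposure$concept_id,
                            drug_exposure$event_date), , drop = FALSE]
  grp <- paste(de$person_id, de$concept_id, sep = "\r")
  new_grp <- !duplicated(grp)
  gap <- c(TRUE, diff(as.integer(de$event_date)) > gap_days)
  era_break <- new_grp | gap
  era_id <- cumsum(era_break)
  out <- data.frame(
    era_id = seq_len(max(era_id)),
    person_id = de$person_id[era_break],
    drug_concept_id = de$concept_id[era_break],
    drug_era_start_date = de$event_date[era_break],
    drug_era_end_date = as.Date(vapply(split(de$event_date, era_id), max,
                                       numeric(1L)),
                                origin = "1970-01-01") + duration_days,
    drug_exposure_count = as.integer(tabulate(era_id)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate a CDM bundle's structural invariants
#'
#' Checks that every person referenced by an event table exists in
#' person, that observation periods are at most one per person, and that
#' visit ids are unique.
#'
#' @param cdm a `cdm_bundle`.
#' @return data.frame of violations (zero rows when valid).
#' @export
validate_cdm <- function(cdm) {
  bad <- list()
  note <- function(table, rows, reason) {
    if (length(rows)) bad[[length(bad) + 1L]] <<- data.frame(
      table = table, row = rows, reason = reason, stringsAsFactors = FALSE)
  }
  for (t in c(CDM_EVENT_TABLES, "visit_occurrence", "observation_period")) {
    tb <- cdm[[t]]
    if (is.null(tb) || !nrow(tb)) next
    dangle <- which(!tb$person_id %in% cdm$person$person_id)
    note(t, dangle, "person_id absent from person table")
  }
  note("observation_period",
       which(duplicated(cdm$observation_period$person_id)),
       "more than one observation period per person")
  note("visit_occurrence",
       which(duplicated(cdm$visit_occurrence$visit_occurrence_id)),
       "duplicate visit id")
  if (length(bad)) do.call(rbind, bad) else
    data.frame(table = character(), row = integer(), reason = character(),
               stringsAsFactors = FALSE)
}

count_populated_slots <- function(tb, cols) {
  sum(vapply(cols, function(cn) sum(!is.na(tb[[cn]]) & tb[[cn]] != ""), 0L))
}

#' Source-event conservation accounting
#'
#' For every source table, the number of source events (rows for
#' consultation/clinical/therapy; populated slots for the wide hospital,
#' death, test and additional tables; one encounter event per hospital
#' row) must equal the number of distinct provenance pointers in the CDM
#' tables plus the number of exclusion-ledger entries. One-to-many
#' concept fan-out shares a provenance pointer and so is counted once.
#'
#' @param cdm a `cdm_bundle`.
#' @param bundle the `source_bundle` it was built from.
#' @return data.frame (source_table, events_in, emitted, ledgered, ok).
#' @export
check_conservation <- function(cdm, bundle) {
  events_in <- c(
    consultation = nrow(bundle$consultation),
    clinical = nrow(bundle$clinical),
    therapy = nrow(bundle$therapy),
    test = count_populated_slots(bundle$test, paste0("value_", 1:8)),
    additional = count_populated_slots(bundle$additional,
                                       paste0("value_", 1:8)),
    hospital = nrow(bundle$hospital) +
      count_populated_slots(bundle$hospital, sprintf("diag_%02d", 1:20)) +
      count_populated_slots(bundle$hospital, sprintf("proc_%02d", 1:4)),
    death = count_populated_slots(bundle$death, sprintf("cause_%02d", 1:15)))

  prov <- list()
  for (t in CDM_EVENT_TABLES) {
    tb <- cdm[[t]]
    if (nrow(tb)) prov[[t]] <- unique(
      tb[, c("source_table", "source_row_id", "source_slot")])
  }
  vis <- cdm$visit_occurrence
  if (nrow(vis)) {
    prov$visit <- data.frame(
      source_table = ifelse(vis$visit_source == "primary-care",
                            "consultation", "hospital"),
      source_row_id = vis$source_encounter_id,
      source_slot = 0L, stringsAsFactors = FALSE)
  }
  prov <- unique(do.call(rbind, prov))
  emitted <- table(factor(prov$source_table, levels = names(events_in)))
  ledg <- cdm$exclusions[cdm$exclusions$source_table %in% names(events_in), ,
                         drop = FALSE]
  ledgered <- table(factor(ledg$source_table, levels = names(events_in)))
  out <- data.frame(source_table = names(events_in),
                    events_in = as.integer(events_in),
                    emitted = as.integer(emitted),
                    ledgered = as.integer(ledgered),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(
    source_table = "patient", events_in = nrow(bundle$patient),
    emitted = nrow(cdm$person),
    ledgered = sum(cdm$exclusions$source_table == "patient"),
    stringsAsFactors = FALSE))
  out$ok <- out$events_in == out$emitted + out$ledgered
  rownames(out) <- NULL
  out
}

CDM_TABLE_FILES <- c(person = "person.csv",
                     observation_period = "observation_period.csv",
                     visit_occurrence = "visit_occurrence.csv",
                     condition_occurrence = "condition_occurrence.csv",
                     procedure_occurrence = "procedure_occurrence.csv",
                     drug_exposure = "drug_exposure.csv",
                     drug_era = "drug_era.csv",
                     measurement = "measurement.csv",
                     observation = "observation.csv",
                     death = "death.csv",
                     exclusions = "exclusions.csv",
                     code_mappings = "code_mappings.csv")

cdm_schema_key <- c(death = "cdm_death")

#' Write a CDM bundle to disk
#'
#' One delimited file per populated table plus the two ledgers, in a
#' deterministic column order. Fails with an integrity error when the
#' bundle violates its invariants.
#'
#' @param cdm a `cdm_bundle`.
#' @param dir output directory (created if absent).
#' @export
write_cdm <- function(cdm, dir) {
  viol <- validate_cdm(cdm)
  if (nrow(viol)) {
    stop("integrity error: ", nrow(viol), " invariant violation(s), e.g. ",
         viol$table[1], " row ", viol$row[1], ": ", viol$reason[1],
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- bundle_schemas()
  for (t in names(CDM_TABLE_FILES)) {
    key <- if (t %in% names(cdm_schema_key)) cdm_schema_key[[t]] else t
    write_table(cdm[[t]], file.path(dir, CDM_TABLE_FILES[[t]]), s[[key]])
  }
  meta <- data.frame(key = c("study_end", "era_gap", "drug_duration"),
                     value = c(format(cdm$meta$study_end),
                               cdm$meta$era_gap, cdm$meta$drug_duration))
  utils::write.csv(meta, file.path(dir, "cdm_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a CDM bundle from disk
#' @param dir directory written by [write_cdm()].
#' @return a `cdm_bundle`.
#' @export
read_cdm <- function(dir) {
  s <- bundle_schemas()
  out <- lapply(names(CDM_TABLE_FILES), function(t) {
    key <- if (t %in% names(cdm_schema_key)) cdm_schema_key[[t]] else t
    read_table(file.path(dir, CDM_TABLE_FILES[[t]]), s[[key]])
  })
  names(out) <- names(CDM_TABLE_FILES)
  meta <- list()
  mp <- file.path(dir, "cdm_meta.csv")
  if (file.exists(mp)) {
    m <- utils::read.csv(mp, colClasses = "character")
    meta <- list(study_end = as.Date(m$value[m$key == "study_end"]),
                 era_gap = as.integer(m$value[m$key == "era_gap"]),
                 drug_duration = as.integer(m$value[m$key == "drug_duration"]))
  }
  out$meta <- meta
  structure(out, class = "cdm_bundle")
}

#' File-level ETL entry point
#'
#' Reads a source bundle and vocabulary from disk, runs [etl_run()], and
#' writes the CDM bundle. Single-shot contract: running the ETL on a
#' directory that already contains CDM output (its own or another run's)
#' is refused.
#'
#' @param source_dir directory with the source bundle CSVs.
#' @param vocab_dir directory with the vocabulary bundle CSVs.
#' @param out_dir output directory for the CDM bundle.
#' @param study_end,era_gap,drug_duration see [etl_run()].
#' @return the `cdm_bundle`, invisibly.
#' @export
etl_run_files <- function(source_dir, vocab_dir, out_dir, study_end = NULL,
                          era_gap = 30L, drug_duration = 30L) {
  if (file.exists(file.path(source_dir, "cdm_meta.csv"))) {
    stop("refusing to run the ETL on a CDM output directory: ", source_dir,
         call. = FALSE)
  }
  bundle <- read_source_bundle(source_dir)
  vocab <- read_vocabulary(vocab_dir)
  cdm <- etl_run(bundle, vocab, study_end = study_end, era_gap = era_gap,
                 drug_duration = drug_duration)
  write_cdm(cdm, out_dir)
  invisible(cdm)
}
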