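# minimal two-patient bundle for rule-level checks
micro_bundle <- function(transfer_out_2 = NA, uts = "1999-06-01",
                         last_collection = "2010-01-01") {
  empty_entity <- function() {
    out <- data.frame(row_id = integer(), patient_id = integer(),
                      event_date = as.Date(character()),
                      entity_type_id = integer())
    for (i in 1:8) out[[paste0("value_", i)]] <- character()
    out$unit_code <- character()
    out
  }
  hosp <- data.frame(spell_id = 1L, patient_id = 1L,
                     admission_date = as.Date("2005-03-01"))
  for (i in 1:20) hosp[[sprintf("diag_%02d", i)]] <- NA_character_
  for (i in 1:4) hosp[[sprintf("proc_%02d", i)]] <- NA_character_
  hosp$diag_01 <- "I1"
  hosp$ethnicity_code <- "E2"
  death <- data.frame(patient_id = integer(),
                      death_date = as.Date(character()),
                      cause_01 = character())
  for (i in 2:15) death[[sprintf("cause_%02d", i)]] <- character()
  death$deprivation_quintile <- integer()
  structure(list(
    patient = data.frame(
      patient_id = 1:2, sex = c("F", "M"), year_of_birth = c(1950L, 1960L),
      ethnicity_code = c("E1", "E1"),
      registration_date = as.Date(c("2000-01-01", "2001-01-01")),
      transfer_out_date = as.Date(c(NA, transfer_out_2)),
      practice_id = c(1L, 1L), death_date = as.Date(c(NA, NA))),
    practice = data.frame(practice_id = 1L,
                          up_to_standard_date = as.Date(uts),
                          last_collection_date = as.Date(last_collection)),
    consultation = data.frame(consultation_id = 1:3, patient_id = c(1L, 1L, 2L),
                              event_date = as.Date(c("2004-05-01",
                                                     "2005-06-01", NA))),
    clinical = data.frame(row_id = 1:3, patient_id = c(1L, 1L, 2L),
                          consultation_id = c(1L, 1L, 3L),
                          event_date = as.Date(c("2004-05-01", "2004-05-01",
                                                 "2004-07-01")),
                          code = c("A1", "A2", "A1")),
    therapy = data.frame(row_id = 1L, patient_id = 1L,
                         consultation_id = 99L,
                         event_date = as.Date("2004-05-01"),
                         drug_code = "G1"),
    test = empty_entity(), additional = empty_entity(),
    hospital = hosp, death = death,
    study_start = as.Date("2000-01-01"), study_end = as.Date("2016-03-08")),
    class = "source_bundle")
}

test_that("person assembly takes ethnicity exclusively from hospital records", {
  b <- micro_bundle()
  person <- build_person(b)
  expect_equal(nrow(person), 2L)
  # patient 1 has hospital ethnicity E2 which overrides primary care E1
  expect_equal(person$ethnicity_source_value[person$person_id == 1L], "E2")
  # patient 2 has ethnicity only in primary care -> null in CDM
  expect_true(is.na(person$ethnicity_source_value[person$person_id == 2L]))
  b$patient <- rbind(b$patient, b$patient[1, ])
  expect_error(build_person(b), "integrity error")
})

test_that("observation periods follow the max/min rule and reject inversions", {
  b <- micro_bundle()
  op <- build_observation_period(b, as.Date("2016-03-08"))
  p1 <- op$periods[op$periods$patient_id == 1L, ]
  # start = max(registration 2000-01-01, up-to-standard 1999-06-01)
  expect_equal(p1$start, as.Date("2000-01-01"))
  # end = min(last collection 2010-01-01, study end)
  expect_equal(p1$end, as.Date("2010-01-01"))
  expect_equal(nrow(op$rejected), 0L)

  # up-to-standard after last collection inverts every period
  op2 <- build_observation_period(micro_bundle(uts = "2017-01-01"),
                                  as.Date("2016-03-08"))
  expect_equal(sort(op2$rejected$patient_id), 1:2)
  expect_equal(nrow(op2$periods), 0L)

  # transfer-out before registration rejects only that patient
  op3 <- build_observation_period(micro_bundle(transfer_out_2 = "2000-06-01"),
                                  as.Date("2016-03-08"))
  expect_equal(op3$rejected$patient_id, 2L)
})

test_that("rejected patients contribute zero rows to every CDM table", {
  rates <- zero_defects
  rates["inverted_observation_period"] <- 0.05
  cfg <- generator_config(n_patients = 300L, seed = 17L,
                          defect_rates = rates)
  uni <- synthetic_vocabulary(cfg)
  gen <- generate_source(cfg, uni)
  planted <- gen$manifest$defects$inverted_observation_period
  expect_gt(length(planted), 0L)
  cdm <- etl_run(gen$bundle, uni$vocab)
  expect_setequal(cdm$meta$rejected_patients, planted)
  for (t in c("person", "observation_period", "visit_occurrence",
              omopetl:::CDM_EVENT_TABLES)) {
    ids <- cdm[[t]]$person_id
    expect_length(intersect(ids, planted), 0L)
  }
  ex <- cdm$exclusions
  expect_setequal(ex$row_id[ex$source_table == "patient"], planted)
})

test_that("visits are keyed by encounter and null dates are excluded", {
  b <- micro_bundle()
  vb <- build_visits(b)
  # two dated consultations + one hospital admission
  expect_equal(nrow(vb$visits), 3L)
  expect_equal(sum(vb$visits$visit_source == "hospital"), 1L)
  # consultation 3 has a null date
  expect_equal(vb$exclusions$row_id[vb$exclusions$reason == "missing-date"],
               3L)
  # two clinical rows share consultation 1: still one visit, both events
  # reference it
  cdm <- etl_run(b, tiny_vocab())
  v1 <- vb$visits$visit_occurrence_id[vb$visits$source_encounter_id == 1L &
                                        vb$visits$visit_source ==
                                          "primary-care"]
  cond <- cdm$condition_occurrence
  expect_equal(sum(cond$visit_occurrence_id == v1, na.rm = TRUE), 2L)
})

test_that("events route by domain and orphan encounters keep a flagged null visit", {
  b <- micro_bundle()
  cdm <- etl_run(b, tiny_vocab())
  # A1/A2 are condition-domain; patient 2's row references an undated
  # consultation so it keeps a null visit and is flagged
  cond <- cdm$condition_occurrence
  expect_equal(nrow(cond), 4L)  # 3 clinical + 1 hospital diagnosis
  p2 <- cond[cond$person_id == 2L, ]
  expect_true(is.na(p2$visit_occurrence_id))
  expect_equal(p2$invalid_visit, 1L)
  # therapy row references a consultation absent from the table
  de <- cdm$drug_exposure
  expect_equal(nrow(de), 1L)
  expect_true(is.na(de$visit_occurrence_id))
  expect_equal(de$invalid_visit, 1L)
  expect_equal(de$concept_id, 8L)
  # unmapped code A3 would land in the ledger; here all codes map
  expect_true(all(cdm$code_mappings$source_code %in% c("A1", "A2", "G1",
                                                       "D-G1", "I1")))
})

test_that("source events are conserved through the ETL", {
  for (seed in c(3L, 19L)) {
    cfg <- generator_config(n_patients = 250L, seed = seed)
    uni <- synthetic_vocabulary(cfg)
    gen <- generate_source(cfg, uni)
    cdm <- etl_run(gen$bundle, uni$vocab)
    cons <- check_conservation(cdm, gen$bundle)
    expect_true(all(cons$ok), label = paste("seed", seed))
    expect_equal(nrow(validate_cdm(cdm)), 0L)
  }
})

test_that("drug era merging matches the brute-force oracle", {
  # forced cases
  one <- data.frame(person_id = 1L, concept_id = 5L,
                    event_date = as.Date("2010-01-01"))
  e1 <- derive_drug_eras(one, 30L, 30L)
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$drug_era_start_date, as.Date("2010-01-01"))
  expect_equal(e1$drug_era_end_date, as.Date("2010-01-31"))

  two <- data.frame(person_id = 1L, concept_id = 5L,
                    event_date = as.Date(c("2010-01-01", "2010-01-11")))
  e2 <- derive_drug_eras(two, 30L, 30L)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$drug_exposure_count, 2L)
  expect_equal(e2$drug_era_end_date, as.Date("2010-01-11") + 30)

  # randomized instances against the oracle
  for (i in 1:60) {
    set.seed(i)
    n <- sample(1:12, 1)
    dates <- as.Date("2010-01-01") + sort(sample(0:200, n, replace = TRUE))
    gap <- sample(c(7L, 30L, 60L), 1)
    de <- data.frame(person_id = 1L, concept_id = 5L, event_date = dates)
    got <- derive_drug_eras(de, gap, 30L)
    want <- oracle_eras(dates, gap, 30L)
    expect_equal(got$drug_era_start_date, want$start)
    expect_equal(got$drug_era_end_date, want$end)
    expect_equal(got$drug_exposure_count, want$n)
  }
})

test_that("the ETL refuses to run on its own output directory", {
  cfg <- clean_config(n = 60L, seed = 4L)
  uni <- synthetic_vocabulary(cfg)
  gen <- generate_source(cfg, uni)
  src <- withr::local_tempdir(); vd <- withr::local_tempdir()
  out <- withr::local_tempdir()
  write_source_bundle(gen$bundle, src)
  write_vocabulary(uni$vocab, vd)
  etl_run_files(src, vd, out)
  expect_error(etl_run_files(out, vd, withr::local_tempdir()),
               "refusing")
})
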