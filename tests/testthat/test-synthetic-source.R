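test_that("identical config and seed give byte-identical bundles", {
  cfg <- generator_config(n_patients = 200L, seed = 9L)
  a <- generate_source(cfg)
  b <- generate_source(cfg)
  expect_identical(a$bundle, b$bundle)
  expect_identical(a$manifest, b$manifest)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_source_bundle(a$bundle, d1)
  write_source_bundle(b$bundle, d2)
  for (f in names(omopetl:::SOURCE_TABLE_FILES)) {
    fn <- omopetl:::SOURCE_TABLE_FILES[[f]]
    expect_identical(readBin(file.path(d1, fn), "raw", 1e7),
                     readBin(file.path(d2, fn), "raw", 1e7), label = fn)
  }
})

test_that("zero defect rates leave every defect list empty", {
  gen <- generate_source(clean_config(n = 150L, seed = 2L))
  d <- gen$manifest$defects
  expect_length(d$missing_event_date$consultation, 0L)
  expect_length(d$missing_event_date$hospital, 0L)
  expect_length(d$inverted_observation_period, 0L)
  expect_length(d$orphan_therapy_row, 0L)
  expect_length(d$unmappable_code, 0L)
  expect_length(d$zero_value_entity_row, 0L)
  expect_false(anyNA(gen$bundle$consultation$event_date))
})

test_that("planted prevalence lands in the exact binomial 99% interval", {
  cfg <- generator_config(
    n_patients = 2000L, seed = 7L,
    phenotype_prevalences = c(copd = 0.5), defect_rates = zero_defects)
  gen <- generate_source(cfg)
  n_copd <- sum(gen$manifest$membership$copd)
  ci <- qbinom(c(0.005, 0.995), 2000L, 0.5)
  expect_gte(n_copd, ci[1])
  expect_lte(n_copd, ci[2])
  # membership flags are consistent with emitted codes: every member
  # carries at least one COPD code in at least one source
  uni <- synthetic_vocabulary(cfg)
  res <- find_patients_source(uni$definitions$copd, gen$bundle)
  expect_setequal(res$patients,
                  gen$manifest$membership$patient_id[
                    gen$manifest$membership$copd])
  expect_equal(length(res$patients), n_copd)
})

test_that("defect lists record the realized rate exactly", {
  gen <- generate_source(generator_config(n_patients = 400L, seed = 5L))
  m <- gen$manifest
  n_md <- length(m$defects$missing_event_date$consultation) +
    length(m$defects$missing_event_date$hospital)
  eligible <- nrow(gen$bundle$consultation) + nrow(gen$bundle$hospital)
  expect_equal(m$defect_rates_realized[["missing_event_date"]],
               n_md / eligible)
  expect_equal(m$defect_rates_realized[["inverted_observation_period"]],
               length(m$defects$inverted_observation_period) / 400)
  expect_equal(m$defect_rates_realized[["orphan_therapy_row"]],
               length(m$defects$orphan_therapy_row) /
                 nrow(gen$bundle$therapy))
  # planted rows really carry the defect
  expect_true(all(is.na(gen$bundle$consultation$event_date[
    match(m$defects$missing_event_date$consultation,
          gen$bundle$consultation$consultation_id)])))
  orphans <- gen$bundle$therapy[match(m$defects$orphan_therapy_row,
                                      gen$bundle$therapy$row_id), ]
  expect_false(any(orphans$consultation_id %in%
                     gen$bundle$consultation$consultation_id))
})

test_that("changing one defect rate does not reshuffle the others", {
  base <- generate_source(generator_config(n_patients = 300L, seed = 13L))
  rates <- c(missing_event_date = 0.02, inverted_observation_period = 0.02,
             orphan_therapy_row = 0.5, unmappable_code = 0.02,
             zero_value_entity_row = 0.02)
  other <- generate_source(generator_config(n_patients = 300L, seed = 13L,
                                            defect_rates = rates))
  expect_identical(base$manifest$defects$missing_event_date,
                   other$manifest$defects$missing_event_date)
  expect_identical(base$manifest$defects$inverted_observation_period,
                   other$manifest$defects$inverted_observation_period)
  expect_identical(base$manifest$defects$zero_value_entity_row,
                   other$manifest$defects$zero_value_entity_row)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generator_config(n_patients = 0), "n_patients")
  expect_error(generator_config(study_start = "2017-01-01",
                                study_end = "2016-01-01"), "study_start")
  expect_error(generator_config(
    phenotype_prevalences = c(hf = 1.2)), "phenotype_prevalences")
  expect_error(generator_config(
    defect_rates = c(missing_event_date = 0.5)), "defect_rates")
  expect_error(generator_config(visits_per_patient_mean = -1),
               "visits_per_patient_mean")
})

test_that("many-to-one injection records the expected incorrectly-mapped count", {
  cfg <- clean_config(n = 250L, seed = 21L)
  uni <- synthetic_vocabulary(cfg)
  gen <- generate_source(cfg, uni)
  members <- gen$manifest$membership$patient_id[gen$manifest$membership$copd]
  non_members <- setdiff(gen$bundle$patient$patient_id, members)

  # no carriers: nothing changes downstream
  inj0 <- inject_many_to_one_mapping(gen$bundle, uni$vocab, gen$manifest,
                                     "copd", n_codes = 1L, n_carriers = 0L)
  expect_equal(inj0$manifest$injected$copd$expected_incorrectly_mapped, 0L)
  expect_equal(nrow(inj0$bundle$clinical), nrow(gen$bundle$clinical))

  # carriers including true members count only the non-members
  carriers <- c(members[1:5], non_members[1:20])
  inj <- inject_many_to_one_mapping(gen$bundle, uni$vocab, gen$manifest,
                                    "copd", n_codes = 2L,
                                    carriers = carriers)
  expect_equal(inj$manifest$injected$copd$expected_incorrectly_mapped, 20L)
  # injected codes resolve into the existing COPD concept set
  defn <- translate_codelist(uni$definitions$copd, inj$vocab)
  for (cd in inj$manifest$injected$copd$codes) {
    expect_true(all(resolve(inj$vocab, cd, "READ") %in% defn$concept_set))
  }
  expect_error(inject_many_to_one_mapping(gen$bundle, uni$vocab,
                                          gen$manifest, "nonexistent"),
               "unknown phenotype")
})
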