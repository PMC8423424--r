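test_that("codelist translation collapses many-to-one and reports unmapped codes", {
  v <- tiny_vocab()
  d <- phenotype_definition("demo", "condition", "primary-care",
                            codelists = list(READ = c("A1", "A2", "A3")))
  td <- translate_codelist(d, v)
  expect_equal(td$concept_set, 4L)       # 2 mapped codes, 1 concept
  expect_equal(td$unmapped_codes$code, "A3")
  expect_false(td$untranslatable)

  d2 <- phenotype_definition("none", "condition", "primary-care",
                             codelists = list(READ = "A3"))
  expect_true(translate_codelist(d2, v)$untranslatable)

  # random codelists against a brute-force union oracle
  uni <- synthetic_vocabulary(generator_config())
  read_codes <- uni$vocab$concepts$code[
    uni$vocab$concepts$vocabulary_name == "READ"]
  for (i in 1:30) {
    set.seed(i)
    codes <- sample(read_codes, sample(3:12, 1))
    dd <- translate_codelist(
      phenotype_definition("r", "condition", "primary-care",
                           codelists = list(READ = codes)), uni$vocab)
    want <- sort(unique(unlist(lapply(codes, resolve, vocab = uni$vocab,
                                      vocabulary = "READ"))))
    expect_equal(dd$concept_set, want)
  }
})

test_that("source phenotyping unions membership across sources", {
  cfg <- clean_config(n = 200L, seed = 31L)
  uni <- synthetic_vocabulary(cfg)
  gen <- generate_source(cfg, uni)
  m <- gen$manifest$membership

  # planted prevalence recovered exactly on a defect-free bundle
  for (p in c("hf", "copd", "ami")) {
    res <- find_patients_source(uni$definitions[[p]], gen$bundle)
    expect_setequal(res$patients, m$patient_id[m[[p]]])
  }

  # membership via the death source alone
  hf_codes <- uni$definitions$hf$codelists$ICD10
  b <- gen$bundle
  extra_pat <- max(b$patient$patient_id) + 1L
  b$patient <- rbind(b$patient, data.frame(
    patient_id = extra_pat, sex = "F", year_of_birth = 1940L,
    ethnicity_code = "E1", registration_date = as.Date("2001-01-01"),
    transfer_out_date = as.Date(NA), practice_id = 1L,
    death_date = as.Date("2010-01-01")))
  dr <- b$death[0, ]
  dr[1, "patient_id"] <- extra_pat
  dr[1, "death_date"] <- as.Date("2010-01-01")
  dr[1, "cause_01"] <- hf_codes[1]
  dr[1, "deprivation_quintile"] <- 3L
  b$death <- rbind(b$death, dr)
  res <- find_patients_source(uni$definitions$hf, b)
  expect_true(extra_pat %in% res$patients)
  expect_equal(res$first_date$date[res$first_date$patient_id == extra_pat],
               as.Date("2010-01-01"))

  # an empty code list for a source contributes nothing
  d <- uni$definitions$copd
  d$codelists$ICD10 <- character()
  res_pc <- find_patients_source(d, gen$bundle)
  cl_only <- unique(gen$bundle$clinical$patient_id[
    gen$bundle$clinical$code %in% d$codelists$READ])
  expect_setequal(res_pc$patients, cl_only)
})

test_that("CDM phenotyping round-trips under a bijective vocabulary", {
  cfg <- clean_config(n = 250L, seed = 37L)
  uni <- synthetic_vocabulary(cfg)
  gen <- generate_source(cfg, uni)
  cdm <- etl_run(gen$bundle, uni$vocab)
  for (p in c("hf", "af", "ht", "loop_diuretic")) {
    d <- translate_codelist(uni$definitions[[p]], uni$vocab)
    src <- find_patients_source(d, gen$bundle)
    tgt <- find_patients_cdm(d, cdm)
    expect_setequal(tgt$patients, src$patients)
  }
  untr <- phenotype_definition("x", "condition", "primary-care",
                               codelists = list(READ = "R101"))
  expect_error(find_patients_cdm(untr, cdm), "translated")
})

test_that("many-to-one injection enlarges the CDM set by exactly the carriers", {
  cfg <- clean_config(n = 250L, seed = 41L)
  uni <- synthetic_vocabulary(cfg)
  gen <- generate_source(cfg, uni)
  inj <- inject_many_to_one_mapping(gen$bundle, uni$vocab, gen$manifest,
                                    "copd", n_codes = 2L, n_carriers = 25L,
                                    seed = 5L)
  d <- translate_codelist(uni$definitions$copd, inj$vocab)
  src <- find_patients_source(d, inj$bundle)
  cdm <- etl_run(inj$bundle, inj$vocab)
  tgt <- find_patients_cdm(d, cdm)
  carriers <- inj$manifest$injected$copd$carriers
  expect_setequal(tgt$patients, union(src$patients, carriers))
  expect_equal(length(setdiff(tgt$patients, src$patients)),
               inj$manifest$injected$copd$expected_incorrectly_mapped)
})

test_that("cohort rules enforce their boundaries exactly", {
  rules <- cohort_rules()
  periods <- data.frame(patient_id = 1:4,
                        start = as.Date("2000-01-01"),
                        end = as.Date("2012-01-01"))
  yob <- data.frame(patient_id = 1:4,
                    year_of_birth = c(1950L, 1950L, 1984L, 1983L))
  # index exactly 365 days after period start is included; 364 is not
  # (2000 is a leap year: 2000-12-31 is day 365, 2000-12-30 is day 364)
  dates <- data.frame(
    patient_id = 1:4,
    date = as.Date(c("2000-12-30", "2000-12-31", "2001-06-01",
                     "2001-06-01")))
  res <- structure(list(name = "hf", patients = 1:4, dates = dates,
                        first_date = dates), class = "phenotype_result")
  cohort <- build_hf_cohort(res, periods, yob, rules)
  expect_equal(cohort$reason[cohort$patient_id == 1],
               "insufficient-prior-registration")
  expect_true(cohort$included[cohort$patient_id == 2])
  # patient 3 is 17 at index (2001 - 1984), patient 4 is 18
  expect_equal(cohort$reason[cohort$patient_id == 3], "under-age")
  expect_true(cohort$included[cohort$patient_id == 4])
  expect_equal(cohort$follow_up_end[cohort$included][1],
               as.Date("2012-01-01"))
})

test_that("cohort construction matches per-patient oracle evaluation", {
  rules <- cohort_rules()
  for (i in 1:20) {
    set.seed(100 + i)
    n <- 40L
    periods <- data.frame(
      patient_id = sample(1:n, 35),
      start = as.Date("1996-01-01") + sample(0:3000, 35, TRUE))
    periods$end <- periods$start + sample(100:6000, 35, TRUE)
    yob <- data.frame(patient_id = 1:n,
                      year_of_birth = sample(1930:1995, n, TRUE))
    k <- sample(30:80, 1)
    dates <- data.frame(patient_id = sample(1:n, k, TRUE),
                        date = as.Date("1996-01-01") +
                          sample(0:8000, k, TRUE))
    res <- structure(list(name = "hf",
                          patients = sort(unique(dates$patient_id)),
                          dates = dates, first_date = dates),
                     class = "phenotype_result")
    got <- build_hf_cohort(res, periods, yob, rules)
    want <- oracle_cohort(dates, periods, yob, rules)
    expect_equal(got$included, want$included)
    expect_equal(got$reason, want$reason)
  }
})

test_that("biomarker summaries match the quantile oracle", {
  cohort <- data.frame(patient_id = 1:3,
                       index_date = as.Date("2005-01-01"),
                       follow_up_end = as.Date("2010-01-01"),
                       included = TRUE, reason = "included")
  vals <- data.frame(patient_id = c(1L, 2L, 3L),
                     date = as.Date("2006-01-01"), value = c(1, 2, 3))
  res <- structure(list(name = "b", patients = 1:3,
                        dates = vals[, 1:2], first_date = vals[, 1:2],
                        values = vals), class = "phenotype_result")
  s <- summarize_biomarker(res, cohort)
  expect_equal(s$median, 2); expect_equal(s$mean, 2); expect_equal(s$n, 3L)

  for (i in 1:20) {
    set.seed(200 + i)
    n <- sample(5:40, 1)
    vals <- data.frame(
      patient_id = sample(1:10, n, TRUE),
      date = as.Date("2005-01-01") + sample(-200:400, n, TRUE),
      value = round(rnorm(n, 100, 20), 1))
    res$values <- vals
    s <- summarize_biomarker(res, data.frame(
      patient_id = 1:10, index_date = as.Date("2005-01-01"),
      follow_up_end = as.Date("2010-01-01"), included = TRUE,
      reason = "included"))
    el <- vals[vals$date >= as.Date("2005-01-01"), ]
    el <- el[order(el$patient_id, el$date, el$value), ]
    first <- el$value[!duplicated(el$patient_id)]
    if (length(first)) {
      expect_equal(s$mean, mean(first), tolerance = 1e-9)
      expect_equal(s$median, unname(quantile(first, 0.5, type = 7)),
                   tolerance = 1e-9)
      expect_equal(s$iqr, unname(diff(quantile(first, c(0.25, 0.75),
                                               type = 7))),
                   tolerance = 1e-9)
      expect_equal(s$n, length(first))
    } else {
      expect_equal(s$n, 0L)
    }
  }
  expect_equal(summarize_biomarker(res, cohort[0, ])$n, 0L)
})

test_that("medication exposure percentages hit their bounds", {
  cohort <- data.frame(patient_id = 1:4, index_date = as.Date("2005-01-01"),
                       follow_up_end = as.Date("2010-01-01"),
                       included = c(TRUE, TRUE, TRUE, FALSE),
                       reason = "included")
  res <- structure(list(name = "m", patients = integer(), dates = NULL,
                        first_date = NULL), class = "phenotype_result")
  expect_equal(medication_flag(res, cohort), 0)
  res$patients <- 1:3
  expect_equal(medication_flag(res, cohort), 100)
  res$patients <- c(1L, 99L)
  expect_equal(medication_flag(res, cohort), 33.3)
})
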