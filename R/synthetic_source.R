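# Synthetic three-source EHR bundle generator. Emulates the table shapes
# of a linked UK primary-care / hospitalisation / mortality extract:
# Read-like codes in primary care, ICD-like discharge diagnoses (20
# slots) and OPCS-like procedures in hospital spells, cause-of-death
# codes (underlying + up to 14 secondary) with a deprivation quintile in
# the mortality register, prescriptions under a Gemscript-like code
# system, and wide entity-type laboratory/examination rows with eight
# value slots. Code systems are structurally realistic but fully
# self-contained; no licensed vocabulary is used or required.

CONDITION_PHENOTYPES <- c("hf", "af", "copd", "t2dm", "ami", "ht", "cancer")
MEDICATION_PHENOTYPES <- c("loop_diuretic", "ace_inhibitor", "beta_blocker")
LIFESTYLE_PHENOTYPES <- c("smoker", "never_smoker")

#' Generator configuration
#'
#' Defaults mirror the within-cohort frequencies of a national
#' heart-failure population: comorbidity prevalences (AF 0.35, COPD 0.50,
#' type-2 diabetes 0.24, AMI 0.20, hypertension 0.66, cancer 0.27),
#' medication exposure (loop diuretics 0.42, ACE inhibitors 0.50,
#' beta-blockers 0.48), smoking mix (65% smoker / 31% never), 52.4%
#' female, 90.8% recorded as the majority ethnic group, and a 0.35%
#' primary-care/hospital ethnicity disagreement rate. Heart failure
#' itself is planted at 0.30 so the cohort is sizeable at desk scale.
#'
#' @param n_patients number of patients (>= 1).
#' @param study_start,study_end ISO dates bounding the study window.
#' @param phenotype_prevalences named fractions in `[0,1]`, one per
#'   condition/medication/lifestyle phenotype.
#' @param codes_per_phenotype codes per terminology per phenotype.
#' @param defect_rates named fractions for the five planted defect modes:
#'   `missing_event_date`, `inverted_observation_period`,
#'   `orphan_therapy_row`, `unmappable_code`, `zero_value_entity_row`.
#' @param visits_per_patient_mean mean primary-care consultations per
#'   patient (>= 2 enforced per patient).
#' @param ethnicity_disagreement_rate fraction of hospital rows whose
#'   ethnicity disagrees with the primary-care record.
#' @param seed integer RNG seed.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 2000L,
    study_start = "2000-01-01",
    study_end = "2016-03-08",
    phenotype_prevalences = c(
      hf = 0.30, af = 0.35, copd = 0.50, t2dm = 0.24, ami = 0.20,
      ht = 0.66, cancer = 0.27,
      loop_diuretic = 0.42, ace_inhibitor = 0.50, beta_blocker = 0.48,
      smoker = 0.52, never_smoker = 0.31),
    codes_per_phenotype = 4L,
    defect_rates = c(missing_event_date = 0.02,
                     inverted_observation_period = 0.02,
                     orphan_therapy_row = 0.02,
                     unmappable_code = 0.02,
                     zero_value_entity_row = 0.02),
    visits_per_patient_mean = 8,
    ethnicity_disagreement_rate = 0.0035,
    seed = 1L) {
  fail <- function(field, why) {
    stop("invalid generator configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  if (!is.numeric(n_patients) || n_patients < 1) fail("n_patients", "must be >= 1")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (is.na(study_start)) fail("study_start", "is not a date")
  if (is.na(study_end)) fail("study_end", "is not a date")
  if (!(study_start < study_end)) fail("study_start", "must precede study_end")
  if (is.null(names(phenotype_prevalences)) ||
      any(names(phenotype_prevalences) == "")) {
    fail("phenotype_prevalences", "must be a named vector")
  }
  if (any(phenotype_prevalences < 0 | phenotype_prevalences > 1)) {
    fail("phenotype_prevalences", "must lie in [0,1]")
  }
  need <- c("missing_event_date", "inverted_observation_period",
            "orphan_therapy_row", "unmappable_code", "zero_value_entity_row")
  if (!all(need %in% names(defect_rates))) {
    fail("defect_rates", paste("must name all of:", paste(need, collapse = ", ")))
  }
  if (any(defect_rates < 0 | defect_rates > 1)) {
    fail("defect_rates", "must lie in [0,1]")
  }
  if (!is.numeric(visits_per_patient_mean) || visits_per_patient_mean <= 0) {
    fail("visits_per_patient_mean", "must be positive")
  }
  if (ethnicity_disagreement_rate < 0 || ethnicity_disagreement_rate > 1) {
    fail("ethnicity_disagreement_rate", "must lie in [0,1]")
  }
  if (!is.numeric(seed) || is.na(seed)) fail("seed", "must be an integer")
  structure(list(
    n_patients = as.integer(n_patients),
    study_start = study_start, study_end = study_end,
    phenotype_prevalences = phenotype_prevalences,
    codes_per_phenotype = as.integer(codes_per_phenotype),
    defect_rates = defect_rates[need],
    visits_per_patient_mean = visits_per_patient_mean,
    ethnicity_disagreement_rate = ethnicity_disagreement_rate,
    seed = as.integer(seed)), class = "generator_config")
}

# Deterministic synthetic code universe: phenotype code lists, the
# vocabulary store mapping them (bijectively by default, so that the
# source->CDM round trip is exact unless many-to-one mappings are
# injected), and executable phenotype definitions.
#' Build the synthetic vocabulary bundle and phenotype definitions
#'
#' Deterministic (no randomness): each phenotype receives
#' `codes_per_phenotype` Read-like and ICD-like codes, each mapped to
#' its own standard concept; prescriptions map through a complete
#' two-hop chain (Gemscript-like -> drug-dictionary -> standard drug
#' concept). The vocabulary additionally carries unused unmapped terms
#' and broken drug chains so term coverage differs from event coverage,
#' as in real extracts.
#'
#' @param config a [generator_config].
#' @return list with elements `vocab` (a [vocabulary_store]) and
#'   `definitions` (named list of [phenotype_definition]s).
#' @export
synthetic_vocabulary <- function(config = generator_config()) {
  K <- config$codes_per_phenotype
  concepts <- list(); edges <- list(); defs <- list()
  next_id <- 1000L
  new_concept <- function(code, vocabulary, domain, standard) {
    id <- next_id; next_id <<- next_id + 1L
    concepts[[length(concepts) + 1L]] <<- data.frame(
      concept_id = id, code = code, vocabulary_name = vocabulary,
      domain = domain, standard = as.integer(standard),
      stringsAsFactors = FALSE)
    id
  }
  add_edge <- function(code, vocabulary, target, rel = "maps-to") {
    edges[[length(edges) + 1L]] <<- data.frame(
      edge_id = length(edges) + 1L, source_code = code,
      source_vocabulary = vocabulary, target_concept_id = target,
      relationship = rel, stringsAsFactors = FALSE)
  }
  map_codes <- function(codes, vocabulary, domain) {
    vapply(codes, function(cd) {
      new_concept(cd, vocabulary, NA_character_, 0L)
      std <- new_concept(paste0("STD-", cd), "SNOMED", domain, 1L)
      add_edge(cd, vocabulary, std)
      std
    }, integer(1L))
  }

  read_lists <- list(); icd_lists <- list()
  for (i in seq_along(CONDITION_PHENOTYPES)) {
    p <- CONDITION_PHENOTYPES[i]
    read_lists[[p]] <- sprintf("R%d%02d", i, seq_len(K))
    icd_lists[[p]] <- sprintf("I%d%02d", i, seq_len(K))
    map_codes(read_lists[[p]], "READ", "condition")
    map_codes(icd_lists[[p]], "ICD10", "condition")
  }
  bg_read <- sprintf("RB%02d", 1:10)
  bg_icd <- sprintf("IB%02d", 1:5)
  map_codes(bg_read, "READ", "condition")
  map_codes(bg_icd, "ICD10", "condition")
  # vocabulary-only unmapped terms (term coverage < 100%)
  for (cd in sprintf("RU%02d", 1:5)) new_concept(cd, "READ", NA_character_, 0L)
  for (cd in sprintf("IU%02d", 1:3)) new_concept(cd, "ICD10", NA_character_, 0L)

  opcs <- sprintf("P%02d", 1:5)
  map_codes(opcs, "OPCS4", "procedure")
  new_concept("PU1", "OPCS4", NA_character_, 0L)

  smoking_codes <- c(smoker = "RS1", ex_smoker = "RS2", never_smoker = "RS3")
  for (cd in smoking_codes) {
    new_concept(cd, "READ", NA_character_, 0L)
    std <- new_concept(paste0("STD-", cd), "SNOMED", "observation", 1L)
    add_edge(cd, "READ", std)
  }

  gems_lists <- list()
  for (j in seq_along(MEDICATION_PHENOTYPES)) {
    p <- MEDICATION_PHENOTYPES[j]
    gems_lists[[p]] <- sprintf("G%d%02d", j, seq_len(K))
    for (cd in gems_lists[[p]]) {
      new_concept(cd, "GEMSCRIPT", NA_character_, 0L)
      dmd_code <- paste0("D-", cd)
      dmd_id <- new_concept(dmd_code, "DMD", NA_character_, 0L)
      std <- new_concept(paste0("RX-", cd), "RXNORM", "drug", 1L)
      add_edge(cd, "GEMSCRIPT", dmd_id, rel = "translates-to")
      add_edge(dmd_code, "DMD", std)
    }
  }
  # broken chains: first hop only (no dictionary->standard mapping)
  for (cd in sprintf("GX%02d", 1:3)) {
    new_concept(cd, "GEMSCRIPT", NA_character_, 0L)
    dmd_id <- new_concept(paste0("D-", cd), "DMD", NA_character_, 0L)
    add_edge(cd, "GEMSCRIPT", dmd_id, rel = "translates-to")
  }
  for (cd in sprintf("GZ%02d", 1:2)) new_concept(cd, "GEMSCRIPT", NA_character_, 0L)

  loinc <- function(what) new_concept(paste0("LN-", what), "LOINC",
                                      "measurement", 1L)
  dbp_id <- loinc("dbp"); sbp_id <- loinc("sbp"); bmi_id <- loinc("bmi")
  lab_id <- loinc("lab467")
  efm <- data.frame(
    map_id = 1:6,
    entity_type_id = c(1L, 1L, 1L, 13L, 467L, 467L),
    field_index = c(1L, 2L, 3L, 1L, 1L, 2L),
    target_concept_id = c(dbp_id, sbp_id, NA_integer_, bmi_id, lab_id,
                          NA_integer_),
    value_semantics = c("numeric", "numeric", "coded", "numeric",
                        "ignore-zero", "coded"),
    stringsAsFactors = FALSE)

  mmhg <- new_concept("mmHg", "UCUM", "unit", 1L)
  kgm2 <- new_concept("kg/m2", "UCUM", "unit", 1L)
  new_concept("U-arb", "UNIT", NA_character_, 0L)
  new_concept("U-mmHg", "UNIT", NA_character_, 0L)
  new_concept("U-kgm2", "UNIT", NA_character_, 0L)
  unit_map <- data.frame(unit_id = 1:2, unit_code = c("U-mmHg", "U-kgm2"),
                         target_concept_id = c(mmhg, kgm2),
                         stringsAsFactors = FALSE)

  vocab <- vocabulary_store(do.call(rbind, concepts), do.call(rbind, edges),
                            efm, unit_map)

  for (p in CONDITION_PHENOTYPES) {
    srcs <- if (p == "hf") c("primary-care", "hospital", "death") else
      c("primary-care", "hospital")
    defs[[p]] <- phenotype_definition(
      p, kind = "condition", sources = srcs,
      codelists = list(READ = read_lists[[p]], ICD10 = icd_lists[[p]]))
  }
  for (p in MEDICATION_PHENOTYPES) {
    defs[[p]] <- phenotype_definition(
      p, kind = "medication-class", sources = "primary-care",
      codelists = list(GEMSCRIPT = gems_lists[[p]]))
  }
  defs$smoker <- phenotype_definition(
    "smoker", kind = "lifestyle", sources = "primary-care",
    codelists = list(READ = unname(smoking_codes["smoker"])),
    status_universe = unname(smoking_codes))
  defs$never_smoker <- phenotype_definition(
    "never_smoker", kind = "lifestyle", sources = "primary-care",
    codelists = list(READ = unname(smoking_codes["never_smoker"])),
    status_universe = unname(smoking_codes))
  defs$sbp <- phenotype_definition(
    "sbp", kind = "biomarker", sources = "primary-care",
    entity_fields = data.frame(entity_type_id = 1L, field_index = 2L))
  defs$dbp <- phenotype_definition(
    "dbp", kind = "biomarker", sources = "primary-care",
    entity_fields = data.frame(entity_type_id = 1L, field_index = 1L))
  defs$bmi <- phenotype_definition(
    "bmi", kind = "biomarker", sources = "primary-care",
    entity_fields = data.frame(entity_type_id = 13L, field_index = 1L))

  list(vocab = vocab, definitions = defs,
       codebook = list(read = read_lists, icd = icd_lists,
                       gemscript = gems_lists, background_read = bg_read,
                       background_icd = bg_icd, opcs = opcs,
                       smoking = smoking_codes))
}

rdate <- function(n, from, to) {
  span <- pmax(as.integer(to) - as.integer(from), 0L)
  from + floor(stats::runif(n) * (span + 1L))
}

# dedicated, isolable random stream per defect type
defect_seed <- function(seed, k) (abs(seed) %% 100000L) * 13L + k * 1009L

#' Generate a synthetic source bundle with ground truth
#'
#' Draws per-patient phenotype membership by independent Bernoulli
#' trials at the configured prevalences; every member carries at least
#' one phenotype code in primary care (and possibly hospital or death
#' records). Data-quality defects are then planted by row-level
#' Bernoulli draws from a dedicated random stream per defect type, so
#' changing one rate does not reshuffle the others. All affected row
#' identifiers, membership flags and realized rates are recorded in the
#' returned manifest. Deterministic for a fixed config (byte-identical
#' bundles on repeat runs).
#'
#' @param config a [generator_config].
#' @param universe code universe from [synthetic_vocabulary()]; defaults
#'   to the universe implied by `config`.
#' @return list with `bundle` (class `source_bundle`) and `manifest`
#'   (class `ground_truth_manifest`).
#' @export
generate_source <- function(config = generator_config(),
                            universe = synthetic_vocabulary(config)) {
  stopifnot(inherits(config, "generator_config"))
  cb <- universe$codebook
  n <- config$n_patients
  prev <- config$phenotype_prevalences
  set.seed(config$seed)

  n_practices <- max(2L, ceiling(n / 500))
  practice <- data.frame(
    practice_id = seq_len(n_practices),
    up_to_standard_date = rdate(n_practices, config$study_start - 730,
                                config$study_start),
    last_collection_date = rdate(n_practices, config$study_end - 180,
                                 config$study_end),
    stringsAsFactors = FALSE)

  reg <- rdate(n, config$study_start, config$study_end - 1095)
  yob <- sample(1915:1975, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.524, 0.476))
  eth <- sample(paste0("E", 1:5), n, replace = TRUE,
                prob = c(0.908, 0.04, 0.03, 0.015, 0.007))
  has_transfer <- stats::runif(n) < 0.08
  transfer <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  transfer[has_transfer] <- rdate(sum(has_transfer), reg[has_transfer] + 730,
                                  config$study_end)
  # guard against empty windows patient by patient
  transfer[has_transfer & transfer < reg] <- NA

  dies <- stats::runif(n) < 0.25
  death_date <- as.Date(rep(NA_real_, n), origin = "1970-01-01")
  lo <- reg + 365
  ok <- dies & lo < config$study_end
  death_date[ok] <- rdate(sum(ok), lo[ok], config$study_end)

  patient <- data.frame(
    patient_id = seq_len(n), sex = sex, year_of_birth = yob,
    ethnicity_code = eth, registration_date = reg,
    transfer_out_date = transfer,
    practice_id = rep_len(seq_len(n_practices), n),
    death_date = death_date, stringsAsFactors = FALSE)

  # phenotype membership
  membership <- data.frame(patient_id = seq_len(n))
  for (p in intersect(names(prev), c(CONDITION_PHENOTYPES,
                                     MEDICATION_PHENOTYPES))) {
    membership[[p]] <- stats::runif(n) < prev[[p]]
  }
  u <- stats::runif(n)
  p_smoke <- if ("smoker" %in% names(prev)) prev[["smoker"]] else 0
  p_never <- if ("never_smoker" %in% names(prev)) prev[["never_smoker"]] else 0
  smoking_status <- ifelse(u < p_smoke, "smoker",
                           ifelse(u < p_smoke + p_never, "never_smoker",
                                  "ex_smoker"))
  if ("smoker" %in% names(prev)) membership$smoker <- smoking_status == "smoker"
  if ("never_smoker" %in% names(prev)) {
    membership$never_smoker <- smoking_status == "never_smoker"
  }

  upper <- pmin(death_date, config$study_end, na.rm = TRUE)
  upper <- pmax(upper, reg)

  # consultations
  k_cons <- 2L + stats::rpois(n, max(config$visits_per_patient_mean - 2, 0.1))
  cons_pat <- rep(seq_len(n), k_cons)
  consultation <- data.frame(
    consultation_id = seq_along(cons_pat), patient_id = cons_pat,
    event_date = rdate(length(cons_pat), reg[cons_pat], upper[cons_pat]),
    stringsAsFactors = FALSE)
  cons_idx_by_pat <- split(seq_len(nrow(consultation)), consultation$patient_id)
  pick_cons <- function(patids) {
    vapply(as.character(patids), function(p) {
      pool <- cons_idx_by_pat[[p]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1L), USE.NAMES = FALSE)
  }

  # clinical rows: phenotype codes + background + smoking status
  cl_pat <- integer(); cl_code <- character()
  for (p in intersect(names(prev), CONDITION_PHENOTYPES)) {
    members <- which(membership[[p]])
    if (!length(members)) next
    k <- 1L + stats::rpois(length(members), 0.5)
    pats <- rep(members, k)
    cl_pat <- c(cl_pat, pats)
    cl_code <- c(cl_code, sample(cb$read[[p]], length(pats), replace = TRUE))
  }
  bg_k <- stats::rpois(n, 2)
  bg_pats <- rep(seq_len(n), bg_k)
  cl_pat <- c(cl_pat, bg_pats)
  cl_code <- c(cl_code, sample(cb$background_read, length(bg_pats),
                               replace = TRUE))
  bg_row_flag <- c(rep(FALSE, length(cl_pat) - length(bg_pats)),
                   rep(TRUE, length(bg_pats)))
  smoke_code <- cb$smoking[smoking_status]
  cl_pat <- c(cl_pat, seq_len(n))
  cl_code <- c(cl_code, unname(smoke_code))
  bg_row_flag <- c(bg_row_flag, rep(FALSE, n))
  cl_cons <- pick_cons(cl_pat)
  clinical <- data.frame(
    row_id = seq_along(cl_pat), patient_id = cl_pat,
    consultation_id = consultation$consultation_id[cl_cons],
    event_date = consultation$event_date[cl_cons],
    code = cl_code, stringsAsFactors = FALSE)

  # therapy rows
  th_pat <- integer(); th_code <- character()
  for (p in intersect(names(prev), MEDICATION_PHENOTYPES)) {
    members <- which(membership[[p]])
    if (!length(members)) next
    k <- 1L + stats::rpois(length(members), 1.5)
    pats <- rep(members, k)
    th_pat <- c(th_pat, pats)
    th_code <- c(th_code, sample(cb$gemscript[[p]], length(pats),
                                 replace = TRUE))
  }
  th_cons <- pick_cons(th_pat)
  therapy <- data.frame(
    row_id = seq_along(th_pat), patient_id = th_pat,
    consultation_id = consultation$consultation_id[th_cons],
    event_date = consultation$event_date[th_cons],
    drug_code = th_code, stringsAsFactors = FALSE)

  # test rows: blood pressure (entity 1, fields 1=DBP 2=SBP) and BMI (13)
  entity_row <- function(pat, entity, v1, v2, unit) {
    out <- data.frame(row_id = NA_integer_, patient_id = pat,
                      event_date = as.Date(NA), entity_type_id = entity,
                      stringsAsFactors = FALSE)
    for (i in 1:8) out[[paste0("value_", i)]] <- NA_character_
    out$value_1 <- v1
    if (!is.null(v2)) out$value_2 <- v2
    out$unit_code <- unit
    out
  }
  n_bp <- 1L + stats::rpois(n, 1)
  bp_pat <- rep(seq_len(n), n_bp)
  bp <- entity_row(bp_pat, 1L,
                   sprintf("%.1f", stats::rnorm(length(bp_pat), 80.05, 12.19)),
                   sprintf("%.1f", stats::rnorm(length(bp_pat), 143.07, 22.42)),
                   "U-mmHg")
  n_bmi <- 1L + stats::rpois(n, 0.5)
  bmi_pat <- rep(seq_len(n), n_bmi)
  bmi <- entity_row(bmi_pat, 13L,
                    sprintf("%.1f", stats::rnorm(length(bmi_pat), 28.9, 6.44)),
                    NULL, "U-kgm2")
  test <- rbind(bp, bmi)
  test$row_id <- seq_len(nrow(test))
  tcons <- pick_cons(test$patient_id)
  test$event_date <- consultation$event_date[tcons]

  # additional rows: miscellaneous lab entity with ignore-zero semantics
  has_lab <- which(stats::runif(n) < 0.3)
  additional <- entity_row(has_lab, 467L,
                           sprintf("%.1f", stats::runif(length(has_lab), 1, 100)),
                           NULL, NA_character_)
  additional$row_id <- seq_len(nrow(additional))
  if (nrow(additional)) {
    acons <- pick_cons(additional$patient_id)
    additional$event_date <- consultation$event_date[acons]
  }

  # hospital spells
  cond_names <- intersect(names(prev), CONDITION_PHENOTYPES)
  any_cond <- Reduce(`|`, lapply(cond_names, function(p) membership[[p]]),
                     rep(FALSE, n))
  p_hosp <- ifelse(any_cond, 0.6, 0.15)
  has_spell <- stats::runif(n) < p_hosp
  sp_pat <- which(has_spell)
  hospital <- data.frame(spell_id = seq_along(sp_pat), patient_id = sp_pat,
                         admission_date = rdate(length(sp_pat), reg[sp_pat],
                                                upper[sp_pat]),
                         stringsAsFactors = FALSE)
  for (i in 1:20) hospital[[sprintf("diag_%02d", i)]] <- NA_character_
  for (i in 1:4) hospital[[sprintf("proc_%02d", i)]] <- NA_character_
  hospital$ethnicity_code <- eth[sp_pat]
  for (r in seq_len(nrow(hospital))) {
    pt <- hospital$patient_id[r]
    own <- cond_names[vapply(cond_names, function(p) membership[[p]][pt], TRUE)]
    codes <- if (length(own)) {
      vapply(own, function(p) sample(cb$icd[[p]], 1L), "")
    } else {
      sample(cb$background_icd, 1L)
    }
    keep <- c(codes[1L], codes[-1L][stats::runif(length(codes) - 1L) < 0.5])
    keep <- utils::head(keep, 20L)
    hospital[r, sprintf("diag_%02d", seq_along(keep))] <- keep
    if (stats::runif(1) < 0.3) {
      hospital[r, "proc_01"] <- sample(cb$opcs, 1L)
    }
  }

  # mortality register
  dec <- which(!is.na(death_date))
  death <- data.frame(patient_id = dec, death_date = death_date[dec],
                      stringsAsFactors = FALSE)
  hf_member <- if ("hf" %in% names(membership)) membership$hf else
    rep(FALSE, n)
  death$cause_01 <- vapply(dec, function(pt) {
    if (hf_member[pt] && stats::runif(1) < 0.6) sample(cb$icd$hf, 1L) else
      sample(cb$background_icd, 1L)
  }, "")
  for (i in 2:15) death[[sprintf("cause_%02d", i)]] <- NA_character_
  for (r in seq_len(nrow(death))) {
    k <- stats::rpois(1, 1)
    if (k > 0) {
      pool <- c(cb$background_icd, unlist(lapply(cond_names, function(p) {
        if (membership[[p]][death$patient_id[r]]) cb$icd[[p]] else character()
      })))
      sec <- sample(pool, min(k, 14L), replace = TRUE)
      death[r, sprintf("cause_%02d", seq_along(sec) + 1L)] <- sec
    }
  }
  death$deprivation_quintile <- sample(1:5, nrow(death), replace = TRUE,
                                       prob = c(0.22, 0.21, 0.21, 0.2082,
                                                0.1518))

  bundle <- structure(list(
    patient = patient, practice = practice, consultation = consultation,
    clinical = clinical, therapy = therapy, test = test,
    additional = additional, hospital = hospital, death = death,
    study_start = config$study_start, study_end = config$study_end),
    class = "source_bundle")

  # ---- planted defects, one isolated stream per defect type ----
  rates <- config$defect_rates
  defects <- list()
  realized <- c()
  draw <- function(k, n_eligible, rate) {
    set.seed(defect_seed(config$seed, k))
    which(stats::runif(n_eligible) < rate)
  }

  idx <- draw(1L, nrow(bundle$consultation) + nrow(bundle$hospital),
              rates[["missing_event_date"]])
  n_cons <- nrow(bundle$consultation)
  cons_hit <- idx[idx <= n_cons]
  hosp_hit <- idx[idx > n_cons] - n_cons
  bundle$consultation$event_date[cons_hit] <- as.Date(NA)
  bundle$hospital$admission_date[hosp_hit] <- as.Date(NA)
  defects$missing_event_date <- list(
    consultation = bundle$consultation$consultation_id[cons_hit],
    hospital = bundle$hospital$spell_id[hosp_hit])
  realized["missing_event_date"] <-
    length(idx) / (nrow(bundle$consultation) + nrow(bundle$hospital))

  idx <- draw(2L, n, rates[["inverted_observation_period"]])
  bundle$patient$transfer_out_date[idx] <-
    bundle$patient$registration_date[idx] - 30
  defects$inverted_observation_period <- bundle$patient$patient_id[idx]
  realized["inverted_observation_period"] <- length(idx) / n

  idx <- draw(3L, nrow(bundle$therapy), rates[["orphan_therapy_row"]])
  bundle$therapy$consultation_id[idx] <- 900000L + bundle$therapy$row_id[idx]
  defects$orphan_therapy_row <- bundle$therapy$row_id[idx]
  realized["orphan_therapy_row"] <-
    if (nrow(bundle$therapy)) length(idx) / nrow(bundle$therapy) else 0

  # only background rows are made unmappable, so membership flags stay
  # consistent with the emitted phenotype codes
  eligible <- which(bg_row_flag)
  idx <- draw(4L, length(eligible), rates[["unmappable_code"]])
  hit <- eligible[idx]
  bundle$clinical$code[hit] <- paste0("ZZ", bundle$clinical$row_id[hit])
  defects$unmappable_code <- bundle$clinical$row_id[hit]
  realized["unmappable_code"] <-
    if (length(eligible)) length(idx) / length(eligible) else 0

  idx <- draw(5L, nrow(bundle$additional), rates[["zero_value_entity_row"]])
  bundle$additional$value_1[idx] <- "0"
  defects$zero_value_entity_row <- bundle$additional$row_id[idx]
  realized["zero_value_entity_row"] <-
    if (nrow(bundle$additional)) length(idx) / nrow(bundle$additional) else 0

  idx <- draw(6L, nrow(bundle$hospital), config$ethnicity_disagreement_rate)
  if (length(idx)) {
    cur <- bundle$hospital$ethnicity_code[idx]
    bundle$hospital$ethnicity_code[idx] <- ifelse(cur == "E1", "E2", "E1")
  }
  defects$ethnicity_disagreement <- bundle$hospital$spell_id[idx]

  true_prev <- vapply(setdiff(names(membership), "patient_id"),
                      function(p) mean(membership[[p]]), 0)
  manifest <- structure(list(
    membership = membership, true_prevalence = true_prev,
    defects = defects, defect_rates_realized = realized,
    injected = list()), class = "ground_truth_manifest")

  list(bundle = bundle, manifest = manifest)
}

#' @export
print.source_bundle <- function(x, ...) {
  tabs <- setdiff(names(x), c("study_start", "study_end"))
  cat("<source_bundle>\n")
  for (t in tabs) cat(sprintf("  %-13s %6d rows\n", t, nrow(x[[t]])))
  invisible(x)
}

#' Inject many-to-one code mappings and their carriers
#'
#' Emulates the dominant source of "incorrectly mapped" patients: source
#' codes outside a phenotyping algorithm's code list that nevertheless
#' map to a concept inside the phenotype's translated concept set. Adds
#' `n_codes` new Read-like codes mapping onto an existing concept of the
#' phenotype and emits one primary-care row per carrier. Carriers are
#' sampled among non-members unless given explicitly; the count of
#' carriers that are not true members is recorded in the manifest as the
#' expected incorrectly-mapped count.
#'
#' @param bundle a `source_bundle`.
#' @param vocab the matching [vocabulary_store].
#' @param manifest the matching `ground_truth_manifest`.
#' @param phenotype phenotype name (must have Read-like codes in `vocab`).
#' @param n_codes number of extra codes to create.
#' @param n_carriers number of patients to emit the codes for.
#' @param carriers optional explicit patient ids (overrides `n_carriers`).
#' @param seed RNG seed for carrier sampling.
#' @return list with updated `bundle`, `vocab`, `manifest`.
#' @export
inject_many_to_one_mapping <- function(bundle, vocab, manifest, phenotype,
                                       n_codes = 2L, n_carriers = 25L,
                                       carriers = NULL, seed = 1L) {
  if (!phenotype %in% names(manifest$membership)) {
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  }
  i <- match(phenotype, CONDITION_PHENOTYPES)
  base_code <- sprintf("R%d01", i)
  target <- resolve(vocab, base_code, "READ")
  if (!length(target)) {
    stop("phenotype '", phenotype, "' has no mapped codes in vocabulary",
         call. = FALSE)
  }
  target <- target[1L]
  set.seed(seed)
  members <- manifest$membership$patient_id[manifest$membership[[phenotype]]]
  if (is.null(carriers)) {
    pool <- setdiff(bundle$patient$patient_id, members)
    carriers <- sort(sample(pool, min(n_carriers, length(pool))))
  }
  new_codes <- sprintf("RMO-%s-%02d", phenotype, seq_len(n_codes))
  next_id <- max(vocab$concepts$concept_id) + 1L
  add_con <- data.frame(concept_id = next_id + seq_len(n_codes) - 1L,
                        code = new_codes, vocabulary_name = "READ",
                        domain = NA_character_, standard = 0L,
                        stringsAsFactors = FALSE)
  add_edges <- data.frame(edge_id = max(vocab$edges$edge_id) +
                            seq_len(n_codes),
                          source_code = new_codes,
                          source_vocabulary = "READ",
                          target_concept_id = target,
                          relationship = "maps-to", stringsAsFactors = FALSE)
  vocab <- vocabulary_store(rbind(vocab$concepts, add_con),
                            rbind(vocab$edges, add_edges),
                            vocab$entity_field_map, vocab$unit_map)
  if (length(carriers)) {
    cons <- bundle$consultation[!is.na(bundle$consultation$event_date), ,
                                drop = FALSE]
    pick <- vapply(carriers, function(p) {
      pool <- which(cons$patient_id == p)
      if (!length(pool)) NA_integer_ else pool[sample.int(length(pool), 1L)]
    }, integer(1L))
    if (anyNA(pick)) {
      stop("carrier without a dated consultation; cannot emit code",
           call. = FALSE)
    }
    new_rows <- data.frame(
      row_id = max(bundle$clinical$row_id) + seq_along(carriers),
      patient_id = carriers,
      consultation_id = cons$consultation_id[pick],
      event_date = cons$event_date[pick],
      code = rep_len(new_codes, length(carriers)),
      stringsAsFactors = FALSE)
    bundle$clinical <- rbind(bundle$clinical, new_rows)
  }
  expected <- length(setdiff(carriers, members))
  manifest$injected[[phenotype]] <- list(
    codes = new_codes, carriers = carriers,
    expected_incorrectly_mapped = expected)
  list(bundle = bundle, vocab = vocab, manifest = manifest)
}

SOURCE_TABLE_FILES <- c(patient = "patient.csv", practice = "practice.csv",
                        consultation = "consultation.csv",
                        clinical = "clinical.csv", therapy = "therapy.csv",
                        test = "test.csv", additional = "additional.csv",
                        hospital = "hospital.csv", death = "death.csv")

#' Write a source bundle as one CSV per table
#' @param bundle a `source_bundle`.
#' @param dir output directory (created if absent).
#' @export
write_source_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- bundle_schemas()
  for (t in names(SOURCE_TABLE_FILES)) {
    write_table(bundle[[t]], file.path(dir, SOURCE_TABLE_FILES[[t]]), s[[t]])
  }
  meta <- data.frame(key = c("study_start", "study_end"),
                     value = c(format(bundle$study_start),
                               format(bundle$study_end)))
  utils::write.csv(meta, file.path(dir, "bundle_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a source bundle from disk
#' @param dir directory written by [write_source_bundle()].
#' @return a `source_bundle`.
#' @export
read_source_bundle <- function(dir) {
  s <- bundle_schemas()
  out <- lapply(names(SOURCE_TABLE_FILES), function(t) {
    read_table(file.path(dir, SOURCE_TABLE_FILES[[t]]), s[[t]])
  })
  names(out) <- names(SOURCE_TABLE_FILES)
  meta_path <- file.path(dir, "bundle_meta.csv")
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, colClasses = "character")
    out$study_start <- as.Date(meta$value[meta$key == "study_start"])
    out$study_end <- as.Date(meta$value[meta$key == "study_end"])
  }
  structure(out, class = "source_bundle")
}

#' Write a ground-truth manifest as JSON
#' @param manifest a `ground_truth_manifest`.
#' @param path output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}
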