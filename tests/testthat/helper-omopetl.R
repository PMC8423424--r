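# Shared fixtures and independent brute-force oracles.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

zero_defects <- c(missing_event_date = 0, inverted_observation_period = 0,
                  orphan_therapy_row = 0, unmappable_code = 0,
                  zero_value_entity_row = 0)

clean_config <- function(n = 300L, seed = 1L, ...) {
  generator_config(n_patients = n, seed = seed, defect_rates = zero_defects,
                   ethnicity_disagreement_rate = 0, ...)
}

# minimal hand-built vocabulary: two Read codes onto one concept
# (many-to-one), one unmapped Read code, one complete and one broken
# drug chain, a blood-pressure-like entity type
tiny_vocab <- function() {
  concepts <- data.frame(
    concept_id = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L),
    code = c("A1", "A2", "A3", "STD-A", "STD-B", "G1", "D-G1", "RX-G1",
             "G2", "D-G2", "LN-sbp", "I1"),
    vocabulary_name = c("READ", "READ", "READ", "SNOMED", "SNOMED",
                        "GEMSCRIPT", "DMD", "RXNORM", "GEMSCRIPT", "DMD",
                        "LOINC", "ICD10"),
    domain = c(NA, NA, NA, "condition", "condition", NA, NA, "drug", NA,
               NA, "measurement", NA),
    standard = c(0L, 0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    edge_id = 1:6,
    source_code = c("A1", "A2", "G1", "D-G1", "G2", "I1"),
    source_vocabulary = c("READ", "READ", "GEMSCRIPT", "DMD", "GEMSCRIPT",
                          "ICD10"),
    target_concept_id = c(4L, 4L, 7L, 8L, 10L, 5L),
    relationship = c("maps-to", "maps-to", "translates-to", "maps-to",
                     "translates-to", "maps-to"),
    stringsAsFactors = FALSE)
  efm <- data.frame(map_id = 1:3, entity_type_id = c(1L, 1L, 9L),
                    field_index = c(1L, 2L, 1L),
                    target_concept_id = c(11L, NA, 11L),
                    value_semantics = c("numeric", "coded", "ignore-zero"),
                    stringsAsFactors = FALSE)
  um <- data.frame(unit_id = 1L, unit_code = "U-mmHg",
                   target_concept_id = 11L, stringsAsFactors = FALSE)
  vocabulary_store(concepts, edges, efm, um)
}

# ---- independent oracles -------------------------------------------------

# brute-force interval merging for drug eras
oracle_eras <- function(dates, gap, duration) {
  dates <- sort(dates)
  eras <- list()
  cur <- c(dates[1], dates[1]); n_exp <- 1L
  for (d in dates[-1]) {
    d <- as.Date(d, origin = "1970-01-01")
    if (as.integer(d - cur[2]) <= gap) {
      cur[2] <- d; n_exp <- n_exp + 1L
    } else {
      eras[[length(eras) + 1L]] <- list(start = cur[1], last = cur[2],
                                        n = n_exp)
      cur <- c(d, d); n_exp <- 1L
    }
  }
  eras[[length(eras) + 1L]] <- list(start = cur[1], last = cur[2], n = n_exp)
  data.frame(start = as.Date(vapply(eras, function(e) as.numeric(e$start), 0),
                             origin = "1970-01-01"),
             end = as.Date(vapply(eras, function(e) as.numeric(e$last), 0),
                           origin = "1970-01-01") + duration,
             n = vapply(eras, function(e) as.integer(e$n), 0L))
}

# element-by-element set algebra for concordance
oracle_set_diffs <- function(a, b) {
  a <- unique(a); b <- unique(b)
  unmapped <- 0L; incorrect <- 0L
  for (x in a) if (!any(b == x)) unmapped <- unmapped + 1L
  for (x in b) if (!any(a == x)) incorrect <- incorrect + 1L
  list(unmapped = unmapped, incorrect = incorrect)
}

# direct counting for coverage columns
oracle_coverage <- function(codes, excluded, terms, mapped_terms) {
  used <- unique(codes)
  mapped_ev <- sum(!excluded & codes %in% mapped_terms)
  list(total_terms = length(terms),
       total_mapped_terms_pct = round(100 * sum(terms %in% mapped_terms) /
                                        length(terms), 2),
       used_terms = length(used),
       used_mapped_terms_pct = round(100 * sum(used %in% mapped_terms) /
                                       length(used), 2),
       total_events = length(codes),
       excluded_events_pct = round(100 * sum(excluded) / length(codes), 2),
       mapped_events_pct = round(100 * mapped_ev / length(codes), 2))
}

# per-patient rule-by-rule cohort evaluation
oracle_cohort <- function(dates, periods, yob, rules) {
  pats <- sort(unique(dates$patient_id))
  out <- lapply(pats, function(p) {
    dts <- dates$date[dates$patient_id == p]
    dts <- dts[!is.na(dts) & dts >= rules$entry_start]
    i <- match(p, periods$patient_id)
    y <- yob$year_of_birth[match(p, yob$patient_id)]
    if (!length(dts)) return(data.frame(patient_id = p, included = FALSE,
                                        reason = "no-index-event"))
    idx <- min(dts)
    if (is.na(i)) return(data.frame(patient_id = p, included = FALSE,
                                    reason = "no-observation-period"))
    if (as.integer(format(idx, "%Y")) - y < rules$min_age) {
      return(data.frame(patient_id = p, included = FALSE,
                        reason = "under-age"))
    }
    if (as.integer(idx - periods$start[i]) < rules$min_prior_days) {
      return(data.frame(patient_id = p, included = FALSE,
                        reason = "insufficient-prior-registration"))
    }
    data.frame(patient_id = p, included = TRUE, reason = "included")
  })
  do.call(rbind, out)
}

# precedence-aware expected ledger/QC counts derived from the bundle
# itself (independent of the ETL's own bookkeeping)
expected_defect_recovery <- function(bundle, manifest) {
  rejected <- manifest$defects$inverted_observation_period
  cons <- bundle$consultation
  missing_cons <- sum(is.na(cons$event_date) &
                        !cons$patient_id %in% rejected)
  missing_hosp <- sum(is.na(bundle$hospital$admission_date) &
                        !bundle$hospital$patient_id %in% rejected)
  # therapy rows flagged with a dangling visit reference: consultation id
  # absent from the consultation table or pointing at an undated
  # consultation, on a non-rejected patient with a mapped drug code
  th <- bundle$therapy
  cons_date <- cons$event_date[match(th$consultation_id,
                                     cons$consultation_id)]
  orphan <- (!th$consultation_id %in% cons$consultation_id |
               is.na(cons_date)) &
    !th$patient_id %in% rejected & !is.na(th$event_date)
  cl <- bundle$clinical
  unmappable <- sum(startsWith(cl$code, "ZZ") &
                      !cl$patient_id %in% rejected & !is.na(cl$event_date))
  ad <- bundle$additional
  zero_rows <- sum(!is.na(ad$value_1) & ad$value_1 == "0" &
                     ad$entity_type_id == 467L &
                     !ad$patient_id %in% rejected & !is.na(ad$event_date))
  list(rejected = length(rejected), missing_consultation = missing_cons,
       missing_hospital = missing_hosp, orphan_flags = sum(orphan),
       unmappable = unmappable, zero_value = zero_rows)
}
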