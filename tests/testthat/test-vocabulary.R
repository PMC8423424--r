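test_that("resolve returns sorted targets, empty for unmapped, errors on unknown vocabulary", {
  v <- tiny_vocab()
  expect_identical(resolve(v, "A3", "READ"), integer(0))
  expect_identical(resolve(v, "A1", "READ"), 4L)
  expect_identical(resolve(v, "A2", "READ"), 4L)  # many-to-one
  expect_error(resolve(v, "A1", "NOPE"), "unknown vocabulary")
})

test_that("a vocabulary with k mapped codes yields exactly k non-empty resolutions", {
  codes <- sprintf("C%02d", 1:10)
  concepts <- rbind(
    data.frame(concept_id = 1:10, code = codes, vocabulary_name = "READ",
               domain = NA_character_, standard = 0L),
    data.frame(concept_id = 101:107, code = paste0("S", 1:7),
               vocabulary_name = "SNOMED", domain = "condition",
               standard = 1L))
  edges <- data.frame(edge_id = 1:7, source_code = codes[1:7],
                      source_vocabulary = "READ",
                      target_concept_id = 101:107,
                      relationship = "maps-to")
  v <- vocabulary_store(concepts, edges)
  res <- lapply(codes, resolve, vocab = v, vocabulary = "READ")
  expect_equal(sum(lengths(res) > 0L), 7L)
})

test_that("drug chain resolves only when both hops exist", {
  v <- tiny_vocab()
  expect_identical(resolve_drug(v, "G1"), 8L)       # complete chain
  expect_true(is.na(resolve_drug(v, "G2")))         # broken second hop
  expect_true(is.na(resolve_drug(v, "G9")))         # no chain at all
  expect_identical(resolve_drug(v, c("G1", "G2", "G1")), c(8L, NA, 8L))
  # counting complete chains over the default synthetic vocabulary
  uni <- synthetic_vocabulary(generator_config())
  gems <- uni$vocab$concepts$code[
    uni$vocab$concepts$vocabulary_name == "GEMSCRIPT"]
  complete <- !grepl("^G[XZ]", gems)
  expect_equal(sum(!is.na(resolve_drug(uni$vocab, gems))), sum(complete))
})

test_that("entity rows expand wide fields into measurement candidates", {
  v <- tiny_vocab()
  vals <- c("80.5", "140.0", rep("", 6))
  r <- resolve_entity_row(v, 1L, vals, "U-mmHg")
  # field 1 mapped, field 2 populated but unmappable
  expect_equal(nrow(r$candidates), 1L)
  expect_equal(r$candidates$concept_id, 11L)
  expect_equal(r$candidates$value_as_number, 80.5)
  expect_equal(r$candidates$unit_concept_id, 11L)
  expect_equal(r$unmapped, 2L)

  expect_equal(resolve_entity_row(v, 1L, rep("", 8)),
               list(candidates = r$candidates[0, ], unmapped = integer(),
                    excluded = integer()), ignore_attr = TRUE)

  rz <- resolve_entity_row(v, 9L, c("0", rep("", 7)))
  expect_equal(nrow(rz$candidates), 0L)
  expect_equal(rz$excluded, 1L)
  rnz <- resolve_entity_row(v, 9L, c("42", rep("", 7)))
  expect_equal(nrow(rnz$candidates), 1L)

  # unknown entity type: every populated field is unmapped
  ru <- resolve_entity_row(v, 99L, c("1", "", "2", rep("", 5)))
  expect_equal(ru$unmapped, c(1L, 3L))
  # unmapped unit keeps the value with a null unit concept
  rn <- resolve_entity_row(v, 1L, vals, "U-unknown")
  expect_equal(nrow(rn$candidates), 1L)
  expect_true(is.na(rn$candidates$unit_concept_id))
})

test_that("coverage columns match direct counting and conserve events", {
  codes <- sprintf("C%02d", 1:10)
  concepts <- rbind(
    data.frame(concept_id = 1:10, code = codes, vocabulary_name = "READ",
               domain = NA_character_, standard = 0L),
    data.frame(concept_id = 101:108, code = paste0("S", 1:8),
               vocabulary_name = "SNOMED", domain = "condition",
               standard = 1L))
  edges <- data.frame(edge_id = 1:8, source_code = codes[1:8],
                      source_vocabulary = "READ",
                      target_concept_id = 101:108, relationship = "maps-to")
  v <- vocabulary_store(concepts, edges)
  # 100 events on 5 distinct codes of which 4 mapped; 2 excluded
  set.seed(1)
  ev_codes <- c(sample(codes[c(1:4, 10)], 98, replace = TRUE,
                       prob = c(rep(0.235, 4), 0.06)), codes[10], codes[1])
  excluded <- c(rep(FALSE, 98), TRUE, TRUE)
  row <- coverage(data.frame(code = ev_codes, excluded = excluded), v, "READ")
  want <- oracle_coverage(ev_codes, excluded, codes, codes[1:8])
  expect_equal(row$total_terms, want$total_terms)
  expect_equal(row$total_mapped_terms_pct, want$total_mapped_terms_pct)
  expect_equal(row$used_terms, want$used_terms)
  expect_equal(row$used_mapped_terms_pct, want$used_mapped_terms_pct)
  expect_equal(row$excluded_events_pct, want$excluded_events_pct)
  expect_equal(row$mapped_events_pct, want$mapped_events_pct)
  expect_equal(row$mapped_events + row$unmapped_events + row$excluded_events,
               row$total_events)

  empty <- coverage(data.frame(code = character(), excluded = logical()),
                    v, "READ")
  expect_true(empty$empty)
  expect_equal(empty$mapped_events_pct, 0)
})

test_that("adding a mapping edge never decreases any mapped percentage", {
  codes <- sprintf("C%02d", 1:8)
  concepts <- rbind(
    data.frame(concept_id = 1:8, code = codes, vocabulary_name = "READ",
               domain = NA_character_, standard = 0L),
    data.frame(concept_id = 101:108, code = paste0("S", 1:8),
               vocabulary_name = "SNOMED", domain = "condition",
               standard = 1L))
  for (seed in 1:25) {
    set.seed(seed)
    n_map <- sample(0:7, 1)
    mapped_idx <- sort(sample(8, n_map))
    edges <- data.frame(edge_id = seq_len(n_map + 1),
                        source_code = c(codes[mapped_idx], "X-dummy"),
                        source_vocabulary = "READ",
                        target_concept_id = c(100L + mapped_idx, 101L),
                        relationship = "maps-to")
    v1 <- vocabulary_store(concepts, edges)
    extra <- setdiff(seq_len(8), mapped_idx)[1]
    edges2 <- rbind(edges, data.frame(
      edge_id = max(edges$edge_id) + 1L, source_code = codes[extra],
      source_vocabulary = "READ", target_concept_id = 100L + extra,
      relationship = "maps-to"))
    v2 <- vocabulary_store(concepts, edges2)
    ev <- data.frame(code = sample(codes, 40, replace = TRUE),
                     excluded = runif(40) < 0.1)
    r1 <- coverage(ev, v1, "READ"); r2 <- coverage(ev, v2, "READ")
    expect_gte(r2$total_mapped_terms_pct, r1$total_mapped_terms_pct)
    expect_gte(r2$used_mapped_terms_pct, r1$used_mapped_terms_pct)
    expect_gte(r2$mapped_events_pct, r1$mapped_events_pct)
  }
})

test_that("vocabulary bundles survive a disk round trip", {
  uni <- synthetic_vocabulary(generator_config())
  dir <- withr::local_tempdir()
  write_vocabulary(uni$vocab, dir)
  back <- read_vocabulary(dir)
  for (part in c("concepts", "edges", "entity_field_map", "unit_map")) {
    got <- back[[part]]
    attr(got, "parse_warnings") <- NULL
    expect_equal(got, uni$vocab[[part]], ignore_attr = TRUE, label = part)
  }
})
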