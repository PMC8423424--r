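# Vocabulary store: concepts plus directed mapping edges between source
# terminologies and standard concepts. Source terms are carried as
# non-standard concept rows (the OMOP convention), so term-coverage
# denominators come from the concept table itself.

#' Construct a vocabulary store
#'
#' @param concepts data.frame per the `concept` schema. Standard concepts
#'   carry `standard = 1` and a domain; source terms carry `standard = 0`
#'   and the name of their terminology in `vocabulary_name`.
#' @param edges data.frame per the `mapping_edge` schema; `relationship`
#'   is `maps-to` (source term to standard concept) or `translates-to`
#'   (intermediate hop, e.g. a prescription code to the national drug
#'   dictionary).
#' @param entity_field_map data.frame per the `entity_field_map` schema:
#'   one row per (entity type, field index) with a target measurement
#'   concept (or `NA` for unmappable fields) and value semantics among
#'   `numeric`, `coded`, `ignore-zero`.
#' @param unit_map data.frame per the `unit_map` schema.
#' @return object of class `vocabulary_store`.
#' @export
vocabulary_store <- function(concepts, edges,
                             entity_field_map = NULL, unit_map = NULL) {
  schemas <- bundle_schemas()
  if (is.null(entity_field_map)) entity_field_map <-
      new_empty_table(schemas$entity_field_map)
  if (is.null(unit_map)) unit_map <- new_empty_table(schemas$unit_map)
  if (anyDuplicated(concepts$concept_id)) {
    stop("concept ids must be unique", call. = FALSE)
  }
  no_domain <- concepts$standard == 1L & (is.na(concepts$domain) |
                                            concepts$domain == "")
  if (any(no_domain)) {
    stop("standard concepts must carry a domain", call. = FALSE)
  }
  dangling <- !edges$target_concept_id %in% concepts$concept_id
  if (any(dangling)) {
    stop("mapping edge target(s) absent from concept table: ",
         paste(utils::head(edges$target_concept_id[dangling]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(concepts = concepts, edges = edges,
                 entity_field_map = entity_field_map, unit_map = unit_map),
            class = "vocabulary_store")
}

#' @export
print.vocabulary_store <- function(x, ...) {
  cat("<vocabulary_store>", nrow(x$concepts), "concepts,",
      nrow(x$edges), "edges,", nrow(x$entity_field_map),
      "entity-field rows\n")
  invisible(x)
}

known_vocabularies <- function(vocab) {
  unique(c(vocab$concepts$vocabulary_name, vocab$edges$source_vocabulary))
}

#' Resolve a source code to standard concepts
#'
#' Pure lookup over `maps-to` edges. A code with no edge resolves to an
#' empty vector (the code is "unmapped"); many-to-one and one-to-many
#' mappings are both permitted. Order is deterministic (ascending
#' concept id).
#'
#' @param vocab a [vocabulary_store].
#' @param code source code (scalar).
#' @param vocabulary terminology name the code belongs to.
#' @return integer vector of standard concept ids (possibly empty).
#' @export
resolve <- function(vocab, code, vocabulary) {
  stopifnot(inherits(vocab, "vocabulary_store"))
  if (!vocabulary %in% known_vocabularies(vocab)) {
    stop("unknown vocabulary: ", vocabulary, call. = FALSE)
  }
  e <- vocab$edges
  hit <- e$relationship == "maps-to" & e$source_vocabulary == vocabulary &
    e$source_code == code
  sort(unique(e$target_concept_id[hit]))
}

# Vectorised resolve used by the ETL: returns a list of integer vectors,
# one element per code, via a single match pass.
resolve_many <- function(vocab, codes, vocabulary) {
  e <- vocab$edges
  e <- e[e$relationship == "maps-to" & e$source_vocabulary == vocabulary, ,
         drop = FALSE]
  e <- e[order(e$source_code, e$target_concept_id), , drop = FALSE]
  split_targets <- split(e$target_concept_id, e$source_code)
  out <- split_targets[match(codes, names(split_targets))]
  out[vapply(out, is.null, TRUE)] <- list(integer())
  names(out) <- NULL
  out
}

#' Resolve a prescription code through the two-hop drug chain
#'
#' Prescription codes first translate to the national drug dictionary
#' (`translates-to` edge) and only then map to a standard drug concept
#' (`maps-to` edge from the dictionary code). The final concept is
#' returned only when BOTH hops exist; a broken second hop yields `NA`
#' — the dominant drug-mapping failure mode in UK primary-care extracts.
#'
#' @param vocab a [vocabulary_store].
#' @param drug_code prescription (Gemscript-like) code, vectorised.
#' @return integer vector, `NA` where the chain is broken.
#' @export
resolve_drug <- function(vocab, drug_code) {
  e <- vocab$edges
  hop1 <- e[e$relationship == "translates-to", , drop = FALSE]
  hop1 <- hop1[order(hop1$source_code, hop1$target_concept_id), , drop = FALSE]
  mid_id <- hop1$target_concept_id[match(drug_code, hop1$source_code)]
  mid <- vocab$concepts[match(mid_id, vocab$concepts$concept_id), , drop = FALSE]
  hop2 <- e[e$relationship == "maps-to", , drop = FALSE]
  hop2 <- hop2[order(hop2$source_vocabulary, hop2$source_code,
                     hop2$target_concept_id), , drop = FALSE]
  key2 <- paste(hop2$source_vocabulary, hop2$source_code, sep = "\r")
  out <- hop2$target_concept_id[match(
    paste(mid$vocabulary_name, mid$code, sep = "\r"), key2)]
  out[is.na(mid_id)] <- NA_integer_
  as.integer(out)
}

#' Expand one wide entity-type row into measurement candidates
#'
#' Laboratory and examination results arrive in a wide format: an entity
#' type id plus up to eight value slots, each slot mapped (or not) to a
#' measurement concept. One candidate is produced per populated, mapped
#' field. Fields whose map target is `NA` count as unmapped events;
#' populated `ignore-zero` fields holding the literal value "0"
#' ("value not entered") count as excluded events; empty fields produce
#' nothing. An unknown entity type makes every populated field unmapped.
#'
#' @param vocab a [vocabulary_store].
#' @param entity_type_id integer entity type.
#' @param values character vector of length 8 (empty string/NA = empty).
#' @param unit_code optional unit code, mapped through the unit map;
#'   an unmapped unit keeps the value with a null unit concept.
#' @return list with `candidates` (data.frame field_index, concept_id,
#'   value_as_number, unit_concept_id), `unmapped` (field indices) and
#'   `excluded` (field indices).
#' @export
resolve_entity_row <- function(vocab, entity_type_id, values,
                               unit_code = NA_character_) {
  stopifnot(length(values) == 8L)
  values <- as.character(values)
  populated <- which(!is.na(values) & values != "")
  empty_cand <- data.frame(field_index = integer(), concept_id = integer(),
                           value_as_number = numeric(),
                           unit_concept_id = integer(),
                           stringsAsFactors = FALSE)
  if (!length(populated)) {
    return(list(candidates = empty_cand, unmapped = integer(),
                excluded = integer()))
  }
  efm <- vocab$entity_field_map
  efm <- efm[efm$entity_type_id == entity_type_id, , drop = FALSE]
  if (!nrow(efm)) {
    return(list(candidates = empty_cand, unmapped = populated,
                excluded = integer()))
  }
  unit_concept <- vocab$unit_map$target_concept_id[
    match(unit_code, vocab$unit_map$unit_code)]
  cand <- list(); unmapped <- integer(); excluded <- integer()
  for (fi in populated) {
    m <- efm[efm$field_index == fi, , drop = FALSE]
    if (!nrow(m) || is.na(m$target_concept_id[1L])) {
      unmapped <- c(unmapped, fi)
    } else if (m$value_semantics[1L] == "ignore-zero" && values[fi] == "0") {
      excluded <- c(excluded, fi)
    } else {
      cand[[length(cand) + 1L]] <- data.frame(
        field_index = fi, concept_id = m$target_concept_id[1L],
        value_as_number = suppressWarnings(as.numeric(values[fi])),
        unit_concept_id = as.integer(unit_concept),
        stringsAsFactors = FALSE)
    }
  }
  list(candidates = if (length(cand)) do.call(rbind, cand) else empty_cand,
       unmapped = unmapped, excluded = excluded)
}

#' Term and event coverage of one terminology
#'
#' Reproduces the columns of a terminology-coverage table: total unique
#' terms in the terminology, percentage of them mapped, unique terms
#' actually used in events, percentage of used terms mapped, total
#' events, percentage excluded (dropped for non-mapping reasons:
#' missing dates, rejected patients, value-not-entered), and percentage
#' of events on mapped codes. Percentages are reported to 2 decimals;
#' mapped, unmapped and excluded event counts always sum to the total.
#'
#' @param events data.frame with columns `code` and logical `excluded`.
#' @param vocab a [vocabulary_store].
#' @param vocabulary terminology name.
#' @param resolver how codes map: `"maps-to"` for direct terminologies or
#'   `"drug-chain"` for the two-hop prescription chain.
#' @return one-row data.frame of class `coverage_row`.
#' @export
coverage <- function(events, vocab, vocabulary, resolver = "maps-to") {
  stopifnot(all(c("code", "excluded") %in% names(events)))
  con <- vocab$concepts
  terms <- unique(con$code[con$vocabulary_name == vocabulary &
                             con$standard == 0L])
  mapped_term <- function(codes) {
    if (!length(codes)) return(logical())
    if (resolver == "drug-chain") {
      !is.na(resolve_drug(vocab, codes))
    } else {
      lengths(resolve_many(vocab, codes, vocabulary)) > 0L
    }
  }
  total_terms <- length(terms)
  total_mapped_terms <- sum(mapped_term(terms))
  used <- unique(events$code)
  used_mapped <- sum(mapped_term(used))
  total_events <- nrow(events)
  excluded_events <- sum(events$excluded)
  code_mapped <- mapped_term(used)
  mapped_events <- sum(!events$excluded &
                         code_mapped[match(events$code, used)])
  unmapped_events <- total_events - excluded_events - mapped_events
  pct <- function(num, den) if (den == 0) 0 else round(100 * num / den, 2)
  out <- data.frame(
    vocabulary = vocabulary,
    total_terms = total_terms,
    total_mapped_terms_pct = pct(total_mapped_terms, total_terms),
    used_terms = length(used),
    used_mapped_terms_pct = pct(used_mapped, length(used)),
    total_events = total_events,
    excluded_events_pct = pct(excluded_events, total_events),
    mapped_events_pct = pct(mapped_events, total_events),
    mapped_events = mapped_events,
    unmapped_events = unmapped_events,
    excluded_events = excluded_events,
    empty = total_events == 0L,
    stringsAsFactors = FALSE)
  stopifnot(mapped_events + unmapped_events + excluded_events == total_events)
  class(out) <- c("coverage_row", class(out))
  out
}

#' Read a vocabulary bundle from disk
#' @param dir directory holding concept.csv, mapping_edge.csv,
#'   entity_field_map.csv, unit_map.csv.
#' @return a [vocabulary_store].
#' @export
read_vocabulary <- function(dir) {
  s <- bundle_schemas()
  vocabulary_store(
    concepts = read_table(file.path(dir, "concept.csv"), s$concept),
    edges = read_table(file.path(dir, "mapping_edge.csv"), s$mapping_edge),
    entity_field_map = read_table(file.path(dir, "entity_field_map.csv"),
                                  s$entity_field_map),
    unit_map = read_table(file.path(dir, "unit_map.csv"), s$unit_map))
}

#' Write a vocabulary bundle to disk
#' @param vocab a [vocabulary_store].
#' @param dir output directory (created if absent).
#' @export
write_vocabulary <- function(vocab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- bundle_schemas()
  write_table(vocab$concepts, file.path(dir, "concept.csv"), s$concept)
  write_table(vocab$edges, file.path(dir, "mapping_edge.csv"), s$mapping_edge)
  write_table(vocab$entity_field_map, file.path(dir, "entity_field_map.csv"),
              s$entity_field_map)
  write_table(vocab$unit_map, file.path(dir, "unit_map.csv"), s$unit_map)
  invisible(dir)
}
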