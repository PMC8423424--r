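# Data-quality profiling of a CDM bundle, limited to the four defect
# families observed in national EHR-to-CDM conversions: records outside
# valid observation periods, dangling person references, dangling visit
# references, and visits whose end precedes their start.

#' Run the data-quality checks
#'
#' Each check is a single read-only pass over one table. An event is
#' outside the observation period when its date is before the period
#' start or after the period end (boundary days are inside); persons
#' without any observation period count all their events as outside.
#' Rates are reported to 1 decimal.
#'
#' @param cdm a `cdm_bundle`.
#' @return list of class `quality_report`: `outside_period` (per-domain
#'   count, total and percentage), `dangling_person` (per-table counts),
#'   `dangling_visit` (per-table counts of flagged null visit
#'   references), `inverted_visits` (count of visits with end < start).
#' @export
run_checks <- function(cdm) {
  op <- cdm$observation_period
  start_of <- op$observation_period_start_date[
    match(cdm$person$person_id, op$person_id)]
  names_start <- cdm$person$person_id
  period_lookup <- function(person_id) {
    i <- match(person_id, op$person_id)
    list(start = op$observation_period_start_date[i],
         end = op$observation_period_end_date[i])
  }
  domains <- c(condition = "condition_occurrence", visit = "visit_occurrence",
               drug = "drug_exposure", death = "death",
               procedure = "procedure_occurrence",
               measurement = "measurement", observation = "observation")
  outside <- do.call(rbind, lapply(names(domains), function(d) {
    tb <- cdm[[domains[[d]]]]
    if (is.null(tb) || !nrow(tb)) {
      return(data.frame(domain = d, n_outside = 0L, n_total = 0L,
                        pct = 0, stringsAsFactors = FALSE))
    }
    dt <- if (d == "visit") tb$visit_start_date else tb$event_date
    p <- period_lookup(tb$person_id)
    out <- is.na(p$start) | dt < p$start | dt > p$end
    data.frame(domain = d, n_outside = sum(out), n_total = nrow(tb),
               pct = if (nrow(tb)) round(100 * sum(out) / nrow(tb), 1) else 0,
               stringsAsFactors = FALSE)
  }))

  dangling_person <- vapply(
    c("visit_occurrence", CDM_EVENT_TABLES), function(t) {
      tb <- cdm[[t]]
      if (is.null(tb) || !nrow(tb)) return(0L)
      sum(!tb$person_id %in% cdm$person$person_id)
    }, integer(1L))

  dangling_visit <- vapply(CDM_EVENT_TABLES, function(t) {
    tb <- cdm[[t]]
    if (is.null(tb) || !nrow(tb) || !"invalid_visit" %in% names(tb)) {
      return(0L)
    }
    sum(tb$invalid_visit == 1L)
  }, integer(1L))

  inverted <- sum(cdm$visit_occurrence$visit_end_date <
                    cdm$visit_occurrence$visit_start_date)

  structure(list(outside_period = outside,
                 dangling_person = as.list(dangling_person),
                 dangling_visit = as.list(dangling_visit),
                 inverted_visits = as.integer(inverted)),
            class = "quality_report")
}

#' Render the quality report as deterministic files
#'
#' Writes `qc.json` and a tabular `qc.md` summary whose totals equal the
#' report's.
#'
#' @param report a `quality_report`.
#' @param dir output directory (created if absent).
#' @export
render_dashboard <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tabs <- names(report$dangling_person)
  dp <- data.frame(table = tabs,
                   dangling_person = unlist(report$dangling_person),
                   dangling_visit = vapply(tabs, function(t) {
                     v <- report$dangling_visit[[t]]
                     if (is.null(v)) 0L else as.integer(v)
                   }, integer(1L)),
                   stringsAsFactors = FALSE)
  md <- c("# Data-quality summary", "",
          "## Records outside observation periods",
          render_md_table(report$outside_period), "",
          "## Dangling references", render_md_table(dp), "",
          sprintf("Visits with end date before start date: %d",
                  report$inverted_visits), "")
  writeLines(md, file.path(dir, "qc.md"))
  invisible(dir)
}
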