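# Delimited-table reading/writing with schema enforcement.
# Dialect: comma-separated, double-quote escaping, UTF-8, LF line endings,
# header row, empty string as the null encoding, ISO-8601 dates only.

parse_iso_date <- function(x) {
  d <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  ok <- !is.na(x) & x != ""
  if (any(ok)) {
    # strict ISO: reject anything that does not round-trip, e.g. 2016-02-30
    cand <- as.Date(x[ok], format = "%Y-%m-%d")
    bad <- !is.na(cand) & format(cand, "%Y-%m-%d") != x[ok]
    cand[bad] <- as.Date(NA)
    d[ok] <- cand
  }
  d
}

convert_column <- function(x, type) {
  x[!is.na(x) & x == ""] <- NA_character_
  switch(type,
    id = ,
    integer = ,
    quintile = suppressWarnings(as.integer(x)),
    real = suppressWarnings(as.numeric(x)),
    date = parse_iso_date(x),
    code = ,
    text = x,
    stop("unknown semantic type: ", type))
}

#' Read a delimited table under a schema
#'
#' Reads a CSV file and types every column according to `schema`.
#' Unparseable or non-calendar dates (e.g. `2016-02-30`) become `NA` and
#' are counted; the counts are attached as the `parse_warnings`
#' attribute, a data.frame of (table, row, column, reason). Row order is
#' preserved.
#'
#' @param path file to read.
#' @param schema a [table_schema].
#' @return a typed data.frame with attribute `parse_warnings`.
#' @export
read_table <- function(path, schema) {
  stopifnot(inherits(schema, "table_schema"))
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(schema$columns$name, names(raw))
  if (length(missing_cols)) {
    stop("schema error in '", schema$name, "': missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[, schema$columns$name, drop = FALSE]
  out <- raw
  warnings <- list()
  for (i in seq_len(nrow(schema$columns))) {
    nm <- schema$columns$name[i]
    ty <- schema$columns$type[i]
    val <- convert_column(raw[[nm]], ty)
    newly_na <- which(is.na(val) & !is.na(raw[[nm]]) & raw[[nm]] != "")
    if (length(newly_na)) {
      warnings[[length(warnings) + 1L]] <- data.frame(
        table = schema$name, row = newly_na, column = nm,
        reason = paste0("unparseable ", ty), stringsAsFactors = FALSE)
    }
    out[[nm]] <- val
  }
  pw <- if (length(warnings)) do.call(rbind, warnings) else
    data.frame(table = character(), row = integer(), column = character(),
               reason = character(), stringsAsFactors = FALSE)
  pk <- schema$primary_key
  if (!is.null(pk) && nrow(out)) {
    if (anyNA(out[[pk]]) || anyDuplicated(out[[pk]])) {
      stop("integrity error in '", schema$name, "': duplicate or missing '",
           pk, "'", call. = FALSE)
    }
  }
  attr(out, "parse_warnings") <- pw
  out
}

format_cell <- function(x) {
  if (inherits(x, "Date")) {
    out <- format(x, "%Y-%m-%d")
  } else if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, scientific = FALSE,
                                              trim = TRUE, digits = 15)
    }, "")
  } else {
    out <- as.character(x)
  }
  out[is.na(out)] <- ""
  out
}

#' Write a table in the package's CSV dialect
#'
#' Columns are written in schema order; dates as ISO-8601; nulls as the
#' empty string. Deterministic: two identical tables produce identical
#' files.
#'
#' @param tbl data.frame conforming to `schema`.
#' @param path output file.
#' @param schema a [table_schema].
#' @export
write_table <- function(tbl, path, schema) {
  stopifnot(inherits(schema, "table_schema"))
  missing_cols <- setdiff(schema$columns$name, names(tbl))
  if (length(missing_cols)) {
    stop("schema error in '", schema$name, "': table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tbl[, schema$columns$name, drop = FALSE]
  for (nm in names(out)) out[[nm]] <- format_cell(out[[nm]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, na = "",
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a typed table against its schema
#'
#' Total validation: every non-conforming cell is reported with
#' (table, row, column, reason); conforming tables yield zero rows.
#'
#' @param tbl typed data.frame.
#' @param schema a [table_schema].
#' @return data.frame of violations.
#' @export
validate_table <- function(tbl, schema) {
  stopifnot(inherits(schema, "table_schema"))
  bad <- list()
  note <- function(rows, column, reason) {
    if (length(rows)) {
      bad[[length(bad) + 1L]] <<- data.frame(
        table = schema$name, row = rows, column = column, reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(schema$columns))) {
    nm <- schema$columns$name[i]
    if (!nm %in% names(tbl)) {
      note(0L, nm, "missing column")
      next
    }
    col <- tbl[[nm]]
    if (!schema$columns$nullable[i]) {
      note(which(is.na(col)), nm, "null in non-nullable column")
    }
    if (schema$columns$type[i] == "quintile") {
      note(which(!is.na(col) & (col < 1L | col > 5L)), nm,
           "quintile outside 1-5")
    }
  }
  pk <- schema$primary_key
  if (!is.null(pk) && pk %in% names(tbl) && nrow(tbl)) {
    note(which(duplicated(tbl[[pk]])), pk, "duplicate primary key")
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(table = character(), row = integer(), column = character(),
               reason = character(), stringsAsFactors = FALSE)
}

new_empty_table <- function(schema) {
  cols <- lapply(seq_len(nrow(schema$columns)), function(i) {
    switch(schema$columns$type[i],
           id = , integer = , quintile = integer(),
           real = numeric(),
           date = as.Date(character()),
           character())
  })
  names(cols) <- schema$columns$name
  as.data.frame(cols, stringsAsFactors = FALSE)
}
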