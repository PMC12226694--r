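# Bit-stable readers/writers for the record schema. CSV: one header row,
# comma separator, "." decimal point, UTF-8, booleans as true/false, absent
# optionals as empty fields, enums lowercase. JSON-lines mirrors the same
# field names, omitting absent fields.

.parse_logical_column <- function(x, column) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(x))   # canonical form is lowercase; accept TRUE/FALSE
  known <- x %in% c("true", "false", "", NA)
  if (any(!known)) {
    row <- which(!known)[1]
    stop(sprintf("row %d, column '%s': malformed boolean '%s'",
                 row, column, x[row]), call. = FALSE)
  }
  out[x %in% "true"] <- TRUE
  out[x %in% "false"] <- FALSE
  out
}

.parse_numeric_column <- function(x, column) {
  x <- trimws(x)
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("row %d, column '%s': malformed number '%s'",
                 bad[1], column, x[bad[1]]), call. = FALSE)
  out
}

.coerce_record_types <- function(df) {
  for (col in .logical_columns)
    df[[col]] <- .parse_logical_column(as.character(df[[col]]), col)
  for (col in .numeric_columns)
    df[[col]] <- .parse_numeric_column(as.character(df[[col]]), col)
  for (col in c("id", "laterality", "enhancement_grade", "locularity",
                "fluid_type", "histology")) {
    v <- as.character(df[[col]])
    v[!is.na(v) & trimws(v) == ""] <- NA
    df[[col]] <- v
  }
  df[, .record_columns]
}

#' Read patient records from CSV or JSON-lines
#'
#' @param path Input file. Format is inferred from the extension (`.csv`
#'   vs `.jsonl`/`.ndjson`/`.json`) unless given explicitly.
#' @param format `"auto"`, `"csv"` or `"jsonl"`.
#' @return Data frame in the record schema. Raises, naming the first
#'   offending row and column, on malformed values or missing schema
#'   columns.
#' @export
read_lesion_records <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty_records())
    rows <- lapply(lines, function(ln) {
      obj <- jsonlite::fromJSON(ln)
      miss <- setdiff(.record_columns, names(obj))
      for (m in miss) obj[[m]] <- NA
      as.data.frame(lapply(obj[.record_columns], function(v)
        if (is.null(v)) NA else as.character(v)),
        stringsAsFactors = FALSE, col.names = .record_columns)
    })
    df <- do.call(rbind, rows)
  }
  miss <- setdiff(.record_columns, names(df))
  if (length(miss))
    stop("input is missing schema columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(empty_records())
  .coerce_record_types(df)
}

.serialize_record_frame <- function(records) {
  out <- records[, intersect(c(.record_columns, "orads_class",
                               "simplified_label", "risk_group"),
                             names(records)), drop = FALSE]
  for (col in names(out)) {
    v <- out[[col]]
    s <- if (is.logical(v)) ifelse(v, "true", "false") else as.character(v)
    s[is.na(v)] <- ""
    out[[col]] <- s
  }
  out
}

#' Write patient records to CSV or JSON-lines
#'
#' Serializes the record schema (plus any `orads_class`, `simplified_label`
#' and `risk_group` annotations) deterministically: booleans as
#' `true`/`false`, absent optionals as empty CSV fields or omitted JSON
#' keys, stable column order. `read_lesion_records()` of the output is the
#' identity on the schema columns.
#'
#' @param records Record table.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_lesion_records <- function(records, path,
                                 format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(.serialize_record_frame(records), path,
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      row <- as.list(records[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA,
                                  null = "null"), con)
    }
  }
  invisible(path)
}
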