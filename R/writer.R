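# Serializing datasets back to ISA-Tab and applying provenance-tracked
# updates. Output dialect: tab-separated, "\n" line endings, UTF-8 without
# BOM, cells quoted only when they contain a tab, newline or double quote.
# Round-trip is structural, not byte-exact: quoting style and line endings
# normalize, content never changes.

format_tsv_row <- function(fields) {
  needs_quote <- grepl("[\t\n\r\"]", fields)
  fields[needs_quote] <- paste0(
    '"', gsub('"', '""', fields[needs_quote]), '"')
  paste(fields, collapse = "\t")
}

write_tsv_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

write_table_file <- function(tf, path) {
  lines <- format_tsv_row(tf$columns$label)
  if (nrow(tf$cells) > 0) {
    lines <- c(lines, apply(tf$cells, 1, format_tsv_row))
  }
  write_tsv_lines(enc2utf8(lines), path)
}

#' Write an ISA dataset back to ISA-Tab
#'
#' Serializes the investigation file (verbatim field rows, as parsed) and
#' every study and assay table, preserving column and row order and any
#' unknown or `Comment[x]` columns untouched. Re-reading the written archive
#' yields a dataset structurally equal to the input.
#'
#' @param ds A validated `isa_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_isatab <- function(ds, out_dir) {
  issues <- validate_isa(ds)
  if (any(issues$severity == "error")) {
    isa_abort("validation", "dataset does not validate; not writing",
              issues = issues)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) isa_abort("io", sprintf("cannot create '%s'", out_dir))
  }
  written <- character(0)
  put <- function(writer, relname) {
    target <- file.path(out_dir, relname)
    tryCatch(writer(target),
             error = function(e) {
               isa_abort("io", sprintf("cannot write '%s': %s", target,
                                       conditionMessage(e)))
             })
    written <<- c(written, target)
  }
  put(function(p) {
    write_tsv_lines(enc2utf8(vapply(ds$investigation_rows, format_tsv_row,
                                    character(1))), p)
  }, ds$investigation_filename)
  for (st in ds$studies) {
    if (!is.null(st$table)) {
      put(function(p) write_table_file(st$table, p), st$filename)
    }
  }
  for (af in names(ds$assay_tables)) {
    put(function(p) write_table_file(ds$assay_tables[[af]], p), af)
  }
  invisible(written)
}

#' Update or add an assay-table column, with provenance
#'
#' The incremental-metadata operation of the analysis loop: replace the
#' values of an existing column, or append a new column at the end of the
#' assay table (appending keeps position-sensitive qualifier attachment of
#' existing columns intact). A single value recycles to every row — handy
#' for pipeline outputs like a metabolite assignment file shared by all
#' samples. Every call appends an entry to the dataset's provenance log.
#'
#' @param ds An `isa_dataset`.
#' @param assay_filename Declared assay filename.
#' @param column_label Header label of the column to update or add.
#' @param values Character vector: either one value (recycled) or exactly
#'   one value per assay row.
#' @return The updated `isa_dataset` (design structures re-derived).
#' @export
update_assay_column <- function(ds, assay_filename, column_label, values) {
  if (!assay_filename %in% names(ds$assay_tables)) {
    isa_abort("unknown_assay", sprintf("unknown assay '%s'", assay_filename))
  }
  tf <- ds$assay_tables[[assay_filename]]
  n <- nrow(tf$cells)
  values <- as.character(values)
  if (length(values) == 1L) values <- rep(values, n)
  if (length(values) != n) {
    isa_abort("length_mismatch", sprintf(
      "assay '%s' has %d rows but %d values were supplied",
      assay_filename, n, length(values)))
  }
  idx <- which(tf$columns$label == column_label)
  if (length(idx) > 0) {
    tf$cells[, idx[1]] <- values
    action <- "update"
  } else {
    tf$cells <- cbind(tf$cells, values, deparse.level = 0)
    tf$columns <- classify_columns(c(tf$columns$label, column_label))
    action <- "add"
  }
  ds$assay_tables[[assay_filename]] <- tf
  ds$provenance <- dplyr::bind_rows(ds$provenance, tibble::tibble(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    assay_filename = assay_filename,
    column = column_label,
    action = action,
    n_values = n
  ))
  derive_design(ds)
}

#' Write a single assay table
#'
#' Rewrites only the named assay file; every other file of the archive is
#' left untouched.
#'
#' @param ds An `isa_dataset`.
#' @param assay_filename Declared assay filename.
#' @param out_dir Output directory, defaulting to the dataset root.
#' @return The written file path, invisibly.
#' @export
save_assay <- function(ds, assay_filename, out_dir = ds$path) {
  if (!assay_filename %in% names(ds$assay_tables)) {
    isa_abort("unknown_assay", sprintf("unknown assay '%s'", assay_filename))
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) isa_abort("io", sprintf("cannot create '%s'", out_dir))
  }
  target <- file.path(out_dir, assay_filename)
  write_table_file(ds$assay_tables[[assay_filename]], target)
  invisible(target)
}

#' Provenance log of a dataset
#'
#' Append-only record of metadata updates: one row per
#' [update_assay_column()] call, in call order.
#'
#' @param ds An `isa_dataset`.
#' @return A tibble with `timestamp`, `assay_filename`, `column`, `action`
#'   (`"update"` or `"add"`), `n_values`.
#' @export
provenance_log <- function(ds) {
  ds$provenance
}

#' Serialize the provenance log as JSON lines
#'
#' @param ds An `isa_dataset`.
#' @param path Output file; one JSON object per line, in log order.
#' @return `path`, invisibly.
#' @export
write_provenance_jsonl <- function(ds, path) {
  log <- provenance_log(ds)
  lines <- vapply(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
  }, character(1))
  write_tsv_lines(lines, path)
  invisible(path)
}
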