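#' Ontology annotation
#'
#' A term with an optional ontology source and accession, mirroring the
#' `Term Source REF` / `Term Accession Number` qualifier columns of ISA-Tab.
#' An accession without a source is tolerated with a warning: the term is
#' still usable, but its provenance is incomplete.
#'
#' @param term Term text (may be empty, never `NULL`).
#' @param source_ref Short name of the ontology source, e.g. `"OBI"`.
#' @param accession Term accession identifier.
#' @return An object of class `isa_ontology_annotation`.
#' @examples
#' ontology_annotation("mass spectrometry", "OBI", "OBI:0000470")
#' @export
ontology_annotation <- function(term = "", source_ref = "", accession = "") {
  stopifnot(is.character(term), length(term) == 1L, !is.na(term))
  if (nzchar(accession) && !nzchar(source_ref)) {
    isa_warn("dangling_accession",
      sprintf("accession '%s' has no Term Source REF", accession))
  }
  structure(
    list(term = term, source_ref = source_ref, accession = accession),
    class = "isa_ontology_annotation"
  )
}

#' Qualified cell value
#'
#' A raw cell value together with its optional `Unit` and ontology
#' annotation. The *grouping key* of a qualified value — the string under
#' which treatment identity is decided — is the raw text alone, or the raw
#' text and the unit term joined by a single space.
#'
#' @param raw Verbatim cell text.
#' @param unit An [ontology_annotation()] for the `Unit` qualifier, or `NULL`.
#' @param annotation An [ontology_annotation()] for the value itself, or `NULL`.
#' @return An object of class `isa_qualified_value`.
#' @examples
#' render_grouping_key(qualified_value("10", unit = ontology_annotation("mg")))
#' @export
qualified_value <- function(raw, unit = NULL, annotation = NULL) {
  stopifnot(is.character(raw), length(raw) == 1L, !is.na(raw))
  structure(
    list(raw = raw, unit = unit, annotation = annotation),
    class = "isa_qualified_value"
  )
}

#' @rdname qualified_value
#' @param v An `isa_qualified_value`.
#' @export
render_grouping_key <- function(v) {
  stopifnot(inherits(v, "isa_qualified_value"))
  if (is.null(v$unit) || !nzchar(v$unit$term)) v$raw else paste(v$raw, v$unit$term)
}

# Vectorised key rendering straight from raw/unit character vectors; the
# single-space join must match render_grouping_key() exactly.
render_keys <- function(raw, unit_term) {
  ifelse(is.na(unit_term) | !nzchar(unit_term), raw, paste(raw, unit_term))
}

#' Study factor declaration
#'
#' @param name Factor name as declared under `STUDY FACTORS`.
#' @param type An [ontology_annotation()] for the factor type.
#' @return An object of class `isa_study_factor`.
#' @export
study_factor <- function(name, type = ontology_annotation()) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, type = type), class = "isa_study_factor")
}

#' Assay declaration
#'
#' One row of a `STUDY ASSAYS` block: the measurement type / technology type
#' pair that defines an assay, its platform, and the assay table filename.
#'
#' @param measurement_type,technology_type [ontology_annotation()] objects.
#' @param technology_platform Free-text platform description.
#' @param assay_filename Relative path of the assay table.
#' @return An object of class `isa_assay_declaration`.
#' @export
assay_declaration <- function(measurement_type, technology_type,
                              technology_platform = "", assay_filename) {
  stopifnot(is.character(assay_filename), nzchar(assay_filename))
  structure(
    list(
      measurement_type = measurement_type,
      technology_type = technology_type,
      technology_platform = technology_platform,
      assay_filename = assay_filename
    ),
    class = "isa_assay_declaration"
  )
}

#' Parsed ISA table file
#'
#' A study or assay table: the classified header plus the verbatim cell
#' grid. Constructed by [parse_table_file()]; direct construction validates
#' the column/row shape invariants.
#'
#' @param filename Relative path of the table file.
#' @param columns A column-specification tibble as returned by
#'   [classify_columns()].
#' @param cells Character matrix, one row per data row, `ncol(cells)` equal
#'   to `nrow(columns)` (a 0-row matrix is a header-only table).
#' @return An object of class `isa_table_file`.
#' @export
new_table_file <- function(filename, columns, cells) {
  stopifnot(is.character(filename), is.data.frame(columns), is.matrix(cells))
  if (ncol(cells) != nrow(columns)) {
    isa_abort("validation", sprintf(
      "table '%s': %d columns declared but rows have %d cells",
      filename, nrow(columns), ncol(cells)))
  }
  if (nrow(columns) > 0 && !identical(columns$position, seq_len(nrow(columns)) - 1L)) {
    isa_abort("validation", sprintf(
      "table '%s': column positions must be 0..%d in order", filename,
      nrow(columns) - 1L))
  }
  structure(
    list(filename = filename, columns = columns, cells = cells),
    class = "isa_table_file"
  )
}

#' @export
print.isa_table_file <- function(x, ...) {
  cat(sprintf("<isa_table_file> %s: %d rows x %d columns\n",
              x$filename, nrow(x$cells), nrow(x$columns)))
  invisible(x)
}

#' Tidy view of a table file
#'
#' @param x An `isa_table_file`.
#' @param ... Unused.
#' @return A tibble with the original header labels as (possibly repeated)
#'   column names and verbatim cell text as values.
#' @export
as_tibble.isa_table_file <- function(x, ...) {
  m <- x$cells
  colnames(m) <- x$columns$label
  tibble::as_tibble(m, .name_repair = "minimal")
}

table_column_values <- function(tf, label) {
  idx <- which(tf$columns$label == label)
  if (length(idx) == 0) return(NULL)
  tf$cells[, idx[1]]
}

#' Assembled ISA dataset
#'
#' The root object produced by [read_isatab()]. Holds the archive path, the
#' investigation metadata, the parsed study and assay tables, and the derived
#' design structures (factor assignments, treatments, groups) per assay.
#' Not normally constructed by hand.
#'
#' @param path Archive root directory.
#' @param investigation_filename Relative filename of the investigation file.
#' @param investigation Structured investigation metadata (see
#'   [parse_investigation()]).
#' @param investigation_rows The investigation file's rows as a list of
#'   character vectors, kept verbatim for round-trip writing.
#' @param studies Named list of study objects.
#' @param assay_tables Named list (assay filename -> `isa_table_file`).
#' @param provenance Provenance log tibble (may be empty).
#' @return An object of class `isa_dataset`, validated; a partition violation
#'   or duplicate assay filename raises a validation error.
#' @export
new_isa_dataset <- function(path, investigation_filename, investigation,
                            investigation_rows, studies, assay_tables,
                            provenance = empty_provenance()) {
  ds <- structure(
    list(
      path = path,
      investigation_filename = investigation_filename,
      investigation = investigation,
      investigation_rows = investigation_rows,
      studies = studies,
      assay_tables = assay_tables,
      samples = list(),
      factor_assignments = list(),
      treatments = list(),
      groups = list(),
      provenance = provenance
    ),
    class = "isa_dataset"
  )
  ds <- derive_design(ds)
  issues <- validate_isa(ds)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    isa_abort("validation",
      paste0("invalid ISA dataset:\n",
             paste0("- ", errs$component, ": ", errs$message, collapse = "\n")),
      issues = issues)
  }
  for (w in which(issues$severity == "warning")) {
    isa_warn("validation", paste0(issues$component[w], ": ", issues$message[w]))
  }
  ds
}

# (Re)compute samples, factor assignments, treatments and groups for every
# declared assay. Called on construction and after metadata updates.
derive_design <- function(ds) {
  decls <- assay_declarations(ds)
  ds$samples <- ds$factor_assignments <- ds$treatments <- ds$groups <-
    stats::setNames(vector("list", nrow(decls)), decls$assay_filename)
  for (af in decls$assay_filename) {
    tf <- ds$assay_tables[[af]]
    smp <- table_column_values(tf, "Sample Name")
    ds$samples[[af]] <- if (is.null(smp)) character(0) else unname(smp)
    fa <- extract_factors(ds, af)
    ds$factor_assignments[[af]] <- fa
    tr <- derive_treatments(fa)
    ds$treatments[[af]] <- tr
    ds$groups[[af]] <- derive_groups(fa, tr)
  }
  ds
}

#' All assay declarations of a dataset
#'
#' @param ds An `isa_dataset`.
#' @return A tibble with one row per declared assay: `study`, `assay_filename`,
#'   `measurement`, `technology`, `platform`, `technology_tag`.
#' @export
assay_declarations <- function(ds) {
  rows <- purrr::imap(ds$studies, function(st, sid) {
    if (length(st$assays) == 0) return(NULL)
    tibble::tibble(
      study = sid,
      assay_filename = purrr::map_chr(st$assays, "assay_filename"),
      measurement = purrr::map_chr(st$assays, ~ .x$measurement_type$term),
      technology = purrr::map_chr(st$assays, ~ .x$technology_type$term),
      platform = purrr::map_chr(st$assays, "technology_platform")
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(study = character(), assay_filename = character(),
                          measurement = character(), technology = character(),
                          platform = character())
  }
  out$technology_tag <- vapply(out$technology, classify_technology, character(1),
                               USE.NAMES = FALSE)
  out
}

empty_provenance <- function() {
  tibble::tibble(timestamp = character(), assay_filename = character(),
                 column = character(), action = character(),
                 n_values = integer())
}

#' Validate an ISA dataset
#'
#' Walks every model invariant — column-grammar consistency, factor
#' declarations, assay-filename uniqueness, and the group-partition law
#' (groups of one assay are disjoint and jointly cover the deduplicated
#' sample list) — and reports violations instead of stopping at the first.
#'
#' @param ds An `isa_dataset`.
#' @return A tibble with columns `severity` (`"error"` or `"warning"`),
#'   `component`, `message`; zero rows when the dataset is clean.
#' @export
validate_isa <- function(ds) {
  out <- list()
  note <- function(severity, component, message) {
    out[[length(out) + 1]] <<- tibble::tibble(
      severity = severity, component = component, message = message)
  }

  decls <- assay_declarations(ds)
  if (anyDuplicated(decls$assay_filename)) {
    note("error", "assays", sprintf(
      "duplicate assay filename(s): %s",
      paste(unique(decls$assay_filename[duplicated(decls$assay_filename)]),
            collapse = ", ")))
  }
  missing_tabs <- setdiff(decls$assay_filename, names(ds$assay_tables))
  if (length(missing_tabs)) {
    note("error", "assays",
         sprintf("declared assay table(s) not parsed: %s",
                 paste(missing_tabs, collapse = ", ")))
  }
  extra_tabs <- setdiff(names(ds$assay_tables), decls$assay_filename)
  if (length(extra_tabs)) {
    note("error", "assays",
         sprintf("parsed assay table(s) never declared: %s",
                 paste(extra_tabs, collapse = ", ")))
  }

  for (sid in names(ds$studies)) {
    st <- ds$studies[[sid]]
    fnames <- purrr::map_chr(st$factors, "name")
    if (anyDuplicated(fnames)) {
      note("error", paste0("study ", sid),
           sprintf("duplicate factor name(s): %s",
                   paste(unique(fnames[duplicated(fnames)]), collapse = ", ")))
    }
    if (!is.null(st$table) && !identical(st$table$filename, st$filename)) {
      note("error", paste0("study ", sid), "study table filename mismatch")
    }
    # declared factors should be visible as Factor Value columns somewhere
    visible <- character(0)
    tabs <- c(list(st$table),
              ds$assay_tables[purrr::map_chr(st$assays, "assay_filename")])
    for (tf in purrr::compact(tabs)) {
      fv <- tf$columns$bracket_arg[tf$columns$kind == "factor_value"]
      visible <- c(visible, fv)
    }
    orphaned <- setdiff(fnames, visible)
    if (length(orphaned)) {
      note("warning", paste0("study ", sid),
           sprintf("declared factor(s) with no Factor Value column: %s",
                   paste(orphaned, collapse = ", ")))
    }
  }

  for (tf in c(purrr::map(ds$studies, "table"), ds$assay_tables)) {
    if (is.null(tf)) next
    cols <- tf$columns
    bracket_kinds <- cols$kind %in%
      c("characteristic", "factor_value", "parameter_value", "comment")
    bad <- xor(bracket_kinds, !is.na(cols$bracket_arg) & nzchar(cols$bracket_arg))
    if (any(bad)) {
      note("error", tf$filename, sprintf(
        "bracket argument inconsistent for column(s) %s",
        paste(cols$label[bad], collapse = ", ")))
    }
    qual <- cols$kind %in% c("unit", "term_source_ref", "term_accession")
    if (any(qual & is.na(cols$owner))) {
      note("warning", tf$filename,
           "qualifier column with no preceding value column to attach to")
    }
  }

  for (af in names(ds$groups)) {
    grp <- ds$groups[[af]]
    tr <- ds$treatments[[af]]
    if (nrow(grp) != nrow(tr)) {
      note("error", af, sprintf("%d groups but %d treatments",
                                nrow(grp), nrow(tr)))
    }
    members <- unlist(grp$samples, use.names = FALSE)
    uniq <- unique(ds$samples[[af]])
    if (anyDuplicated(members)) {
      note("error", af, "group sample lists overlap")
    }
    if (!setequal(members, uniq)) {
      note("error", af, "groups do not cover the sample set")
    }
    if (any(purrr::map_int(grp$samples, length) == 0)) {
      note("error", af, "empty treatment group")
    }
  }

  if (length(out) == 0) {
    tibble::tibble(severity = character(), component = character(),
                   message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' @export
print.isa_dataset <- function(x, ...) {
  decls <- assay_declarations(x)
  cat("<isa_dataset> ", x$path, "\n", sep = "")
  cat(sprintf("  investigation: %s (%s)\n", x$investigation_filename,
              x$investigation$identifier))
  cat(sprintf("  %d study(ies), %d assay(s)\n", length(x$studies), nrow(decls)))
  for (i in seq_len(nrow(decls))) {
    af <- decls$assay_filename[i]
    cat(sprintf("  - %s [%s]: %s / %s; %d samples, %d treatments\n",
                af, decls$technology_tag[i], decls$measurement[i],
                decls$technology[i], length(unique(x$samples[[af]])),
                nrow(x$treatments[[af]])))
  }
  invisible(x)
}
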