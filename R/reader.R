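# Reading ISA-Tab archives: investigation discovery, zip unpacking, the
# row-oriented investigation parser and the column-oriented table parser.

#' Locate the investigation file of an ISA-Tab directory
#'
#' ISA-Tab archives name their root file `i_*.txt`; discovery is
#' case-insensitive on the prefix and suffix.
#'
#' @param path Directory to search.
#' @return The investigation filename, relative to `path`.
#' @export
locate_investigation <- function(path) {
  stopifnot(dir.exists(path))
  hits <- list.files(path, pattern = "^i_.*\\.txt$", ignore.case = TRUE)
  if (length(hits) == 0) {
    isa_abort("no_investigation",
      sprintf("no investigation file (i_*.txt) found in '%s'", path))
  }
  if (length(hits) > 1) {
    isa_abort("ambiguous_investigation",
      sprintf("multiple investigation files in '%s': %s", path,
              paste(hits, collapse = ", ")))
  }
  hits
}

#' Unpack a zipped ISA-Tab archive
#'
#' Extracts into a fresh temporary directory. If the zip wraps everything in
#' a single top-level folder, that folder becomes the dataset root.
#'
#' @param zipfile Path to a `.zip` archive.
#' @return The extracted dataset root directory.
#' @export
unpack_archive <- function(zipfile) {
  if (!file.exists(zipfile)) {
    isa_abort("bad_archive", sprintf("archive '%s' does not exist", zipfile))
  }
  exdir <- tempfile("isatab_unzip_")
  dir.create(exdir)
  files <- tryCatch(
    withCallingHandlers(
      utils::unzip(zipfile, exdir = exdir),
      warning = function(w) {
        isa_abort("bad_archive",
          sprintf("cannot unpack '%s': %s", zipfile, conditionMessage(w)))
      }
    ),
    error = function(e) {
      if (inherits(e, "isa_bad_archive_error")) stop(e)
      isa_abort("bad_archive",
        sprintf("cannot unpack '%s': %s", zipfile, conditionMessage(e)))
    }
  )
  if (length(files) == 0) {
    isa_abort("bad_archive", sprintf("archive '%s' is empty", zipfile))
  }
  entries <- list.files(exdir, all.files = FALSE)
  if (length(entries) == 1 && dir.exists(file.path(exdir, entries))) {
    return(file.path(exdir, entries))
  }
  exdir
}

# Low-level record reader shared by the investigation and table parsers.
# Returns a character matrix (quotes stripped, embedded tabs/newlines inside
# quoted cells preserved, NA-free) plus a raggedness flag per parsed row.
read_tsv_records <- function(file) {
  # ISA files are ragged (the row-oriented investigation file especially),
  # so measure the widest record first and read with a fixed width; shorter
  # records are padded with empty cells. count.fields and read.table share
  # the same quoting rules (double quotes, embedded tabs/newlines kept).
  # refuse undecodable bytes up front: the reencoding connection used below
  # would silently drop them, corrupting metadata
  bytes <- readBin(file, "raw", file.info(file)$size)
  txt <- tryCatch(rawToChar(bytes), error = function(e) NULL)
  if (is.null(txt) || !validUTF8(txt)) {
    isa_abort("encoding",
      sprintf("'%s' contains bytes that are not valid UTF-8", file))
  }
  widths <- tryCatch(
    utils::count.fields(file, sep = "\t", quote = "\"",
                        blank.lines.skip = TRUE),
    error = function(e) integer(0))
  if (length(widths) == 0) {
    return(list(cells = matrix(character(0), 0, 0), widths = integer(0)))
  }
  n_max <- max(c(1L, widths), na.rm = TRUE)
  df <- suppressWarnings(utils::read.table(
    file,
    sep = "\t", quote = "\"", header = FALSE,
    col.names = sprintf("X%d", seq_len(n_max)),
    colClasses = "character", na.strings = character(0),
    fill = TRUE, blank.lines.skip = TRUE, comment.char = "",
    strip.white = FALSE, check.names = FALSE,
    fileEncoding = "UTF-8-BOM", encoding = "UTF-8"
  ))
  m <- as.matrix(df)
  m[is.na(m)] <- ""
  dimnames(m) <- NULL
  # per-record field counts; NA when a quoted cell spans lines
  if (anyNA(widths) || length(widths) != nrow(m)) {
    widths <- rep(NA_integer_, nrow(m))
  }
  list(cells = m, widths = widths)
}

#' Parse one ISA study or assay table
#'
#' Reads a tab-separated table whose first row is the header, classifies
#' every column with [classify_columns()], and keeps every cell verbatim
#' (double-quoted cells are unquoted; tabs and newlines inside quotes
#' survive). Rows shorter than the header are padded with empty cells,
#' with a warning.
#'
#' @param file Path to the table file.
#' @param filename Relative name recorded on the result (defaults to the
#'   basename of `file`).
#' @param registry Data-file column registry for classification.
#' @return An [new_table_file()] object.
#' @export
parse_table_file <- function(file, filename = basename(file),
                             registry = default_data_file_registry()) {
  if (!file.exists(file)) {
    isa_abort("missing_file", sprintf("table file '%s' not found", file))
  }
  rec <- read_tsv_records(file)
  if (nrow(rec$cells) == 0) {
    isa_abort("empty_table", sprintf("'%s' has no header row", file))
  }
  header <- rec$cells[1, ]
  cells <- rec$cells[-1, , drop = FALSE]
  ragged <- if (is.na(rec$widths[1])) rep(FALSE, nrow(cells)) else {
    !is.na(rec$widths[-1]) & rec$widths[-1] < rec$widths[1]
  }
  if (any(ragged)) {
    isa_warn("ragged_rows", sprintf(
      "'%s': %d row(s) shorter than the header were padded with empty cells",
      filename, sum(ragged)))
  }
  new_table_file(filename, classify_columns(header, registry), cells)
}

# ---- investigation parsing --------------------------------------------------

investigation_section_names <- c(
  "ONTOLOGY SOURCE REFERENCE", "INVESTIGATION", "INVESTIGATION PUBLICATIONS",
  "INVESTIGATION CONTACTS", "STUDY", "STUDY DESIGN DESCRIPTORS",
  "STUDY PUBLICATIONS", "STUDY FACTORS", "STUDY ASSAYS", "STUDY PROTOCOLS",
  "STUDY CONTACTS"
)

is_section_header <- function(fields) {
  length(fields) >= 1 && grepl("^[A-Z][A-Z0-9 ]*$", fields[1]) &&
    all(!nzchar(fields[-1]))
}

# rows: list of character vectors (trailing empty fields stripped)
split_sections <- function(rows) {
  sections <- list()
  current <- NULL
  for (i in seq_along(rows)) {
    fields <- rows[[i]]
    if (is_section_header(fields)) {
      current <- list(name = fields[1], rows = list(), lines = integer())
      sections[[length(sections) + 1]] <- current
    } else if (is.null(current)) {
      isa_abort("malformed_row", sprintf(
        "line %d: row '%s' appears before any section header",
        i, fields[1]))
    } else {
      current$rows[[length(current$rows) + 1]] <- fields
      current$lines <- c(current$lines, i)
      sections[[length(sections)]] <- current
    }
  }
  sections
}

section_field <- function(section, label) {
  for (r in section$rows) {
    if (identical(r[1], label)) return(r[-1])
  }
  character(0)
}

section_scalar <- function(section, label) {
  v <- section_field(section, label)
  if (length(v) == 0) "" else v[1]
}

# Column-aligned record block (publications, contacts, factors, assays):
# each label row holds one field per record.
section_records <- function(section, labels, names) {
  cols <- lapply(labels, section_field, section = section)
  n <- max(c(0L, lengths(cols)))
  cols <- lapply(cols, function(v) c(v, rep("", n - length(v))))
  names(cols) <- names
  tibble::as_tibble(cols)
}

contact_labels <- function(prefix) {
  list(
    labels = paste(prefix, c("Last Name", "First Name", "Mid Initials",
                             "Email", "Phone", "Fax", "Address", "Affiliation",
                             "Roles")),
    names = c("last_name", "first_name", "mid_initials", "email", "phone",
              "fax", "address", "affiliation", "roles")
  )
}

publication_labels <- function(prefix) {
  list(
    labels = c(paste(prefix, "PubMed ID"),
               paste(prefix, "Publication DOI"),
               paste(prefix, "Publication Author List"),
               paste(prefix, "Publication Title"),
               paste(prefix, "Publication Status")),
    names = c("pubmed_id", "doi", "author_list", "title", "status")
  )
}

#' Parse an ISA investigation file
#'
#' The investigation file is row-oriented: ALL-CAPS section headers
#' (`INVESTIGATION`, `STUDY`, `STUDY FACTORS`, ...) followed by label-first
#' rows whose subsequent tab-separated fields hold one value per record.
#' Produces the investigation metadata and one study shell per `STUDY`
#' section, in file order; factors and assay declarations are populated from
#' the `STUDY FACTORS` and `STUDY ASSAYS` blocks.
#'
#' @param file Path to the `i_*.txt` file.
#' @return A list with `investigation` (identifier, title, description,
#'   ontology sources, publications, contacts), `studies` (list of study
#'   shells, tables not yet attached), and `rows` (the verbatim field rows,
#'   used for round-trip writing).
#' @export
parse_investigation <- function(file) {
  if (!file.exists(file)) {
    isa_abort("missing_file", sprintf("investigation file '%s' not found", file))
  }
  rec <- read_tsv_records(file)
  rows <- lapply(seq_len(nrow(rec$cells)), function(i) {
    r <- rec$cells[i, ]
    last <- max(c(0L, which(nzchar(r))))
    r[seq_len(last)]
  })
  rows <- rows[lengths(rows) > 0]
  sections <- split_sections(rows)
  names <- purrr::map_chr(sections, "name")
  if (!"STUDY" %in% names) {
    isa_abort("missing_section", sprintf("'%s' has no STUDY section", file))
  }

  get_section <- function(nm, from = 1, to = length(sections)) {
    idx <- which(names == nm & seq_along(names) >= from & seq_along(names) <= to)
    if (length(idx)) sections[[idx[1]]] else list(name = nm, rows = list())
  }

  inv_sec <- get_section("INVESTIGATION")
  cl <- contact_labels("Investigation Person")
  pl <- publication_labels("Investigation")
  osr <- get_section("ONTOLOGY SOURCE REFERENCE")
  investigation <- list(
    identifier = section_scalar(inv_sec, "Investigation Identifier"),
    title = section_scalar(inv_sec, "Investigation Title"),
    description = section_scalar(inv_sec, "Investigation Description"),
    ontology_sources = section_records(
      osr,
      c("Term Source Name", "Term Source File", "Term Source Version",
        "Term Source Description"),
      c("name", "file", "version", "description")),
    publications = section_records(get_section("INVESTIGATION PUBLICATIONS"),
                                   pl$labels, pl$names),
    contacts = section_records(get_section("INVESTIGATION CONTACTS"),
                               cl$labels, cl$names)
  )

  study_idx <- which(names == "STUDY")
  bounds <- c(study_idx, length(sections) + 1L)
  studies <- list()
  for (k in seq_along(study_idx)) {
    from <- study_idx[k]
    to <- bounds[k + 1] - 1L
    sec <- sections[[from]]
    sf <- section_records(
      get_section("STUDY FACTORS", from, to),
      c("Study Factor Name", "Study Factor Type",
        "Study Factor Type Term Accession Number",
        "Study Factor Type Term Source REF"),
      c("name", "type", "accession", "source_ref"))
    sf <- sf[nzchar(sf$name), , drop = FALSE]
    factors <- purrr::map(seq_len(nrow(sf)), function(i) {
      study_factor(sf$name[i],
                   ontology_annotation(sf$type[i], sf$source_ref[i],
                                       sf$accession[i]))
    })

    sa <- section_records(
      get_section("STUDY ASSAYS", from, to),
      c("Study Assay File Name", "Study Assay Measurement Type",
        "Study Assay Measurement Type Term Source REF",
        "Study Assay Measurement Type Term Accession Number",
        "Study Assay Technology Type",
        "Study Assay Technology Type Term Source REF",
        "Study Assay Technology Type Term Accession Number",
        "Study Assay Technology Platform"),
      c("filename", "measurement", "m_source", "m_accession",
        "technology", "t_source", "t_accession", "platform"))
    sa <- sa[nzchar(sa$filename), , drop = FALSE]
    assays <- purrr::map(seq_len(nrow(sa)), function(i) {
      assay_declaration(
        measurement_type = ontology_annotation(sa$measurement[i],
                                               sa$m_source[i],
                                               sa$m_accession[i]),
        technology_type = ontology_annotation(sa$technology[i],
                                              sa$t_source[i],
                                              sa$t_accession[i]),
        technology_platform = sa$platform[i],
        assay_filename = sa$filename[i]
      )
    })

    dd <- section_records(
      get_section("STUDY DESIGN DESCRIPTORS", from, to),
      c("Study Design Type", "Study Design Type Term Accession Number",
        "Study Design Type Term Source REF"),
      c("type", "accession", "source_ref"))
    dd <- dd[nzchar(dd$type), , drop = FALSE]
    design_descriptors <- purrr::map(seq_len(nrow(dd)), function(i) {
      ontology_annotation(dd$type[i], dd$source_ref[i], dd$accession[i])
    })

    protocols <- section_records(
      get_section("STUDY PROTOCOLS", from, to),
      c("Study Protocol Name", "Study Protocol Type",
        "Study Protocol Description"),
      c("name", "type", "description"))
    protocols <- protocols[nzchar(protocols$name), , drop = FALSE]

    scl <- contact_labels("Study Person")
    spl <- publication_labels("Study")
    studies[[k]] <- list(
      identifier = section_scalar(sec, "Study Identifier"),
      title = section_scalar(sec, "Study Title"),
      description = section_scalar(sec, "Study Description"),
      filename = section_scalar(sec, "Study File Name"),
      table = NULL,
      factors = factors,
      assays = assays,
      protocols = protocols,
      design_descriptors = design_descriptors,
      publications = section_records(get_section("STUDY PUBLICATIONS", from, to),
                                     spl$labels, spl$names),
      contacts = section_records(get_section("STUDY CONTACTS", from, to),
                                 scl$labels, scl$names)
    )
  }
  ids <- purrr::map_chr(studies, "identifier")
  ids[!nzchar(ids)] <- paste0("study", which(!nzchar(ids)))
  names(studies) <- make.unique(ids)

  list(investigation = investigation, studies = studies, rows = rows)
}

#' Read an ISA-Tab archive into an `isa_dataset`
#'
#' The main entry point of the package. Accepts a directory or a `.zip`
#' archive; locates and parses the investigation file, parses every declared
#' study and assay table, extracts the ordered sample list of every assay,
#' merges `Factor Value` columns from study and assay tables into per-sample
#' factor assignments, derives treatments (observed factor-level
#' combinations) and treatment groups, and validates the assembled model.
#'
#' @param path Directory or zip archive containing the ISA-Tab dataset.
#' @param investigation Optional investigation filename, overriding `i_*.txt`
#'   discovery.
#' @param registry Data-file column registry (see
#'   [default_data_file_registry()]).
#' @return A validated `isa_dataset`.
#' @examples
#' dir <- gen_faahko_like(tempfile())
#' ds <- read_isatab(dir)
#' ds
#' @export
read_isatab <- function(path, investigation = NULL,
                        registry = default_data_file_registry()) {
  if (!dir.exists(path)) {
    if (file.exists(path) && grepl("\\.zip$", path, ignore.case = TRUE)) {
      path <- unpack_archive(path)
    } else {
      isa_abort("missing_file", sprintf("'%s' is not a directory or zip", path))
    }
  }
  inv_file <- investigation %||% locate_investigation(path)
  parsed <- parse_investigation(file.path(path, inv_file))

  studies <- parsed$studies
  assay_tables <- list()
  for (sid in names(studies)) {
    st <- studies[[sid]]
    if (nzchar(st$filename)) {
      sp <- file.path(path, st$filename)
      if (!file.exists(sp)) {
        isa_abort("missing_file",
          sprintf("declared study file '%s' is missing", st$filename))
      }
      studies[[sid]]$table <- parse_table_file(sp, st$filename, registry)
    }
    for (decl in st$assays) {
      ap <- file.path(path, decl$assay_filename)
      if (!file.exists(ap)) {
        isa_abort("missing_file",
          sprintf("declared assay file '%s' is missing", decl$assay_filename))
      }
      assay_tables[[decl$assay_filename]] <-
        parse_table_file(ap, decl$assay_filename, registry)
    }
  }

  new_isa_dataset(
    path = path,
    investigation_filename = inv_file,
    investigation = parsed$investigation,
    investigation_rows = parsed$rows,
    studies = studies,
    assay_tables = assay_tables
  )
}

# Which study declares a given assay filename.
study_for_assay <- function(ds, assay_filename) {
  for (sid in names(ds$studies)) {
    fns <- purrr::map_chr(ds$studies[[sid]]$assays, "assay_filename")
    if (assay_filename %in% fns) return(ds$studies[[sid]])
  }
  isa_abort("unknown_assay",
    sprintf("assay '%s' is not declared in this dataset", assay_filename))
}
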