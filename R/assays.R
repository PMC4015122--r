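# Technology-specific assay views. An assay view wraps one assay table with
# its declaration and a technology tag; data-file retrieval dispatches on the
# tag through the data-file column registry, with a generic fallback so no
# technology ever falls through without a result.

#' Classify an assay's technology
#'
#' Case-insensitive substring rules on the declared technology type:
#' "mass spectrometry" -> `ms`, "microarray" -> `microarray` (DNA or
#' protein), "sequencing" -> `sequencing`, "NMR" -> `nmr`; anything else is
#' `generic`. Substring matching absorbs the variation across ISA
#' configurations ("DNA microarray", "protein microarray", ...).
#'
#' @param decl An `isa_assay_declaration`, or a technology-type string.
#' @return One of `"ms"`, `"microarray"`, `"sequencing"`, `"nmr"`,
#'   `"generic"`.
#' @examples
#' classify_assay("mass spectrometry")
#' classify_assay("unknown tech")
#' @export
classify_assay <- function(decl) {
  tech <- if (inherits(decl, "isa_assay_declaration")) {
    decl$technology_type$term
  } else {
    decl
  }
  classify_technology(tech)
}

classify_technology <- function(tech) {
  t <- tolower(tech)
  if (grepl("mass spectrometry", t, fixed = TRUE)) return("ms")
  if (grepl("microarray", t, fixed = TRUE)) return("microarray")
  if (grepl("sequencing", t, fixed = TRUE)) return("sequencing")
  if (grepl("nmr", t, fixed = TRUE)) return("nmr")
  "generic"
}

view_class_for_tag <- c(
  ms = "isa_ms_assay_view", microarray = "isa_microarray_assay_view",
  sequencing = "isa_seq_assay_view", nmr = "isa_nmr_assay_view",
  generic = "isa_generic_assay_view"
)

#' Technology-tagged view over one assay
#'
#' @param ds An `isa_dataset`.
#' @param assay_filename Declared assay filename.
#' @return An object of class `isa_<tag>_assay_view` / `isa_assay_view`
#'   holding the declaration, the parsed table and the technology tag.
#' @export
assay_view <- function(ds, assay_filename) {
  st <- study_for_assay(ds, assay_filename)
  decl <- purrr::detect(st$assays,
                        ~ identical(.x$assay_filename, assay_filename))
  tag <- classify_assay(decl)
  structure(
    list(declaration = decl, table = ds$assay_tables[[assay_filename]],
         technology_tag = tag),
    class = c(view_class_for_tag[[tag]], "isa_assay_view")
  )
}

#' @export
print.isa_assay_view <- function(x, ...) {
  cat(sprintf("<%s> %s: %s / %s (%d rows)\n", class(x)[1],
              x$declaration$assay_filename, x$declaration$measurement_type$term,
              x$declaration$technology_type$term, nrow(x$table$cells)))
  invisible(x)
}

# Cells of the first registry column present in the table; per-row, possibly
# empty strings.
data_file_cells <- function(view, which = c("raw", "derived"), registry) {
  which <- match.arg(which)
  labels <- registry[[view$technology_tag]][[which]]
  for (lab in labels) {
    v <- table_column_values(view$table, lab)
    if (!is.null(v)) return(v)
  }
  isa_warn("missing_column", sprintf(
    "assay '%s' has no %s data-file column (looked for: %s)",
    view$declaration$assay_filename, which, paste(labels, collapse = ", ")))
  NULL
}

#' Raw and derived data filenames of an assay
#'
#' Reads the technology-appropriate data-file column of the view's table —
#' `Raw Spectral Data File` for mass spectrometry, `Free Induction Decay
#' Data File` for NMR, `Array Data File` for microarray, `Raw Data File`
#' otherwise (and the `Derived ...` counterparts) — returning non-empty cell
#' values in file order, duplicates preserved. A missing column yields an
#' empty list with a warning, never an error.
#'
#' @param view An `isa_assay_view`.
#' @param registry Data-file column registry.
#' @return Character vector of relative file names.
#' @export
raw_data_filenames <- function(view, registry = default_data_file_registry()) {
  UseMethod("raw_data_filenames")
}

#' @export
raw_data_filenames.isa_assay_view <- function(view, registry = default_data_file_registry()) {
  v <- data_file_cells(view, "raw", registry)
  if (is.null(v)) character(0) else v[nzchar(v)]
}

#' @rdname raw_data_filenames
#' @export
derived_data_filenames <- function(view, registry = default_data_file_registry()) {
  UseMethod("derived_data_filenames")
}

#' @export
derived_data_filenames.isa_assay_view <- function(view, registry = default_data_file_registry()) {
  v <- data_file_cells(view, "derived", registry)
  if (is.null(v)) character(0) else v[nzchar(v)]
}

#' Data filenames of every assay in a dataset
#'
#' Dispatches [raw_data_filenames()] (or [derived_data_filenames()]) through
#' the technology-specific view of each declared assay.
#'
#' @param ds An `isa_dataset`.
#' @param registry Data-file column registry.
#' @return A named list, assay filename -> character vector of file names.
#' @export
dataset_raw_data_filenames <- function(ds, registry = default_data_file_registry()) {
  afs <- assay_declarations(ds)$assay_filename
  stats::setNames(
    purrr::map(afs, ~ raw_data_filenames(assay_view(ds, .x), registry)), afs)
}

#' @rdname dataset_raw_data_filenames
#' @export
dataset_derived_data_filenames <- function(ds, registry = default_data_file_registry()) {
  afs <- assay_declarations(ds)$assay_filename
  stats::setNames(
    purrr::map(afs, ~ derived_data_filenames(assay_view(ds, .x), registry)), afs)
}

# Per-row class labels for manifest building; n is the assay row count.
row_labels <- function(fa, mode, join, n) {
  if (length(fa$factor_names) == 0) return(rep("", n))
  keys <- lapply(fa$factor_names, function(fn) {
    fr <- fa$per_row[fa$per_row$factor == fn, , drop = FALSE]
    fr$key[order(fr$row)]
  })
  if (mode == "first_factor") {
    keys[[1]]
  } else {
    do.call(paste, c(keys, sep = join))
  }
}

new_manifest <- function(assay_filename, raw_files, class_labels, phenotype,
                         label_mode) {
  stopifnot(length(raw_files) == length(class_labels))
  structure(
    list(assay_filename = assay_filename, raw_files = raw_files,
         class_labels = class_labels, phenotype = phenotype,
         label_mode = label_mode),
    class = "isa_analysis_manifest"
  )
}

#' @export
print.isa_analysis_manifest <- function(x, ...) {
  cat(sprintf("<isa_analysis_manifest> %s (%s): %d raw files, %d classes\n",
              x$assay_filename, x$label_mode, length(x$raw_files),
              length(unique(x$class_labels))))
  invisible(x)
}

#' Build an analysis manifest for a mass-spectrometry assay
#'
#' The bridge towards peak-picking pipelines: the ordered raw spectral files
#' of the assay resolved against the dataset root, one class label per file
#' (the first factor's level, or the joined combination of all factor
#' levels), and the annotated sample table as phenotype data. The manifest
#' is a neutral, serializable stand-in for a peak-picking input set; no
#' spectral data is read.
#'
#' @param ds An `isa_dataset`.
#' @param assay_filename A declared mass-spectrometry assay.
#' @param label_mode `"first_factor"` or `"all_factors"`.
#' @param join Label join character for `all_factors` mode (some level
#'   strings contain `"."`, so this is configurable).
#' @param check_files If `TRUE`, error when a resolved raw file is absent on
#'   disk (metadata routinely precedes data, so the default is `FALSE`).
#' @param registry Data-file column registry.
#' @return An `isa_analysis_manifest`.
#' @export
build_ms_manifest <- function(ds, assay_filename,
                              label_mode = c("first_factor", "all_factors"),
                              join = ".", check_files = FALSE,
                              registry = default_data_file_registry()) {
  label_mode <- match.arg(label_mode)
  view <- assay_view(ds, assay_filename)
  if (view$technology_tag != "ms") {
    isa_abort("not_mass_spectrometry", sprintf(
      "assay '%s' is %s, not mass spectrometry", assay_filename,
      view$technology_tag))
  }
  build_manifest(ds, view, label_mode, join, check_files, registry)
}

#' Build an analysis manifest for a microarray assay
#'
#' Like [build_ms_manifest()] but for microarray assays: raw files come from
#' the `Array Data File` column (CEL names and the like) and class labels
#' always use all factors. The expression-measure computation itself (e.g.
#' RMA normalisation) is deliberately out of scope: the manifest carries
#' everything such a pipeline needs and nothing it computes.
#'
#' @inheritParams build_ms_manifest
#' @return An `isa_analysis_manifest`.
#' @export
build_microarray_manifest <- function(ds, assay_filename, join = ".",
                                      check_files = FALSE,
                                      registry = default_data_file_registry()) {
  view <- assay_view(ds, assay_filename)
  if (view$technology_tag != "microarray") {
    isa_abort("not_microarray", sprintf(
      "assay '%s' is %s, not microarray", assay_filename, view$technology_tag))
  }
  build_manifest(ds, view, "all_factors", join, check_files, registry)
}

build_manifest <- function(ds, view, label_mode, join, check_files, registry) {
  af <- view$declaration$assay_filename
  raw <- data_file_cells(view, "raw", registry)
  if (is.null(raw)) raw <- character(0)
  has_file <- nzchar(raw)
  if (!any(has_file)) {
    isa_abort("missing_raw_files",
      sprintf("assay '%s' lists no raw data files", af))
  }
  fa <- ds$factor_assignments[[af]] %||% extract_factors(ds, af)
  labels <- row_labels(fa, label_mode, join, nrow(view$table$cells))
  resolved <- file.path(ds$path, raw[has_file])
  if (check_files && !all(file.exists(resolved))) {
    isa_abort("missing_raw_files", sprintf(
      "missing on disk: %s",
      paste(resolved[!file.exists(resolved)], collapse = ", ")))
  }
  new_manifest(af, resolved, labels[has_file], annotated_table(ds, af),
               label_mode)
}

#' Serialize an analysis manifest to JSON
#'
#' Schema: an object with `assay_filename` (string), `label_mode` (string),
#' `raw_files` (array of strings), `class_labels` (array of strings, same
#' length), and `phenotype` (array of row objects keyed by column name).
#'
#' @param manifest An `isa_analysis_manifest`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(
    list(
      assay_filename = manifest$assay_filename,
      label_mode = manifest$label_mode,
      raw_files = manifest$raw_files,
      class_labels = manifest$class_labels,
      phenotype = manifest$phenotype
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Build a MIAME-style record from ISA metadata
#'
#' Maps investigation/study metadata onto the fields of a minimum-information
#' record for a microarray experiment: first study contact (falling back to
#' investigation contacts) -> experimenter name, laboratory and contact;
#' study title -> title; study description -> abstract; publication PubMed
#' IDs; and the assay's distinct sample count. Fields absent from the
#' metadata stay empty — nothing is invented.
#'
#' @param ds An `isa_dataset`.
#' @param assay_filename Declared assay filename.
#' @return An `isa_miame_record` (a named list).
#' @export
build_miame_record <- function(ds, assay_filename) {
  st <- study_for_assay(ds, assay_filename)
  contacts <- st$contacts
  if (nrow(contacts) == 0) contacts <- ds$investigation$contacts
  name <- lab <- contact <- ""
  if (nrow(contacts) > 0) {
    name <- trimws(paste(contacts$first_name[1], contacts$last_name[1]))
    lab <- contacts$affiliation[1]
    contact <- contacts$email[1]
  }
  pubs <- st$publications
  if (nrow(pubs) == 0) pubs <- ds$investigation$publications
  pubmed_ids <- pubs$pubmed_id[nzchar(pubs$pubmed_id)]
  structure(
    list(
      name = name, lab = lab, contact = contact,
      title = st$title, abstract = st$description, url = "",
      pubmed_ids = pubmed_ids,
      sample_count = length(unique(ds$samples[[assay_filename]]))
    ),
    class = "isa_miame_record"
  )
}

#' @export
print.isa_miame_record <- function(x, ...) {
  cat("<isa_miame_record>\n")
  cat(sprintf("  title: %s\n  experimenter: %s (%s)\n  lab: %s\n", x$title,
              x$name, x$contact, x$lab))
  cat(sprintf("  pubmed: %s\n  samples: %d\n",
              paste(x$pubmed_ids, collapse = ", "), x$sample_count))
  invisible(x)
}
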