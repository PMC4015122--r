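# Recommending analysis-package categories: a bundled table maps each ISA
# configuration's measurement/technology pair to category tags, and a
# versioned offline package index turns tags into package suggestions.

#' The bundled measurement/technology-to-category mapping
#'
#' One row per ISA configuration: configuration id, measurement type with
#' its mapped category tags, technology type with its mapped tags. Several
#' configurations (clinical chemistry, hematology, histology, the bare
#' study-sample layout) map to no categories at all; their rows are kept so
#' the table is a complete transcription.
#'
#' @param path Alternative mapping file (same TSV layout; tags
#'   semicolon-separated) to use instead of the bundled one.
#' @return A tibble with columns `config_id`, `measurement`,
#'   `measurement_views` (list of character), `technology`,
#'   `technology_views` (list of character).
#' @export
load_view_mappings <- function(path = NULL) {
  path <- path %||% system.file("extdata", "biocviews_mapping.tsv",
                                package = "isakit", mustWork = TRUE)
  tb <- utils::read.delim(path, sep = "\t", quote = "\"",
                          colClasses = "character",
                          na.strings = character(0), fill = TRUE,
                          check.names = FALSE, comment.char = "")
  tb[is.na(tb)] <- ""
  split_tags <- function(x) {
    purrr::map(x, ~ if (nzchar(.x)) strsplit(.x, ";", fixed = TRUE)[[1]]
               else character(0))
  }
  tibble::tibble(
    config_id = tb$config_id,
    measurement = tb$measurement,
    measurement_views = split_tags(tb$measurement_views),
    technology = tb$technology,
    technology_views = split_tags(tb$technology_views)
  )
}

#' Map a measurement/technology pair to category tags
#'
#' Case-insensitive match of the (measurement, technology) pair against the
#' bundled mapping; an unknown pair yields two empty tag sets with a
#' warning, never an error.
#'
#' @param measurement,technology Declared assay type strings.
#' @param mappings Mapping table, see [load_view_mappings()].
#' @return A list with character vectors `measurement_views` and
#'   `technology_views`.
#' @examples
#' map_views("metabolite profiling", "mass spectrometry")
#' @export
map_views <- function(measurement, technology,
                      mappings = load_view_mappings()) {
  norm <- function(x) tolower(trimws(x))
  hit <- norm(mappings$measurement) == norm(measurement) &
    norm(mappings$technology) == norm(technology)
  if (!any(hit)) {
    isa_warn("unknown_mapping", sprintf(
      "no category mapping for measurement '%s' / technology '%s'",
      measurement, technology))
    return(list(measurement_views = character(0),
                technology_views = character(0)))
  }
  list(
    measurement_views = unique(unlist(mappings$measurement_views[hit])),
    technology_views = unique(unlist(mappings$technology_views[hit]))
  )
}

#' Load an offline package index
#'
#' The index is a versioned snapshot mapping category tags to package names,
#' shipped as JSON (the bundled snapshot is a small synthetic curation; pass
#' your own file for a real repository dump). Requesting a snapshot id other
#' than the one a file provides is an error; looking up a tag the index does
#' not know returns an empty list, never an error.
#'
#' @param path JSON file with fields `snapshot_id` and
#'   `category_to_packages`; default is the bundled snapshot.
#' @param snapshot Optional snapshot id the caller expects.
#' @return An `isa_package_index`.
#' @export
load_package_index <- function(path = NULL, snapshot = NULL) {
  path <- path %||% system.file("extdata", "package_index_synthetic.json",
                                package = "isakit", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- structure(
    list(snapshot_id = raw$snapshot_id,
         category_to_packages = purrr::map(raw$category_to_packages,
                                           as.character)),
    class = "isa_package_index"
  )
  if (!is.null(snapshot) && !identical(snapshot, idx$snapshot_id)) {
    isa_abort("unknown_snapshot", sprintf(
      "requested snapshot '%s' but '%s' provides '%s'", snapshot, path,
      idx$snapshot_id))
  }
  idx
}

#' @export
print.isa_package_index <- function(x, ...) {
  cat(sprintf("<isa_package_index> snapshot %s: %d categories, %d packages\n",
              x$snapshot_id, length(x$category_to_packages),
              length(unique(unlist(x$category_to_packages)))))
  invisible(x)
}

index_lookup <- function(index, tags) {
  hits <- unlist(index$category_to_packages[
    intersect(tags, names(index$category_to_packages))])
  sort(unique(as.character(hits %||% character(0))))
}

#' Suggest analysis packages for every assay of a dataset
#'
#' For each declared assay, maps its measurement/technology pair to category
#' tags and unions the index entries of all mapped tags, deduplicated and
#' sorted. The result depends only on the set of tags, not on assay or
#' index order.
#'
#' @param ds An `isa_dataset`.
#' @param index An `isa_package_index` (see [load_package_index()]).
#' @param mappings Mapping table (see [load_view_mappings()]).
#' @return A named list, assay filename -> sorted character vector of
#'   package names.
#' @export
suggest_packages <- function(ds, index = load_package_index(),
                             mappings = load_view_mappings()) {
  decls <- assay_declarations(ds)
  out <- purrr::map(seq_len(nrow(decls)), function(i) {
    views <- map_views(decls$measurement[i], decls$technology[i], mappings)
    index_lookup(index, c(views$measurement_views, views$technology_views))
  })
  stats::setNames(out, decls$assay_filename)
}
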