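# ISA-Tab column grammar: every header label of a study or assay table is
# classified into exactly one kind. Qualifier columns (Unit, Term Source REF,
# Term Accession Number) attach to the nearest preceding non-qualifier column.

node_labels <- c(
  "Source Name", "Sample Name", "Extract Name", "Labeled Extract Name",
  "Assay Name", "MS Assay Name", "NMR Assay Name", "Hybridization Assay Name",
  "Scan Name", "Normalization Name", "Data Transformation Name"
)

qualifier_kinds <- c("unit", "term_source_ref", "term_accession")

#' Data-file column registry
#'
#' Which header labels hold raw and derived data filenames, per technology.
#' Mass-spectrometry assays link raw data through `Raw Spectral Data File`,
#' NMR assays through `Free Induction Decay Data File`, microarray assays
#' through `Array Data File`, and sequencing (and unrecognised technologies)
#' through the generic `Raw Data File`. Pass a modified copy to the
#' retrieval functions to override.
#'
#' @return A named list (one element per technology tag, plus `"generic"`),
#'   each with character vectors `raw` and `derived`.
#' @examples
#' default_data_file_registry()$nmr$raw
#' @export
default_data_file_registry <- function() {
  list(
    ms = list(raw = "Raw Spectral Data File",
              derived = "Derived Spectral Data File"),
    nmr = list(raw = "Free Induction Decay Data File",
               derived = "Derived Spectral Data File"),
    microarray = list(raw = "Array Data File",
                      derived = c("Derived Array Data File",
                                  "Derived Array Data Matrix File")),
    sequencing = list(raw = "Raw Data File", derived = "Derived Data File"),
    generic = list(raw = "Raw Data File", derived = "Derived Data File")
  )
}

all_data_file_labels <- function(registry = default_data_file_registry()) {
  unique(unlist(registry, use.names = FALSE))
}

#' Classify table header labels
#'
#' Maps each header label of a study or assay table to its grammatical role:
#' material/data nodes (`Sample Name`, `Extract Name`, ...), `Protocol REF`,
#' the bracketed attribute kinds (`Characteristics[x]`, `Factor Value[x]`,
#' `Parameter Value[x]`, `Comment[x]`), the qualifiers (`Unit`,
#' `Term Source REF`, `Term Accession Number`), data-file columns from the
#' technology registry, and `other_attribute` for anything else. Unknown
#' labels never fail. Matching is case-insensitive on the keyword; bracket
#' contents are kept verbatim.
#'
#' @param labels Character vector of header labels (surrounding whitespace is
#'   trimmed; cell text elsewhere never is).
#' @param registry Data-file column registry, see
#'   [default_data_file_registry()].
#' @return A tibble with one row per column: `position` (0-based), `kind`,
#'   `label`, `bracket_arg` (`NA` unless bracketed), and `owner` — for
#'   qualifier columns, the `position` of the nearest preceding non-qualifier
#'   column they annotate (`NA` otherwise, or when none precedes).
#' @examples
#' classify_columns(c("Sample Name", "Factor Value[dose]", "Unit"))
#' @export
classify_columns <- function(labels, registry = default_data_file_registry()) {
  stopifnot(is.character(labels), length(labels) > 0)
  labels <- trimws(labels)
  lower <- tolower(labels)
  data_file_lower <- tolower(all_data_file_labels(registry))

  n <- length(labels)
  kind <- character(n)
  bracket_arg <- rep(NA_character_, n)

  bracket_re <- "^(characteristics|factor value|parameter value|comment)\\s*\\[(.*)\\]$"
  for (i in seq_len(n)) {
    lab <- lower[i]
    if (grepl(bracket_re, lab)) {
      keyword <- sub(bracket_re, "\\1", lab)
      kind[i] <- switch(keyword,
        "characteristics" = "characteristic",
        "factor value" = "factor_value",
        "parameter value" = "parameter_value",
        "comment" = "comment")
      # keep the bracket contents verbatim from the original label
      bracket_arg[i] <- sub("^[^\\[]*\\[(.*)\\]$", "\\1", labels[i])
    } else if (lab %in% tolower(node_labels)) {
      kind[i] <- "node"
    } else if (lab == "protocol ref") {
      kind[i] <- "protocol_ref"
    } else if (lab == "unit") {
      kind[i] <- "unit"
    } else if (lab == "term source ref") {
      kind[i] <- "term_source_ref"
    } else if (lab == "term accession number") {
      kind[i] <- "term_accession"
    } else if (lab %in% data_file_lower) {
      kind[i] <- "data_file"
    } else {
      kind[i] <- "other_attribute"
    }
  }

  owner <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (kind[i] %in% qualifier_kinds) {
      prev <- which(!(kind[seq_len(i - 1L)] %in% qualifier_kinds))
      if (length(prev)) owner[i] <- max(prev) - 1L
    }
  }

  tibble::tibble(
    position = seq_len(n) - 1L,
    kind = kind,
    label = labels,
    bracket_arg = bracket_arg,
    owner = owner
  )
}

# For a value column at 0-based position p, the attached Unit column's
# 0-based position, or NA.
unit_position_for <- function(columns, p) {
  hit <- which(columns$kind == "unit" & !is.na(columns$owner) & columns$owner == p)
  if (length(hit)) columns$position[hit[1]] else NA_integer_
}
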