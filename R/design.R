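# Experimental-design derivation: the constructs the ISA syntax leaves
# implicit. Factor assignments merge Factor Value columns from the study and
# assay tables; treatments are the observed combinations of factor levels;
# groups are the sample sets receiving each treatment.

# Factor Value columns of a table: name, column index (1-based), attached
# Unit column index (NA if none).
fv_columns <- function(tf, kind = "factor_value") {
  if (is.null(tf)) {
    return(tibble::tibble(name = character(), col = integer(),
                          unit_col = integer()))
  }
  idx <- which(tf$columns$kind == kind)
  tibble::tibble(
    name = tf$columns$bracket_arg[idx],
    col = idx,
    unit_col = vapply(idx, function(i) {
      up <- unit_position_for(tf$columns, tf$columns$position[i])
      if (is.na(up)) NA_integer_ else up + 1L
    }, integer(1))
  )
}

col_values <- function(tf, col) if (nrow(tf$cells)) tf$cells[, col] else character(0)

col_units <- function(tf, unit_col) {
  if (is.na(unit_col)) rep(NA_character_, nrow(tf$cells)) else tf$cells[, unit_col]
}

#' Extract the factor assignment of an assay
#'
#' Collects every `Factor Value` column reachable from an assay — in the
#' assay table itself and in its study table, joined through `Sample Name` —
#' into per-row and per-sample assignments. Factor order is the declaration
#' order under `STUDY FACTORS`, followed by any undeclared `Factor Value`
#' columns in table-column order (study table first). Values are compared by
#' their grouping key (see [render_grouping_key()]); the same factor defined
#' for one sample with two different keys is an error, not a silent
#' precedence. Empty cells form an explicit `""` level, with a warning.
#'
#' @param ds An `isa_dataset`.
#' @param assay_filename Declared assay filename.
#' @return An `isa_factor_assignment`: a list with `assay_filename`,
#'   `factor_names`, `per_row` (long tibble: `row`, `sample`, `factor`,
#'   `raw`, `unit`, `key`) and `per_sample` (wide tibble: `sample` plus one
#'   key column per factor).
#' @export
extract_factors <- function(ds, assay_filename) {
  if (!assay_filename %in% names(ds$assay_tables)) {
    isa_abort("unknown_assay", sprintf("unknown assay '%s'", assay_filename))
  }
  st <- study_for_assay(ds, assay_filename)
  atf <- ds$assay_tables[[assay_filename]]
  samples <- table_column_values(atf, "Sample Name")
  n <- nrow(atf$cells)
  if (is.null(samples)) samples <- rep("", n)

  a_fv <- fv_columns(atf)
  s_fv <- fv_columns(st$table)
  s_samples <- if (is.null(st$table)) character(0) else {
    v <- table_column_values(st$table, "Sample Name")
    if (is.null(v)) character(0) else v
  }

  declared <- purrr::map_chr(st$factors, "name")
  observed <- c(s_fv$name, a_fv$name)
  factor_names <- c(intersect(declared, observed),
                    setdiff(observed, declared))
  factor_names <- unique(factor_names)

  # study-side lookup: sample -> (raw, unit) per factor, conflict-checked
  study_lookup <- list()
  for (j in seq_len(nrow(s_fv))) {
    fn <- s_fv$name[j]
    raw <- col_values(st$table, s_fv$col[j])
    unit <- col_units(st$table, s_fv$unit_col[j])
    key <- render_keys(raw, unit)
    tab <- list()
    for (i in seq_along(s_samples)) {
      sm <- s_samples[i]
      if (!is.null(tab[[sm]]) && !identical(tab[[sm]]$key, key[i])) {
        isa_abort("conflicting_factor", sprintf(
          "factor '%s' has conflicting values '%s' and '%s' for sample '%s'",
          fn, tab[[sm]]$key, key[i], sm))
      }
      tab[[sm]] <- list(raw = raw[i], unit = unit[i], key = key[i])
    }
    study_lookup[[fn]] <- tab
  }

  rows <- list()
  for (fn in factor_names) {
    a_j <- match(fn, a_fv$name)
    if (!is.na(a_j)) {
      raw <- col_values(atf, a_fv$col[a_j])
      unit <- col_units(atf, a_fv$unit_col[a_j])
      key <- render_keys(raw, unit)
    } else {
      raw <- unit <- key <- rep(NA_character_, n)
    }
    stab <- study_lookup[[fn]]
    for (i in seq_len(n)) {
      sv <- stab[[samples[i]]]
      if (!is.na(key[i]) && !is.null(sv)) {
        if (!identical(sv$key, key[i])) {
          isa_abort("conflicting_factor", sprintf(
            "factor '%s' has conflicting values '%s' (study) and '%s' (assay) for sample '%s'",
            fn, sv$key, key[i], samples[i]))
        }
      } else if (is.na(key[i])) {
        if (!is.null(sv)) {
          raw[i] <- sv$raw; unit[i] <- sv$unit; key[i] <- sv$key
        } else {
          raw[i] <- ""; unit[i] <- NA_character_; key[i] <- ""
        }
      }
    }
    if (n > 0 && any(!nzchar(key))) {
      isa_warn("empty_factor_level", sprintf(
        "assay '%s': factor '%s' has empty cells; they form an explicit \"\" level",
        assay_filename, fn))
    }
    rows[[fn]] <- tibble::tibble(row = seq_len(n), sample = samples,
                                 factor = fn, raw = raw, unit = unit, key = key)
  }

  per_row <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(row = integer(), sample = character(), factor = character(),
                   raw = character(), unit = character(), key = character())
  }
  per_row <- dplyr::arrange(per_row, .data$row)

  # per-sample wide table in first-occurrence order
  uniq <- unique(samples)
  per_sample <- tibble::tibble(sample = uniq)
  for (fn in factor_names) {
    fr <- per_row[per_row$factor == fn, , drop = FALSE]
    key_by_sample <- fr$key[match(uniq, fr$sample)]
    # a sample seen twice with different keys within the assay is a conflict
    agg <- tapply(fr$key, fr$sample, function(k) length(unique(k)))
    if (any(agg > 1)) {
      bad <- names(agg)[agg > 1][1]
      isa_abort("conflicting_factor", sprintf(
        "factor '%s' takes multiple values for repeated sample '%s'", fn, bad))
    }
    per_sample[[fn]] <- key_by_sample
  }

  structure(
    list(assay_filename = assay_filename, factor_names = factor_names,
         per_row = per_row, per_sample = per_sample),
    class = "isa_factor_assignment"
  )
}

#' @export
print.isa_factor_assignment <- function(x, ...) {
  cat(sprintf("<isa_factor_assignment> %s: %d factor(s) over %d sample(s)\n",
              x$assay_filename, length(x$factor_names), nrow(x$per_sample)))
  if (length(x$factor_names)) {
    cat("  factors:", paste(x$factor_names, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Derive treatments from a factor assignment
#'
#' A treatment is a distinct observed combination of factor levels
#' (grouping keys) across the samples of one assay — observed, not the full
#' Cartesian product, since factorial designs are frequently incomplete.
#' Treatments are ordered lexicographically by their key tuple. An assay
#' with samples but no factors has exactly one empty-combination treatment.
#'
#' @param fa An `isa_factor_assignment`.
#' @return A tibble with one row per treatment and one column per factor, in
#'   declared factor order.
#' @export
derive_treatments <- function(fa) {
  stopifnot(inherits(fa, "isa_factor_assignment"))
  ps <- fa$per_sample
  if (nrow(ps) == 0) {
    return(tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(fa$factor_names)), fa$factor_names)))
  }
  if (length(fa$factor_names) == 0) {
    return(tibble::tibble(.rows = 1))
  }
  combos <- dplyr::distinct(ps[, fa$factor_names, drop = FALSE])
  dplyr::arrange(combos, dplyr::across(dplyr::all_of(fa$factor_names)))
}

#' Derive treatment groups
#'
#' One group per treatment: the deduplicated samples whose factor-level
#' combination equals the treatment, in first-occurrence order. Groups
#' partition the sample set of the assay.
#'
#' @param fa An `isa_factor_assignment`.
#' @param treatments Treatments derived from `fa` (see [derive_treatments()]).
#' @return A tibble with the factor columns of `treatments`, a list-column
#'   `samples`, and `n_samples`.
#' @export
derive_groups <- function(fa, treatments) {
  stopifnot(inherits(fa, "isa_factor_assignment"))
  ps <- fa$per_sample
  fns <- fa$factor_names
  if (length(fns) == 0) {
    grp <- treatments
    grp$samples <- if (nrow(treatments)) list(ps$sample) else list()
    grp$n_samples <- purrr::map_int(grp$samples, length)
    return(grp)
  }
  member_key <- function(df) do.call(paste, c(unname(as.list(df[, fns, drop = FALSE])), sep = "\r"))
  ps_key <- member_key(ps)
  tr_key <- member_key(treatments)
  grp <- treatments
  grp$samples <- purrr::map(tr_key, ~ ps$sample[ps_key == .x])
  grp$n_samples <- purrr::map_int(grp$samples, length)
  grp
}

#' Annotated sample table of an assay
#'
#' A row-based, record-like view connecting each assay row's sample to every
#' factor and characteristic visible to the assay — the phenotype table that
#' downstream analysis containers consume. Row keys are sample names,
#' deduplicated with `.1`, `.2`, ... suffixes on repeats. Cell values are
#' rendered grouping keys (raw text, plus the unit term when present).
#'
#' @param ds An `isa_dataset`.
#' @param assay_filename Declared assay filename.
#' @return A tibble with `row_key` followed by one column per
#'   `Factor Value[...]` and `Characteristics[...]` column visible to the
#'   assay.
#' @export
annotated_table <- function(ds, assay_filename) {
  if (!assay_filename %in% names(ds$assay_tables)) {
    isa_abort("unknown_assay", sprintf("unknown assay '%s'", assay_filename))
  }
  fa <- ds$factor_assignments[[assay_filename]] %||% extract_factors(ds, assay_filename)
  atf <- ds$assay_tables[[assay_filename]]
  st <- study_for_assay(ds, assay_filename)
  n <- nrow(atf$cells)
  samples <- table_column_values(atf, "Sample Name")
  if (is.null(samples)) samples <- rep("", n)

  out <- tibble::tibble(row_key = make.unique(samples))
  for (fn in fa$factor_names) {
    fr <- fa$per_row[fa$per_row$factor == fn, , drop = FALSE]
    out[[paste0("Factor Value[", fn, "]")]] <- fr$key[order(fr$row)]
  }

  a_ch <- fv_columns(atf, kind = "characteristic")
  s_ch <- fv_columns(st$table, kind = "characteristic")
  s_samples <- if (is.null(st$table)) character(0) else {
    v <- table_column_values(st$table, "Sample Name")
    if (is.null(v)) character(0) else v
  }
  for (j in seq_len(nrow(a_ch))) {
    key <- render_keys(col_values(atf, a_ch$col[j]), col_units(atf, a_ch$unit_col[j]))
    out[[paste0("Characteristics[", a_ch$name[j], "]")]] <- key
  }
  for (j in seq_len(nrow(s_ch))) {
    lab <- paste0("Characteristics[", s_ch$name[j], "]")
    if (lab %in% names(out)) next  # assay-level column takes precedence
    key <- render_keys(col_values(st$table, s_ch$col[j]),
                       col_units(st$table, s_ch$unit_col[j]))
    out[[lab]] <- key[match(samples, s_samples)]
  }
  attr(out, "assay_filename") <- assay_filename
  out
}
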