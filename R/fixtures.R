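# Synthetic ISA-Tab archive generators. Two presets reproduce classic study
# designs — a one-factor knockout/wild-type LC/MS metabolomics study (6 + 6
# mice) and a two-factor leukemia stem-cell microarray study (3x3 grid with
# 5 observed combinations, 3 replicates each) — plus a seeded random-design
# generator for property testing. Raw-file names (.CDF, .CEL, ...) are
# metadata strings only; no binary payloads are written.

write_fixture_archive <- function(out_dir, name, investigation_rows,
                                  study_rows, assay_rows,
                                  study_filename, assay_filename) {
  root <- file.path(out_dir, name)
  ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root)) isa_abort("io", sprintf("cannot create '%s'", root))
  write_tsv_lines(vapply(investigation_rows, format_tsv_row, character(1)),
                  file.path(root, paste0("i_", name, ".txt")))
  write_tsv_lines(vapply(study_rows, format_tsv_row, character(1)),
                  file.path(root, study_filename))
  write_tsv_lines(vapply(assay_rows, format_tsv_row, character(1)),
                  file.path(root, assay_filename))
  root
}

fixture_investigation_rows <- function(id, title, description, study_filename,
                                       assay_filename, factors, factor_types,
                                       measurement, technology, platform,
                                       contact = NULL, pubmed = NULL,
                                       extra_rows = list()) {
  rows <- list(
    c("ONTOLOGY SOURCE REFERENCE"),
    c("Term Source Name", "NCBITAXON", "OBI"),
    c("Term Source Description", "NCBI Taxonomy", "Ontology for Biomedical Investigations"),
    c("INVESTIGATION"),
    c("Investigation Identifier", id),
    c("Investigation Title", title),
    c("Investigation Description", description)
  )
  rows <- c(rows, extra_rows)
  rows <- c(rows, list(
    c("STUDY"),
    c("Study Identifier", id),
    c("Study Title", title),
    c("Study Description", description),
    c("Study File Name", study_filename),
    c("STUDY DESIGN DESCRIPTORS"),
    c("Study Design Type", "parallel group design"),
    c("STUDY PUBLICATIONS")
  ))
  if (!is.null(pubmed)) {
    rows <- c(rows, list(
      c("Study PubMed ID", pubmed$id),
      c("Study Publication Title", pubmed$title),
      c("Study Publication Status", "published")
    ))
  }
  rows <- c(rows, list(
    c("STUDY FACTORS"),
    c("Study Factor Name", factors),
    c("Study Factor Type", factor_types),
    c("STUDY ASSAYS"),
    c("Study Assay File Name", assay_filename),
    c("Study Assay Measurement Type", measurement),
    c("Study Assay Technology Type", technology),
    c("Study Assay Technology Platform", platform),
    c("STUDY PROTOCOLS"),
    c("Study Protocol Name", "sample collection", "data acquisition"),
    c("Study Protocol Type", "material collection", "data collection"),
    c("Study Protocol Description", "Collection of biological material.",
      "Instrument acquisition run."),
    c("STUDY CONTACTS")
  ))
  if (!is.null(contact)) {
    rows <- c(rows, list(
      c("Study Person Last Name", contact$last),
      c("Study Person First Name", contact$first),
      c("Study Person Email", contact$email),
      c("Study Person Affiliation", contact$affiliation)
    ))
  }
  rows
}

#' Generate a knockout/wild-type metabolomics preset archive
#'
#' A one-factor LC/MS study in the classic two-condition design: 12 samples
#' (`WT_1..WT_6`, `KO_1..KO_6`), one declared factor `Genotype` with levels
#' `WT` and `KO` matching the sample names, an organism characteristic, and
#' one mass-spectrometry assay linking each sample to a NetCDF-style raw
#' spectral file (`<sample>.CDF`).
#'
#' @param out_dir Directory under which the archive directory is created.
#' @return Path of the generated archive root.
#' @examples
#' read_isatab(gen_faahko_like(tempfile()))
#' @export
gen_faahko_like <- function(out_dir) {
  samples <- c(paste0("WT_", 1:6), paste0("KO_", 1:6))
  genotype <- rep(c("WT", "KO"), each = 6)
  study_rows <- c(
    list(c("Source Name", "Characteristics[organism]", "Term Source REF",
           "Term Accession Number", "Protocol REF", "Sample Name",
           "Factor Value[Genotype]")),
    purrr::map(seq_along(samples), function(i) {
      c(paste0("mouse_", i), "Mus musculus", "NCBITAXON", "10090",
        "sample collection", samples[i], genotype[i])
    })
  )
  assay_rows <- c(
    list(c("Sample Name", "Protocol REF", "MS Assay Name",
           "Raw Spectral Data File")),
    purrr::map(seq_along(samples), function(i) {
      c(samples[i], "data acquisition", paste0(samples[i], ".ms"),
        paste0(samples[i], ".CDF"))
    })
  )
  inv <- fixture_investigation_rows(
    id = "faahko-like",
    title = "Metabolite profiling of FAAH knockout and wild-type spinal cords",
    description = paste("LC/MS positive-mode metabolite profiling of spinal",
                        "cords from 6 wild-type and 6 fatty acid amide",
                        "hydrolase knockout mice."),
    study_filename = "s_faahko_like.txt",
    assay_filename = "a_faahko_like_ms.txt",
    factors = "Genotype", factor_types = "genotype",
    measurement = "metabolite profiling", technology = "mass spectrometry",
    platform = "LC/MS (positive mode)",
    contact = list(last = "Doe", first = "Jane", email = "jane.doe@example.org",
                   affiliation = "Example Metabolomics Lab"),
    pubmed = list(id = "00000000", title = "Synthetic preset archive")
  )
  write_fixture_archive(out_dir, "faahko_like", inv, study_rows, assay_rows,
                        "s_faahko_like.txt", "a_faahko_like_ms.txt")
}

#' Generate a two-factor leukemia stem-cell microarray preset archive
#'
#' A transcription-profiling DNA-microarray study with two three-level
#' factors — hematopoietic progenitor cell type and genetic modification —
#' of which only five of the nine level combinations are observed (the
#' three cell types in the wild-type state, plus the two oncogene-transduced
#' conditions), with three replicate samples per combination: 15 samples,
#' each linked to a `.CEL` array data file.
#'
#' @param out_dir Directory under which the archive directory is created.
#' @return Path of the generated archive root.
#' @export
gen_armstrong_like <- function(out_dir) {
  cell_types <- c("common myeloid progenitor",
                  "granulocyte macrophage progenitor",
                  "hematopoietic stem cell")
  mods <- c("Hoxa9/Meis1a fusion protein transduced HSC",
            "murine stem cell virus (MSCV)-MLL-AF9 fusion protein transduced GMP",
            "wild type")
  combos <- list(
    c(cell_types[1], "wild type"),
    c(cell_types[2], "wild type"),
    c(cell_types[3], "wild type"),
    c(cell_types[3], mods[1]),
    c(cell_types[2], mods[2])
  )
  design <- dplyr::bind_rows(purrr::imap(combos, function(cb, k) {
    tibble::tibble(
      sample = paste0("LSC_", k, "_", 1:3),
      cell_type = cb[1], modification = cb[2])
  }))
  study_rows <- c(
    list(c("Source Name", "Characteristics[organism]", "Protocol REF",
           "Sample Name", "Factor Value[hematopoietic progenitor cell type]",
           "Factor Value[genetic modification]")),
    purrr::map(seq_len(nrow(design)), function(i) {
      c(paste0("mouse_", i), "Mus musculus", "sample collection",
        design$sample[i], design$cell_type[i], design$modification[i])
    })
  )
  assay_rows <- c(
    list(c("Sample Name", "Protocol REF", "Hybridization Assay Name",
           "Array Data File")),
    purrr::map(seq_len(nrow(design)), function(i) {
      c(design$sample[i], "data acquisition", paste0(design$sample[i], ".hyb"),
        paste0(design$sample[i], ".CEL"))
    })
  )
  inv <- fixture_investigation_rows(
    id = "armstrong-like",
    title = "Transcription profiling of leukemia stem cell models",
    description = paste("DNA microarray transcription profiling of mouse",
                        "hematopoietic progenitor populations in wild-type",
                        "and oncogene-transduced states."),
    study_filename = "s_armstrong_like.txt",
    assay_filename = "a_armstrong_like_tx.txt",
    factors = c("hematopoietic progenitor cell type", "genetic modification"),
    factor_types = c("cell type", "genotype"),
    measurement = "transcription profiling", technology = "DNA microarray",
    platform = "Affymetrix",
    contact = list(last = "Roe", first = "Riley", email = "riley.roe@example.org",
                   affiliation = "Example Stem Cell Lab"),
    pubmed = list(id = "00000001", title = "Synthetic preset archive")
  )
  write_fixture_archive(out_dir, "armstrong_like", inv, study_rows, assay_rows,
                        "s_armstrong_like.txt", "a_armstrong_like_tx.txt")
}

fixture_technologies <- list(
  ms = list(measurement = "metabolite profiling",
            technology = "mass spectrometry", raw_col = "Raw Spectral Data File",
            node = "MS Assay Name", ext = ".CDF"),
  microarray = list(measurement = "transcription profiling",
                    technology = "DNA microarray", raw_col = "Array Data File",
                    node = "Hybridization Assay Name", ext = ".CEL"),
  sequencing = list(measurement = "transcription profiling",
                    technology = "nucleotide sequencing",
                    raw_col = "Raw Data File", node = "Assay Name",
                    ext = ".fastq"),
  nmr = list(measurement = "metabolite profiling",
             technology = "NMR spectroscopy",
             raw_col = "Free Induction Decay Data File",
             node = "NMR Assay Name", ext = ".fid"),
  generic = list(measurement = "phenotyping", technology = "observation",
                 raw_col = "Raw Data File", node = "Assay Name", ext = ".dat")
)

#' Generate a seeded random factorial-design archive
#'
#' Samples `ceiling(occupancy * prod(levels))` combinations of the factorial
#' grid without replacement under a fixed seed, assigns `replicates` samples
#' to each chosen combination, and writes a complete single-assay archive.
#' The generator's own bookkeeping (the sample-to-combination table) is
#' attached to the returned path as attribute `"design"`, so parsers can be
#' checked against it. Identical seeds yield identical archives; the seed is
#' recorded in a `Comment[Fixture Seed]` row of the investigation.
#'
#' @param out_dir Directory under which the archive directory is created.
#' @param n_factors Number of factors (0 allowed: a single unfactored batch).
#' @param levels_per_factor Integer vector of level counts, recycled to
#'   `n_factors`.
#' @param replicates Samples per chosen combination (>= 1).
#' @param occupancy Fraction of the factorial grid that is observed, in
#'   (0, 1].
#' @param technology One of `"ms"`, `"microarray"`, `"sequencing"`, `"nmr"`,
#'   `"generic"`.
#' @param seed Integer seed driving all randomness.
#' @param factors_in Where the `Factor Value` columns live: the study table
#'   (usual) or the assay table.
#' @return Archive root path, with attribute `"design"` (a tibble:
#'   `sample`, one column per factor).
#' @export
gen_random_design <- function(out_dir, n_factors = 2,
                              levels_per_factor = 2, replicates = 2,
                              occupancy = 1, technology = "ms", seed = 1,
                              factors_in = c("study", "assay")) {
  factors_in <- match.arg(factors_in)
  if (!technology %in% names(fixture_technologies)) {
    isa_abort("invalid_parameter",
      sprintf("unknown technology '%s'", technology))
  }
  if (n_factors < 0 || replicates < 1 || occupancy <= 0 || occupancy > 1) {
    isa_abort("invalid_parameter",
      "need n_factors >= 0, replicates >= 1, occupancy in (0, 1]")
  }
  levels_per_factor <- rep_len(as.integer(levels_per_factor), max(n_factors, 1L))
  if (n_factors > 0 && any(levels_per_factor < 1)) {
    isa_abort("invalid_parameter", "every factor needs at least one level")
  }
  tech <- fixture_technologies[[technology]]
  factor_names <- if (n_factors > 0) paste0("factor", seq_len(n_factors)) else character(0)

  design <- with_local_seed(seed, {
    if (n_factors == 0) {
      tibble::tibble(sample = sprintf("S%03d", seq_len(replicates)))
    } else {
      grid <- expand.grid(
        purrr::imap(stats::setNames(levels_per_factor[seq_len(n_factors)],
                                    factor_names),
                    ~ paste0(.y, "_L", seq_len(.x))),
        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      n_combo <- ceiling(occupancy * nrow(grid))
      chosen <- grid[sample.int(nrow(grid), n_combo), , drop = FALSE]
      out <- chosen[rep(seq_len(n_combo), each = replicates), , drop = FALSE]
      out$sample <- sprintf("S%03d", seq_len(nrow(out)))
      tibble::as_tibble(out[, c("sample", factor_names)])
    }
  })

  fv_labels <- paste0("Factor Value[", factor_names, "]", recycle0 = TRUE)
  fv_cells <- function(i) as.character(unlist(design[i, factor_names]))
  study_header <- c("Source Name", "Characteristics[organism]", "Protocol REF",
                    "Sample Name", if (factors_in == "study") fv_labels)
  study_rows <- c(list(study_header), purrr::map(seq_len(nrow(design)), function(i) {
    c(paste0("src_", i), "Mus musculus", "sample collection",
      design$sample[i], if (factors_in == "study") fv_cells(i))
  }))
  assay_header <- c("Sample Name", "Protocol REF", tech$node,
                    if (factors_in == "assay") fv_labels, tech$raw_col)
  assay_rows <- c(list(assay_header), purrr::map(seq_len(nrow(design)), function(i) {
    c(design$sample[i], "data acquisition", paste0(design$sample[i], ".run"),
      if (factors_in == "assay") fv_cells(i),
      paste0(design$sample[i], tech$ext))
  }))

  name <- sprintf("random_%s_seed%d", technology, seed)
  inv <- fixture_investigation_rows(
    id = name,
    title = "Randomly generated factorial design",
    description = sprintf(
      "Synthetic %d-factor design, occupancy %.2f, %d replicate(s) per combination.",
      n_factors, occupancy, replicates),
    study_filename = paste0("s_", name, ".txt"),
    assay_filename = paste0("a_", name, ".txt"),
    factors = if (n_factors > 0) factor_names else "",
    factor_types = if (n_factors > 0) rep("synthetic factor", n_factors) else "",
    measurement = tech$measurement, technology = tech$technology,
    platform = "synthetic",
    extra_rows = list(c("Comment[Fixture Seed]", as.character(seed)))
  )
  root <- write_fixture_archive(out_dir, name, inv, study_rows, assay_rows,
                                paste0("s_", name, ".txt"),
                                paste0("a_", name, ".txt"))
  attr(root, "design") <- design
  root
}
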