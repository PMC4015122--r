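# Shared test fixtures: a tiny hand-built archive writer for edge cases, a
# structural dataset comparator, and an independent transcription of the
# bundled measurement/technology-to-category mapping.

tsv_line <- function(...) paste(c(...), collapse = "\t")

# Write a minimal single-study archive from raw line vectors. Any section
# can be overridden; defaults give a valid one-assay MS archive.
write_mini_archive <- function(dir,
                               study_lines = NULL,
                               assay_lines = NULL,
                               investigation_lines = NULL,
                               study_filename = "s_mini.txt",
                               assay_filename = "a_mini.txt",
                               measurement = "metabolite profiling",
                               technology = "mass spectrometry") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(investigation_lines)) {
    investigation_lines <- c(
      "INVESTIGATION",
      tsv_line("Investigation Identifier", "mini"),
      "STUDY",
      tsv_line("Study Identifier", "mini-study"),
      tsv_line("Study Title", "Minimal archive"),
      tsv_line("Study File Name", study_filename),
      "STUDY FACTORS",
      tsv_line("Study Factor Name", "dose"),
      tsv_line("Study Factor Type", "dose"),
      "STUDY ASSAYS",
      tsv_line("Study Assay File Name", assay_filename),
      tsv_line("Study Assay Measurement Type", measurement),
      tsv_line("Study Assay Technology Type", technology)
    )
  }
  if (is.null(study_lines)) {
    study_lines <- c(
      tsv_line("Source Name", "Sample Name", "Factor Value[dose]", "Unit"),
      tsv_line("src1", "S1", "10", "mg"),
      tsv_line("src2", "S2", "20", "mg")
    )
  }
  if (is.null(assay_lines)) {
    assay_lines <- c(
      tsv_line("Sample Name", "Raw Spectral Data File"),
      tsv_line("S1", "S1.CDF"),
      tsv_line("S2", "S2.CDF")
    )
  }
  writeLines(investigation_lines, file.path(dir, "i_mini.txt"))
  writeLines(study_lines, file.path(dir, study_filename))
  if (!is.null(assay_lines)) {
    writeLines(assay_lines, file.path(dir, assay_filename))
  }
  dir
}

# Structural equality of two datasets, ignoring where they live on disk and
# their provenance history.
expect_dataset_equal <- function(a, b) {
  strip <- function(ds) {
    ds$path <- NULL
    ds$provenance <- NULL
    ds
  }
  expect_equal(strip(a), strip(b))
}

# Independent transcription of the measurement/technology-to-category
# mapping shipped in extdata, kept separate from the loader on purpose.
expected_view_mappings <- function() {
  row <- function(config_id, measurement, mv, technology, tv) {
    tibble::tibble(config_id = config_id, measurement = measurement,
                   measurement_views = list(mv), technology = technology,
                   technology_views = list(tv))
  }
  dplyr::bind_rows(
    row("cellcount_flowcytometry", "cell counting", character(0),
        "flow cytometry", "FlowCytometry"),
    row("cellsorting_flowcyt", "cell sorting", character(0),
        "flow cytometry", "FlowCytometry"),
    row("clinical_chemistry", "clinical chemistry analysis", character(0),
        "", character(0)),
    row("copynumvariation_micro", "copy number variation profiling",
        "CopyNumberVariants", "DNA microarray", c("Microarray", "aCGH")),
    row("dnamethylation_micro", "DNA methylation profiling", "DNAMethylation",
        "DNA microarray", c("Microarray", "ChIPchip", "CpGIsland", "Methylseq")),
    row("dnamethylation_seq", "DNA methylation profiling", "DNAMethylation",
        "nucleotide sequencing",
        c("Sequencing", "ChIPseq", "CpGIsland", "Methylseq")),
    row("envgen survey_seq", "environmental gene survey", character(0),
        "nucleotide sequencing", "Sequencing"),
    row("genome_seq", "genome sequencing", character(0),
        "nucleotide sequencing", "Sequencing"),
    row("hematology", "hematology", character(0), "", character(0)),
    row("heterozygosity_micro", "loss of heterozygosity profiling",
        c("SNP", "CopyNumberVariants"), "DNA microarray", "Microarray"),
    row("histology", "histology", character(0), "", character(0)),
    row("histonemodification_seq", "histone modification profiling",
        "Regulation", "nucleotide sequencing", c("Sequencing", "ChIPseq")),
    row("metaboliteprofiling_ms", "metabolite profiling", "Metabolomics",
        "mass spectrometry", "MassSpectrometry"),
    row("metaboliteprofiling_nmr", "metabolite profiling", "Metabolomics",
        "NMR spectroscopy", character(0)),
    row("metagenome_seq", "metagenome sequencing", character(0),
        "nucleotide sequencing", "Sequencing"),
    row("ppi_detection_micro", "protein-protein interaction detection",
        character(0), "protein microarray", "Microarray"),
    row("protein_dna_binding_ident_micro",
        "protein-DNA binding site identification", "Regulation",
        "DNA microarray", c("Microarray", "ChIPchip")),
    row("protein_dna_binding_ident_seq",
        "protein-DNA binding site identification", "Regulation",
        "nucleotide sequencing", c("Sequencing", "ChIPseq")),
    row("protein expression_ge", "protein expression profiling", "Proteomics",
        "gel electrophoresis", character(0)),
    row("protein expression_micro", "protein expression profiling",
        "Proteomics", "protein microarray", "Microarray"),
    row("protein expression_ms", "protein expression profiling", "Proteomics",
        "mass spectrometry", c("MassSpectrometry", "Proteomics")),
    row("proteinident_ms", "protein identification", character(0),
        "mass spectrometry", c("MassSpectrometry", "Proteomics")),
    row("snpanalysis_micro", "SNP analysis", "SNP", "DNA microarray",
        c("Microarray", "GeneticVariability")),
    row("studySample", "", character(0), "", character(0)),
    row("tfbsident_micro", "transcription factor binding site identification",
        "Regulation", "DNA microarray", c("Microarray", "ChIPchip")),
    row("tfbsident_seq", "transcription factor binding site identification",
        "Regulation", "nucleotide sequencing", c("Sequencing", "ChIPseq")),
    row("transcription_micro", "transcription profiling",
        c("Transcription", "GeneExpression"), "DNA microarray",
        c("Microarray", "DifferentialExpression", "ExonArray")),
    row("transcription_rtpcr", "transcription profiling",
        c("Transcription", "GeneExpression", "DifferentialExpression"),
        "real time PCR", "qPCR"),
    row("transcription_seq", "transcription profiling",
        c("Transcription", "GeneExpression"), "nucleotide sequencing",
        c("Sequencing", "DifferentialExpression", "RNAseq"))
  )
}

# Brute-force design oracle: group samples by hashing their factor-level
# combination, independently of the package's treatment/group derivation.
oracle_groups <- function(sample_names, combo_keys) {
  stopifnot(length(sample_names) == length(combo_keys))
  env <- new.env(parent = emptyenv())
  order_seen <- character(0)
  for (i in seq_along(sample_names)) {
    k <- combo_keys[i]
    if (!exists(k, envir = env, inherits = FALSE)) {
      assign(k, character(0), envir = env)
      order_seen <- c(order_seen, k)
    }
    cur <- get(k, envir = env)
    if (!sample_names[i] %in% cur) {
      assign(k, c(cur, sample_names[i]), envir = env)
    }
  }
  lapply(stats::setNames(order_seen, order_seen), get, envir = env)
}
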