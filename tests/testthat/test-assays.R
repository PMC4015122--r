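test_that("technology classification is substring-based with a generic fallback", {
  expect_identical(classify_assay("mass spectrometry"), "ms")
  expect_identical(classify_assay("DNA microarray"), "microarray")
  expect_identical(classify_assay("protein microarray"), "microarray")
  expect_identical(classify_assay("nucleotide sequencing"), "sequencing")
  expect_identical(classify_assay("NMR spectroscopy"), "nmr")
  expect_identical(classify_assay("unknown tech"), "generic")
  decl <- assay_declaration(ontology_annotation("metabolite profiling"),
                            ontology_annotation("mass spectrometry"),
                            assay_filename = "a.txt")
  expect_identical(classify_assay(decl), "ms")
})

test_that("every declaration dispatches to a tagged view subtype", {
  tags <- c(ms = "isa_ms_assay_view", microarray = "isa_microarray_assay_view",
            sequencing = "isa_seq_assay_view", nmr = "isa_nmr_assay_view",
            generic = "isa_generic_assay_view")
  for (tech in names(tags)) {
    root <- gen_random_design(withr::local_tempdir(), n_factors = 1,
                              levels_per_factor = 2, replicates = 1,
                              technology = tech, seed = 5)
    ds <- read_isatab(root)
    v <- assay_view(ds, names(ds$assay_tables))
    expect_s3_class(v, tags[[tech]])
    expect_s3_class(v, "isa_assay_view")
    expect_identical(v$technology_tag, tech)
  }
})

test_that("raw-file retrieval reads the technology-appropriate column", {
  ms <- read_isatab(gen_faahko_like(withr::local_tempdir()))
  msv <- assay_view(ms, names(ms$assay_tables))
  files <- raw_data_filenames(msv)
  expect_length(files, 12)
  expect_true(all(grepl("\\.CDF$", files)))
  expect_identical(files, paste0(c(paste0("WT_", 1:6), paste0("KO_", 1:6)),
                                 ".CDF"))

  nmr_root <- gen_random_design(withr::local_tempdir(), n_factors = 1,
                                levels_per_factor = 2, replicates = 2,
                                technology = "nmr", seed = 9)
  nmr <- read_isatab(nmr_root)
  nv <- assay_view(nmr, names(nmr$assay_tables))
  tf <- nv$table
  fid_col <- which(tf$columns$label == "Free Induction Decay Data File")
  expect_length(fid_col, 1)
  expect_identical(raw_data_filenames(nv), unname(tf$cells[, fid_col]))

  # a view whose table lacks the registry column yields [] with a warning
  d <- write_mini_archive(
    withr::local_tempdir(),
    assay_lines = c(tsv_line("Sample Name", "Comment[note]"),
                    tsv_line("S1", "x"), tsv_line("S2", "y")))
  ds <- read_isatab(d)
  v <- assay_view(ds, "a_mini.txt")
  expect_warning(files <- raw_data_filenames(v),
                 class = "isa_missing_column_warning")
  expect_identical(files, character(0))
})

test_that("derived-file retrieval skips empty cells and honours the registry", {
  d <- write_mini_archive(
    withr::local_tempdir(),
    assay_lines = c(
      tsv_line("Sample Name", "Raw Spectral Data File",
               "Derived Spectral Data File"),
      tsv_line("S1", "S1.CDF", "S1.peaks"),
      tsv_line("S2", "S2.CDF", ""),
      tsv_line("S3", "S3.CDF", "S3.peaks"),
      tsv_line("S3", "S3b.CDF", "S3.peaks")))
  ds <- suppressWarnings(read_isatab(d))
  v <- assay_view(ds, "a_mini.txt")
  expect_identical(derived_data_filenames(v),
                   c("S1.peaks", "S3.peaks", "S3.peaks"))  # duplicates kept
  expect_length(raw_data_filenames(v), 4)

  micro <- write_mini_archive(
    withr::local_tempdir(),
    technology = "DNA microarray",
    assay_lines = c(
      tsv_line("Sample Name", "Array Data File", "Derived Array Data File"),
      tsv_line("S1", "S1.CEL", "S1.rma")))
  mds <- suppressWarnings(read_isatab(micro))
  mv <- assay_view(mds, "a_mini.txt")
  expect_identical(derived_data_filenames(mv), "S1.rma")
  expect_identical(raw_data_filenames(mv), "S1.CEL")
})

test_that("dataset-level retrieval dispatches per assay", {
  ds <- read_isatab(gen_faahko_like(withr::local_tempdir()))
  out <- dataset_raw_data_filenames(ds)
  expect_named(out, names(ds$assay_tables))
  expect_length(out[[1]], 12)

  empty <- write_mini_archive(
    withr::local_tempdir(),
    investigation_lines = c(
      "INVESTIGATION", "STUDY",
      tsv_line("Study Identifier", "noassay"),
      tsv_line("Study File Name", "s_mini.txt")))
  expect_identical(dataset_raw_data_filenames(read_isatab(empty)),
                   stats::setNames(list(), character(0)))
})

test_that("mass-spectrometry manifests carry per-file class labels", {
  ds <- read_isatab(gen_faahko_like(withr::local_tempdir()))
  af <- names(ds$assay_tables)
  m <- build_ms_manifest(ds, af, label_mode = "first_factor")
  expect_identical(m$class_labels, rep(c("WT", "KO"), each = 6))
  expect_identical(length(m$raw_files), 12L)
  expect_identical(basename(m$raw_files)[1], "WT_1.CDF")
  expect_true(all(startsWith(m$raw_files, ds$path)))
  expect_identical(nrow(m$phenotype), 12L)

  root <- gen_random_design(withr::local_tempdir(), n_factors = 2,
                            levels_per_factor = 2, replicates = 1,
                            seed = 13)
  ds2 <- read_isatab(root)
  design <- attr(root, "design")
  m2 <- build_ms_manifest(ds2, names(ds2$assay_tables),
                          label_mode = "all_factors")
  expect_identical(m2$class_labels,
                   paste(design$factor1, design$factor2, sep = "."))

  # first-factor labels are the projection of all-factor labels on factor 1
  m1 <- build_ms_manifest(ds2, names(ds2$assay_tables),
                          label_mode = "first_factor")
  expect_identical(m1$class_labels,
                   vapply(strsplit(m2$class_labels, ".", fixed = TRUE),
                          `[`, character(1), 1))
})

test_that("manifest builders refuse wrong technologies and empty file lists", {
  arm <- read_isatab(gen_armstrong_like(withr::local_tempdir()))
  arm_af <- names(arm$assay_tables)
  expect_error(build_ms_manifest(arm, arm_af),
               class = "isa_not_mass_spectrometry_error")

  ms <- read_isatab(gen_faahko_like(withr::local_tempdir()))
  expect_error(build_microarray_manifest(ms, names(ms$assay_tables)),
               class = "isa_not_microarray_error")

  bare <- write_mini_archive(
    withr::local_tempdir(),
    assay_lines = c(tsv_line("Sample Name", "Raw Spectral Data File"),
                    tsv_line("S1", ""), tsv_line("S2", "")))
  ds <- read_isatab(bare)
  expect_error(build_ms_manifest(ds, "a_mini.txt"),
               class = "isa_missing_raw_files_error")
})

test_that("the microarray manifest exposes the five treatment groups", {
  ds <- read_isatab(gen_armstrong_like(withr::local_tempdir()))
  af <- names(ds$assay_tables)
  m <- build_microarray_manifest(ds, af)
  expect_length(m$raw_files, 15)
  expect_true(all(grepl("\\.CEL$", m$raw_files)))
  expect_length(unique(m$class_labels), 5)
  expect_identical(as.integer(table(m$class_labels)), rep(3L, 5))
  expect_identical(m$label_mode, "all_factors")
})

test_that("manifests serialize to JSON and read back intact", {
  ds <- read_isatab(gen_faahko_like(withr::local_tempdir()))
  m <- build_ms_manifest(ds, names(ds$assay_tables))
  f <- tempfile(fileext = ".json")
  write_manifest_json(m, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$assay_filename, m$assay_filename)
  expect_identical(back$class_labels, m$class_labels)
  expect_identical(back$raw_files, m$raw_files)
  expect_identical(nrow(back$phenotype), 12L)
})

test_that("MIAME records trace every populated field to the metadata", {
  ds <- read_isatab(gen_armstrong_like(withr::local_tempdir()))
  af <- names(ds$assay_tables)
  rec <- build_miame_record(ds, af)
  expect_identical(rec$name, "Riley Roe")
  expect_identical(rec$lab, "Example Stem Cell Lab")
  expect_identical(rec$contact, "riley.roe@example.org")
  expect_identical(rec$title, ds$studies[[1]]$title)
  expect_identical(rec$pubmed_ids, "00000001")
  expect_identical(rec$sample_count, 15L)

  plain <- write_mini_archive(withr::local_tempdir())
  pds <- suppressWarnings(read_isatab(plain))
  prec <- build_miame_record(pds, "a_mini.txt")
  expect_identical(prec$name, "")
  expect_identical(prec$pubmed_ids, character(0))
  expect_identical(prec$sample_count, 2L)
})
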