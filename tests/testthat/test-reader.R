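test_that("investigation discovery follows the i_*.txt convention", {
  d <- withr::local_tempdir()
  file.create(file.path(d, "s_study.txt"))
  expect_error(locate_investigation(d), class = "isa_no_investigation_error")
  file.create(file.path(d, "i_Investigation.txt"))
  expect_identical(locate_investigation(d), "i_Investigation.txt")
  file.create(file.path(d, "I_other.TXT"))  # prefix/suffix case-insensitive
  expect_error(locate_investigation(d),
               class = "isa_ambiguous_investigation_error")
})

test_that("zip archives unpack, unwrapping a single top-level folder", {
  d <- gen_faahko_like(withr::local_tempdir())

  flat <- unpack_archive(zip_archive_dir(d, wrap = FALSE))
  expect_true(file.exists(file.path(flat, "i_faahko_like.txt")))

  wrapped <- unpack_archive(zip_archive_dir(d, wrap = TRUE))
  expect_identical(basename(wrapped), "faahko_like")
  expect_true(file.exists(file.path(wrapped, "i_faahko_like.txt")))

  truncated <- tempfile(fileext = ".zip")
  full <- zip_archive_dir(d)
  bytes <- readBin(full, "raw", file.info(full)$size)
  writeBin(bytes[seq_len(40)], truncated)
  expect_error(unpack_archive(truncated), class = "isa_bad_archive_error")
})

test_that("the investigation parser yields study shells in file order", {
  d <- write_mini_archive(withr::local_tempdir())
  parsed <- parse_investigation(file.path(d, "i_mini.txt"))
  expect_length(parsed$studies, 1)
  st <- parsed$studies[[1]]
  expect_identical(st$identifier, "mini-study")
  expect_identical(purrr::map_chr(st$factors, "name"), "dose")
  expect_identical(st$factors[[1]]$type$term, "dose")
  expect_identical(purrr::map_chr(st$assays, "assay_filename"), "a_mini.txt")
  expect_identical(st$assays[[1]]$measurement_type$term, "metabolite profiling")

  two <- c(
    "INVESTIGATION",
    "STUDY", tsv_line("Study Identifier", "first"),
    "STUDY", tsv_line("Study Identifier", "second"),
    tsv_line("Study Title", "the second one")
  )
  f <- file.path(withr::local_tempdir(), "i_two.txt")
  writeLines(two, f)
  parsed <- parse_investigation(f)
  expect_identical(purrr::map_chr(parsed$studies, "identifier"),
                   c(first = "first", second = "second"))
  expect_identical(parsed$studies[[2]]$title, "the second one")
})

test_that("investigation files without STUDY or with stray rows fail loudly", {
  d <- withr::local_tempdir()
  f <- file.path(d, "i_bad.txt")
  writeLines(c("INVESTIGATION", tsv_line("Investigation Identifier", "x")), f)
  expect_error(parse_investigation(f), class = "isa_missing_section_error")
  writeLines(c(tsv_line("Investigation Identifier", "x"), "STUDY"), f)
  expect_error(parse_investigation(f), class = "isa_malformed_row_error")
})

test_that("column classification is total and position-faithful", {
  cols <- classify_columns(c(
    "Sample Name", "Factor Value[Genotype]", "Characteristics[organism]",
    "Term Source REF", "Term Accession Number", "Protocol REF",
    "Parameter Value[ionisation]", "Unit", "Comment[note]",
    "Raw Spectral Data File", "Free Induction Decay Data File",
    "Completely Unknown Header"))
  expect_identical(cols$kind, c(
    "node", "factor_value", "characteristic", "term_source_ref",
    "term_accession", "protocol_ref", "parameter_value", "unit", "comment",
    "data_file", "data_file", "other_attribute"))
  expect_identical(cols$position, 0:11)
  expect_identical(cols$bracket_arg[cols$kind == "factor_value"], "Genotype")
  # qualifiers attach to the nearest preceding non-qualifier column
  expect_identical(cols$owner[4], 2L)
  expect_identical(cols$owner[5], 2L)
  expect_identical(cols$owner[8], 6L)
  expect_true(all(is.na(cols$owner[!cols$kind %in%
    c("unit", "term_source_ref", "term_accession")])))
})

test_that("arbitrary header labels always classify to exactly one kind", {
  set.seed(42)
  pool <- c("Sample Name", "Factor Value[f]", "Unit", "Weird [x",
            "characteristics[lower case]", "Array Data File", "", "  padded  ",
            "Term Source REF", "Derived Data File", "Label", "Comment[c]")
  for (i in 1:25) {
    labels <- sample(pool, sample(1:8, 1), replace = TRUE)
    cols <- classify_columns(labels)
    expect_identical(nrow(cols), length(labels))
    expect_true(all(cols$kind %in% c(
      "node", "protocol_ref", "characteristic", "factor_value",
      "parameter_value", "unit", "term_source_ref", "term_accession",
      "data_file", "comment", "other_attribute")))
  }
})

test_that("table parsing keeps order, pads ragged rows, unquotes cells", {
  d <- withr::local_tempdir()
  f <- file.path(d, "a_t.txt")
  writeLines(c(
    tsv_line("Sample Name", "Factor Value[dose]", "Comment[note]"),
    tsv_line("S1", "10", "\"a b\""),
    tsv_line("S2", "20"),          # ragged: one cell short
    tsv_line("S3", "30", "plain")
  ), f)
  expect_warning(tf <- parse_table_file(f), class = "isa_ragged_rows_warning")
  expect_identical(nrow(tf$cells), 3L)
  expect_identical(tf$cells[, 1], c("S1", "S2", "S3"))  # file order
  expect_identical(tf$cells[1, 3], "a b")               # quotes stripped
  expect_identical(tf$cells[2, 3], "")                  # padded

  writeLines(character(0), f)
  expect_error(parse_table_file(f), class = "isa_empty_table_error")
})

test_that("quoted cells preserve embedded tabs and a UTF-8 BOM is tolerated", {
  d <- withr::local_tempdir()
  f <- file.path(d, "a_q.txt")
  writeLines(c(tsv_line("Sample Name", "Comment[note]"),
               tsv_line("S1", "\"has\tan embedded tab\"")), f)
  tf <- parse_table_file(f)
  expect_identical(tf$cells[1, 2], "has\tan embedded tab")

  g <- file.path(d, "a_bom.txt")
  con <- file(g, open = "wb")
  writeBin(as.raw(c(0xEF, 0xBB, 0xBF)), con)
  writeLines(c(tsv_line("Sample Name", "Raw Data File"),
               tsv_line("S1", "S1.dat")), con)
  close(con)
  tf <- parse_table_file(g)
  expect_identical(tf$columns$label[1], "Sample Name")
})

test_that("a full archive assembles with samples, design and clean validation", {
  ds <- read_isatab(gen_faahko_like(withr::local_tempdir()))
  expect_length(ds$studies, 1)
  expect_length(ds$assay_tables, 1)
  af <- names(ds$assay_tables)
  expect_identical(length(ds$samples[[af]]), 12L)
  expect_identical(ds$factor_assignments[[af]]$factor_names, "Genotype")
  expect_identical(nrow(validate_isa(ds)), 0L)

  # parsing is deterministic: two parses of one archive are equal
  d2 <- gen_faahko_like(withr::local_tempdir())
  expect_dataset_equal(read_isatab(d2), read_isatab(d2))
})

test_that("archives without assays parse; missing declared files do not", {
  d <- write_mini_archive(
    withr::local_tempdir(),
    investigation_lines = c(
      "INVESTIGATION",
      "STUDY",
      tsv_line("Study Identifier", "empty"),
      tsv_line("Study File Name", "s_mini.txt")
    ))
  ds <- read_isatab(d)
  expect_length(ds$assay_tables, 0)
  expect_identical(length(ds$treatments), 0L)

  d2 <- write_mini_archive(withr::local_tempdir())
  file.remove(file.path(d2, "a_mini.txt"))
  expect_error(read_isatab(d2), class = "isa_missing_file_error")
})

test_that("study/assay factor conflicts error; agreement merges silently", {
  conflict <- write_mini_archive(
    withr::local_tempdir(),
    study_lines = c(
      tsv_line("Source Name", "Sample Name", "Factor Value[dose]"),
      tsv_line("src1", "S1", "10"),
      tsv_line("src2", "S2", "20")),
    assay_lines = c(
      tsv_line("Sample Name", "Factor Value[dose]", "Raw Spectral Data File"),
      tsv_line("S1", "10", "S1.CDF"),
      tsv_line("S2", "99", "S2.CDF")))  # disagrees with the study table
  err <- expect_error(read_isatab(conflict),
                      class = "isa_conflicting_factor_error")
  expect_match(conditionMessage(err), "dose")
  expect_match(conditionMessage(err), "S2")

  agree <- write_mini_archive(
    withr::local_tempdir(),
    study_lines = c(
      tsv_line("Source Name", "Sample Name", "Factor Value[dose]"),
      tsv_line("src1", "S1", "10"),
      tsv_line("src2", "S2", "20")),
    assay_lines = c(
      tsv_line("Sample Name", "Factor Value[dose]", "Raw Spectral Data File"),
      tsv_line("S1", "10", "S1.CDF"),
      tsv_line("S2", "20", "S2.CDF")))
  ds <- read_isatab(agree)
  expect_identical(ds$factor_assignments[[1]]$per_sample$dose, c("10", "20"))
})

test_that("undecodable bytes abort the parse instead of being replaced", {
  d <- withr::local_tempdir()
  f <- file.path(d, "a_latin.txt")
  con <- file(f, open = "wb")
  writeBin(charToRaw("Sample Name\tComment[note]\nS1\tcaf\xe9\n"), con)
  close(con)
  expect_error(parse_table_file(f), class = "isa_encoding_error")
})
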