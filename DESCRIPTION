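Package: isakit
Title: Parse, Model, Augment and Write ISA-Tab Experimental Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with ISA-Tab archives, the tab-separated
    Investigation/Study/Assay format for multi-omics experimental metadata.
    Parses a directory or zip archive into a typed dataset object, classifies
    every table column by its grammatical role, derives experimental-design
    constructs that the ISA syntax leaves implicit (factor assignments,
    treatments as observed factor-level combinations, treatment groups),
    exposes technology-specific assay views (mass spectrometry, microarray,
    sequencing, NMR) with analysis-ready raw-file manifests and MIAME-style
    records, writes datasets back to ISA-Tab with provenance-tracked column
    updates, and recommends analysis-package categories from a bundled
    measurement/technology mapping. Includes generators for synthetic
    ISA-Tab archives, including presets reproducing two classic study
    designs (a one-factor knockout/wild-type metabolomics study and a
    two-factor leukemia stem-cell microarray study).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
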