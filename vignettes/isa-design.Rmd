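---
title: "From ISA-Tab metadata to experimental design: the isakit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ISA-Tab metadata to experimental design: the isakit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isakit)
```

## The problem

Multi-omics experiments are described, increasingly, in ISA-Tab: a
tab-separated hierarchy of one *Investigation* file (project metadata,
contacts, publications, declared factors and assays), one or more *Study*
files (the subjects and what was done to them) and *Assay* files (how each
sample became a measurement, and which raw and derived data files hold that
measurement, with each assay defined by a measurement type / technology type
pair). The format is deliberately generic, which means the
concepts an analyst actually needs — which variables were deliberately
varied, which samples received the same combination of factor levels, which
files belong to which experimental condition — are present only implicitly,
spread across `Factor Value[...]` columns in two different tables.

isakit parses ISA-Tab archives into a typed R object, derives those implicit
design constructs, exposes technology-aware views of each assay, writes
archives back (including provenance-tracked column updates), and maps assay
types to analysis-package categories. This vignette explains the model and
the choices behind it.

## The column grammar

Study and assay tables are column-oriented: nodes (`Source Name`,
`Sample Name`, `Extract Name`, assay-name variants, ...), `Protocol REF`
edges, bracketed attributes (`Characteristics[x]`, `Factor Value[x]`,
`Parameter Value[x]`, `Comment[x]`), data-file pointers, and the qualifier
columns `Unit`, `Term Source REF` and `Term Accession Number`, which carry
no meaning of their own: each qualifier attaches to the nearest preceding
non-qualifier column. `classify_columns()` implements this grammar totally —
every label maps to exactly one kind, unknown labels become
`other_attribute` and survive round trips untouched — because failing on an
unrecognized header would make the parser unusable on the long tail of
real-world archives.

Cell text is kept verbatim: no whitespace trimming inside values (header
labels are trimmed of surrounding whitespace only), no numeric coercion, no
encoding repair. A file that is not valid UTF-8 is an error rather than a
silent substitution; metadata corruption is worse than a refusal.

## Factors, treatments, groups

A *factor* is a deliberately varied variable, declared under
`STUDY FACTORS` and valued in `Factor Value[name]` columns. Values carry an
optional `Unit`; the identity of a level is its *grouping key* — the raw
cell text, or raw text and unit term joined by one space (`"10"` + `mg` →
`"10 mg"`). Keys are compared by exact string equality, case-sensitively:
`"10 mg"` and `"10.0 mg"` are different levels. Curation fidelity beats
convenience here; a parser that second-guesses units or number formats will
eventually merge conditions that a curator kept apart.

`Factor Value` columns may sit in the study table, the assay table, or
both. `extract_factors()` merges them through `Sample Name`. When both
tables value the same factor for the same sample, agreement merges silently
and disagreement is an error naming the sample and factor — silent
precedence would hide exactly the curation mistakes this merge is meant to
surface. Empty factor cells form an explicit `""` level, with a warning:
dropping those rows would break the partition property below.

From the assignment the package derives:

* **treatments** — the distinct *observed* combinations of factor-level
  keys, ordered lexicographically. Observed, not the full Cartesian
  product: real factorial designs are routinely incomplete (the bundled
  two-factor microarray preset observes 5 of its 9 possible combinations).
  An assay with samples but no factors has exactly one empty-combination
  treatment. The lexicographic order is a determinism choice; nothing in
  the format prescribes one.
* **groups** — per treatment, the deduplicated samples carrying that
  combination, in first-occurrence order. Groups always partition the
  deduplicated sample list; `validate_isa()` enforces this, along with
  `|groups| == |treatments|`, on every constructed dataset.

Repeated sample names across assay rows are legal (one sample, several
extracts); the ordered `samples` vector keeps duplicates, group membership
does not, and the row-keyed `annotated_table()` disambiguates repeats with
`make.unique`-style `.1`, `.2` suffixes. Annotated-table cells are rendered
grouping keys rather than nested value records — the key *is* the identity
used everywhere else, and a flat tibble is what downstream phenotype
consumers want; the raw/unit split remains available from
`extract_factors()$per_row`.

## Assay views and manifests

Each declared assay is classified by case-insensitive substring rules on
its technology type (`"mass spectrometry"` → `ms`, `"microarray"` →
`microarray`, `"sequencing"` → `sequencing`, `"NMR"` → `nmr`, anything else
→ `generic`). Substrings, because configuration vocabularies vary ("DNA
microarray", "protein microarray"); a strict table can be supplied by
overriding the registry. Data-file retrieval dispatches through a
per-technology column registry — mass spectrometry reads
`Raw Spectral Data File`, NMR reads `Free Induction Decay Data File`,
microarray reads `Array Data File`, sequencing and the generic fallback
read `Raw Data File`, with the analogous derived-file columns. A missing
column yields an empty result with a warning, never an error, so dataset
level sweeps do not die on one incomplete assay.

Manifest builders (`build_ms_manifest()`, `build_microarray_manifest()`)
bundle the resolved raw-file list, one class label per file (the first
factor's key, or all keys joined with a configurable `"."`), and the
annotated phenotype table into a JSON-serializable object. This is the
package's bridge to peak-picking and normalization pipelines: everything
such a tool needs, none of what it computes. Reading spectral or array data
and any numeric processing (peak detection, RMA) are out of scope by
design. Raw-file paths are resolved against the archive root but not
required to exist — metadata legitimately precedes data — unless
`check_files = TRUE`. `build_miame_record()` maps contacts, title,
description and PubMed IDs onto a minimum-information record for microarray
experiments, leaving absent fields empty rather than inventing them.

## Writing and provenance

`write_isatab()` emits tab-separated files with `\n` endings and UTF-8
without BOM, quoting cells only when they contain a tab, newline or quote.
Round-trip is structural, not byte-exact: quoting style and line endings
normalize, but `read(write(read(A)))` equals `read(A)` over the whole
model, a property the test-suite asserts for every fixture family. The
investigation file is re-emitted from its verbatim parsed rows, which is
what lets rarely-used labels survive without being individually modelled.

`update_assay_column()` replaces an existing column's values or appends a
new column at the table end (appending anywhere else would re-parent
position-sensitive qualifiers); a single value recycles across rows. Every
update appends a timestamped entry to an append-only provenance log,
serializable as JSON lines — the archive's chain of custody through an
analysis pipeline.

## Category mapping and recommendations

A bundled table maps each measurement/technology pair to analysis-package
category tags (29 configuration rows, several of which intentionally map to
no categories at all — clinical chemistry, hematology, histology and the
bare study-sample layout have no dedicated analysis-package categories).
Matching keys are the measurement and technology strings, not the
configuration filename, because parsed datasets carry the former.
`suggest_packages()` unions the index entries of all mapped tags,
deduplicated and sorted, so the result is independent of assay and index
order. The shipped index (`package_index_synthetic.json`) is a small,
hand-curated, versioned snapshot: recommendations must be reproducible
offline, and a live repository changes continuously. Any user-supplied JSON
index with a `snapshot_id` and a `category_to_packages` map can be
substituted; asking for a snapshot id a file does not provide is an error,
while looking up an unknown tag just returns nothing.

## The synthetic archive generators

Because real archives cannot be redistributed inside the package, the
fixture module generates them:

* `gen_faahko_like()` — a one-factor, two-condition LC/MS metabolomics
  study: 12 samples (`WT_1..WT_6`, `KO_1..KO_6`), factor `Genotype` with
  levels `WT`/`KO`, one `.CDF` raw spectral file per sample, an organism
  characteristic, one contact and one publication. This replicates the
  classic 6 + 6 knockout/wild-type design used throughout the examples.
* `gen_armstrong_like()` — a two-factor transcription-profiling microarray
  study of leukemia stem-cell models: factors *hematopoietic progenitor
  cell type* and *genetic modification*, three levels each, with exactly
  five observed combinations (the three cell types in the wild-type state,
  plus HSC × Hoxa9/Meis1a and GMP × MLL-AF9) and three replicates per
  combination — 15 samples, 15 `.CEL` files. The choice of *which* five
  combinations are observed follows the biology of the modelled study (an
  oncogene-transduced condition exists only for the progenitor type it
  transforms); the counts — 2 factors, 3 levels, 5 treatments, groups of
  3 — are the anchored quantities.
* `gen_random_design()` — a seeded random factorial design: a fraction
  `occupancy` of the level grid is sampled without replacement, each chosen
  combination receives `replicates` samples, and the generator's own
  bookkeeping is attached to the result so parsers can be verified against
  it. All randomness flows through the single seed (restored afterwards, so
  callers' RNG streams are untouched), and the seed is self-described in a
  `Comment[Fixture Seed]` investigation row.

What these archives emulate is the *metadata* of real studies: structure,
design shape, file-name conventions. What they do not emulate is everything
else — real instrument output, messy hand-curated headers, vendor dialect
quirks, multi-study investigations with shared samples. A green test suite
on generated archives demonstrates the model, the derivations and the
round-trip; it does not certify the parser against every archive in the
wild, which is why unknown columns are preserved rather than rejected and
why validation reports violations in bulk instead of stopping at the first.

## Numerical and scale choices

There are no tunable numeric parameters in the model itself; the
quantities that matter are exact counts. Property suites run on synthetic
designs of 1–3 factors with 2–3 levels and 1–3 replicates — around a
hundred seeded designs at occupancies 0.3, 0.6 and 1.0 — which covers the
combinatorial edge cases (single level, empty grid fraction rounding via
the ceiling, full factorials) while keeping the default test run fast.
Degenerate inputs are defined, not rejected: zero factors give one empty
treatment; zero samples give zero groups; an assay without a `Sample Name`
column has an empty sample list.

## Known limitations

* One investigation per archive; ISA-JSON and configuration-XML validation
  are out of scope.
* Ontology annotations are carried, not verified against term sources.
* The study/assay conflict rule (error, not precedence) is this package's
  own decision; other ISA tooling may resolve the same situation silently.
* Byte-exact round-trips of exotic TSV dialects are deliberately not
  promised.
* The bundled package index is a curated stand-in, versioned and swappable,
  not a live repository snapshot.
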