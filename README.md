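# isakit

Parse, model, augment and write ISA-Tab experimental-metadata archives —
and recover the experimental design they describe.

## The problem

ISA-Tab is the tab-separated *Investigation / Study / Assay* format used to
describe multi-omics experiments (metabolomics, transcriptomics,
proteomics, ...): one investigation file aggregates project metadata and
declares studies; study tables describe subjects and applied treatments;
assay tables trace each sample to its raw and derived data files, with each
assay typed by a *measurement type* / *technology type* pair. The format is
generic on purpose, so the constructs an analyst needs are only implicit:

* **factor assignments** — which `Factor Value[X]` applies to which sample,
  merged across study and assay tables;
* **treatments** — the distinct observed combinations of factor levels
  (what the statistical literature calls *runs*);
* **groups** — the set of samples receiving each treatment, which must
  partition the sample list.

isakit derives all three at parse time, exposes technology-specific assay
views (mass spectrometry, microarray, sequencing, NMR) whose raw-file
retrieval dispatches on the declared technology, builds analysis-ready
manifests (file list + per-file class labels + phenotype table) and
MIAME-style records, writes archives back to ISA-Tab with
provenance-tracked column updates, and recommends analysis-package
categories from a bundled measurement/technology mapping.

Formally: with factors $F_1, \dots, F_k$ and per-sample level keys
$\ell_i(s)$ (raw cell text, unit-qualified as `"raw unit"`), the treatments
of an assay are the distinct observed tuples
$t = (\ell_1(s), \dots, \ell_k(s))$ over its samples — a subset of the
Cartesian product $L_1 \times \dots \times L_k$, with equality only for
full factorials — and group $G_t = \{ s : \ell(s) = t \}$, so that
$\{G_t\}$ partitions the deduplicated sample set and
$|\mathrm{groups}| = |\mathrm{treatments}|$ always.

## Worked example

The package ships generators for synthetic archives, including a preset
replicating a classic two-condition metabolomics design: spinal cords from
6 wild-type and 6 FAAH-knockout mice, profiled by LC/MS, one NetCDF raw
spectral file per sample.

```r
library(isakit)
archive <- gen_faahko_like(tempdir())
ds <- read_isatab(archive)
ds
#> <isa_dataset> /tmp/Rtmp0XvsLc/faahko_like
#>   investigation: i_faahko_like.txt (faahko-like)
#>   1 study(ies), 1 assay(s)
#>   - a_faahko_like_ms.txt [ms]: metabolite profiling / mass spectrometry; 12 samples, 2 treatments
```

`glance()` summarises the parsed design; the derived groups show the 6 + 6
partition by genotype:

```r
glance(ds)
#> # A tibble: 1 × 6
#>   n_studies n_assays n_samples n_factors n_treatments n_groups
#>       <int>    <int>     <int>     <int>        <int>    <int>
#> 1         1        1        12         1            2        2

ds$groups[["a_faahko_like_ms.txt"]]
#> # A tibble: 2 × 3
#>   Genotype samples   n_samples
#>   <chr>    <list>        <int>
#> 1 KO       <chr [6]>         6
#> 2 WT       <chr [6]>         6
```

That is the design as described: one factor (`Genotype`), two treatments
(`KO`, `WT`), and two groups of six samples each. A mass-spectrometry
manifest bundles the raw files with one class label per file, ready for a
peak-picking pipeline (the numeric processing itself is out of scope):

```r
m <- build_ms_manifest(ds, "a_faahko_like_ms.txt", label_mode = "first_factor")
m
#> <isa_analysis_manifest> a_faahko_like_ms.txt (first_factor): 12 raw files, 2 classes
table(m$class_labels)
#> KO WT
#>  6  6

suggest_packages(ds)
#> $a_faahko_like_ms.txt
#> [1] "CAMERA"  "MAIT"    "metaMS"  "MSnbase" "mzR"     "xcms"
```

The last call unions the categories mapped from the assay's
measurement/technology pair ("metabolite profiling" / "mass spectrometry" →
Metabolomics + MassSpectrometry) over a bundled offline package index.

A second preset, `gen_armstrong_like()`, reproduces a two-factor microarray
design (3 × 3 level grid, 5 observed combinations, 3 replicates each), and
`gen_random_design()` generates seeded random factorial archives for
property testing. A command-line wrapper lives at `inst/cli/isakit`
(subcommands `parse`, `summary`, `design`, `datafiles`, `update`, `write`,
`recommend`, `fixture`).

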