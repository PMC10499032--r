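# matriomics

Annotation, tabulation and composition charts for extracellular-matrix
(ECM) content in omics tables.

## The problem

The matrisome is the compendium of all genes encoding ECM and
ECM-associated proteins of an organism. It is organized as a two-level
classification:

| Division | Categories |
|---|---|
| Core matrisome (structural) | ECM Glycoproteins, Collagens, Proteoglycans |
| Matrisome-associated (non-structural) | ECM-affiliated Proteins, ECM Regulators, Secreted Factors |

Anything outside the matrisome is *Non-matrisome*. Labelling each row of a
proteomics, transcriptomics or exome table with its division and category —
and then summing each numeric column by those labels — is the first step of
almost every ECM-focused analysis, but doing it by hand means resolving
identifiers across namespaces (gene symbols, NCBI gene, UniProt, and the
species-specific Ensembl, ZFIN, FlyBase, WormBase and common-name systems)
for five model organisms: human, mouse, zebrafish, fruit fly and nematode.

`matriomics` does this mechanically and reproducibly:

- **`matriannotate()`** — normalizes the identifiers of any tabular dataset
  (case folding, multi-ID cells, UniProt isoform suffixes, Ensembl version
  suffixes), matches them against an indexed per-species matrisome
  reference list, and prepends `Annotated Matrisome Division` /
  `Annotated Matrisome Category` columns (plus an optional GO Cellular
  Component column). Non-matching rows are returned as Non-matrisome; no
  row is ever dropped.
- **`matrianalyze()`** — sums every numerically coercible column by
  division and category. Number formats are sniffed per column (dot or
  comma decimals); percent-formatted columns are excluded, and ambiguous
  thousands-grouped columns are refused rather than guessed.
- **`matribar()` / `matriring()` / `matristar()` / `matriflow()`** — bar,
  donut, polar-bar and alluvial composition charts with a fixed palette,
  built as renderer-independent specs and drawn with ggplot2
  (`render_chart()`).
- **`read_table()` / `read_skyline()` / `write_csv()`** — dialect-sniffed
  delimited input, minimal Skyline XML protein extraction, and minimally
  quoted round-trippable CSV output.
- **`make_fixture_table()`** — a deterministic generator of synthetic
  proteomics / expression / exome-count test tables.
- **`run_workflow()`** and `inst/cli/matriomics.R` — the end-to-end
  annotate and annotate+analyze workflows, from the command line if wanted.

The bundled reference lists (tags `test-human`, `test-mouse`,
`test-zebrafish`, `test-fruit_fly`, `test-nematode`) are small synthetic
test lists, 12 entries per species. Real curated matrisome lists can be
used by converting them to the documented reference CSV schema (one row
per gene: `species, division, category, gene_symbol` plus `:`-delimited
identifier-list columns) and passing the file path instead of a tag.

## Worked example

```r
library(matriomics)

ref <- load_reference("test-human", "human")
tab <- data.frame(
  Accession   = c("col1a1", "P02462", "P02751", "4313", "ZZZ999"),
  Spectra_A   = c(12, 5, 9, 4, 21),
  Spectra_B   = c(10, 7, 11, 2, 19),
  Probability = c("99.8%", "98.1%", "99.9%", "95.0%", "97.4%"))

ann <- matriannotate(tab, "Accession", "human", ref)
ann
#> Annotated table: 5 rows, 4 matrisome (80%), species human
#>   Accession Annotated Matrisome Division Annotated Matrisome Category Spectra_A
#> 1      4313         Matrisome-associated               ECM Regulators         4
#> 2    col1a1               Core matrisome                    Collagens        12
#> 3    P02462               Core matrisome                    Collagens         5
#> 4    P02751               Core matrisome            ECM Glycoproteins         9
#> 5    ZZZ999                Non-matrisome                Non-matrisome        21
```

Identifiers are matched case-insensitively across namespaces (`col1a1` by
symbol, `P02462`/`P02751` by UniProt accession, `4313` by NCBI gene ID),
rows are returned sorted by identifier, and the unknown `ZZZ999` is kept as
Non-matrisome. Tabulating:

```r
matrianalyze(ann)
#>       Matrisome Annotations Spectra_A Spectra_B
#> 1            Core matrisome        26        28
#> 2      Matrisome-associated         4         2
#> 3             Non-matrisome        21        19
#> 4         ECM Glycoproteins         9        11
#> 5                 Collagens        17        17
#> 6             Proteoglycans         0         0
#> 7   ECM-affiliated Proteins         0         0
#> 8            ECM Regulators         4         2
#> 9          Secreted Factors         0         0
#> 10 Non-matrisome (category)        21        19
```

The two spectral-count columns are summed by annotation (the three
division rows and the seven category rows each add up to the column total,
51 and 49), while the percent-formatted `Probability` column is excluded
from tabulation. `summary_counts(ann)` gives the molecule counts behind
the charts:

```r
cs <- summary_counts(ann)
render_chart(matribar(cs), "matribar.pdf")            # bar chart to PDF
render_chart(matriring(cs, "categories"), show = FALSE)  # ggplot object
```

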