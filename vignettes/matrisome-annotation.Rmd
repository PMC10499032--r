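---
title: "Annotating and tabulating matrisome content in omics tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and tabulating matrisome content in omics tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matriomics)
```

## The classification model

The matrisome classification is a fixed two-level partition of the genes
encoding extracellular-matrix and ECM-associated proteins. Six categories
map deterministically onto two divisions — ECM glycoproteins, collagens and
proteoglycans form the *core matrisome* (structural components);
ECM-affiliated proteins, ECM regulators and secreted factors form the
*matrisome-associated* division (non-structural components) — and
everything else is *Non-matrisome*. The map is exposed as
`category_division_map()` and is enforced, not inferred: a reference list
whose rows contradict it is refused at load time, because a single
inconsistent entry would silently corrupt every downstream tabulation.

Annotation is a pure lookup. There is no fuzzy matching, no ortholog
mapping and no remote queries: a row is matrisome if and only if one of
its normalized identifiers is an alias of a reference entry. This makes
the operation deterministic, order-free and auditable — the per-row
`match_log` records which alias matched and in which namespace.

## Identifier normalization

Matching across five organisms and eight identifier namespaces requires a
single normalization rule applied identically to reference aliases and to
input cells:

- trim, upper-case (human symbols are upper-case, mouse title-case,
  zebrafish lower-case; case carries no identity);
- split multi-identifier cells on `;`, `,`, `|`, preserving order — the
  first sub-identifier that hits the reference wins, the proteomics
  "leading protein" convention; no majority voting, so the outcome is
  deterministic;
- strip a UniProt isoform suffix (`P02452-2` → `P02452`) only when the
  stem is a syntactically valid UniProt accession — this guard matters
  because nematode gene names (`unc-52`, `epi-1`) end in hyphen-digits
  that are part of the name;
- strip a trailing `.version` from Ensembl-style IDs
  (`ENSG00000108821.13` → `ENSG00000108821`).

Within a reference, an identifier shared by two entries with the same
(division, category) is tolerated as a warning (real lists contain such
collisions; the first-loaded entry wins for provenance reporting), but a
key shared across *different* classifications is a validation error: we
chose to refuse rather than pick a winner, since any silent precedence
rule would be invisible to the user whose protein it misclassifies.

## Output contracts

The annotated table keeps the identifier column first, then the division,
category and optional GO:CC columns, then all remaining input columns in
their original order; row count always equals input row count (blank
identifiers are logged and kept as Non-matrisome rather than dropped).
Rows are sorted byte-wise on the upper-cased identifier — plain codepoint
ordering, not locale collation, so the same input produces the same file
on any machine. Ties between duplicate identifiers are broken by the
row's remaining cell values, which makes the sorted output a pure
function of the row *set*: permuting the input cannot change the output.
Re-annotating an annotated table replaces its annotation columns instead
of stacking new ones, so the operation is idempotent.

The tabulation has a fixed 10-row schema — the three divisions, then the
six categories plus "Non-matrisome (category)" — emitted in one table,
with zero-member annotations present as 0. A fixed schema keeps outputs
from different datasets diffable and lets the conservation identities be
checked mechanically: for every coercible column, division rows and
category rows each sum to the column total (exactly, for integer data),
and each division equals the sum of its categories. Sums are reported at
full precision; rounding is the caller's decision.

## Number-format sniffing

Tabulation must decide which text columns are numbers. Per column, using
only non-empty cells and a 90% agreement threshold (sporadic footnote
cells should not flip a numeric column):

- ≥90% dot-decimal numerics → coercible, dot rule;
- ≥90% single-comma numerics with no dots → comma-decimal (`3,14` =
  3.14), *unless* every comma placement is consistent with 3-digit
  thousands grouping (`1,204`), in which case the column is refused:
  silently reading `1,204` as 1.204 would corrupt sums, and exclusion is
  the safer error;
- ≥90% numeric-prefix-`%` cells → flagged percent and excluded, since a
  percentage is not an additive quantity;
- anything else → non-coercible.

Empty cells in coercible columns count as 0 in sums — the
spreadsheet-style expectation for count data — and classification depends
only on the multiset of cell values, so it is invariant under row
permutation. Note that any plain-number column is tabulated, including
metadata such as molecular masses; the package does not try to guess which
numeric columns are scientifically meaningful to sum.

## Charts

All four chart types are built as renderer-independent specs (label,
value, geometry hints, palette) and only then drawn with ggplot2; the spec
is serializable to JSON (`chart_spec_json()`) so chart geometry can be
tested and diffed without a graphics device.

- *matribar*: molecule counts per division and per category.
- *matriring*: angular fraction = count / total over non-zero groups
  (fractions sum to 1).
- *matristar*: angular width ∝ molecule count, radial bar height ∝ the
  per-category aggregate (e.g. mean expression), both normalized per
  chart — width to fractions of the circle, height linearly to the unit
  radius, with the normalization constants recorded in the spec.
  Per-chart (not global) height scaling was chosen so a single chart is
  always readable in isolation; comparing bar heights *across* charts
  therefore requires the recorded `height_norm`.
- *matriflow*: a two-pillar alluvial — grouping values flow into
  categories, ribbon weight = row count, so per-source weights sum to the
  source's row count. Ribbons are drawn as straight-edged polygons.

The palette is a pure constant (`matrisome_palette()`): a label has the
same hue in every chart, dataset and species, which is the actual
contract — the specific hex values are a documented default. Rendering
uses fixed size, resolution and cairo devices, so a given spec yields a
byte-identical PNG on repeated rendering (PDF output embeds device
timestamps and is only content-stable).

## The synthetic-data generator

`make_fixture_table()` emulates the shape of real inputs, most importantly
a label-free proteomics table: an accession column, three integer
spectral-count columns (negative binomial, size 2, mean 20 — overdispersed
counts of a typical magnitude for label-free data), a molecular-mass
column (log-normal around 50 kDa) and a percent-formatted identification
probability column (90–100%), so the percent-exclusion path is exercised
by construction. Matrisome rows draw a random alias from a random
namespace of the reference, in random case, occasionally with an isoform
suffix or packed into a multi-ID cell; decoy rows use identifiers
guaranteed absent. Defaults are 500 rows, 3 samples and a matrisome
fraction of 0.25, in the range of ECM-enriched proteomics experiments.

What the generator does **not** emulate: correlated abundances between
samples, shared peptides between protein groups, missing-at-random
patterns with structure, or real identifier noise (typos, obsolete
accessions). Passing tests therefore demonstrate the *mechanics* —
matching, conservation, ordering, exclusion — on realistic shapes, not
biological validity on any particular real dataset.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence comparison (index vs an
O(rows × entries × aliases) brute-force scan) on 200 random fixtures of up
to 1,000 rows, the conservation identities on 200 fixtures, the chart
identities on 100, and one 100,000-row annotate+tabulate pass; the
acceptance script uses a 5,000-row table for its headline quantities plus
a 100,000-row timing pass. Conservation is asserted exactly for integer
columns and to floating-point tolerance for decimal ones (partial sums of
doubles are order-sensitive). The bundled references are synthetic
12-entry-per-species test lists with every legal namespace populated;
converting an official curated list into the reference CSV schema is a
one-off reformatting exercise documented in `?load_reference`.

## Known limitations

- Reference lists are consumed as data; cross-references are not
  re-derived from genome annotation databases.
- The Skyline reader extracts only protein identifiers and peptide counts
  from a minimal element/attribute subset, not the full document model.
- GO:CC annotation requires a user-supplied local mapping table; the
  package ships only a tiny synthetic one for tests and performs no live
  ontology queries. The GO:CC column is filled for matrisome rows too —
  strictly more informative than restricting it to non-matrisome rows.
- The workflow bundle is a gzip-compressed tar archive written with R's
  built-in archiver, requiring no external tooling.
- Identifier ordering is plain codepoint ordering on the upper-cased key;
  mixed-script identifiers sort by byte value, not by any linguistic
  collation.
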