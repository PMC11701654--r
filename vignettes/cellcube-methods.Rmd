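---
title: "Corpus aggregation, marker derivation and validation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corpus aggregation, marker derivation and validation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcube)
```

`cellcube` implements the computational core of a curated single-cell
corpus: schema validation of contributed datasets, the quality-control and
normalization pipeline, ontology-aware aggregation into an expression
cube, computationally derived marker genes, and the statistics used to
validate both. This vignette documents the models, the parameters that
matter, and the design decisions that were genuinely open.

## The data model and schema

A dataset is a cells x genes matrix of **raw counts** (mapped but not
normalized) with per-cell metadata and at least one two-dimensional
embedding. The metadata schema is deliberately minimal — eleven required
fields: eight ontology CURIEs (organism, tissue, cell type, assay,
disease, sex, self-reported ethnicity, developmental stage), a free-text
donor id, the `suspension_type` enum (`cell`, `nucleus`, `na`) and the
logical `is_primary_data`. The last field exists because corpora contain
duplicated observations (an original study and a meta-analysis may both
submit the same cells); flagging each observation as primary exactly once
lets corpus-wide aggregation avoid double counting.
`check_primary_uniqueness()` enforces that rule across datasets, keying
cells by barcode + donor since no global cell registry exists.

Validation is syntactic by default: CURIE fields must match their
configured prefix (`cc_schema()` makes every prefix overridable), and
term-existence checking only applies when an ontology is supplied —
pinning ontology releases is out of scope. Missing fields and malformed
values are errors; unknown extra columns are informational only, because
the schema is explicitly extensible.

## Preprocessing pipeline

`run_preprocess()` applies, in order:

1. **Primary-data deduplication** — only cells with
   `is_primary_data = TRUE` proceed.
2. **Low-coverage filter** — a cell expressing (raw count > 0) fewer than
   500 genes is removed; exactly 500 is retained. "Expressed" must mean a
   positive raw count here because the step precedes normalization.
3. **Assay allow-list** — only assays that measure expression without
   gene-length normalization are kept; the 12 eligible EFO terms ship in
   `inst/extdata/assay_allowlist.tsv`.
4. **ln(CPTT + 1) normalization** — each count becomes
   `ln(count / total * 10000 + 1)` (counts per ten thousand). Before the
   log, per-cell scaled counts sum exactly to the scale factor; the
   transform is strictly increasing in the count at fixed total. The
   batch-effect analyses use a scale factor of 1e6 instead.
5. **Low-expression masking** — values at or below 3 become *missing*
   (dropped from the sparse structure), never zero, so non-zero means are
   unaffected by masking artifacts.

The masking threshold's scale is the one genuinely ambiguous rule: "counts
less or equal than 3" appears immediately after the normalization step, so
the default applies the threshold to the normalized values; a `scale =
"raw"` switch applies it to raw counts instead, and the threshold itself is
configurable. A rankit quantile normalization
(`normalize_quantile()`: non-zero entries mapped by rank to
`qnorm((r - 0.5)/m)`, zeros untouched) is provided purely as a comparison
arm for the validation statistics, not for display.

## The expression cube and ontology roll-up

`build_cube()` summarizes each (tissue, cell type, gene) stratum —
optionally subdivided by metadata facets such as sex or disease — by the
mean over *present* values only (the heatmap dot color), the count of
expressing cells, and the post-QC stratum size (together, the dot size).
Both numerator and denominator are stored so either display convention is
reproducible. Datasets are combined along the union of their gene axes; a
gene absent from a dataset's gene list is treated as unmeasured, not zero,
for that dataset's cells — absence of measurement is not a measured zero —
so it contributes to neither the mean nor that gene's cell-count
denominator.

Because different datasets annotate at different granularity (one study's
"lymphocyte" is another's "B cell"), `cube_rollup()` attributes each
cell's measurements to every ancestor of its annotated Cell Ontology term.
Roll-up uses **set semantics**: a term's value is the sum over the set of
cells annotated at the term or any descendant, so a cell is counted once
per ancestor even when a true DAG offers multiple paths (the ontology is
tree-*like* but not a tree; summing along paths would inflate diamonds).
Rolled means are recomputed from rolled sums and rolled expressing-cell
counts — exact, whereas averaging per-term means would weight terms
instead of cells. Roll-up is computed within each tissue (and facet)
stratum separately, matching the per-tissue concatenation of the
normalization step. `prune_colinear()` implements the evaluation-side
counterpart: when two evaluated types lie on one ancestor–descendant
path, the more basal type is redundant and removed, leaving an antichain.

## Marker genes

For a target cell type in a tissue, every gene is compared against each
other cell type in the same tissue with Welch's t-test on the masked
normalized values (a Student's pooled-variance variant mirrors the
sensitivity study). The ranking statistic is not the t value but a
standardized mean difference with unpooled average variance,

$$d = \frac{\bar{x}_a - \bar{x}_b}{\sqrt{(s_a^2 + s_b^2)/2}},$$

so group sizes do not dominate the ordering. Per gene, the effects across
comparisons are summarized by the **10th percentile** — a "worst typical"
discrimination, demanding that the gene separates the target from
essentially all other types, not just one. With few comparisons that
percentile is noisy, so it is bootstrap-smoothed: resample the effect list
with replacement, take each replicate's 10th percentile (linear
interpolation between order statistics), and average the replicates. The
top 25 genes by aggregated effect are reported, ties broken by gene id.

Open parameters, decided here: 100 bootstrap replicates (the estimate's
Monte-Carlo error is already far below between-seed ranking differences at
100; replicates resample the *effect list*, not cells, since it is the
percentile that needs smoothing); a minimum of 5 present values per group,
below which a comparison is skipped rather than producing an unstable
variance estimate; no expression floor on candidate genes; zero-variance
comparisons with unequal means are clamped to a ±1e6 sentinel and flagged
rather than propagating infinities. Resample indices are drawn once per
comparison count and shared across genes — a valid bootstrap for each gene
individually, and what makes the computation vectorizable. Facet filters
(disease, sex, …) deliberately do not re-trigger marker computation: the
cube honours facets, markers ignore them.

## Validation statistics

**Marker recall.** Predicted markers are compared against a reference
table per (tissue, cell type): recall = overlap / reference size. The
"probability of observing this level of sensitivity by chance" is not
specified in form anywhere; it is modelled here as the exact
hypergeometric upper tail `P[X >= overlap]` for drawing
`n_predicted` genes from the tissue's expressed-gene universe containing
`n_reference` reference genes — the standard overlap null. Colinear
reference types are pruned first, and the recall study uses the Student
variant, matching how the sensitivity analysis was run.

**Batch effects.** A one-way repeated-measures ANOVA treats each gene's
per-covariate-level average expression (zeros excluded) as the dependent
variable, genes as the repeated subjects, and the covariate (dataset id or
assay) as the within-subject factor. Unbalanced designs are accepted by
dropping genes that miss a level (complete-case); a single complete gene
leaves no error degrees of freedom, and the row is reported with an
undefined statistic rather than silently dropped. The study runs under raw
counts, ln(counts-per-million + 1) and quantile normalization so the three
can be compared. No marker or housekeeping list is bundled as truth; gene
sets are user-supplied.

## Streaming statistics

Corpus-scale computations cannot hold cells x genes in memory, so
per-gene mean and variance are computed in one pass over fixed-size cell
chunks (`iter_chunks()`) with Welford/Chan state updates: the state is
O(genes) — count, running mean, running sum of squared deviations — and
two states over disjoint cell ranges merge exactly. Within a chunk the
squared deviations are accumulated *centered*; the uncentered
sum-of-squares shortcut cancels catastrophically on data with large means
and tiny variances, which is exactly the regime the agreement tests
exercise (mean 1e8 with unit variance, a relative spread of 1e-8, within 1e-9
relative of the two-pass reference). Highly variable genes are ranked by the variance of the
normalized values — the simplest criterion computable in one pass — with a
dispersion (variance/mean) alternative for count-scale input; the ranking
is chunking-invariant and reports the sample (n−1) variance by default.

## The synthetic corpus generator

`generate_corpus()` emulates the corpus structure the pipeline assumes,
not transcriptome realism: relative gene abundances are Gamma(2, 2),
per-cell library sizes log-normal (sdlog 0.3) around an expected depth of
4000 counts, and counts Poisson given rate x library size — the standard
Gamma–Poisson (negative binomial) stand-in for droplet data. Defaults: 2
datasets x 2 tissues x 4 cell types x 200 cells, 1000 genes, 5 planted
markers per type at fold-change 4. The cell-type labels come from a small
Cell Ontology fragment that includes a colinear pair (plasma cell under B
cell), so mixed annotation granularity, roll-up and colinear pruning are
exercised by default.

Three generator decisions matter for interpreting test results:

* **Planted markers are drawn from the upper abundance quartile.** After
  the ≤3 mask, a fold-change planted on a lowly expressed gene leaves
  almost no present values in the comparison groups — every comparison is
  skipped at the 5-cell minimum and the gene is unobservable *by any
  method*. Canonical marker sets are robustly expressed genes, so the
  generator plants signal where signal can exist.
* **The batch effect is a dataset-level global factor**
  (`exp(batch_effect * (i - (n+1)/2))` on expected library size). A
  per-gene random shift is a gene x dataset interaction that inflates the
  repeated-measures error term and produces no main effect under any
  normalization; a dataset-wide depth/efficiency shift is the batch effect
  the normalization comparison is about — raw averages detect it, per-cell
  normalization cancels it.
* **QC truth is exact by construction.** Planted low-coverage cells are
  restricted to 300 expressed genes; every other cell is deterministically
  topped up to at least 500 expressed genes, so the set of cells each
  filter removes is known exactly, not probabilistically.

What passing tests therefore show: the pipeline's algebra (filters,
normalization, roll-up, cube, streaming) is exact, and the marker and
batch statistics behave correctly when their assumptions hold. What they
do not show: performance on real data with ambient RNA, doublets,
cell-type-specific capture biases, correlated genes or noisy annotations —
none of which the generator emulates.

## Numerical choices and problem sizes

Percentiles use linear interpolation between order statistics (R type 7).
Top-k ties break by (effect descending, gene id ascending). Cells with
zero total counts are rejected by normalization with an explicit error
(they cannot occur after the coverage filter, which requires ≥500
expressed genes). All randomness flows from explicit seeds: corpus
generation from `synth_config(seed=)`, marker bootstraps from the `seed`
argument, and the pipeline's single top-level seed; reruns are
byte-identical.

The test suite and the acceptance script run on corpora of 600–1000 genes
and 100–200 cells per type, with 30 replicate corpora for the null
calibration of the batch ANOVA and 200 random DAGs (≤12 nodes, diamonds
included) for the roll-up oracle — sizes chosen so the full suite exercises
every claim in minutes while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

H5AD containers are not read directly; datasets are exchanged as
MatrixMarket + TSV triplets. The ontology reader takes a plain child→parent
edge list and models only `is_a`-style subsumption (no `part_of` or
`develops_from` reasoning, no UBERON tissue roll-up). Mixed-model
alternatives for unbalanced repeated measures are out of scope, as are
doublet detection, ambient-RNA correction and gene-length normalization
for full-length assays (excluded by the assay criterion itself).
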