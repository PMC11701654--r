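Package: cellcube
Title: Schema Validation, Aggregation and Marker Derivation for Curated Single-Cell Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building corpus-level views of curated single-cell
    RNA-seq data: validation of datasets against a minimal 11-field
    cell-level metadata schema, quality filtering (primary-data
    deduplication, low-coverage removal, assay allow-list), ln(CPTT+1)
    normalization with low-expression masking, Cell Ontology roll-up of
    expression sums and cell counts, per cell-type/gene expression cubes,
    computationally derived marker genes ranked by bootstrapped
    10th-percentile Welch effect sizes, batch-effect and marker-recall
    validation statistics, out-of-core streaming mean/variance and highly
    variable gene selection, and a seeded synthetic-corpus generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
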