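# shared fixtures: hand-built datasets, cached synthetic corpora, DAG oracle

make_cells <- function(n, ...) {
  df <- data.frame(
    organism = "NCBITaxon:9606", tissue = "UBERON:0002048",
    cell_type = "CL:0000236", assay = "EFO:0009899",
    disease = "MONDO:0000001", sex = "PATO:0000383",
    self_reported_ethnicity = "HANCESTRO:0005",
    development_stage = "HsapDv:0000087",
    donor_id = "donor01", suspension_type = "cell",
    is_primary_data = TRUE, stringsAsFactors = FALSE)
  df <- df[rep(1, n), , drop = FALSE]
  rownames(df) <- sprintf("BC%03d", seq_len(n))
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

make_dataset <- function(counts, ..., name = "test") {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("G%03d", seq_len(ncol(counts)))
  n <- nrow(counts)
  emb <- matrix(as.numeric(seq_len(2 * n)), n, 2)
  cc_dataset(counts, make_cells(n, ...), embeddings = list(pca = emb),
             name = name)
}

# small corpora are expensive enough to share across tests
.corpus_cache <- new.env(parent = emptyenv())
cached_corpus <- function(key, cfg) {
  if (is.null(.corpus_cache[[key]]))
    assign(key, generate_corpus(cfg), envir = .corpus_cache)
  get(key, envir = .corpus_cache)
}

small_synth_config <- function(n_genes = 600, cells_per_type = 120, ...) {
  synth_config(tissues = "UBERON:0002048", n_genes = n_genes,
               cells_per_type = cells_per_type, ...)
}

# random DAG with a unique super-root, edges child -> parent
random_dag <- function(n, p = 0.35) {
  nodes <- paste0("T", seq_len(n))
  edges <- list()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    if (stats::runif(1) < p)
      edges[[length(edges) + 1L]] <- c(nodes[i], nodes[j])
  em <- do.call(rbind, edges)
  df <- if (is.null(em))
    data.frame(child = character(), parent = character(),
               stringsAsFactors = FALSE)
  else data.frame(child = em[, 1], parent = em[, 2],
                  stringsAsFactors = FALSE)
  roots <- setdiff(nodes, df$child)
  rbind(df, data.frame(child = roots, parent = "ROOT",
                       stringsAsFactors = FALSE))
}

# independent reachability oracle: fixed-point closure on the edge list
brute_descendants <- function(edges, term) {
  desc <- term
  repeat {
    new <- setdiff(edges$child[edges$parent %in% desc], desc)
    if (!length(new)) return(sort(desc))
    desc <- c(desc, new)
  }
}
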