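#' Synthetic-corpus configuration
#'
#' Describes a seeded multi-dataset corpus with known structure so every
#' pipeline stage can be tested without external data: a Gamma-Poisson
#' (negative binomial) count model with log-normal library sizes, planted
#' marker genes with a known fold-change, optional per-dataset
#' multiplicative batch shifts, and planted QC failures (low-coverage
#' cells, non-primary duplicates, disallowed assays).
#'
#' Cell types are drawn from a small Cell Ontology fragment and include a
#' colinear pair (plasma cell below B cell), so annotation granularity is
#' mixed and the roll-up and colinear-pruning paths are exercised by
#' default.
#'
#' @param n_datasets number of datasets in the corpus.
#' @param tissues tissue CURIEs; every dataset covers every tissue.
#' @param cell_types annotated cell-type CURIEs used as labels.
#' @param cell_type_tree data.frame (child, parent) edges of the ontology
#'   fragment covering `cell_types`.
#' @param cells_per_type cells per (dataset, tissue, cell type).
#' @param n_genes genes per dataset.
#' @param depth expected library size (counts per cell).
#' @param gene_mean_shape,gene_mean_rate Gamma parameters for relative
#'   gene abundances.
#' @param libsize_sdlog log-normal sd of per-cell library-size factors.
#' @param markers_per_type planted marker genes per cell type.
#' @param marker_fold expression fold-change of planted markers in their
#'   type.
#' @param marker_abundance_q abundance quantile above which marker genes
#'   are drawn (planted markers are robustly expressed genes).
#' @param batch_effect log-scale magnitude of the per-dataset global
#'   multiplicative expression shift (a depth/capture-efficiency batch
#'   effect); dataset i is scaled by exp(batch_effect * (i - (n+1)/2)), so
#'   0 disables batch effects. Per-cell normalization cancels this shift;
#'   raw-count averages do not.
#' @param frac_low_coverage fraction of cells planted to fail the
#'   500-expressed-genes filter.
#' @param low_coverage_genes expressed genes given to a planted
#'   low-coverage cell (must be < 500).
#' @param frac_nonprimary fraction of cells flagged `is_primary_data =
#'   FALSE`.
#' @param frac_bad_assay fraction of cells assigned an assay outside the
#'   allow-list.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `cc_synth_config` list.
#' @export
synth_config <- function(n_datasets = 2,
                         tissues = c("UBERON:0002048", "UBERON:0000178"),
                         cell_types = c("CL:0000084", "CL:0000236",
                                        "CL:0000786", "CL:0000576"),
                         cell_type_tree = data.frame(
                           child = c("CL:0000084", "CL:0000236",
                                     "CL:0000786", "CL:0000542",
                                     "CL:0000576"),
                           parent = c("CL:0000542", "CL:0000542",
                                      "CL:0000236", "CL:0000988",
                                      "CL:0000988"),
                           stringsAsFactors = FALSE),
                         cells_per_type = 200,
                         n_genes = 1000,
                         depth = 4000,
                         gene_mean_shape = 2, gene_mean_rate = 2,
                         libsize_sdlog = 0.3,
                         markers_per_type = 5,
                         marker_fold = 4,
                         marker_abundance_q = 0.75,
                         batch_effect = 0,
                         frac_low_coverage = 0,
                         low_coverage_genes = 300,
                         frac_nonprimary = 0,
                         frac_bad_assay = 0,
                         seed = 1) {
  cfg <- as.list(environment())
  if (n_datasets < 1 || cells_per_type < 1 || n_genes < 1 || depth <= 0)
    stop("invalid config: sizes must be positive")
  if (low_coverage_genes >= 500)
    stop("invalid config: low_coverage_genes must be < 500")
  if (frac_low_coverage > 0 && (n_genes < 500 || low_coverage_genes >= n_genes))
    stop("invalid config: planting low-coverage cells requires ",
         "n_genes >= 500 (and > low_coverage_genes), or the filter ",
         "removes every cell")
  if (marker_fold <= 0) stop("invalid config: marker_fold must be > 0")
  graph <- cc_ontology(cell_type_tree)  # errors on cycles
  if (!all(cell_types %in% graph$nodes))
    stop("invalid config: cell_types must appear in cell_type_tree")
  structure(cfg, class = "cc_synth_config")
}

#' Generate a synthetic corpus with ground truth
#'
#' Draws counts from the Gamma-Poisson model of [synth_config()]: relative
#' gene abundances are Gamma, a cell's expected library size is depth times
#' a log-normal factor, planted markers multiply their type's rates by the
#' configured fold (renormalized within type), and per-dataset batch shifts
#' multiply gene rates. Planted low-coverage cells are restricted to fewer
#' than 500 expressed genes; all other cells are deterministically topped
#' up to at least 500 so the ground-truth QC table is exact.
#'
#' @param config a [synth_config()].
#' @return list with `datasets` (list of [cc_dataset()]), `graph` (the
#'   ontology fragment) and `truth`: `markers` (tissue, cell_type, gene),
#'   `low_coverage`, `nonprimary`, `bad_assay` (dataset, barcode tables)
#'   and `batch_factors`.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "cc_synth_config"))
  set.seed(config$seed)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  gene_means <- stats::rgamma(config$n_genes, shape = config$gene_mean_shape,
                              rate = config$gene_mean_rate) + 1e-6
  p <- gene_means / sum(gene_means)

  # plant markers on robustly expressed genes (upper abundance quartile):
  # canonical markers are well-expressed, and a fold-change on a gene that
  # never clears the low-expression mask is observable by no method
  eligible <- genes[gene_means >= stats::quantile(gene_means,
                                                  config$marker_abundance_q)]
  marker_pool <- sample(eligible, config$markers_per_type *
                          length(config$cell_types))
  markers <- split(marker_pool,
                   rep(config$cell_types, each = config$markers_per_type))
  type_rates <- lapply(setNames(config$cell_types, config$cell_types),
                       function(ty) {
    fold <- rep(1, config$n_genes)
    fold[match(markers[[ty]], genes)] <- config$marker_fold
    q <- p * fold
    q / sum(q)
  })

  allow <- default_assay_allowlist()
  datasets <- list()
  truth_lc <- truth_np <- truth_ba <- list()
  batch_factors <- list()

  for (di in seq_len(config$n_datasets)) {
    dname <- sprintf("synthds%02d", di)
    bf <- exp(config$batch_effect * (di - (config$n_datasets + 1) / 2))
    batch_factors[[dname]] <- bf

    plan <- expand.grid(tissue = config$tissues,
                        cell_type = config$cell_types,
                        idx = seq_len(config$cells_per_type),
                        stringsAsFactors = FALSE)
    n_cells <- nrow(plan)
    lib <- stats::rlnorm(n_cells, 0, config$libsize_sdlog)
    counts <- matrix(0L, n_cells, config$n_genes)
    for (ty in config$cell_types) {
      rowsel <- which(plan$cell_type == ty)
      lam <- outer(lib[rowsel] * config$depth * bf, type_rates[[ty]])
      counts[rowsel, ] <- stats::rpois(length(lam), lam)
    }

    barcodes <- sprintf("%s-BC%05d", dname, seq_len(n_cells))
    n_lc <- round(config$frac_low_coverage * n_cells)
    lc_cells <- if (n_lc > 0) sort(sample.int(n_cells, n_lc)) else integer()
    for (ci in lc_cells) {
      keep <- sample.int(config$n_genes, config$low_coverage_genes)
      row <- integer(config$n_genes)
      row[keep] <- counts[ci, keep]
      row[keep[row[keep] == 0]] <- 1L  # guarantee expressed, still < 500
      counts[ci, ] <- row
    }
    regular <- setdiff(seq_len(n_cells), lc_cells)
    target <- min(500L, config$n_genes)
    for (ci in regular) {  # deterministic top-up: >= target expressed genes
      nz <- counts[ci, ] > 0
      deficit <- target - sum(nz)
      if (deficit > 0) counts[ci, which(!nz)[seq_len(deficit)]] <- 1L
    }

    n_np <- round(config$frac_nonprimary * n_cells)
    np_cells <- if (n_np > 0) sort(sample.int(n_cells, n_np)) else integer()
    n_ba <- round(config$frac_bad_assay * n_cells)
    ba_cells <- if (n_ba > 0) sort(sample.int(n_cells, n_ba)) else integer()

    assay <- sample(allow, n_cells, replace = TRUE)
    assay[ba_cells] <- "EFO:9999999"
    cells <- data.frame(
      organism = "NCBITaxon:9606",
      tissue = plan$tissue,
      cell_type = plan$cell_type,
      assay = assay,
      disease = "MONDO:0000001",
      sex = sample(c("PATO:0000383", "PATO:0000384"), n_cells,
                   replace = TRUE),
      self_reported_ethnicity = "HANCESTRO:0005",
      development_stage = "HsapDv:0000087",
      donor_id = sample(sprintf("donor%02d", 1:3), n_cells, replace = TRUE),
      suspension_type = "cell",
      is_primary_data = !seq_len(n_cells) %in% np_cells,
      stringsAsFactors = FALSE, row.names = barcodes)

    emb <- matrix(stats::rnorm(n_cells * 2), n_cells, 2)
    datasets[[dname]] <- cc_dataset(counts, cells, genes,
                                    list(umap = emb), name = dname)
    truth_lc[[dname]] <- data.frame(dataset = rep(dname, length(lc_cells)),
                                    barcode = barcodes[lc_cells],
                                    stringsAsFactors = FALSE)
    truth_np[[dname]] <- data.frame(dataset = rep(dname, length(np_cells)),
                                    barcode = barcodes[np_cells],
                                    stringsAsFactors = FALSE)
    truth_ba[[dname]] <- data.frame(dataset = rep(dname, length(ba_cells)),
                                    barcode = barcodes[ba_cells],
                                    stringsAsFactors = FALSE)
  }

  marker_tab <- do.call(rbind, lapply(config$tissues, function(ti)
    do.call(rbind, lapply(config$cell_types, function(ty)
      data.frame(tissue = ti, cell_type = ty, gene = markers[[ty]],
                 stringsAsFactors = FALSE)))))

  list(datasets = datasets,
       graph = cc_ontology(config$cell_type_tree),
       truth = list(markers = marker_tab,
                    low_coverage = do.call(rbind, truth_lc),
                    nonprimary = do.call(rbind, truth_np),
                    bad_assay = do.call(rbind, truth_ba),
                    batch_factors = batch_factors,
                    gene_means = setNames(gene_means, genes)),
       config = config)
}

#' Reference marker table from planted truth
#'
#' Stands in for an external canonical-marker table (synthetic): returns
#' the planted markers per (tissue, cell type), optionally corrupted by
#' replacing a fraction of each set with random non-marker genes to
#' emulate a noisy reference.
#'
#' @param corpus output of [generate_corpus()].
#' @param noise fraction in [0, 1] of each gene set to corrupt.
#' @param seed seed for the corruption draw.
#' @return data.frame `tissue`, `cell_type`, `gene`.
#' @export
generate_reference_markers <- function(corpus, noise = 0, seed = 1) {
  truth <- corpus$truth$markers
  if (is.null(truth) || !nrow(truth)) stop("no planted markers in corpus")
  stopifnot(noise >= 0, noise <= 1)
  if (noise == 0) return(truth)
  set.seed(seed)
  genes <- corpus$datasets[[1]]$genes
  out <- truth
  for (key in unique(paste(truth$tissue, truth$cell_type))) {
    rows <- which(paste(truth$tissue, truth$cell_type) == key)
    n_swap <- round(noise * length(rows))
    if (!n_swap) next
    swap <- rows[seq_len(n_swap)]
    pool <- setdiff(genes, truth$gene)
    out$gene[swap] <- sample(pool, n_swap)
  }
  out
}
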