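#' Build the corpus expression cube
#'
#' Summarizes masked, normalized expression per (tissue, cell type, gene)
#' stratum, optionally stratified further by metadata facets (Group By).
#' For each key the cube stores the mean over *present* values only (the
#' heatmap "dot color": zeros and masked entries are excluded), the number
#' of expressing cells (dot size numerator) and the stratum cell count
#' after QC (dot size denominator).
#'
#' Datasets are combined along the gene axis as a union: a gene absent from
#' a dataset's gene list is *missing* (not zero) for its cells, so those
#' cells neither contribute to the mean nor to that gene's `n_cells`
#' denominator.
#'
#' @param prep output of [run_preprocess()] (list of per-dataset results
#'   with `normalized` and `cells`), or a single such element.
#' @param group_by character vector of metadata facet fields (e.g.
#'   `c("sex", "disease")`); must be columns of the cell metadata.
#' @return a `cc_cube`: long-format data.frame with columns `tissue`,
#'   `cell_type`, facets, `gene`, `mean_nonzero`, `n_expressing`,
#'   `n_cells`, sorted deterministically. Keys with no expressing cell are
#'   absent.
#' @export
build_cube <- function(prep, group_by = character()) {
  if (!is.null(prep$normalized)) prep <- list(prep)
  expressed <- list()
  sizes <- list()
  gene_sets <- list()
  for (di in seq_along(prep)) {
    d <- prep[[di]]
    cells <- d$cells
    miss <- setdiff(group_by, names(cells))
    if (length(miss))
      stop("unknown facet field(s): ", paste(miss, collapse = ", "))
    mat <- Matrix::drop0(d$normalized)
    genes <- colnames(mat)
    gene_sets[[di]] <- genes
    keyfields <- c("tissue", "cell_type", group_by)
    key <- do.call(paste, c(cells[keyfields], list(sep = "\r")))
    for (k in unique(key)) {
      idx <- which(key == k)
      sub <- mat[idx, , drop = FALSE]
      n_expr <- Matrix::colSums(sub != 0)
      keep <- which(n_expr > 0)
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      sizes[[length(sizes) + 1L]] <- data.frame(
        dataset = di, key = k, n_cells = length(idx),
        stringsAsFactors = FALSE)
      if (!length(keep)) next
      row <- as.data.frame(setNames(as.list(parts), keyfields),
                           stringsAsFactors = FALSE)
      expressed[[length(expressed) + 1L]] <- data.frame(
        row[rep(1, length(keep)), , drop = FALSE],
        key = k, gene = genes[keep],
        sum_nonzero = Matrix::colSums(sub)[keep],
        n_expressing = n_expr[keep],
        dataset = di, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(expressed)) {
    out <- data.frame(tissue = character(), cell_type = character(),
                      gene = character(), mean_nonzero = numeric(),
                      n_expressing = integer(), n_cells = integer())
    return(structure(out, group_by = group_by, class = c("cc_cube",
                                                         "data.frame")))
  }
  ex <- do.call(rbind, expressed)
  sz <- do.call(rbind, sizes)
  keyfields <- c("tissue", "cell_type", group_by)
  agg <- stats::aggregate(cbind(sum_nonzero, n_expressing) ~ key + gene,
                          data = ex, FUN = sum)
  # n_cells: stratum sizes summed over the datasets that measure the gene
  agg$n_cells <- 0L
  for (di in seq_along(prep)) {
    szd <- sz[sz$dataset == di, ]
    m <- match(agg$key, szd$key)
    contrib <- ifelse(!is.na(m) & agg$gene %in% gene_sets[[di]],
                      szd$n_cells[m], 0L)
    contrib[is.na(contrib)] <- 0L
    agg$n_cells <- agg$n_cells + contrib
  }
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  colnames(parts) <- keyfields
  out <- data.frame(parts, gene = agg$gene,
                    mean_nonzero = agg$sum_nonzero / agg$n_expressing,
                    n_expressing = as.integer(agg$n_expressing),
                    n_cells = as.integer(agg$n_cells),
                    stringsAsFactors = FALSE)
  out <- out[do.call(order, out[c(keyfields, "gene")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, group_by = group_by, class = c("cc_cube", "data.frame"))
}

#' Roll an expression cube up the cell-type ontology
#'
#' For every ontology term, aggregates the cube rows of the term and its
#' descendants (within each tissue and facet stratum): expression sums
#' (`mean_nonzero * n_expressing`), expressing-cell counts and stratum cell
#' counts are summed over descendant terms and the mean is recomputed from
#' the rolled sums. Annotated terms are disjoint cell sets, so summing over
#' distinct descendant terms keeps each cell counted once per ancestor.
#'
#' @param cube a `cc_cube` built at annotated-term granularity.
#' @param graph a [cc_ontology()] covering all annotated cell types.
#' @return a `cc_cube` whose `cell_type` column ranges over every term that
#'   covers at least one expressing descendant.
#' @export
cube_rollup <- function(cube, graph) {
  stopifnot(inherits(graph, "cc_ontology"))
  group_by <- attr(cube, "group_by")
  if (is.null(group_by)) group_by <- character()
  unknown <- setdiff(unique(cube$cell_type), graph$nodes)
  if (length(unknown))
    stop("cube contains unknown cell type(s): ",
         paste(unknown, collapse = ", "))
  keyfields <- c("tissue", group_by)
  res <- list()
  for (term in graph$nodes) {
    desc <- descendants(graph, term)
    sel <- cube[cube$cell_type %in% desc, , drop = FALSE]
    if (!nrow(sel)) next
    sel$sum_nonzero <- sel$mean_nonzero * sel$n_expressing
    agg <- stats::aggregate(
      cbind(sum_nonzero, n_expressing, n_cells) ~ .,
      data = sel[c(keyfields, "gene", "sum_nonzero", "n_expressing",
                   "n_cells")], FUN = sum)
    agg$cell_type <- term
    res[[length(res) + 1L]] <- agg
  }
  out <- do.call(rbind, res)
  out$mean_nonzero <- out$sum_nonzero / out$n_expressing
  out$sum_nonzero <- NULL
  out$n_expressing <- as.integer(out$n_expressing)
  out$n_cells <- as.integer(out$n_cells)
  cols <- c("tissue", "cell_type", group_by, "gene", "mean_nonzero",
            "n_expressing", "n_cells")
  out <- out[cols]
  out <- out[do.call(order, out[c("tissue", "cell_type", group_by,
                                  "gene")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, group_by = group_by, class = c("cc_cube", "data.frame"))
}
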