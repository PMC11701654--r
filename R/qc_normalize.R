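#' Sequencing-assay allow-list
#'
#' The corpus aggregation only admits cells from sequencing assays that
#' measure gene expression without requiring gene-length normalization
#' (droplet and split-pool protocols; full-length plate assays are
#' excluded). The bundled list carries the 12 eligible EFO terms.
#'
#' @param path optional TSV with an `efo_id` column; defaults to the
#'   bundled list.
#' @return character vector of EFO CURIEs.
#' @export
default_assay_allowlist <- function(path = system.file(
  "extdata", "assay_allowlist.tsv", package = "cellcube")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           quote = "", stringsAsFactors = FALSE)
  tab$efo_id
}

#' Indices of primary cells
#'
#' Only cells demarcated as the primary occurrence of an observation enter
#' corpus-level processing; duplicated submissions are dropped here.
#'
#' @param cells per-cell metadata with an `is_primary_data` logical column.
#' @return integer indices of primary cells.
#' @export
dedup_primary <- function(cells) {
  if (!"is_primary_data" %in% names(cells))
    stop("cells lack an is_primary_data column")
  which(isTRUE_vec(cells$is_primary_data))
}

#' Low-coverage cell filter
#'
#' A cell expressing fewer than `min_genes` genes (raw count > 0) is
#' excluded; a cell with exactly `min_genes` expressed genes is retained.
#' This removes noisy, shallowly sequenced cells before aggregation.
#'
#' @param counts cells x genes matrix of raw counts.
#' @param min_genes retention threshold, default 500.
#' @return integer indices of retained cells.
#' @export
filter_low_coverage <- function(counts, min_genes = 500) {
  nnz <- Matrix::rowSums(counts > 0)
  which(nnz >= min_genes)
}

#' Assay allow-list filter
#'
#' @param cells per-cell metadata with an `assay` CURIE column.
#' @param allow_list character vector of admissible assay CURIEs.
#' @return integer indices of retained cells.
#' @export
filter_assay <- function(cells, allow_list = default_assay_allowlist()) {
  if (!"assay" %in% names(cells)) stop("cells lack an assay column")
  which(cells$assay %in% allow_list)
}

#' ln(CPTT + 1) normalization
#'
#' Scales each cell's counts to counts per `scale_factor` total (CPTT for
#' the default 10 000), then applies the log pseudocount transform:
#' `v = ln(count / total * scale_factor + 1)`. Zero counts map to 0 and the
#' transform is strictly increasing in the count at fixed total, so sparsity
#' and within-cell rank order are preserved.
#'
#' @param counts cells x genes sparse matrix of raw counts (or a single
#'   numeric row).
#' @param scale_factor library-size target; 10 000 by default (1e6 is used
#'   for batch-effect analyses).
#' @return matrix (same shape and sparsity pattern) of normalized values.
#' @export
normalize_cptt <- function(counts, scale_factor = 1e4) {
  if (is.null(dim(counts))) {
    tot <- sum(counts)
    if (tot <= 0) stop("cell has zero total counts; cannot normalize")
    return(log1p(counts / tot * scale_factor))
  }
  counts <- as_dgc(counts)
  tot <- Matrix::rowSums(counts)
  if (any(tot <= 0)) stop(sum(tot <= 0),
    " cell(s) have zero total counts; cannot normalize")
  counts <- Matrix::drop0(counts)
  out <- counts
  rows <- counts@i + 1L  # row index of each stored entry (column-compressed)
  out@x <- log1p(counts@x / tot[rows] * scale_factor)
  out
}

#' Rankit quantile normalization
#'
#' Maps each cell's non-zero counts to standard-normal quantiles by rank:
#' the r-th smallest of m non-zero entries becomes
#' `qnorm((r - 0.5) / m)`. Zeros stay zero. Ties share their average rank.
#' Used as a comparison arm for normalization validation, not for display.
#'
#' @param counts cells x genes matrix of raw counts (or a single row).
#' @return matrix of rankit-normalized values.
#' @export
normalize_quantile <- function(counts) {
  rankit <- function(v) {
    nz <- which(v > 0)
    m <- length(nz)
    if (m) v[nz] <- stats::qnorm((rank(v[nz]) - 0.5) / m)
    v
  }
  if (is.null(dim(counts))) return(rankit(counts))
  dense <- as.matrix(counts)
  methods::as(t(apply(dense, 1, rankit)), "CsparseMatrix")
}

#' Mask ultra-low expression values
#'
#' Noisy, ultra-lowly expressed gene/cell combinations are set to missing
#' after normalization: any present value less than or equal to the
#' threshold is dropped from the sparse structure (missing, never zero), so
#' downstream non-zero means are unaffected by masking artifacts.
#'
#' The threshold applies on the normalized scale by default; `scale =
#' "raw"` instead masks entries whose *raw count* is <= the threshold
#' (supply `counts`), since the prose defining this rule is ambiguous
#' between the two readings.
#'
#' @param normalized cells x genes normalized sparse matrix.
#' @param threshold mask threshold, default 3.
#' @param scale `"normalized"` (default) or `"raw"`.
#' @param counts raw counts matrix, required when `scale = "raw"`.
#' @return sparse matrix with masked entries removed; the applied step is
#'   appended to the `provenance` attribute.
#' @export
mask_low_expression <- function(normalized, threshold = 3,
                                scale = c("normalized", "raw"),
                                counts = NULL) {
  scale <- match.arg(scale)
  prov <- attr(normalized, "provenance")
  out <- as_dgc(normalized)
  if (scale == "normalized") {
    out@x[out@x <= threshold] <- 0
  } else {
    if (is.null(counts)) stop("scale='raw' requires the counts matrix")
    cm <- as_dgc(counts)
    out[cm != 0 & cm <= threshold] <- 0
  }
  out <- Matrix::drop0(out)
  attr(out, "provenance") <-
    c(prov, sprintf("mask_low_expression(threshold=%g, scale=%s)",
                    threshold, scale))
  out
}

#' Default preprocessing configuration
#'
#' @param min_genes low-coverage threshold (expressed genes per cell).
#' @param assay_allowlist admissible assay CURIEs.
#' @param scale_factor normalization library-size target.
#' @param mask_threshold low-expression mask threshold.
#' @param mask_scale `"normalized"` or `"raw"` (see
#'   [mask_low_expression()]).
#' @param steps character vector choosing which steps run, in pipeline
#'   order: dedup, low_coverage, assay, normalize, mask.
#' @return named list of settings for [run_preprocess()].
#' @export
preprocess_config <- function(min_genes = 500,
                              assay_allowlist = default_assay_allowlist(),
                              scale_factor = 1e4,
                              mask_threshold = 3,
                              mask_scale = "normalized",
                              steps = c("dedup", "low_coverage", "assay",
                                        "normalize", "mask")) {
  list(min_genes = min_genes, assay_allowlist = assay_allowlist,
       scale_factor = scale_factor, mask_threshold = mask_threshold,
       mask_scale = mask_scale, steps = steps)
}

#' Run the preprocessing pipeline over a corpus
#'
#' Applies, per dataset and in order: primary-data deduplication,
#' low-coverage filtering, the assay allow-list, ln(CPTT+1) normalization
#' and low-expression masking. Steps are independent per dataset, so output
#' does not depend on dataset ordering.
#'
#' @param datasets list of [cc_dataset()] (a single dataset is accepted).
#' @param config a [preprocess_config()].
#' @return named list per dataset: `normalized` (masked sparse matrix over
#'   retained cells), `retained` (original cell indices), `cells` (metadata
#'   slice), `removed` (per-step removal counts) and `provenance`.
#' @export
run_preprocess <- function(datasets, config = preprocess_config()) {
  if (inherits(datasets, "cc_dataset")) datasets <- list(datasets)
  out <- lapply(datasets, function(d) {
    keep <- seq_len(nrow(d$counts))
    removed <- c()
    prov <- character()
    if ("dedup" %in% config$steps) {
      k <- dedup_primary(d$cells)
      removed["dedup"] <- length(keep) - length(intersect(keep, k))
      keep <- intersect(keep, k)
      prov <- c(prov, "dedup_primary")
    }
    if ("low_coverage" %in% config$steps) {
      k <- filter_low_coverage(d$counts, config$min_genes)
      removed["low_coverage"] <- length(keep) - length(intersect(keep, k))
      keep <- intersect(keep, k)
      prov <- c(prov, sprintf("filter_low_coverage(min_genes=%d)",
                              config$min_genes))
    }
    if ("assay" %in% config$steps) {
      k <- filter_assay(d$cells, config$assay_allowlist)
      removed["assay"] <- length(keep) - length(intersect(keep, k))
      keep <- intersect(keep, k)
      prov <- c(prov, "filter_assay")
    }
    counts <- d$counts[keep, , drop = FALSE]
    norm <- counts
    if ("normalize" %in% config$steps && length(keep)) {
      norm <- normalize_cptt(counts, config$scale_factor)
      prov <- c(prov, sprintf("normalize_cptt(scale_factor=%g)",
                              config$scale_factor))
    }
    attr(norm, "provenance") <- prov
    if ("mask" %in% config$steps && length(keep)) {
      norm <- mask_low_expression(norm, config$mask_threshold,
                                  config$mask_scale, counts = counts)
    }
    list(normalized = norm, retained = keep,
         cells = d$cells[keep, , drop = FALSE],
         removed = removed, provenance = attr(norm, "provenance"),
         name = d$name)
  })
  names(out) <- vapply(datasets, function(d) d$name, character(1))
  out
}
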