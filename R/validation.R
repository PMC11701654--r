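#' Marker recall against a reference set with chance-level probability
#'
#' Recall (sensitivity) is the fraction of reference marker genes recovered
#' among the predicted markers. The probability of achieving at least the
#' observed overlap by chance is the exact hypergeometric upper tail: draw
#' `length(predicted)` genes from a universe of `universe_size` containing
#' `length(reference)` reference genes.
#'
#' @param predicted character vector of predicted marker genes.
#' @param reference non-empty character vector of reference markers.
#' @param universe_size number of genes in the tissue's universe.
#' @return list with `n_reference`, `n_predicted`, `n_overlap`, `recall`,
#'   `p_chance`.
#' @export
marker_recall <- function(predicted, reference, universe_size) {
  reference <- unique(reference)
  predicted <- unique(predicted)
  if (!length(reference)) stop("reference marker set is empty")
  if (universe_size < length(union(predicted, reference)))
    stop("universe smaller than the union of gene sets")
  ov <- length(intersect(predicted, reference))
  p <- stats::phyper(ov - 1, length(reference),
                     universe_size - length(reference),
                     length(predicted), lower.tail = FALSE)
  list(n_reference = length(reference), n_predicted = length(predicted),
       n_overlap = ov, recall = ov / length(reference), p_chance = p)
}

#' Marker-recall study over a corpus
#'
#' Mirrors the sensitivity analysis of computationally derived markers
#' against an external reference table: for each tissue, reference cell
#' types present in the corpus are pruned of colinear (ancestor) terms,
#' markers are computed with the Student's-t variant, and recall plus the
#' hypergeometric chance probability are reported per remaining type.
#'
#' @param prep output of [run_preprocess()].
#' @param reference data.frame with columns `tissue`, `cell_type`, `gene`.
#' @param graph a [cc_ontology()] used for colinear pruning; `NULL` skips
#'   pruning.
#' @param k predicted markers per type, default 25.
#' @param ... further arguments to [compute_markers()].
#' @return data.frame of per-type results (tissue, cell_type, n_reference,
#'   n_predicted, n_overlap, recall, p_chance) with the mean recall in
#'   attribute `mean_recall`. Reference tissues absent from the corpus are
#'   skipped with a warning.
#' @export
recall_study <- function(prep, reference, graph = NULL, k = 25, ...) {
  pooled <- pool_corpus(prep)
  res <- list()
  for (ti in unique(reference$tissue)) {
    if (!ti %in% pooled$cells$tissue) {
      warning("reference tissue ", ti, " absent from corpus; skipped")
      next
    }
    in_tissue <- pooled$cells$tissue == ti
    types <- intersect(unique(reference$cell_type[reference$tissue == ti]),
                       unique(pooled$cells$cell_type[in_tissue]))
    if (!is.null(graph)) types <- prune_colinear(types, graph)
    universe <- sum(Matrix::colSums(
      pooled$normalized[in_tissue, , drop = FALSE] != 0) > 0)
    for (ty in types) {
      pred <- compute_markers(pooled$normalized, pooled$cells, ti, ty,
                              k = k, method = "student", ...)$gene
      ref <- reference$gene[reference$tissue == ti &
                              reference$cell_type == ty]
      r <- marker_recall(pred, ref, universe)
      res[[length(res) + 1L]] <- data.frame(
        tissue = ti, cell_type = ty, n_reference = r$n_reference,
        n_predicted = r$n_predicted, n_overlap = r$n_overlap,
        recall = r$recall, p_chance = r$p_chance,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(tissue = character(), cell_type = character(),
               n_reference = integer(), n_predicted = integer(),
               n_overlap = integer(), recall = numeric(),
               p_chance = numeric(), stringsAsFactors = FALSE)
  attr(out, "mean_recall") <- if (nrow(out)) mean(out$recall) else NA_real_
  out
}

#' One-way repeated-measures ANOVA
#'
#' Tests whether per-gene average expression differs across covariate
#' levels, treating genes as the repeated subjects and the covariate
#' (e.g. dataset id or assay) as the within-subject factor. Designs are
#' accepted unbalanced: genes missing any level are dropped (complete-case)
#' before the sums of squares are formed.
#'
#' @param long data.frame with columns `gene`, `level`, `value` (one
#'   average-expression value per gene x covariate level).
#' @return list with `F`, `p`, `df1`, `df2`, `n_subjects`, `n_levels`.
#' @export
rm_anova <- function(long) {
  stopifnot(all(c("gene", "level", "value") %in% names(long)))
  levels_all <- unique(long$level)
  if (length(levels_all) < 2) stop("need >= 2 covariate levels")
  tab <- table(long$gene, long$level)
  complete <- rownames(tab)[apply(tab == 1, 1, all)]
  if (length(complete) < 2)
    stop("fewer than 2 genes observed at every level")
  d <- long[long$gene %in% complete, ]
  k <- length(levels_all)
  n <- length(complete)
  grand <- mean(d$value)
  m_level <- tapply(d$value, d$level, mean)
  m_subj <- tapply(d$value, d$gene, mean)
  ss_treat <- n * sum((m_level - grand)^2)
  ss_subj <- k * sum((m_subj - grand)^2)
  ss_total <- sum((d$value - grand)^2)
  ss_err <- max(ss_total - ss_treat - ss_subj, 0)
  df1 <- as.integer(k - 1)
  df2 <- as.integer((n - 1) * (k - 1))
  if (ss_treat == 0) {
    f <- 0; p <- 1
  } else if (ss_err == 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ss_treat / df1) / (ss_err / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, p = p, df1 = df1, df2 = df2, n_subjects = n, n_levels = k)
}

#' Batch-effect study via repeated-measures ANOVA
#'
#' Quantifies how much per-gene average expression varies across a batch
#' covariate (dataset id or sequencing assay), for chosen gene sets (e.g.
#' marker vs housekeeping genes) within each cell type. Averages exclude
#' zero values. Supports three normalizations for comparison: raw counts,
#' ln(counts-per-`scale_factor` + 1) and rankit quantile normalization.
#' Batch analyses default to a 1e6 scale factor.
#'
#' @param datasets list of [cc_dataset()].
#' @param covariate `"dataset_id"` or `"assay"`.
#' @param normalization `"cptt_log"`, `"raw"` or `"quantile"`.
#' @param gene_sets named list of gene-id vectors (user-supplied; no list
#'   is bundled as truth).
#' @param cell_types cell types to analyze; default all present.
#' @param scale_factor scale for `cptt_log`, default 1e6.
#' @return data.frame: `gene_set`, `cell_type`, `covariate`, `F`, `p`,
#'   `n_levels`, `n_genes`. Errors if the covariate is constant.
#' @export
batch_effect_study <- function(datasets,
                               covariate = c("dataset_id", "assay"),
                               normalization = c("cptt_log", "raw",
                                                 "quantile"),
                               gene_sets, cell_types = NULL,
                               scale_factor = 1e6) {
  covariate <- match.arg(covariate)
  normalization <- match.arg(normalization)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  mats <- lapply(datasets, function(d) {
    keep <- which(Matrix::rowSums(d$counts) > 0)
    m <- switch(normalization,
                raw = d$counts[keep, , drop = FALSE],
                cptt_log = normalize_cptt(d$counts[keep, , drop = FALSE],
                                          scale_factor),
                quantile = normalize_quantile(d$counts[keep, ,
                                                       drop = FALSE]))
    list(mat = m, cells = d$cells[keep, , drop = FALSE], name = d$name)
  })
  lev_of <- function(x) if (covariate == "dataset_id")
    rep(x$name, nrow(x$cells)) else x$cells$assay
  all_levels <- unique(unlist(lapply(mats, lev_of)))
  if (length(all_levels) < 2)
    stop("covariate ", covariate, " is constant across the corpus")
  if (is.null(cell_types))
    cell_types <- sort(unique(unlist(lapply(mats,
                                            function(x) x$cells$cell_type))))
  res <- list()
  for (ct in cell_types) {
    for (gs in names(gene_sets)) {
      genes <- gene_sets[[gs]]
      rows <- list()
      for (x in mats) {
        sel <- which(x$cells$cell_type == ct)
        if (!length(sel)) next
        gpresent <- intersect(genes, colnames(x$mat))
        if (!length(gpresent)) next
        lv <- lev_of(x)[sel]
        for (l in unique(lv)) {
          sub <- x$mat[sel[lv == l], gpresent, drop = FALSE]
          nnz <- Matrix::colSums(sub != 0)
          avg <- ifelse(nnz > 0, Matrix::colSums(sub) / nnz, NA_real_)
          ok <- !is.na(avg)
          if (any(ok))
            rows[[length(rows) + 1L]] <- data.frame(
              gene = gpresent[ok], level = l, value = avg[ok],
              stringsAsFactors = FALSE)
        }
      }
      if (!length(rows)) next
      long <- do.call(rbind, rows)
      long <- stats::aggregate(value ~ gene + level, data = long,
                               FUN = mean)
      if (length(unique(long$level)) < 2) next
      # fewer than 2 complete subjects leaves no error degrees of freedom;
      # the row is still reported, with an undefined statistic
      a <- tryCatch(rm_anova(long), error = function(e)
        list(F = NA_real_, p = NA_real_,
             n_levels = length(unique(long$level)),
             n_subjects = length(unique(long$gene))))
      res[[length(res) + 1L]] <- data.frame(
        gene_set = gs, cell_type = ct, covariate = covariate,
        F = a$F, p = a$p, n_levels = a$n_levels, n_genes = a$n_subjects,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(gene_set = character(), cell_type = character(),
                      covariate = character(), F = numeric(), p = numeric(),
                      n_levels = integer(), n_genes = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
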