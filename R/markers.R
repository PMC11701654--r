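#' Welch's t statistic and standardized effect size
#'
#' Two-sample t test with unpooled variances: `t = (m_a - m_b) /
#' sqrt(s_a^2/n_a + s_b^2/n_b)` with Welch--Satterthwaite degrees of
#' freedom. The effect size reported for marker ranking is the standardized
#' mean difference with unpooled average variance,
#' `d = (m_a - m_b) / sqrt((s_a^2 + s_b^2)/2)`, so group sizes do not
#' dominate the ranking.
#'
#' Degenerate comparisons (both variances zero with unequal means) would
#' give infinite statistics; they are guarded to a large finite sentinel
#' (+/- 1e6) and flagged.
#'
#' @param group_a,group_b numeric vectors of normalized values (each of
#'   length >= 2).
#' @return list with `t_stat`, `df`, `effect`, `degenerate`.
#' @export
welch_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  se2 <- va / na + vb / nb
  pooled <- (va + vb) / 2
  degenerate <- se2 == 0 || pooled == 0
  if (degenerate) {
    s <- sign(ma - mb)
    t_stat <- if (ma == mb) 0 else s * 1e6
    effect <- t_stat
    df <- na + nb - 2
  } else {
    t_stat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    effect <- (ma - mb) / sqrt(pooled)
  }
  list(t_stat = t_stat, df = df, effect = effect, degenerate = degenerate)
}

#' Student's (pooled-variance) t statistic and effect size
#'
#' Equal-variance variant used by the marker-recall sensitivity study; same
#' effect-size definition as [welch_t()].
#'
#' @inheritParams welch_t
#' @return list with `t_stat`, `df`, `effect`, `degenerate`.
#' @export
student_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  pooled <- (va + vb) / 2
  degenerate <- sp2 == 0 || pooled == 0
  if (degenerate) {
    s <- sign(ma - mb)
    t_stat <- if (ma == mb) 0 else s * 1e6
    effect <- t_stat
  } else {
    t_stat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    effect <- (ma - mb) / sqrt(pooled)
  }
  list(t_stat = t_stat, df = na + nb - 2, effect = effect,
       degenerate = degenerate)
}

#' Bootstrap-aggregated 10th-percentile effect size
#'
#' A gene's marker effect for a target cell type is summarized across its
#' per-comparison effect sizes (one per other cell type in the tissue) by
#' the 10th percentile -- a conservative "worst typical" discrimination. For
#' few comparisons that percentile is noisy, so it is bootstrap-smoothed:
#' resample the effect list with replacement, take each replicate's 10th
#' percentile (linear interpolation between order statistics) and average
#' the replicates.
#'
#' @param effects numeric vector of per-comparison effect sizes (>= 1).
#' @param percentile percentile in [0, 100], default 10.
#' @param reps bootstrap replicates, default 100.
#' @param seed optional integer; when supplied the RNG state is set (and
#'   restored) locally so the result is a pure function of the inputs.
#' @return the aggregated effect (mean of replicate percentiles).
#' @export
aggregate_effect <- function(effects, percentile = 10, reps = 100,
                             seed = NULL) {
  if (!length(effects)) stop("empty effect list")
  if (length(effects) == 1) return(effects)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- length(effects)
  idx <- matrix(sample.int(k, reps * k, replace = TRUE), nrow = reps)
  reps_p <- apply(matrix(effects[idx], nrow = reps), 1,
                  stats::quantile, probs = percentile / 100, names = FALSE)
  mean(reps_p)
}

group_moments <- function(mat, idx) {
  # per-gene n / mean / var over *present* (stored non-zero) values
  sub <- Matrix::drop0(mat[idx, , drop = FALSE])
  n <- Matrix::colSums(sub != 0)
  s <- Matrix::colSums(sub)
  s2 <- Matrix::colSums(sub^2)
  m <- ifelse(n > 0, s / n, NA_real_)
  v <- ifelse(n > 1, (s2 - n * m^2) / (n - 1), NA_real_)
  v[!is.na(v) & v < 0] <- 0  # numeric guard
  list(n = n, mean = m, var = v)
}

effect_from_moments <- function(ma, va, mb, vb) {
  pooled <- (va + vb) / 2
  d <- (ma - mb) / sqrt(pooled)
  deg <- !is.na(pooled) & pooled == 0
  d[deg] <- sign(ma - mb)[deg] * 1e6
  d[deg & !is.na(ma - mb) & ma == mb] <- 0
  d
}

#' Compute marker genes for a cell type within a tissue
#'
#' For each gene, the target type's masked normalized values are compared
#' against every other cell type in the same tissue (effect size per
#' comparison, Welch by default or the Student variant); the per-gene
#' effects are aggregated by [aggregate_effect()] and the top `k` genes by
#' aggregated effect are returned. Comparisons where either group has fewer
#' than `min_cells` present values are skipped. Missing (masked) values are
#' excluded from the group vectors, matching the cube's non-zero semantics.
#'
#' @param normalized masked normalized cells x genes matrix.
#' @param cells aligned per-cell metadata with `tissue` and `cell_type`.
#' @param tissue tissue CURIE to restrict to.
#' @param target_type cell type CURIE; `NULL` computes markers for every
#'   type in the tissue.
#' @param k markers returned per type, default 25.
#' @param method `"welch"` or `"student"`.
#' @param percentile,reps aggregation parameters (see
#'   [aggregate_effect()]).
#' @param seed integer seed controlling the bootstrap.
#' @param min_cells minimum present values per group per comparison.
#' @return data.frame `tissue`, `cell_type`, `rank`, `gene`, `effect`,
#'   ordered by effect descending with ties broken by gene id. A tissue
#'   with a single cell type yields zero rows with a warning.
#' @export
compute_markers <- function(normalized, cells, tissue, target_type = NULL,
                            k = 25, method = c("welch", "student"),
                            percentile = 10, reps = 100, seed = 1,
                            min_cells = 5) {
  method <- match.arg(method)
  stopifnot(nrow(cells) == nrow(normalized))
  in_tissue <- which(cells$tissue == tissue)
  types <- unique(cells$cell_type[in_tissue])
  if (length(types) < 2) {
    warning("tissue ", tissue, " has fewer than 2 cell types; no markers")
    return(data.frame(tissue = character(), cell_type = character(),
                      rank = integer(), gene = character(),
                      effect = numeric(), stringsAsFactors = FALSE))
  }
  targets <- if (is.null(target_type)) sort(types) else target_type
  genes <- colnames(normalized)
  mom <- lapply(setNames(types, types), function(ty)
    group_moments(normalized, in_tissue[cells$cell_type[in_tissue] == ty]))
  out <- list()
  for (tt in targets) {
    if (!tt %in% types) stop("target type ", tt, " not present in ", tissue)
    a <- mom[[tt]]
    eff <- sapply(setdiff(types, tt), function(ot) {
      b <- mom[[ot]]
      ok <- a$n >= min_cells & b$n >= min_cells
      e <- effect_from_moments(a$mean, a$var, b$mean, b$var)
      e[!ok] <- NA_real_
      e
    })
    eff <- matrix(eff, nrow = length(genes))
    set.seed(seed)
    agg <- rep(NA_real_, length(genes))
    ks <- rowSums(!is.na(eff))
    for (kk in sort(unique(ks[ks > 0]))) {
      gsel <- which(ks == kk)
      if (kk == 1) {
        agg[gsel] <- apply(eff[gsel, , drop = FALSE], 1,
                           function(r) r[!is.na(r)])
        next
      }
      # shared resample indices across genes with the same comparison
      # count: a valid bootstrap per gene, drawn once for speed
      idx <- matrix(sample.int(kk, reps * kk, replace = TRUE), nrow = reps)
      for (g in gsel) {
        e <- eff[g, !is.na(eff[g, ])]
        boot <- matrix(e[idx], nrow = reps)
        agg[g] <- mean(apply(boot, 1, stats::quantile,
                             probs = percentile / 100, names = FALSE))
      }
    }
    keep <- which(!is.na(agg))
    if (!length(keep)) next
    ord <- keep[order(-agg[keep], genes[keep])]
    top <- utils::head(ord, k)
    out[[tt]] <- data.frame(tissue = tissue, cell_type = tt,
                            rank = seq_along(top), gene = genes[top],
                            effect = agg[top], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tissue = character(), cell_type = character(),
                      rank = integer(), gene = character(),
                      effect = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Marker tables for every tissue in a preprocessed corpus
#'
#' Convenience wrapper running [compute_markers()] for all (tissue, cell
#' type) pairs of a corpus, pooling the preprocessed datasets.
#'
#' @param prep output of [run_preprocess()].
#' @param ... passed to [compute_markers()].
#' @return combined marker data.frame.
#' @export
markers_all <- function(prep, ...) {
  pooled <- pool_corpus(prep)
  tissues <- sort(unique(pooled$cells$tissue))
  do.call(rbind, lapply(tissues, function(ti)
    compute_markers(pooled$normalized, pooled$cells, ti, NULL, ...)))
}

#' Pool preprocessed datasets over the union of their genes
#'
#' Rows are concatenated; a gene absent from a dataset is missing (no
#' stored values) for that dataset's cells.
#'
#' @param prep output of [run_preprocess()].
#' @return list with `normalized` (pooled sparse matrix) and `cells`.
#' @export
pool_corpus <- function(prep) {
  if (!is.null(prep$normalized)) prep <- list(prep)
  genes <- Reduce(union, lapply(prep, function(d) colnames(d$normalized)))
  mats <- lapply(prep, function(d) {
    m <- d$normalized
    out <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nrow(m), length(genes)),
                                dimnames = list(rownames(m), genes))
    out[, colnames(m)] <- m
    out
  })
  cells <- do.call(rbind, lapply(prep, function(d) d$cells))
  list(normalized = do.call(rbind, mats), cells = cells)
}
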