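#' Running mean/variance state for out-of-core computation
#'
#' Per-gene Welford state: observation count `n`, running mean and `M2`,
#' the running sum of squared deviations. States from disjoint chunks can
#' be merged (parallel/Chan combination), so corpus statistics can be
#' computed one bounded-memory chunk at a time; the state is O(genes),
#' never O(cells x genes).
#'
#' @param genes character vector of gene identifiers (the gene axis).
#' @return object of class `cc_streamstat`.
#' @export
stream_stat <- function(genes) {
  structure(list(genes = genes,
                 n = setNames(numeric(length(genes)), genes),
                 mean = setNames(numeric(length(genes)), genes),
                 M2 = setNames(numeric(length(genes)), genes)),
            class = "cc_streamstat")
}

#' Update a stream state with a chunk of cells
#'
#' Incorporates a cells x genes block in one pass using the chunked Welford
#' update: the chunk's own count/mean/M2 are formed and combined with the
#' running state. Every cell contributes one observation per gene (zeros
#' included); the gene axis must match the state.
#'
#' @param state a [stream_stat()].
#' @param chunk_values cells x genes matrix (or a chunk from
#'   [iter_chunks()], whose `submatrix` is used), columns aligned with
#'   `state$genes`.
#' @return the updated state.
#' @export
welford_update <- function(state, chunk_values) {
  stopifnot(inherits(state, "cc_streamstat"))
  if (is.list(chunk_values) && !is.null(chunk_values$submatrix))
    chunk_values <- chunk_values$submatrix
  if (is.null(dim(chunk_values)))
    chunk_values <- matrix(chunk_values, nrow = 1,
                           dimnames = list(NULL, state$genes))
  if (ncol(chunk_values) != length(state$genes))
    stop("gene axis mismatch: chunk has ", ncol(chunk_values),
         " columns, state expects ", length(state$genes))
  if (!is.null(colnames(chunk_values)) &&
      !identical(colnames(chunk_values), state$genes))
    stop("gene axis mismatch: column names differ from state genes")
  nb <- nrow(chunk_values)
  if (nb == 0) return(state)
  dense <- as.matrix(chunk_values)
  mb <- colMeans(dense)
  # centered sums keep ill-conditioned data (huge mean, tiny variance)
  # accurate; the uncentered sum-of-squares shortcut cancels catastrophically
  m2b <- colSums((dense - rep(mb, each = nb))^2)
  combine_welford(state, nb, unname(mb), unname(m2b))
}

combine_welford <- function(state, nb, mb, m2b) {
  na <- state$n
  delta <- mb - state$mean
  n <- na + nb
  state$mean <- ifelse(n > 0, state$mean + delta * nb / pmax(n, 1),
                       state$mean)
  state$M2 <- state$M2 + m2b + delta^2 * na * nb / pmax(n, 1)
  state$n <- n
  state
}

#' Merge two stream states
#'
#' Combines states accumulated over disjoint slices of the cell axis; the
#' result equals sequential processing of both slices (to floating-point
#' tolerance), making the computation parallelizable and
#' chunking-invariant.
#'
#' @param a,b `cc_streamstat` objects over the same gene axis.
#' @return merged `cc_streamstat`.
#' @export
merge_states <- function(a, b) {
  stopifnot(inherits(a, "cc_streamstat"), inherits(b, "cc_streamstat"))
  if (!identical(a$genes, b$genes)) stop("gene axis mismatch")
  combine_welford(a, b$n, b$mean, b$M2)
}

#' Finalize a stream state into mean and variance
#'
#' @param state a `cc_streamstat`.
#' @param sample if `TRUE` (default) the sample (n-1) variance is reported,
#'   otherwise the population variance.
#' @return data.frame `gene`, `n`, `mean`, `var`; variance is `NA`
#'   (undefined) where fewer than 2 observations were seen.
#' @export
stream_finalize <- function(state, sample = TRUE) {
  denom <- if (sample) state$n - 1 else state$n
  v <- ifelse(denom > 0 & state$n > 1, state$M2 / pmax(denom, 1), NA_real_)
  data.frame(gene = state$genes, n = as.numeric(state$n),
             mean = unname(state$mean), var = unname(v),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Streaming highly variable gene selection
#'
#' Ranks genes by the variance of their normalized values, computed in one
#' pass over fixed-size chunks via the Welford state, and returns the top
#' `n_top`. The ranking is invariant to the chunk size. Ties are broken by
#' gene identifier for determinism.
#'
#' @param x a [cc_dataset()], a cells x genes matrix of normalized values,
#'   or an iterator from [iter_chunks()].
#' @param n_top number of genes to return (>= 1).
#' @param chunk_size cells per chunk when `x` is a dataset/matrix.
#' @param criterion `"variance"` (default) or `"dispersion"`
#'   (variance/mean, for count-scale input).
#' @return data.frame `gene`, `mean`, `var`, `score`, ordered by
#'   decreasing score, first `n_top` rows.
#' @export
hvg_streaming <- function(x, n_top, chunk_size = 1000,
                          criterion = c("variance", "dispersion")) {
  criterion <- match.arg(criterion)
  if (!is.numeric(n_top) || n_top < 1) stop("n_top must be >= 1")
  it <- if (is.function(x)) x else iter_chunks(x, chunk_size)
  state <- NULL
  while (!is.null(ch <- it())) {
    m <- ch$submatrix
    if (is.null(state)) state <- stream_stat(colnames(m))
    state <- welford_update(state, m)
  }
  if (is.null(state)) stop("empty input")
  fin <- stream_finalize(state)
  fin$score <- switch(criterion,
                      variance = fin$var,
                      dispersion = ifelse(fin$mean > 0, fin$var / fin$mean,
                                          0))
  fin$score[is.na(fin$score)] <- -Inf
  fin <- fin[order(-fin$score, fin$gene), c("gene", "mean", "var",
                                            "score")]
  rownames(fin) <- NULL
  utils::head(fin, n_top)
}
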