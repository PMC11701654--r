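#' Write a dataset as an MTX + TSV triplet
#'
#' Serializes a dataset to a directory containing `matrix.mtx` (MatrixMarket
#' coordinate format, 1-based indices, cells as rows), `cells.tsv` (metadata,
#' first column `barcode`), `genes.tsv` and one `embedding_<name>.tsv` per
#' embedding. Writers emit a deterministic column order so outputs diff
#' cleanly.
#'
#' @param dataset a [cc_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cc_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(dataset$counts, file.path(dir, "matrix.mtx"))
  cells <- cbind(barcode = rownames(dataset$cells), dataset$cells)
  utils::write.table(cells, file.path(dir, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dataset$genes, file.path(dir, "genes.tsv"))
  for (nm in names(dataset$embeddings)) {
    utils::write.table(dataset$embeddings[[nm]],
                       file.path(dir, paste0("embedding_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  writeLines(dataset$name, file.path(dir, "name.txt"))
  invisible(dir)
}

#' Read a dataset from disk
#'
#' @param path directory containing an MTX + TSV triplet as written by
#'   [write_dataset()].
#' @param format on-disk layout; only `"mtx_triplet"` is supported.
#' @return a [cc_dataset()]. MatrixMarket files use 1-based coordinates;
#'   these are converted to the package's internal 0-based sparse storage by
#'   the Matrix reader.
#' @export
read_dataset <- function(path, format = c("mtx_triplet", "h5ad")) {
  format <- match.arg(format)
  if (format == "h5ad")
    stop("h5ad input is not supported by this build; ",
         "convert to an MTX + TSV triplet (see write_dataset)")
  if (!dir.exists(path)) stop("I/O error: no such directory: ", path)
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) stop("I/O error: missing matrix.mtx in ", path)
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  cells <- utils::read.table(file.path(path, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = NA, check.names = FALSE)
  rownames(cells) <- cells$barcode
  cells$barcode <- NULL
  if ("is_primary_data" %in% names(cells))
    cells$is_primary_data <- as.logical(cells$is_primary_data)
  genes <- readLines(file.path(path, "genes.tsv"))
  embf <- list.files(path, pattern = "^embedding_.*\\.tsv$")
  embeddings <- lapply(embf, function(f)
    as.matrix(utils::read.table(file.path(path, f), sep = "\t")))
  names(embeddings) <- sub("^embedding_(.*)\\.tsv$", "\\1", embf)
  embeddings <- lapply(embeddings, unname)
  nmf <- file.path(path, "name.txt")
  name <- if (file.exists(nmf)) readLines(nmf)[1] else basename(path)
  cc_dataset(counts, cells, genes, embeddings, name)
}

#' Iterate over a dataset in fixed-size cell chunks
#'
#' Returns an iterator delivering consecutive blocks of at most `chunk_size`
#' cells, each with the aligned metadata slice. Chunks partition the cell
#' axis in order, so concatenating them reproduces the dataset exactly; peak
#' memory for downstream streaming computations is bounded by one chunk.
#'
#' @param dataset a [cc_dataset()], or any cells x genes matrix.
#' @param chunk_size maximum cells per chunk (>= 1).
#' @return a function; each call returns a list with `row_offset` (0-based
#'   offset of the chunk's first cell), `cell_ids`, `submatrix` and
#'   `metadata_rows`, or `NULL` when exhausted.
#' @export
iter_chunks <- function(dataset, chunk_size) {
  if (!is.numeric(chunk_size) || chunk_size < 1)
    stop("chunk_size must be >= 1")
  chunk_size <- as.integer(chunk_size)
  is_ds <- inherits(dataset, "cc_dataset")
  mat <- if (is_ds) dataset$counts else dataset
  n <- nrow(mat)
  pos <- 0L
  function() {
    if (pos >= n) return(NULL)
    take <- seq.int(pos + 1L, min(pos + chunk_size, n))
    out <- list(
      row_offset = pos,
      cell_ids = rownames(mat)[take],
      submatrix = mat[take, , drop = FALSE],
      metadata_rows = if (is_ds) dataset$cells[take, , drop = FALSE] else NULL)
    pos <<- pos + length(take)
    out
  }
}

#' Collect all chunks from an iterator
#' @param it iterator from [iter_chunks()].
#' @return list of chunks.
#' @export
collect_chunks <- function(it) {
  out <- list()
  while (!is.null(ch <- it())) out[[length(out) + 1L]] <- ch
  out
}

#' Read a cell-type ontology from a child-parent edge list
#'
#' @param path TSV with columns `child`, `parent` (header optional; two
#'   unnamed columns are taken in that order), ids as CURIEs.
#' @return a `cc_ontology` directed acyclic graph (see [cc_ontology()]).
#'   A cycle raises an error naming one of its members.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  first <- readLines(path, n = 1)
  header <- grepl("child", first, ignore.case = TRUE)
  edges <- utils::read.table(path, sep = "\t", header = header,
                             stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("child", "parent")
  cc_ontology(edges)
}

#' Write an expression cube or marker table as TSV
#' @param x data.frame-like result (e.g. from [build_cube()] or
#'   [compute_markers()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a long-format expression cube written by [write_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cube <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
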