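#' Minimal cell-level schema configuration
#'
#' The corpus schema requires eleven per-cell metadata fields. Ten are
#' categorical annotations (eight of them ontology CURIEs, plus the free-text
#' `donor_id` and the `suspension_type` enum) and the eleventh is the
#' `is_primary_data` flag marking the canonical occurrence of each observation
#' so corpus-wide aggregations can avoid counting a cell twice.
#'
#' @param curie_prefixes named character vector mapping each CURIE-valued
#'   field to its required ontology prefix. Override entries to relax or
#'   retarget individual fields.
#' @param suspension_levels allowed values of `suspension_type`.
#' @param extra_fields additional required free-text fields, if any.
#' @return an object of class `cc_schema` used by [validate_dataset()].
#' @export
cc_schema <- function(curie_prefixes = c(
                        organism = "NCBITaxon",
                        tissue = "UBERON",
                        cell_type = "CL",
                        assay = "EFO",
                        disease = "MONDO",
                        sex = "PATO",
                        self_reported_ethnicity = "HANCESTRO",
                        development_stage = "HsapDv"),
                      suspension_levels = c("cell", "nucleus", "na"),
                      extra_fields = character()) {
  stopifnot(is.character(curie_prefixes), !is.null(names(curie_prefixes)))
  structure(list(
    curie_fields = names(curie_prefixes),
    curie_prefixes = curie_prefixes,
    suspension_levels = suspension_levels,
    required_fields = c(names(curie_prefixes), "donor_id", "suspension_type",
                        "is_primary_data", extra_fields)
  ), class = "cc_schema")
}

#' Construct a single-cell dataset
#'
#' Bundles a raw (non-normalized) counts matrix with its per-cell metadata,
#' gene identifiers and at least one low-dimensional embedding. Counts are
#' stored sparsely, cells as rows and genes as columns.
#'
#' @param counts cells x genes matrix of non-negative integer counts
#'   (coerced to `dgCMatrix`).
#' @param cells data.frame of per-cell metadata; row names are the
#'   dataset-local cell barcodes.
#' @param genes character vector of unique gene identifiers; defaults to
#'   `colnames(counts)`.
#' @param embeddings named list of cells x d coordinate matrices, d >= 2.
#' @param name dataset identifier (used as `dataset_id` downstream).
#' @return an object of class `cc_dataset`.
#' @export
cc_dataset <- function(counts, cells, genes = colnames(counts),
                       embeddings = list(), name = "dataset") {
  counts <- as_dgc(counts)
  if (is.null(genes)) stop("gene identifiers are required")
  if (nrow(cells) != nrow(counts))
    stop("cell metadata rows must match counts rows")
  if (length(genes) != ncol(counts))
    stop("gene identifiers must match counts columns")
  colnames(counts) <- genes
  if (is.null(rownames(cells)))
    rownames(cells) <- paste0("cell", seq_len(nrow(cells)))
  rownames(counts) <- rownames(cells)
  structure(list(counts = counts, cells = cells, genes = genes,
                 embeddings = embeddings, name = name),
            class = "cc_dataset")
}

#' @method print cc_dataset
#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("<cc_dataset '%s'> %d cells x %d genes, %d embedding(s)\n",
              x$name, nrow(x$counts), ncol(x$counts), length(x$embeddings)))
  cat("metadata fields:", paste(names(x$cells), collapse = ", "), "\n")
  invisible(x)
}

#' @method print cc_validation
#' @export
print.cc_validation <- function(x, ...) {
  cat(sprintf("<validation> passed: %s, %d issue(s)\n",
              x$passed, nrow(x$issues)))
  if (nrow(x$issues)) print(x$issues, row.names = FALSE)
  invisible(x)
}

new_validation <- function(issues) {
  if (is.null(issues) || !nrow(issues)) {
    issues <- data.frame(severity = character(), location = character(),
                         message = character(), stringsAsFactors = FALSE)
  }
  structure(list(passed = !any(issues$severity == "error"), issues = issues),
            class = "cc_validation")
}

issue <- function(severity, location, message) {
  data.frame(severity = severity, location = location, message = message,
             stringsAsFactors = FALSE)
}

curie_ok <- function(x, prefix) {
  grepl(paste0("^", prefix, ":[A-Za-z0-9][A-Za-z0-9_.-]*$"), x)
}

#' Validate a dataset against the cell-level schema
#'
#' Checks the eleven required metadata fields (presence, non-emptiness, CURIE
#' prefixes, the `suspension_type` enum, a logical `is_primary_data`), the
#' counts matrix (non-negative integral values), gene-identifier uniqueness
#' and the presence of at least one embedding with >= 2 dimensions. Unknown
#' extra metadata columns are reported at `info` severity only: the schema is
#' deliberately extensible.
#'
#' @param dataset a [cc_dataset()].
#' @param schema a [cc_schema()]; defaults to the standard configuration.
#' @return a `cc_validation` report: `passed` is `TRUE` iff no issue has
#'   severity `error`; `issues` enumerates every violated invariant.
#' @export
validate_dataset <- function(dataset, schema = cc_schema()) {
  stopifnot(inherits(dataset, "cc_dataset"))
  iss <- list()
  cells <- dataset$cells

  for (f in schema$required_fields) {
    if (!f %in% names(cells)) {
      iss[[length(iss) + 1L]] <- issue("error", f, "required field missing")
      next
    }
    v <- cells[[f]]
    if (f == "is_primary_data") {
      if (!is.logical(v) || anyNA(v))
        iss[[length(iss) + 1L]] <-
          issue("error", f, "must be a non-missing logical flag")
      next
    }
    bad <- is.na(v) | !nzchar(as.character(v))
    if (any(bad))
      iss[[length(iss) + 1L]] <- issue("error", f,
        sprintf("empty or missing in %d cell(s)", sum(bad)))
    if (f == "suspension_type") {
      out <- !v %in% schema$suspension_levels & !bad
      if (any(out))
        iss[[length(iss) + 1L]] <- issue("error", f,
          sprintf("%d value(s) outside {%s}", sum(out),
                  paste(schema$suspension_levels, collapse = ", ")))
    }
    if (f %in% schema$curie_fields) {
      mal <- !curie_ok(as.character(v), schema$curie_prefixes[[f]]) & !bad
      if (any(mal))
        iss[[length(iss) + 1L]] <- issue("error", f,
          sprintf("%d value(s) do not match CURIE prefix '%s'",
                  sum(mal), schema$curie_prefixes[[f]]))
    }
  }

  extra <- setdiff(names(cells), schema$required_fields)
  for (f in extra)
    iss[[length(iss) + 1L]] <- issue("info", f, "extra metadata column")

  x <- dataset$counts@x
  if (any(x < 0))
    iss[[length(iss) + 1L]] <- issue("error", "counts", "negative count")
  if (any(x != floor(x)))
    iss[[length(iss) + 1L]] <- issue("error", "counts", "non-integral count")

  if (anyDuplicated(dataset$genes))
    iss[[length(iss) + 1L]] <-
      issue("error", "genes", "duplicated gene identifiers")

  emb_ok <- vapply(dataset$embeddings, function(e) {
    is.matrix(e) && ncol(e) >= 2 && nrow(e) == nrow(dataset$counts)
  }, logical(1))
  if (!length(dataset$embeddings) || !any(emb_ok))
    iss[[length(iss) + 1L]] <- issue("error", "embeddings",
      "at least one cells x d embedding with d >= 2 is required")

  new_validation(do.call(rbind, iss))
}

#' Cross-dataset primary-data uniqueness check
#'
#' Every observation may be flagged `is_primary_data = TRUE` in at most one
#' dataset across the corpus; duplicate submissions (e.g. a meta-analysis
#' redistributing cells from an original study) must mark their copies
#' non-primary. Cells are identified across datasets by barcode + donor.
#'
#' @param datasets list of [cc_dataset()] objects.
#' @param id_fun function mapping a dataset to its per-cell corpus-wide
#'   identifiers; the default pastes the barcode and `donor_id`.
#' @return a `cc_validation` report with one error per cell identifier that
#'   is primary in more than one dataset.
#' @export
check_primary_uniqueness <- function(datasets,
                                     id_fun = function(d)
                                       paste(rownames(d$cells),
                                             d$cells$donor_id, sep = "|")) {
  ids <- lapply(datasets, function(d) {
    keep <- isTRUE_vec(d$cells$is_primary_data)
    unique(id_fun(d)[keep])
  })
  tab <- table(unlist(ids))
  dup <- names(tab)[tab > 1]
  iss <- if (length(dup)) {
    do.call(rbind, lapply(dup, function(id)
      issue("error", id, "cell flagged primary in more than one dataset")))
  } else NULL
  new_validation(iss)
}

isTRUE_vec <- function(x) !is.na(x) & x
as_dgc <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

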