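#' Cell-type ontology graph
#'
#' A directed acyclic graph over cell-type terms, edges pointing child ->
#' parent ("is_a"). The Cell Ontology relates types hierarchically -- e.g.
#' "B cell" is a descendant of "lymphocyte" -- and datasets may annotate
#' cells at any granularity, so corpus summaries attribute each cell to
#' every ancestor of its annotated term.
#'
#' @param edges data.frame or 2-column matrix of (child, parent) CURIE pairs.
#' @return object of class `cc_ontology`.
#' @export
cc_ontology <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("child", "parent")
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    # name one offender: any vertex on a cycle (self-edges included)
    selfs <- edges$child[edges$child == edges$parent]
    member <- if (length(selfs)) selfs[1] else {
      comp <- igraph::components(g, mode = "strong")
      names(comp$membership)[comp$membership ==
                               which(comp$csize > 1)[1]][1]
    }
    stop("ontology contains a cycle involving term '", member, "'")
  }
  roots <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]
  structure(list(graph = g, nodes = igraph::V(g)$name,
                 edges = edges, roots = roots),
            class = "cc_ontology")
}

#' @method print cc_ontology
#' @export
print.cc_ontology <- function(x, ...) {
  cat(sprintf("<cc_ontology> %d terms, %d edges, root(s): %s\n",
              length(x$nodes), nrow(x$edges),
              paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Descendants of a term (inclusive)
#'
#' Returns the term together with every term from which it is reachable
#' along child -> parent edges, i.e. the reflexive-transitive closure of the
#' reversed edge relation.
#'
#' @param graph a [cc_ontology()].
#' @param term a CURIE present in the graph.
#' @return character vector of terms, each appearing once.
#' @export
descendants <- function(graph, term) {
  stopifnot(inherits(graph, "cc_ontology"))
  if (!term %in% graph$nodes) stop("unknown term: ", term)
  igraph::subcomponent(graph$graph, term, mode = "in")$name
}

#' Roll up per-cell quantities across ontology descendants
#'
#' For each ancestor term, sums a per-cell quantity (and counts cells) over
#' the *set* of cells annotated with that term or any of its descendants.
#' Set semantics guarantee each cell contributes at most once per ancestor
#' even when the DAG offers multiple paths (diamonds), so multi-parent
#' structures never inflate counts.
#'
#' @param cell_terms character vector: annotated term per cell.
#' @param quantities optional numeric vector aligned with `cell_terms`
#'   (e.g. a per-cell expression sum); defaults to counting cells only.
#' @param graph a [cc_ontology()]; every annotated term must be a node.
#' @return data.frame with `term`, `quantity`, `n_cells`, one row per term
#'   that covers at least one annotated cell (terms with no labelled cells
#'   anywhere below them are excluded).
#' @export
rollup <- function(cell_terms, quantities = NULL, graph) {
  stopifnot(inherits(graph, "cc_ontology"))
  unknown <- setdiff(unique(cell_terms), graph$nodes)
  if (length(unknown))
    stop("cells labelled with unknown term(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(quantities)) quantities <- rep(1, length(cell_terms))
  stopifnot(length(quantities) == length(cell_terms))
  used <- unique(cell_terms)
  res <- lapply(graph$nodes, function(term) {
    desc <- descendants(graph, term)
    sel <- cell_terms %in% desc
    if (!any(sel)) return(NULL)
    data.frame(term = term, quantity = sum(quantities[sel]),
               n_cells = sum(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Remove colinear (ancestor) terms from a set
#'
#' When two terms of a set lie on one ancestor--descendant path in the
#' ontology, the more basal (ancestral) term is redundant for evaluation
#' and is removed. The result is an antichain: no remaining term is an
#' ancestor of another.
#'
#' @param terms character vector of terms (subset of the graph's nodes).
#' @param graph a [cc_ontology()].
#' @return the pruned character vector, original order preserved.
#' @export
prune_colinear <- function(terms, graph) {
  stopifnot(inherits(graph, "cc_ontology"))
  terms <- unique(terms)
  stopifnot(all(terms %in% graph$nodes))
  drop <- logical(length(terms))
  for (i in seq_along(terms)) {
    desc <- setdiff(descendants(graph, terms[i]), terms[i])
    if (any(terms %in% desc)) drop[i] <- TRUE  # an ancestor of another term
  }
  terms[!drop]
}
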