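#' Build the weighted co-occurrence network of significant terms
#'
#' Nodes are the significant terms (their statistics travel along as node
#' attributes); an edge joins two terms when at least one Group A record
#' lists both in its substance field, weighted by the number of such
#' records. Only Group A — the interaction-indexed articles — contributes
#' edges: their co-mentions are the relationships the analysis set out to
#' surface. The query drug is never a node; every record lists it, so it
#' would connect to everything and carry no information.
#'
#' @param significant tibble of significant term statistics (needs at least
#'   a `term` column; `frequency` and `p_adjusted` are carried as node
#'   attributes when present).
#' @param group_a records tibble of the interaction group.
#' @param drug optional query drug name, excluded from the nodes.
#' @param min_weight minimum shared-record count for an edge to be kept
#'   (default 1 = no thresholding).
#' @return a `term_network`: list with `nodes` (the input statistics rows)
#'   and `edges` (tibble `term_a`, `term_b`, `weight`, with
#'   `term_a < term_b` lexicographically).
#' @export
build_network <- function(significant, group_a, drug = NULL, min_weight = 1) {
  nodes <- significant
  if (!is.null(drug)) {
    nodes <- nodes[tolower(nodes$term) != tolower(drug), , drop = FALSE]
  }
  terms <- nodes$term
  if (length(terms) < 2) {
    edges <- tibble::tibble(term_a = character(0), term_b = character(0),
                            weight = integer(0))
    return(structure(list(nodes = nodes, edges = edges), class = "term_network"))
  }
  m <- term_membership(group_a, terms)
  co <- crossprod(m) # co[s, t] = number of records listing both s and t
  pairs <- which(upper.tri(co) & co >= min_weight, arr.ind = TRUE)
  a <- terms[pairs[, 1]]
  b <- terms[pairs[, 2]]
  swap <- a > b
  edges <- tibble::tibble(
    term_a = ifelse(swap, b, a),
    term_b = ifelse(swap, a, b),
    weight = as.integer(co[pairs])
  )
  edges <- edges[order(edges$term_a, edges$term_b), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat(sprintf("<term_network> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a term network to an igraph object
#'
#' Node attributes `frequency` and `p_adjusted` (when present) and the edge
#' attribute `weight` are carried over.
#'
#' @param network a `term_network`.
#' @return an undirected [igraph::graph].
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "term_network"))
  vertex_df <- data.frame(name = network$nodes$term, stringsAsFactors = FALSE)
  for (col in intersect(c("frequency", "p_adjusted"), names(network$nodes))) {
    vertex_df[[col]] <- network$nodes[[col]]
  }
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges),
    directed = FALSE,
    vertices = vertex_df
  )
}

#' Export a term network to GraphML or a TSV edge list
#'
#' GraphML keeps the full network (including isolated nodes and the node
#' attributes); the edge list is a 3-column TSV `term_a`, `term_b`,
#' `weight` holding only the connected part. Both re-import losslessly via
#' [import_network()] (the edge list, by construction, only up to isolated
#' nodes and node attributes).
#'
#' @param network a `term_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"edge-list"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "edge-list")) {
  stopifnot(inherits(network, "term_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    write.table(as.data.frame(network$edges), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import a network written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge-list"`.
#' @return a `term_network`.
#' @export
import_network <- function(path, format = c("graphml", "edge-list")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vat <- igraph::vertex_attr(g)
    nodes <- tibble::tibble(term = as.character(vat$name))
    if (!is.null(vat$frequency)) nodes$frequency <- as.integer(round(vat$frequency))
    if (!is.null(vat$p_adjusted)) nodes$p_adjusted <- as.numeric(vat$p_adjusted)
    el <- igraph::as_edgelist(g)
    w <- igraph::edge_attr(g, "weight")
    a <- el[, 1]
    b <- el[, 2]
    swap <- a > b
    edges <- tibble::tibble(
      term_a = as.character(ifelse(swap, b, a)),
      term_b = as.character(ifelse(swap, a, b)),
      weight = as.integer(round(w %||% rep(1, nrow(el))))
    )
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c("character", "character", "integer"))
    edges <- tibble::as_tibble(df)
    nodes <- tibble::tibble(term = sort(unique(c(edges$term_a, edges$term_b))))
  }
  edges <- edges[order(edges$term_a, edges$term_b), , drop = FALSE]
  structure(list(nodes = nodes, edges = edges), class = "term_network")
}
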