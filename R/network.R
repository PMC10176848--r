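#' Construct a TaxonNetwork
#'
#' @param nodes data.frame with columns `taxon_id`, `abundance` (mean
#'   relative abundance across the stratum).
#' @param edges data.frame with columns `taxon_a`, `taxon_b`, `method`,
#'   `rho`, `p`, `sign`; pairs are re-oriented so `taxon_a < taxon_b`.
#' @param stratum free-text description of the sample subset.
#' @return A [TaxonNetwork-class].
#' @export
TaxonNetwork <- function(nodes, edges = NULL, stratum = "all") {
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(taxon_a = character(0), taxon_b = character(0),
                        method = character(0), rho = numeric(0),
                        p = numeric(0), sign = integer(0),
                        stringsAsFactors = FALSE)
  else {
    flip <- edges$taxon_a > edges$taxon_b
    if (any(flip)) {
      tmp <- edges$taxon_a[flip]
      edges$taxon_a[flip] <- edges$taxon_b[flip]
      edges$taxon_b[flip] <- tmp
    }
    edges <- edges[order(edges$taxon_a, edges$taxon_b), , drop = FALSE]
    rownames(edges) <- NULL
    edges$sign <- as.integer(ifelse(edges$rho > 0, 1L, -1L))
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  new("TaxonNetwork", nodes = nodes, edges = edges, stratum = stratum)
}

#' Network node table
#' @param net a [TaxonNetwork-class].
#' @return data.frame of nodes (`taxon_id`, `abundance`).
#' @export
networkNodes <- function(net) net@nodes

#' Network edge table
#' @param net a [TaxonNetwork-class].
#' @return data.frame of edges.
#' @export
networkEdges <- function(net) net@edges

setMethod("show", "TaxonNetwork", function(object) {
  cat(sprintf("TaxonNetwork [%s]: %d nodes, %d edges (%d positive, %d negative)\n",
              object@stratum, nrow(object@nodes), nrow(object@edges),
              sum(object@edges$sign > 0), sum(object@edges$sign < 0)))
})

#' Convert a TaxonNetwork to an igraph object
#'
#' @param net a [TaxonNetwork-class].
#' @param positiveOnly drop negative edges first?
#' @return An undirected `igraph` graph; vertices carry `abundance`, edges
#'   carry `method`, `rho`, `p`, `sign`.
#' @export
asIgraph <- function(net, positiveOnly = FALSE) {
  ed <- net@edges
  if (positiveOnly) ed <- ed[ed$sign > 0, , drop = FALSE]
  vdf <- data.frame(name = net@nodes$taxon_id,
                    net@nodes[setdiff(names(net@nodes), "taxon_id")],
                    stringsAsFactors = FALSE)
  edf <- ed[, c("taxon_a", "taxon_b", "method", "rho", "p", "sign")]
  names(edf)[1:2] <- c("from", "to")
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' @rdname writeNetwork
#' @details GraphML output (for Cytoscape and similar viewers) carries the
#'   node abundance attribute and edge rho/p/sign; `edge_tsv` writes columns
#'   taxon_a, taxon_b, method, rho, p, sign.
setMethod("writeNetwork", "TaxonNetwork",
          function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
  } else {
    write.table(net@edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
})

#' Read a network back from disk
#'
#' Inverse of [writeNetwork()]. For `edge_tsv` the node set is the union of
#' edge endpoints (isolated nodes are not representable in that format) with
#' `NA` abundance unless `nodes` is supplied.
#'
#' @param path file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @param nodes optional node data.frame for `edge_tsv` input.
#' @param stratum stratum description to attach.
#' @return A [TaxonNetwork-class].
#' @export
readNetwork <- function(path, format = c("graphml", "edge_tsv"),
                        nodes = NULL, stratum = "all") {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nd <- data.frame(taxon_id = igraph::V(g)$name,
                     abundance = igraph::V(g)$abundance,
                     stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    ed <- if (nrow(el)) {
      data.frame(taxon_a = el[, 1L], taxon_b = el[, 2L],
                 method = igraph::E(g)$method, rho = igraph::E(g)$rho,
                 p = igraph::E(g)$p, sign = as.integer(igraph::E(g)$sign),
                 stringsAsFactors = FALSE)
    } else NULL
    TaxonNetwork(nd, ed, stratum = stratum)
  } else {
    ed <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (is.null(nodes)) {
      ids <- sort(unique(c(ed$taxon_a, ed$taxon_b)))
      nodes <- data.frame(taxon_id = ids, abundance = NA_real_,
                          stringsAsFactors = FALSE)
    }
    TaxonNetwork(nodes, ed, stratum = stratum)
  }
}
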