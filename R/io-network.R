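#' Write / read an interaction network as an edge-list TSV
#'
#' Three tab-separated columns: \code{gene_a}, \code{gene_b},
#' \code{r} (the signed correlation weight), one row per edge, with a
#' header. [readEdgeList()] reads the same dialect back; vertex names and
#' the weight round-trip, isolated genes do not (they carry no edges).
#'
#' @param net an [InteractionNetwork-class].
#' @param path output path.
#' @return \code{writeEdgeList} returns \code{path} invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  g <- net@graph
  ends <- igraph::ends(g, igraph::E(g))
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(NA_real_, igraph::ecount(g))
  df <- data.frame(gene_a = ends[, 1], gene_b = ends[, 2], r = w)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @param tau threshold to record on the reconstructed network (default 0).
#' @return \code{readEdgeList} returns an [InteractionNetwork-class].
#' @export
readEdgeList <- function(path, tau = 0) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric"))
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::E(g)$weight <- df[[3]]
  .InteractionNetwork(g, tau = tau)
}

#' Write a network in GraphML
#'
#' Exports the underlying igraph with all vertex and edge attributes
#' (edge \code{weight}; for PPNs also node \code{cardinality},
#' \code{selfWeight} and \code{degree}), suitable for Cytoscape import.
#'
#' @param x an [InteractionNetwork-class] or [PPNGraph-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGraphML <- function(x, path) {
  g <- interactionGraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a network in SIF (simple interaction format)
#'
#' One line per edge: \code{source <relation> target}, plus one line per
#' fully isolated node, for Cytoscape import.
#'
#' @param x an [InteractionNetwork-class] or [PPNGraph-class].
#' @param path output path.
#' @param relation the interaction type string; default \code{"cor"}.
#' @return \code{path}, invisibly.
#' @export
writeSIF <- function(x, path, relation = "cor") {
  g <- interactionGraph(x)
  ends <- igraph::ends(g, igraph::E(g))
  lines <- sprintf("%s\t%s\t%s", ends[, 1], relation, ends[, 2])
  lonely <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, lonely), path)
  invisible(path)
}

#' Write a binarized PPN edge view
#'
#' Sidecar TSV giving each inter-pathway edge both with its gene-edge
#' count and as a 0/1 indicator, since weighted and binary readings of the
#' projection are both plausible.
#'
#' @param ppn a [PPNGraph-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePPNEdges <- function(ppn, path) {
  stopifnot(methods::is(ppn, "PPNGraph"))
  g <- ppn@graph
  ends <- igraph::ends(g, igraph::E(g))
  df <- data.frame(pathway_a = ends[, 1], pathway_b = ends[, 2],
                   weight = if (igraph::ecount(g)) igraph::E(g)$weight
                            else numeric(0),
                   present = rep(1L, igraph::ecount(g)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
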