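#' Read a gene-to-pathway annotation table
#'
#' Flat KEGG-style annotation: a TSV with columns gene id, pathway id and
#' (optionally) pathway display name, one row per (gene, pathway) pair;
#' many-to-many. Genes absent from the file are simply unannotated.
#'
#' @param path path to the annotation TSV.
#' @param header logical, whether the first line is a header.
#' @return A [PathwayAnnotation-class].
#' @export
loadPathwayAnnotation <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, colClasses = "character")
  if (ncol(tab) < 2)
    stop("annotation must have at least two columns (gene, pathway id)")
  g2p <- lapply(split(tab[[2]], tab[[1]]), unique)
  nm <- character()
  if (ncol(tab) >= 3) {
    nm <- tab[[3]][!duplicated(tab[[2]])]
    names(nm) <- tab[[2]][!duplicated(tab[[2]])]
  }
  PathwayAnnotation(g2p, nm)
}

#' Condition-specific sub-network of a community
#'
#' Restricts a community to the genes present in network A but absent from
#' network B (e.g. in the normal network and not in the disease network),
#' and returns the sub-network of A induced on those genes. The result may
#' be empty; that is allowed and flagged with a message.
#'
#' @param community character vector of gene ids, all vertices of
#'   \code{netA}.
#' @param netA,netB [InteractionNetwork-class] objects for the two
#'   conditions.
#' @return An [InteractionNetwork-class] induced on
#'   \code{setdiff(community, vertices(netB))}; possibly empty.
#' @export
conditionSpecificSubnetwork <- function(community, netA, netB) {
  stopifnot(methods::is(netA, "InteractionNetwork"),
            methods::is(netB, "InteractionNetwork"))
  vA <- igraph::V(netA@graph)$name
  outside <- setdiff(community, vA)
  if (length(outside))
    stop("community gene(s) not in network A: ",
         paste(utils::head(outside, 5), collapse = ", "))
  keep <- setdiff(community, igraph::V(netB@graph)$name)
  sub <- igraph::induced_subgraph(netA@graph, keep)
  if (length(keep) == 0)
    message("conditionSpecificSubnetwork: community entirely shared with ",
            "network B; empty sub-network")
  .InteractionNetwork(sub, tau = netA@tau)
}

#' Filter sub-networks by vertex cardinality
#'
#' @param subnets list of [InteractionNetwork-class] objects.
#' @param minN minimum number of vertices a sub-network must have to be
#'   kept; default 100.
#' @return The qualifying sub-networks, largest first (stable for ties).
#' @export
filterByCardinality <- function(subnets, minN = 100) {
  if (minN < 1) stop("minN must be >= 1")
  sizes <- vapply(subnets, function(s)
    as.integer(igraph::vcount(s@graph)), integer(1))
  keep <- which(sizes >= minN)
  subnets[keep[order(-sizes[keep])]]
}

#' Maximum-spanning-pathway reduction
#'
#' Collapses the one-to-many gene/pathway relationship of a sub-network to
#' one-to-one: each annotated gene g is assigned, from its candidate set,
#' the pathway p that maximises the number of \emph{other} annotated genes
#' of the sub-network whose candidate set also contains p. Support counts
#' are computed once from the raw candidate sets (a single simultaneous
#' pass, no iterative re-assignment); ties go to the lexicographically
#' smallest pathway id, making the result invariant to gene input order.
#'
#' @param subnet an [InteractionNetwork-class].
#' @param ann a [PathwayAnnotation-class]; sub-network genes missing from
#'   it (or with empty candidate sets) are skipped and counted.
#' @return A [PathwayAssignment-class].
#' @export
reducePathways <- function(subnet, ann) {
  stopifnot(methods::is(subnet, "InteractionNetwork"),
            methods::is(ann, "PathwayAnnotation"))
  genes <- igraph::V(subnet@graph)$name
  cand <- ann@gene2pathway[intersect(genes, names(ann@gene2pathway))]
  cand <- cand[lengths(cand) > 0]
  unann <- setdiff(genes, names(cand))
  if (length(unann))
    message("reducePathways: ", length(unann),
            " unannotated gene(s) skipped")
  if (length(cand) == 0)
    return(methods::new("PathwayAssignment",
                        assignment = stats::setNames(character(0), character(0)),
                        unannotated = unann))
  support <- table(unlist(cand))   # genes containing each pathway
  assignment <- vapply(cand, function(p) {
    p <- sort(p)
    # "other genes": the gene itself is in support for each of its own
    # candidates, so subtracting 1 uniformly preserves the argmax
    p[which.max(support[p])]
  }, character(1))
  methods::new("PathwayAssignment", assignment = assignment,
               unannotated = unann)
}

#' Build the Pathway Projection Network of a sub-network
#'
#' Contracts a gene sub-network by the one-to-one pathway assignment: one
#' node per assigned pathway, with \code{cardinality} = number of genes
#' assigned to it; an edge between two pathways accumulates the gene-gene
#' edges joining their gene sets into its \code{weight}; gene edges inside
#' one pathway accumulate into that node's \code{selfWeight}. Total edge
#' weight plus total self-weight equals the number of gene edges among
#' assigned genes. Node \code{degree} (distinct neighbouring pathways,
#' self-weights excluded) is stored for downstream colour coding, and
#' cardinality drives node size in exported visualisations.
#'
#' @param subnet an [InteractionNetwork-class].
#' @param assign a [PathwayAssignment-class] covering the annotated genes
#'   of \code{subnet}.
#' @return A [PPNGraph-class].
#' @export
buildPPN <- function(subnet, assign) {
  stopifnot(methods::is(subnet, "InteractionNetwork"),
            methods::is(assign, "PathwayAssignment"))
  a <- assign@assignment
  pws <- sort(unique(a))
  card <- table(a)[pws]
  selfW <- stats::setNames(numeric(length(pws)), pws)
  ew <- new.env(parent = emptyenv())
  g <- subnet@graph
  if (igraph::ecount(g)) {
    ends <- igraph::ends(g, igraph::E(g))
    for (idx in seq_len(nrow(ends))) {
      pa <- a[ends[idx, 1]]; pb <- a[ends[idx, 2]]
      if (is.na(pa) || is.na(pb)) next        # endpoint unassigned
      if (pa == pb) {
        selfW[pa] <- selfW[pa] + 1
      } else {
        key <- paste(sort(c(pa, pb)), collapse = "\t")
        ew[[key]] <- (if (is.null(ew[[key]])) 0 else ew[[key]]) + 1
      }
    }
  }
  ppn <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ppn <- igraph::add_vertices(ppn, length(pws), name = pws,
                              cardinality = as.integer(card),
                              selfWeight = as.numeric(selfW))
  keys <- ls(ew)
  if (length(keys)) {
    pairs <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    ppn <- igraph::add_edges(ppn, as.vector(t(pairs)),
                             weight = unname(vapply(keys, function(k) ew[[k]],
                                                    numeric(1))))
  }
  igraph::V(ppn)$degree <- igraph::degree(ppn)
  methods::new("PPNGraph", graph = ppn,
               nUnannotated = length(assign@unannotated))
}

#' Top correlated gene pairs between two pathways
#'
#' Lists the gene edges of a sub-network whose endpoints are assigned to
#' the two query pathways, sorted by decreasing absolute correlation
#' (ties resolved by lexicographic gene pair), truncated to the top k.
#' Each row reports the endpoint assigned to \code{pathwayA} first.
#'
#' @param subnet an [InteractionNetwork-class] whose edges carry the
#'   \code{weight} (signed correlation) attribute.
#' @param assign a [PathwayAssignment-class].
#' @param pathwayA,pathwayB pathway ids, both present in the assignment
#'   (equal ids select intra-pathway edges).
#' @param k maximum number of rows; default 5.
#' @return data.frame with columns \code{gene_a}, \code{pathway_a},
#'   \code{gene_b}, \code{pathway_b}, \code{correlation}.
#' @export
topPairs <- function(subnet, assign, pathwayA, pathwayB, k = 5) {
  stopifnot(methods::is(subnet, "InteractionNetwork"),
            methods::is(assign, "PathwayAssignment"))
  a <- assign@assignment
  for (p in unique(c(pathwayA, pathwayB)))
    if (!p %in% a)
      stop("pathway '", p, "' has no assigned genes in this sub-network")
  g <- subnet@graph
  empty <- data.frame(gene_a = character(0), pathway_a = character(0),
                      gene_b = character(0), pathway_b = character(0),
                      correlation = numeric(0))
  if (igraph::ecount(g) == 0) return(empty)
  ends <- igraph::ends(g, igraph::E(g))
  w <- igraph::E(g)$weight
  if (is.null(w)) stop("sub-network edges carry no correlation weights")
  pa <- unname(a[ends[, 1]]); pb <- unname(a[ends[, 2]])
  fwd <- !is.na(pa) & !is.na(pb) & pa == pathwayA & pb == pathwayB
  rev <- !is.na(pa) & !is.na(pb) & pa == pathwayB & pb == pathwayA &
    pathwayA != pathwayB
  rows <- rbind(
    data.frame(gene_a = ends[fwd, 1], gene_b = ends[fwd, 2],
               correlation = w[fwd]),
    data.frame(gene_a = ends[rev, 2], gene_b = ends[rev, 1],
               correlation = w[rev]))
  if (pathwayA == pathwayB && nrow(rows)) {
    swap <- rows$gene_a > rows$gene_b
    tmp <- rows$gene_a[swap]
    rows$gene_a[swap] <- rows$gene_b[swap]
    rows$gene_b[swap] <- tmp
  }
  if (nrow(rows) == 0) return(empty)
  rows <- rows[order(-abs(rows$correlation), rows$gene_a, rows$gene_b), ,
               drop = FALSE]
  rows <- utils::head(rows, k)
  data.frame(gene_a = rows$gene_a, pathway_a = pathwayA,
             gene_b = rows$gene_b, pathway_b = pathwayB,
             correlation = rows$correlation, row.names = NULL)
}

#' Genes assigned per pathway
#'
#' @param assign a [PathwayAssignment-class].
#' @param pathwayIds character vector of pathway ids to query.
#' @return Named integer vector of assigned-gene counts (0 for pathways
#'   absent from the assignment).
#' @export
pathwayGeneCounts <- function(assign, pathwayIds) {
  stopifnot(methods::is(assign, "PathwayAssignment"))
  counts <- table(assign@assignment)
  out <- stats::setNames(integer(length(pathwayIds)), pathwayIds)
  hit <- intersect(pathwayIds, names(counts))
  out[hit] <- as.integer(counts[hit])
  out
}
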