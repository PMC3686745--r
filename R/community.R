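#' Edge betweenness of an interaction network
#'
#' For each edge, the number of shortest paths between all (unordered)
#' vertex pairs that run along it; when a pair is joined by several equally
#' short paths, each path contributes an equal fraction summing to 1 for
#' that pair. The graph is treated as unweighted and undirected.
#'
#' @param net an [InteractionNetwork-class] (or, internally, an igraph).
#' @return Named numeric vector, one value per edge; names are
#'   \code{"a|b"} with the two endpoint ids in sorted order.
#' @export
edgeBetweenness <- function(net) {
  g <- if (methods::is(net, "InteractionNetwork")) net@graph else net
  if (igraph::ecount(g) == 0)
    return(stats::setNames(numeric(0), character(0)))
  eb <- igraph::edge_betweenness(g, directed = FALSE, weights = NA)
  ends <- igraph::ends(g, igraph::E(g))
  nm <- ifelse(ends[, 1] < ends[, 2],
               paste(ends[, 1], ends[, 2], sep = "|"),
               paste(ends[, 2], ends[, 1], sep = "|"))
  stats::setNames(eb, nm)
}

#' Modularity Q of a partition
#'
#' Builds the k-by-k symmetric community mixing matrix \code{e}, where
#' \code{e[i, j]} is the fraction of all edges of the original network that
#' link community i to community j (an inter-community edge contributes 1/2
#' to each of \code{e[i, j]} and \code{e[j, i]}), and returns
#' \code{Q = Tr(e) - sum(a^2)} with \code{a} the row sums of \code{e}.
#' Q is always evaluated against the network's full edge set, regardless of
#' which edges a divisive algorithm has already removed.
#'
#' @param partition named vector (gene -> community id) covering every
#'   vertex of \code{net}.
#' @param net an [InteractionNetwork-class] (or igraph) with at least one
#'   edge.
#' @return Modularity Q, a number in \code{[-1, 1]}.
#' @examples
#' g <- igraph::make_graph(~ A-B)
#' net <- ppnet:::.InteractionNetwork(g)
#' modularityQ(c(A = 1, B = 2), net)   # -0.5
#' @export
modularityQ <- function(partition, net) {
  g <- if (methods::is(net, "InteractionNetwork")) net@graph else net
  m <- igraph::ecount(g)
  if (m == 0) stop("modularity is undefined for an edgeless network")
  vn <- igraph::V(g)$name
  if (!all(vn %in% names(partition)))
    stop("partition must cover every vertex of the network")
  comm <- as.integer(factor(partition[vn]))
  k <- max(comm)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  c1 <- comm[ends[, 1]]
  c2 <- comm[ends[, 2]]
  e <- matrix(0, k, k)
  for (idx in seq_len(m)) {
    if (c1[idx] == c2[idx]) {
      e[c1[idx], c1[idx]] <- e[c1[idx], c1[idx]] + 1
    } else {
      e[c1[idx], c2[idx]] <- e[c1[idx], c2[idx]] + 0.5
      e[c2[idx], c1[idx]] <- e[c2[idx], c1[idx]] + 0.5
    }
  }
  e <- e / m
  a <- rowSums(e)
  sum(diag(e)) - sum(a^2)
}

#' Divisive edge-betweenness dendrogram
#'
#' Runs the divisive community-detection loop: compute the betweenness of
#' every remaining edge, remove the edge with the largest value (ties are
#' broken uniformly at random under \code{seed}), recompute, and repeat
#' until no edges remain. Whenever the removal increases the number of
#' connected components, the component partition and its modularity Q
#' (evaluated against the original edge set) are recorded as a split. A
#' disconnected input additionally records its initial component partition
#' before any removal. The final recorded partition is all singletons.
#'
#' @param net an [InteractionNetwork-class].
#' @param seed integer seed fixing the random tie-breaks; the same network
#'   and seed reproduce the removal order exactly.
#' @return A [NetworkDendrogram-class].
#' @export
ngDendrogram <- function(net, seed) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  seed <- as.integer(seed)
  g0 <- net@graph
  n <- igraph::vcount(g0)
  if (n == 0) stop("network is empty")
  m <- igraph::ecount(g0)
  vn <- igraph::V(g0)$name

  splits <- list()
  q <- numeric(0)
  removal <- matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))

  record <- function(memb) {
    part <- stats::setNames(as.integer(factor(memb)), vn)
    splits[[length(splits) + 1L]] <<- part
    q[length(q) + 1L] <<- modularityQ(part, g0)
  }

  work <- g0
  nComp <- igraph::count_components(work)
  if (nComp > 1 && m > 0)
    record(igraph::components(work)$membership)

  withr::with_seed(seed, {
    while (igraph::ecount(work) > 0) {
      eb <- igraph::edge_betweenness(work, directed = FALSE, weights = NA)
      top <- which(eb >= max(eb) - 1e-9)
      pick <- if (length(top) > 1) top[sample.int(length(top), 1)] else top
      removal <- rbind(removal, igraph::ends(work, igraph::E(work)[pick]))
      work <- igraph::delete_edges(work, pick)
      nc <- igraph::count_components(work)
      if (nc > nComp) {
        record(igraph::components(work)$membership)
        nComp <- nc
      }
    }
  })

  methods::new("NetworkDendrogram", graph = g0, removalOrder = removal,
               splits = splits, q = q, seed = seed)
}

#' Select the modularity-optimal partition from a dendrogram
#'
#' Returns the recorded split with the largest modularity Q; if several
#' splits tie, the earliest (fewest communities) wins.
#'
#' @param dendro a [NetworkDendrogram-class] with at least one recorded
#'   split.
#' @return A [CommunitySet-class]; its \code{communityList()} is ordered by
#'   decreasing community size.
#' @export
bestPartition <- function(dendro) {
  stopifnot(methods::is(dendro, "NetworkDendrogram"))
  if (length(dendro@splits) == 0) stop("dendrogram records no splits")
  best <- which.max(dendro@q)           # first maximum = earliest split
  memb <- dendro@splits[[best]]
  comms <- split(names(memb), memb)
  comms <- comms[order(-lengths(comms), vapply(comms, min, character(1)))]
  # relabel membership so that community 1 is the largest
  relabel <- stats::setNames(seq_along(comms),
                             vapply(comms, function(v) as.character(memb[[v[1]]]),
                                    character(1)))
  memb <- stats::setNames(as.integer(relabel[as.character(memb)]), names(memb))
  names(comms) <- NULL
  methods::new("CommunitySet", membership = memb, qMax = dendro@q[best],
               communities = comms)
}
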