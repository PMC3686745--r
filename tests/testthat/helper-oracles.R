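# Independent oracles, implemented from first principles in base R so they
# share no code path with the package: brute-force shortest-path
# enumeration for edge betweenness, direct intra-edge/degree counting for
# modularity, and the contingency-table formula for the adjusted Rand
# index.

edgeKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

# fractional edge betweenness by explicit enumeration of every shortest
# path between every unordered vertex pair
bruteForceEdgeBetweenness <- function(g) {
  vs <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  adj <- stats::setNames(vector("list", length(vs)), vs)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  bt <- stats::setNames(numeric(nrow(el)), edgeKey(el[, 1], el[, 2]))

  bfsDist <- function(src) {
    dist <- stats::setNames(rep(NA_real_, length(vs)), vs)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (nb in adj[[u]]) if (is.na(dist[nb])) {
        dist[nb] <- dist[u] + 1
        queue <- c(queue, nb)
      }
    }
    dist
  }
  allShortestPaths <- function(src, dst, dist) {
    paths <- list()
    walk <- function(node, acc) {
      if (node == src) {
        paths[[length(paths) + 1]] <<- c(node, acc)
        return(invisible(NULL))
      }
      for (nb in adj[[node]])
        if (!is.na(dist[nb]) && dist[nb] == dist[node] - 1)
          walk(nb, c(node, acc))
    }
    walk(dst, character(0))
    paths
  }

  for (i in seq_along(vs)) {
    dist <- bfsDist(vs[i])
    for (j in seq_along(vs)) {
      if (j <= i || is.na(dist[vs[j]])) next
      paths <- allShortestPaths(vs[i], vs[j], dist)
      w <- 1 / length(paths)
      for (p in paths)
        for (s in seq_len(length(p) - 1)) {
          key <- edgeKey(p[s], p[s + 1])
          bt[key] <- bt[key] + w
        }
    }
  }
  bt
}

# modularity by direct counting: Q = sum_i [ m_i/m - (d_i / 2m)^2 ]
modularityDirectCount <- function(memb, g) {
  el <- igraph::as_edgelist(g)
  m <- nrow(el)
  q <- 0
  for (cid in unique(memb)) {
    inC <- names(memb)[memb == cid]
    mi <- sum(el[, 1] %in% inC & el[, 2] %in% inC)
    di <- sum(el[, 1] %in% inC) + sum(el[, 2] %in% inC)
    q <- q + mi / m - (di / (2 * m))^2
  }
  q
}

# adjusted Rand index from the contingency table
ariContingency <- function(a, b) {
  a <- a[names(b)]
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sumi * sumj / n2
  maxidx <- (sumi + sumj) / 2
  (sumij - expected) / (maxidx - expected)
}

# enumerate every set partition of a vector (Bell-number many)
allPartitions <- function(items) {
  if (length(items) == 0) return(list(list()))
  first <- items[1]
  rest <- allPartitions(items[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(first, q[[k]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(first))
  }
  out
}
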