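#' Pearson correlation matrix between gene expression profiles
#'
#' Correlates genes (rows) across samples. Genes whose expression has zero
#' variance across samples have no defined correlation; instead of raising,
#' their rows and columns are set to \code{NA} and the gene ids reported in
#' the \code{undefined} slot (such genes never form edges).
#'
#' @param expr an [ExpressionMatrix-class] with at least 2 samples.
#' @return A [CorrelationMatrix-class].
#' @examples
#' m <- rbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(1, 3, 2))
#' colnames(m) <- c("s1", "s2", "s3")
#' e <- ExpressionMatrix(m, rep("normal", 3))
#' correlationValues(correlationMatrix(e))["x", "y"]   # exactly 1
#' @export
correlationMatrix <- function(expr) {
  stopifnot(methods::is(expr, "ExpressionMatrix"))
  values <- SummarizedExperiment::assay(expr, "exprs")
  if (ncol(values) < 2)
    stop("correlation requires at least 2 samples")
  sds <- apply(values, 1, stats::sd)
  undefined <- rownames(values)[sds == 0]
  r <- suppressWarnings(stats::cor(t(values), method = "pearson"))
  if (length(undefined)) {
    r[undefined, ] <- NA_real_
    r[, undefined] <- NA_real_
  }
  diag(r)[!rownames(r) %in% undefined] <- 1
  methods::new("CorrelationMatrix", r = r, undefined = undefined)
}

#' Build the derived interaction network from a correlation matrix
#'
#' An edge joins genes i and j iff \code{abs(r[i, j]) > tau} strictly (so a
#' correlation of exactly \code{tau} yields no edge); the edge carries the
#' signed correlation as its \code{weight}. Genes with no incident edge are
#' dropped from the vertex set and recorded in \code{isolatedGenes()}, as
#' are zero-variance genes, which never form edges.
#'
#' @param corr a [CorrelationMatrix-class].
#' @param tau absolute-correlation threshold in \code{[0, 1)}; default 0.8.
#' @return An [InteractionNetwork-class].
#' @export
buildNetwork <- function(corr, tau = 0.8) {
  stopifnot(methods::is(corr, "CorrelationMatrix"))
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) ||
      tau < 0 || tau >= 1)
    stop("tau must be a single number in [0, 1)")
  r <- corr@r
  genes <- rownames(r)
  adj <- !is.na(r) & abs(r) > tau
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  connected <- unique(c(genes[idx[, 1]], genes[idx[, 2]]))
  isolated <- setdiff(genes, connected)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(connected), name = sort(connected))
  if (nrow(idx)) {
    ep <- rbind(genes[idx[, 1]], genes[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(ep), weight = r[idx])
  }
  message("buildNetwork: tau = ", tau, "; ", igraph::vcount(g),
          " connected genes, ", igraph::ecount(g), " edges; ",
          length(isolated), " isolated gene(s) dropped")
  .InteractionNetwork(g, tau = tau, isolated = isolated)
}

#' Extract the largest connected component
#'
#' Returns the induced sub-network on the largest connected vertex set;
#' when several components tie for the maximum size, the component whose
#' lexicographically smallest vertex id is smallest wins.
#'
#' @param net an [InteractionNetwork-class].
#' @return An [InteractionNetwork-class] on the winning component.
#' @export
largestComponent <- function(net) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  g <- net@graph
  if (igraph::vcount(g) == 0) stop("network is empty")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    anchor <- vapply(best, function(k)
      min(igraph::V(g)$name[comp$membership == k]), character(1))
    best <- best[order(anchor)][1]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  .InteractionNetwork(sub, tau = net@tau, isolated = net@isolated)
}

#' Global topology statistics of an interaction network
#'
#' Computes the conventional network-analyzer panel, all on the unweighted
#' graph: \code{density} = 2E/(n(n-1)); \code{avg_degree} =
#' \code{avg_neighbors} = 2E/n; \code{clustering_coefficient} = mean of the
#' local clustering coefficients, vertices of degree < 2 contributing 0;
#' \code{diameter}, \code{radius} and \code{characteristic_path_length}
#' over connected ordered vertex pairs only (eccentricity of a vertex is
#' taken over the vertices it can reach); \code{pct_shortest_paths} = the
#' percentage of ordered vertex pairs that are connected;
#' \code{centralization} = (n/(n-2)) * (k_max/(n-1) - density);
#' \code{heterogeneity} = sd(degree)/mean(degree) (population sd).
#'
#' @param net an [InteractionNetwork-class].
#' @return A one-row \code{data.frame} with columns \code{n_vertices},
#'   \code{n_edges}, \code{density}, \code{avg_degree},
#'   \code{clustering_coefficient}, \code{n_components}, \code{diameter},
#'   \code{radius}, \code{centralization}, \code{pct_shortest_paths},
#'   \code{characteristic_path_length}, \code{avg_neighbors},
#'   \code{heterogeneity}.
#' @examples
#' tri <- igraph::make_full_graph(3)
#' igraph::V(tri)$name <- c("a", "b", "c")
#' networkStats(ppnet:::.InteractionNetwork(tri))
#' @export
networkStats <- function(net) {
  stopifnot(methods::is(net, "InteractionNetwork"))
  g <- net@graph
  n <- igraph::vcount(g)
  if (n == 0) stop("network is empty")
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)

  density <- if (n > 1) 2 * m / (n * (n - 1)) else 0
  avgDeg <- 2 * m / n

  localCC <- igraph::transitivity(g, type = "local", isolates = "zero")
  localCC[deg < 2] <- 0
  cc <- if (n > 0) mean(localCC) else 0

  d <- igraph::distances(g, weights = NA)   # hop counts, not correlations
  finite <- is.finite(d) & d > 0           # connected ordered pairs (as matrix)
  nPairs <- n * (n - 1)
  if (any(finite)) {
    cpl <- mean(d[finite])
    diam <- max(d[finite])
    ecc <- apply(d, 1, function(row) {
      reach <- is.finite(row) & row > 0
      if (any(reach)) max(row[reach]) else 0
    })
    radius <- min(ecc)
  } else {
    cpl <- 0; diam <- 0; radius <- 0
  }
  pctPaths <- if (nPairs > 0) 100 * sum(finite) / nPairs else 0

  centralization <- if (n > 2)
    (n / (n - 2)) * (max(deg) / (n - 1) - density) else 0
  hetero <- if (mean(deg) > 0)
    sqrt(mean((deg - mean(deg))^2)) / mean(deg) else 0

  data.frame(
    n_vertices = n, n_edges = m, density = density, avg_degree = avgDeg,
    clustering_coefficient = cc,
    n_components = igraph::count_components(g),
    diameter = diam, radius = radius, centralization = centralization,
    pct_shortest_paths = pctPaths, characteristic_path_length = cpl,
    avg_neighbors = avgDeg, heterogeneity = hetero)
}
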