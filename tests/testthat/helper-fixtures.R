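# Graph and data fixtures built in code.

asNet <- function(g, tau = 0) ppnet:::.InteractionNetwork(g, tau = tau)

twoTrianglesBridge <- function() {
  asNet(igraph::make_graph(~ a1-a2, a1-a3, a2-a3, b1-b2, b1-b3, b2-b3,
                           a3-b3))
}

pathGraph <- function(labels = c("A", "B", "C")) {
  g <- igraph::make_ring(length(labels), circular = FALSE)
  igraph::V(g)$name <- labels
  asNet(g)
}

triangleGraph <- function(labels = c("a", "b", "c")) {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- labels
  asNet(g)
}

randomNet <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  asNet(g)
}

writeExprTsv <- function(values, path) {
  df <- data.frame(id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

smallExpr <- function() {
  m <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),
             g3 = c(4, 3, 2, 1))
  colnames(m) <- c("s1", "s2", "s3", "s4")
  ExpressionMatrix(m, c(s1 = "n", s2 = "n", s3 = "d", s4 = "d"))
}

# gene network + annotation fixture for PPN tests: random graph, random
# many-to-many candidate sets
randomPpnFixture <- function(seed, n = 12, p = 0.35, nPathways = 4) {
  withr::with_seed(seed, {
    net <- randomNet(n, p, seed = seed + 1000)
    g <- interactionGraph(net)
    igraph::E(g)$weight <- runif(igraph::ecount(g), -1, 1)
    net <- asNet(g)
    pws <- sprintf("P%02d", seq_len(nPathways))
    genes <- igraph::V(g)$name
    cand <- lapply(genes, function(gn)
      sample(pws, sample.int(nPathways, 1)))
    names(cand) <- genes
    # leave one gene unannotated when possible
    if (length(genes) > 1) cand[[genes[1]]] <- character(0)
    list(net = net, ann = PathwayAnnotation(cand))
  })
}
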