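test_that("edge betweenness matches enumeration on canonical fixtures", {
  # path A-B-C: pairs (A,B),(B,C),(A,C) -> each edge carries 2 paths
  expect_equal(unname(edgeBetweenness(pathGraph())), c(2, 2))

  # star: each spoke carries its own pair plus two leaf-leaf pairs
  st <- igraph::make_star(4, mode = "undirected")
  igraph::V(st)$name <- c("c", "a", "b", "d")
  expect_equal(unname(edgeBetweenness(asNet(st))), c(3, 3, 3))

  # 4-cycle: adjacent pair 1 + two opposite pairs split 0.5 each = 2.0,
  # confirmed by the brute-force oracle (and consistent with
  # sum(betweenness) == sum of pairwise distances == 8)
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- paste0("r", 1:4)
  oracle <- bruteForceEdgeBetweenness(ring)
  expect_equal(unname(oracle), rep(2, 4))
  expect_equal(edgeBetweenness(asNet(ring))[names(oracle)], oracle)

  expect_length(edgeBetweenness(asNet(igraph::make_empty_graph(
    directed = FALSE))), 0)
})

test_that("edge betweenness equals brute-force path enumeration on random graphs", {
  for (seed in 1:12) {
    n <- 5 + (seed %% 4) * 5           # 5..20 vertices
    net <- randomNet(n, 2.5 / n + 0.1, seed + 100)
    if (igraph::ecount(interactionGraph(net)) == 0) next
    got <- edgeBetweenness(net)
    want <- bruteForceEdgeBetweenness(interactionGraph(net))
    expect_equal(got[names(want)], want, tolerance = 1e-9)
    # consistency: total betweenness = sum of distances over connected
    # unordered pairs
    d <- igraph::distances(interactionGraph(net))
    expect_equal(sum(got), sum(d[upper.tri(d)][is.finite(d[upper.tri(d)])]),
                 tolerance = 1e-9)
  }
})

test_that("modularity reproduces hand-derived worked values", {
  net <- twoTrianglesBridge()
  vn <- igraph::V(interactionGraph(net))$name
  one <- stats::setNames(rep(1L, 6), vn)
  expect_equal(modularityQ(one, net), 0)

  twoTri <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), vn)
  expect_equal(modularityQ(twoTri, net), 5 / 14)

  single <- asNet(igraph::make_graph(~ A-B))
  expect_equal(modularityQ(c(A = 1, B = 2), single), -0.5)
  expect_error(modularityQ(c(A = 1), single), "cover")
  expect_error(modularityQ(c(A = 1, B = 1),
                           asNet(igraph::make_graph(~ A, B))),
               "undefined")
})

test_that("modularity agrees with direct-count and igraph oracles over all partitions", {
  for (seed in c(21, 22)) {
    net <- randomNet(6, 0.5, seed)
    g <- interactionGraph(net)
    if (igraph::ecount(g) == 0) next
    vn <- igraph::V(g)$name
    for (p in allPartitions(vn)) {
      memb <- stats::setNames(rep(seq_along(p), lengths(p)), unlist(p))
      q <- modularityQ(memb, net)
      expect_equal(q, modularityDirectCount(memb, g), tolerance = 1e-12)
      expect_equal(q, igraph::modularity(g, memb[vn]), tolerance = 1e-12)
    }
  }
})

test_that("the divisive loop removes the bridge first and recovers the triangles", {
  net <- twoTrianglesBridge()
  d <- ngDendrogram(net, seed = 1)
  expect_setequal(unname(d@removalOrder[1, ]), c("a3", "b3"))
  # every edge eventually removed; last partition all singletons
  expect_identical(nrow(d@removalOrder), 7L)
  last <- d@splits[[length(d@splits)]]
  expect_identical(length(unique(last)), 6L)
  # split community counts strictly increase
  k <- vapply(d@splits, function(m) length(unique(m)), integer(1))
  expect_true(all(diff(k) > 0))

  best <- bestPartition(d)
  expect_equal(qMax(best), 5 / 14)
  expect_setequal(vapply(communityList(best), paste, collapse = ",",
                         FUN.VALUE = character(1)),
                  c("a1,a2,a3", "b1,b2,b3"))
})

test_that("a single edge yields the singleton split with Q = -0.5", {
  d <- ngDendrogram(asNet(igraph::make_graph(~ A-B)), seed = 3)
  expect_length(d@splits, 1)
  best <- bestPartition(d)
  expect_equal(qMax(best), -0.5)
  expect_identical(length(communityList(best)), 2L)
})

test_that("the same seed reproduces the removal order exactly", {
  net <- randomNet(14, 0.35, 77)
  d1 <- ngDendrogram(net, seed = 42)
  d2 <- ngDendrogram(net, seed = 42)
  expect_identical(d1@removalOrder, d2@removalOrder)
  expect_identical(d1@q, d2@q)
})

test_that("disconnected input records its component partition before any removal", {
  g <- igraph::make_graph(~ A-B, B-C, A-C, D-E, E-F, D-F)
  d <- ngDendrogram(asNet(g), seed = 5)
  first <- d@splits[[1]]
  expect_identical(length(unique(first)), 2L)
  expect_identical(length(unique(first[c("A", "B", "C")])), 1L)
  expect_identical(length(unique(first[c("D", "E", "F")])), 1L)
  # two disconnected triangles: Q of the component split is 1 - 1/2 = 0.5
  expect_equal(d@q[1], 0.5)
  expect_equal(qMax(bestPartition(d)), 0.5)
})

test_that("best partition takes the earliest split among modularity ties", {
  d <- methods::new("NetworkDendrogram",
                    graph = interactionGraph(twoTrianglesBridge()),
                    removalOrder = matrix(character(0), ncol = 2),
                    splits = list(stats::setNames(c(1L, 1L, 2L, 2L),
                                                  c("a", "b", "c", "d")),
                                  stats::setNames(c(1L, 2L, 3L, 3L),
                                                  c("a", "b", "c", "d")),
                                  stats::setNames(1:4,
                                                  c("a", "b", "c", "d"))),
                    q = c(0.1, 0.3, 0.3), seed = 1L)
  best <- bestPartition(d)
  expect_identical(length(communityList(best)), 3L)
  expect_equal(qMax(best), 0.3)
})

test_that("planted stochastic-block communities are recovered across seeds", {
  # 4 blocks of 8 vertices, edge probability 0.9 within / 0.02 between
  pm <- matrix(0.02, 4, 4)
  diag(pm) <- 0.9
  nPerfect <- 0
  for (s in 1:20) {
    g <- withr::with_seed(4000 + s, igraph::sample_sbm(32, pm, rep(8, 4)))
    igraph::V(g)$name <- sprintf("v%02d", 1:32)
    truth <- stats::setNames(rep(1:4, each = 8), igraph::V(g)$name)
    best <- bestPartition(ngDendrogram(asNet(g), seed = s))
    memb <- membership(best)
    ari <- evaluateRecovery(memb, truth[names(memb)])
    if (ari == 1 && length(memb) == 32) nPerfect <- nPerfect + 1
  }
  expect_gte(nPerfect, 19)   # >= 95% of seeds
})
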