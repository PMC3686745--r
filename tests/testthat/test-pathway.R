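test_that("condition-specific sub-networks are induced on the set difference", {
  gA <- igraph::make_graph(~ g1-g2, g2-g3, g1-g3, g3-g4)
  igraph::E(gA)$weight <- c(0.9, 0.85, -0.88, 0.92)
  netA <- asNet(gA, tau = 0.8)
  netB <- asNet(igraph::make_graph(~ g2-x1))

  sub <- conditionSpecificSubnetwork(c("g1", "g2", "g3"), netA, netB)
  expect_setequal(igraph::V(interactionGraph(sub))$name, c("g1", "g3"))
  expect_equal(igraph::ecount(interactionGraph(sub)), 1)

  # net B disjoint from the community: full induced community
  disjoint <- asNet(igraph::make_graph(~ y1-y2))
  full <- conditionSpecificSubnetwork(c("g1", "g2", "g3"), netA, disjoint)
  expect_setequal(igraph::V(interactionGraph(full))$name,
                  c("g1", "g2", "g3"))

  # community fully shared with B: empty, flagged by message
  inB <- asNet(igraph::make_graph(~ g1-g2, g2-g3, g1-g3))
  expect_message(
    empty <- conditionSpecificSubnetwork(c("g1", "g2", "g3"), netA, inB),
    "empty sub-network")
  expect_equal(igraph::vcount(interactionGraph(empty)), 0)

  expect_error(conditionSpecificSubnetwork(c("g1", "zz"), netA, netB),
               "not in network A")
})

test_that("cardinality filter keeps large sub-networks, largest first", {
  nets <- lapply(c(15, 12, 9, 4), function(n)
    asNet(igraph::make_ring(n) |>
            igraph::set_vertex_attr("name",
                                    value = sprintf("n%d_%02d", n, 1:n))))
  kept <- filterByCardinality(nets, minN = 10)
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(s)
    igraph::vcount(interactionGraph(s)), numeric(1)), c(15, 12))
  expect_length(filterByCardinality(nets, minN = 1), 4)
  expect_length(filterByCardinality(list(), minN = 10), 0)
  expect_error(filterByCardinality(nets, minN = 0), "minN")
})

test_that("pathway reduction reproduces the worked support-count examples", {
  g <- igraph::make_graph(~ g1-g2, g2-g3)
  net <- asNet(g)

  annA <- PathwayAnnotation(list(g1 = c("P1", "P2"), g2 = "P1",
                                 g3 = c("P1", "P3")))
  outA <- pathwayAssignment(reducePathways(net, annA))
  expect_identical(unname(outA[c("g1", "g2", "g3")]), rep("P1", 3))

  # tie for g1 (P1 and P2 each supported by one other gene) -> smaller id
  annB <- PathwayAnnotation(list(g1 = c("P1", "P2"), g2 = "P1", g3 = "P2"))
  outB <- pathwayAssignment(reducePathways(net, annB))
  expect_identical(unname(outB["g1"]), "P1")
  expect_identical(unname(outB["g2"]), "P1")
  expect_identical(unname(outB["g3"]), "P2")

  # singleton candidate sets pass through unchanged
  annC <- PathwayAnnotation(list(g1 = "PX", g2 = "PY", g3 = "PX"))
  outC <- pathwayAssignment(reducePathways(net, annC))
  expect_identical(unname(outC[c("g1", "g2", "g3")]), c("PX", "PY", "PX"))
})

test_that("pathway reduction tracks unannotated genes and is order-invariant", {
  fix <- randomPpnFixture(9)
  red <- reducePathways(fix$net, fix$ann)
  genes <- igraph::V(interactionGraph(fix$net))$name
  expect_setequal(c(names(pathwayAssignment(red)), unannotatedGenes(red)),
                  genes)
  # assigned pathway always drawn from the candidate set
  for (g in names(pathwayAssignment(red)))
    expect_true(pathwayAssignment(red)[[g]] %in% fix$ann@gene2pathway[[g]])

  # permuting the gene order of the annotation changes nothing
  perm <- withr::with_seed(1, sample(names(fix$ann@gene2pathway)))
  annPerm <- PathwayAnnotation(fix$ann@gene2pathway[perm])
  redPerm <- reducePathways(fix$net, annPerm)
  a1 <- pathwayAssignment(red)
  a2 <- pathwayAssignment(redPerm)
  expect_identical(a1[sort(names(a1))], a2[sort(names(a2))])
})

test_that("PPN construction matches the worked example and conserves edges", {
  g <- igraph::make_graph(~ g1-g2, g2-g3)
  igraph::E(g)$weight <- c(0.9, -0.95)
  net <- asNet(g, tau = 0.8)
  assign <- methods::new("PathwayAssignment",
                         assignment = c(g1 = "PA", g2 = "PA", g3 = "PB"),
                         unannotated = character(0))
  ppn <- buildPPN(net, assign)
  pg <- interactionGraph(ppn)
  expect_setequal(igraph::V(pg)$name, c("PA", "PB"))
  card <- stats::setNames(igraph::V(pg)$cardinality, igraph::V(pg)$name)
  expect_identical(card[["PA"]], 2L)
  expect_identical(card[["PB"]], 1L)
  expect_equal(igraph::ecount(pg), 1)
  expect_equal(igraph::E(pg)$weight, 1)
  selfW <- stats::setNames(igraph::V(pg)$selfWeight, igraph::V(pg)$name)
  expect_equal(selfW[["PA"]], 1)
  expect_equal(selfW[["PB"]], 0)
  deg <- stats::setNames(igraph::V(pg)$degree, igraph::V(pg)$name)
  expect_equal(unname(deg[c("PA", "PB")]), c(1, 1))  # self-edges excluded

  # all genes in one pathway: a single node holding every edge as self-weight
  one <- methods::new("PathwayAssignment",
                      assignment = c(g1 = "PZ", g2 = "PZ", g3 = "PZ"),
                      unannotated = character(0))
  solo <- interactionGraph(buildPPN(net, one))
  expect_equal(igraph::ecount(solo), 0)
  expect_equal(igraph::V(solo)$selfWeight, 2)
})

test_that("PPN edge + self weights conserve the assigned-gene edge count", {
  for (seed in 1:20) {
    fix <- randomPpnFixture(seed)
    red <- reducePathways(fix$net, fix$ann)
    ppn <- buildPPN(fix$net, red)
    pg <- interactionGraph(ppn)
    el <- igraph::as_edgelist(interactionGraph(fix$net))
    a <- pathwayAssignment(red)
    nAssignedEdges <- sum(el[, 1] %in% names(a) & el[, 2] %in% names(a))
    total <- sum(igraph::V(pg)$selfWeight) +
      (if (igraph::ecount(pg)) sum(igraph::E(pg)$weight) else 0)
    expect_identical(as.integer(total), as.integer(nAssignedEdges))
    # cardinalities sum to the number of assigned genes
    expect_identical(sum(igraph::V(pg)$cardinality), length(a))
  }
})

test_that("on one-to-one annotations the PPN equals the quotient graph", {
  for (seed in 31:35) {
    fix <- randomPpnFixture(seed)
    # make the annotation one-to-one by keeping each gene's first candidate
    cand <- lapply(fix$ann@gene2pathway, function(p) utils::head(sort(p), 1))
    cand <- cand[lengths(cand) > 0]
    ann1 <- PathwayAnnotation(cand)
    red <- reducePathways(fix$net, ann1)
    expect_identical(pathwayAssignment(red)[names(cand)],
                     vapply(cand, identity, character(1)))
    ppn <- buildPPN(fix$net, red)
    pg <- interactionGraph(ppn)
    # oracle: contract vertices by label, count multi-edges
    el <- igraph::as_edgelist(interactionGraph(fix$net))
    lab <- unlist(cand)
    keep <- el[, 1] %in% names(lab) & el[, 2] %in% names(lab)
    la <- lab[el[keep, 1]]; lb <- lab[el[keep, 2]]
    crossKey <- edgeKey(la, lb)[la != lb]
    want <- table(crossKey)
    if (igraph::ecount(pg)) {
      pe <- igraph::as_edgelist(pg)
      got <- stats::setNames(igraph::E(pg)$weight, edgeKey(pe[, 1], pe[, 2]))
      expect_setequal(names(got), names(want))
      expect_equal(got[names(want)], unclass(want)[names(want)],
                   ignore_attr = TRUE)
    } else {
      expect_length(want, 0)
    }
    selfWant <- table(la[la == lb])
    selfGot <- stats::setNames(igraph::V(pg)$selfWeight, igraph::V(pg)$name)
    for (p in names(selfWant))
      expect_equal(selfGot[[p]], unclass(selfWant)[[p]])
  }
})

test_that("top pairs are sorted by |r|, truncated, oriented and validated", {
  el <- data.frame(from = c("m1", "m1", "m2", "m2", "m3", "m1", "a1", "m3"),
                   to = c("a1", "a2", "a1", "a2", "a1", "m2", "a2", "a2"),
                   weight = c(0.95, -0.97, 0.81, 0.92, 0.85, 0.99, 0.83,
                              0.90))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  net <- asNet(g, tau = 0.8)
  assign <- methods::new("PathwayAssignment",
                         assignment = c(m1 = "met", m2 = "met", m3 = "met",
                                        a1 = "actin", a2 = "actin"),
                         unannotated = character(0))
  top <- topPairs(net, assign, "met", "actin", k = 5)
  expect_identical(nrow(top), 5L)                       # 6 qualify, k = 5
  expect_true(all(diff(abs(top$correlation)) <= 0))
  expect_identical(top$gene_a[1], "m1")                 # endpoint in pathway A
  expect_identical(top$pathway_a, rep("met", 5))
  expect_equal(top$correlation[1], -0.97)

  all8 <- topPairs(net, assign, "met", "actin", k = 50)
  expect_identical(nrow(all8), 6L)                      # k beyond supply

  expect_error(topPairs(net, assign, "met", "nope", k = 5),
               "'nope' has no assigned genes")
})

test_that("assigned-gene counts per pathway include absent ids as zero", {
  assign <- methods::new("PathwayAssignment",
                         assignment = c(g1 = "hsa00010", g2 = "hsa00010",
                                        g3 = "hsa00010", g4 = "hsa00010",
                                        g5 = "hsa00190"),
                         unannotated = character(0))
  counts <- pathwayGeneCounts(assign, c("hsa00010", "hsa00190", "hsa99999"))
  expect_identical(unname(counts), c(4L, 1L, 0L))

  none <- methods::new("PathwayAssignment",
                       assignment = stats::setNames(character(0),
                                                    character(0)),
                       unannotated = character(0))
  expect_identical(unname(pathwayGeneCounts(none, "hsa00010")), 0L)
})
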