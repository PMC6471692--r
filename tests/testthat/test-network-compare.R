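toyPair <- function() {
  m <- fixtureModel()
  vA <- fixtureTruth()
  vB <- c(R_in = 10, R1 = 10, R2 = 10, R3 = 0, R4 = 10, R5 = 10, R_atp = 10)
  list(
    gA = buildReactionGraph(m, asFluxSolution(m, vA, "lean"),
                            currency = c("ATP", "ADP")),
    gB = buildReactionGraph(m, asFluxSolution(m, vB, "obese"),
                            currency = c("ATP", "ADP")))
}

test_that("toy shortest-path histogram matches the hand-derived BFS", {
  p <- toyPair()
  d <- shortestPathDistribution(p$gA)
  expect_identical(d@histogram, c(`1` = 6L, `2` = 5L, `3` = 2L))
  expect_equal(d@reachablePairs, 13L)
  expect_equal(d@modalLength, 1)
})

test_that("degenerate graphs give empty or cyclic distributions", {
  lone <- new("ConditionGraph", nodeKind = "reaction",
              nodeTable = data.frame(node = "R1", flux = 1),
              edges = data.frame(from = character(), to = character(),
                                 shared = character()),
              condition = "x", provenance = list())
  d <- shortestPathDistribution(lone)
  expect_equal(length(d@histogram), 0L)
  expect_equal(d@reachablePairs, 0L)
  expect_true(is.na(d@modalLength))

  cyc <- new("ConditionGraph", nodeKind = "reaction",
             nodeTable = data.frame(node = c("a", "b", "c"), flux = 1),
             edges = data.frame(from = c("a", "b", "c"),
                                to = c("b", "c", "a"), shared = "m"),
             condition = "x", provenance = list())
  dc <- shortestPathDistribution(cyc)
  expect_identical(dc@histogram, c(`1` = 3L, `2` = 3L))
  expect_equal(dc@modalLength, 1)
})

test_that("path distributions agree with a Floyd-Warshall oracle", {
  for (seed in 1:6) {
    n <- c(10, 25, 50)[(seed %% 3) + 1]
    g <- randomConditionGraph(n, p = 0.08, seed = seed)
    d <- shortestPathDistribution(g)
    D <- floydWarshall(graphNodes(g), graphEdges(g))
    dv <- D[row(D) != col(D)]
    dv <- dv[is.finite(dv)]
    expect_equal(d@reachablePairs, length(dv))
    expect_identical(d@histogram,
                     vapply(split(dv, dv), length, integer(1)))
    ## conservation: counts sum to reachable ordered pairs
    expect_equal(sum(d@histogram), d@reachablePairs)
  }
})

test_that("the union reference network labels membership per node and edge", {
  p <- toyPair()
  ref <- mergeReference(p$gA, p$gB)
  memb <- membershipLabels(ref)
  expect_setequal(names(memb)[memb == "both"],
                  c("R_in", "R1", "R2", "R4", "R5", "R_atp"))
  expect_identical(names(memb)[memb == "A_only"], "R3")
  expect_equal(sum(memb == "B_only"), 0L)
  edMemb <- membershipLabels(ref, "edges")
  expect_equal(unname(edMemb[c("R1 -> R3", "R3 -> R5")]),
               c("A_only", "A_only"))

  ## identical graphs: everything shared
  refSame <- mergeReference(p$gA, p$gA)
  expect_true(all(membershipLabels(refSame) == "both"))
  expect_true(all(membershipLabels(refSame, "edges") == "both"))

  ## disjoint node sets: nothing shared
  gx <- randomConditionGraph(4, 0.5, 1)
  gy <- randomConditionGraph(4, 0.5, 2)
  gy@nodeTable$node <- paste0("Y", gy@nodeTable$node)
  gy@edges$from <- paste0("Y", gy@edges$from)
  gy@edges$to <- paste0("Y", gy@edges$to)
  refDis <- mergeReference(gx, gy)
  expect_equal(sum(membershipLabels(refDis) == "both"), 0L)

  gGene <- new("ConditionGraph", nodeKind = "gene",
               nodeTable = data.frame(node = "G1", flux = NA_real_),
               edges = data.frame(from = character(), to = character(),
                                  shared = character()),
               condition = "g", provenance = list())
  expect_error(mergeReference(p$gA, gGene), "node kind")
})

test_that("rewiring scores count 0.25 per condition-specific incident edge", {
  p <- toyPair()
  ref <- mergeReference(p$gA, p$gB)
  rep_ <- rewiringScores(ref)
  tab <- rep_@table
  dn <- setNames(tab$dn_raw, tab$node)
  expect_equal(dn[["R1"]], 0.25)  # R1 -> R3 lost in obese
  expect_equal(dn[["R5"]], 0.25)  # R3 -> R5 lost in obese
  expect_equal(dn[["R2"]], 0)
  expect_equal(dn[["R_atp"]], 0)
  ## R3 is not shared: it gets no rewiring score
  expect_false("R3" %in% tab$node)
  ## degree correction divides by the union degree
  expect_equal(tab$dn_degree_corrected[tab$node == "R1"],
               0.25 / tab$union_degree[tab$node == "R1"])

  top <- topRewired(rep_, 2)
  expect_identical(top$node, c("R1", "R5"))  # tie broken by id

  ## identical graphs score zero everywhere
  z <- rewiringScores(mergeReference(p$gA, p$gA))
  expect_true(all(z@table$dn_raw == 0))
  ## all-zero scores rank lexicographically
  expect_identical(topRewired(z, 3)$node, sort(z@table$node)[1:3])
  ## k beyond the node count returns everything
  expect_equal(nrow(topRewired(z, 100)), nrow(z@table))
})

test_that("a node with fully state-specific edges scores 0.25 per edge", {
  gA <- randomConditionGraph(5, 0, 1, "A")
  gB <- randomConditionGraph(5, 0, 1, "B")
  ## give A three edges incident to N01 that B lacks
  gA@edges <- data.frame(from = c("N01", "N01", "N02"),
                         to = c("N02", "N03", "N01"), shared = "m")
  ref <- mergeReference(gA, gB)
  tab <- rewiringScores(ref)@table
  expect_equal(tab$dn_raw[tab$node == "N01"], 0.75)
  expect_equal(tab$dn_degree_corrected[tab$node == "N01"], 0.25)
  expect_equal(tab$union_degree[tab$node == "N01"], 3L)
})

test_that("swapping conditions permutes membership and preserves dn", {
  p <- toyPair()
  ab <- mergeReference(p$gA, p$gB)
  ba <- mergeReference(p$gB, p$gA)
  mAB <- membershipLabels(ab); mBA <- membershipLabels(ba)
  expect_setequal(names(mAB)[mAB == "A_only"], names(mBA)[mBA == "B_only"])
  expect_setequal(names(mAB)[mAB == "B_only"], names(mBA)[mBA == "A_only"])
  expect_setequal(names(mAB)[mAB == "both"], names(mBA)[mBA == "both"])
  tAB <- rewiringScores(ab)@table
  tBA <- rewiringScores(ba)@table
  expect_identical(tAB, tBA)
})

test_that("planted knockouts score every union-neighbour of the cut node", {
  for (seed in 1:5) {
    tg <- makeToyGEM(toyGemSpec(seed = seed))
    kos <- feasibleKnockouts(tg$model, tg$v_true)
    if (!length(kos)) next
    pair <- makeConditionPair(tg$model, tg$v_true, knockout = kos[1],
                              currency = c("CUR1", "CUP1"))
    gA <- buildReactionGraph(tg$model,
                             asFluxSolution(tg$model, pair$flux_A, "A"),
                             currency = c("CUR1", "CUP1"))
    gB <- buildReactionGraph(tg$model,
                             asFluxSolution(tg$model, pair$flux_B, "B"),
                             currency = c("CUR1", "CUP1"))
    ref <- mergeReference(gA, gB)
    tab <- rewiringScores(ref)@table
    lost <- graphNodes(gA)[!graphNodes(gA) %in% graphNodes(gB)]
    neigh <- unique(c(gA@edges$to[gA@edges$from %in% lost],
                      gA@edges$from[gA@edges$to %in% lost]))
    neigh <- setdiff(intersect(neigh, tab$node), lost)
    for (nb in neigh) {
      expect_gte(tab$dn_raw[tab$node == nb], 0.25)
    }
  }
})
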