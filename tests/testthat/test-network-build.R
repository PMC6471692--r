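toyGraph <- function(v = fixtureTruth(), currency = c("ATP", "ADP")) {
  m <- fixtureModel()
  buildReactionGraph(m, asFluxSolution(m, v, "toy"), currency = currency)
}

test_that("active reactions are oriented by the sign of their flux", {
  m <- fixtureModel()
  ori <- orientActive(m, asFluxSolution(m, fixtureTruth()))
  expect_setequal(ori$reactions, reactionIds(m))
  ## R4 runs C -> D under the positive ground-truth flux
  expect_equal(unname(ori$stoichiometry["C", "R4"]), -1)
  expect_equal(unname(ori$stoichiometry["D", "R4"]), 1)

  vFlip <- fixtureTruth(); vFlip["R4"] <- -6; vFlip["R2"] <- 16; vFlip["R3"] <- 0
  vFlip["R5"] <- 10  # B: 10-16-0 != 0 is irrelevant here; orientation only
  ori2 <- orientActive(m, asFluxSolution(m, vFlip))
  expect_equal(unname(ori2$stoichiometry["D", "R4"]), -1)
  expect_equal(unname(ori2$stoichiometry["C", "R4"]), 1)
  ## zero-flux reactions are dropped
  expect_false("R3" %in% ori2$reactions)
})

test_that("toy reaction graph equals the hand-derived 7-node / 6-edge graph", {
  g <- toyGraph()
  expect_setequal(graphNodes(g),
                  c("R_in", "R1", "R2", "R3", "R4", "R5", "R_atp"))
  ed <- graphEdges(g)
  expect_equal(nrow(ed), 6L)
  expect_setequal(paste(ed$from, ed$to),
                  c("R_in R1", "R1 R2", "R1 R3", "R2 R4", "R3 R5", "R4 R5"))
  ## R_atp only trades currency metabolites: isolated but retained
  expect_false("R_atp" %in% c(ed$from, ed$to))
  ## edge annotations name the shared metabolite
  expect_equal(ed$shared[ed$from == "R2" & ed$to == "R4"], "C")
})

test_that("emptying the currency list adds the cofactor-mediated edges", {
  g0 <- toyGraph(currency = character(0))
  ed <- paste(g0@edges$from, g0@edges$to)
  expect_true(all(c("R_atp R1", "R1 R_atp") %in% ed))
  ## monotonicity: every currency-filtered edge persists
  g1 <- toyGraph()
  expect_true(all(paste(g1@edges$from, g1@edges$to) %in% ed))
})

test_that("currency matching is compartment-suffix aware and warns on unknowns", {
  m <- makeMetabolicModel(
    data.frame(id = c("M_atp_c", "glc_c"), name = c("ATP", "glucose")),
    data.frame(id = c("Rp", "Rc"), lower_bound = 0, upper_bound = 10),
    list(c(M_atp_c = 1, glc_c = 1), c(M_atp_c = -1, glc_c = -1)),
    list("Gp", "Gc"))
  sol <- asFluxSolution(m, c(Rp = 1, Rc = 1))
  g <- buildReactionGraph(m, sol, currency = "ATP")
  expect_equal(graphEdges(g)$shared, "glc_c")
  expect_warning(buildReactionGraph(m, sol, currency = c("ATP", "NADH")),
                 "NADH")
})

test_that("all-zero and orphan solutions give empty graphs", {
  m <- fixtureModel()
  v0 <- fixtureTruth() * 0
  g <- buildReactionGraph(m, asFluxSolution(m, v0), currency = c("ATP", "ADP"))
  expect_equal(length(graphNodes(g)), 0L)
  expect_equal(nrow(graphEdges(g)), 0L)
  expect_equal(shortestPathDistribution(g)@reachablePairs, 0L)
})

test_that("toy gene graph is the 7-node / 9-edge GPR expansion", {
  m <- fixtureModel()
  g <- buildGeneGraph(m, asFluxSolution(m, fixtureTruth(), "toy"),
                      currency = c("ATP", "ADP"))
  expect_setequal(graphNodes(g), sprintf("G%d", 1:7))
  ed <- graphEdges(g)
  expect_equal(nrow(ed), 9L)
  expect_setequal(paste(ed$from, ed$to),
                  c("G1 G2", "G1 G3", "G1 G4", "G2 G5", "G3 G5",
                    "G4 G6", "G4 G7", "G5 G6", "G5 G7"))
  ## R_in has no gene, so nothing feeds into G1
  expect_false("G1" %in% ed$to)
})

test_that("shared regulators never produce gene self-edges", {
  m <- makeMetabolicModel(
    data.frame(id = c("A", "B")),
    data.frame(id = c("Rin", "R1", "R2", "Rout"),
               lower_bound = 0, upper_bound = 100),
    list(c(A = 1), c(A = -1, B = 1), c(B = -1, A = 1), c(B = -1)),
    list(NULL, "Gx", "Gx", "Gy"))
  v <- c(Rin = 1, R1 = 2, R2 = 1, Rout = 1)
  g <- buildGeneGraph(m, asFluxSolution(m, v), currency = character(0))
  ed <- graphEdges(g)
  expect_false(any(ed$from == ed$to))
  expect_true(all(c("Gx", "Gy") %in% graphNodes(g)))
})

test_that("models without GPRs yield empty gene graphs", {
  m <- makeMetabolicModel(
    data.frame(id = "A"),
    data.frame(id = c("Rin", "Rout"), lower_bound = 0, upper_bound = 10),
    list(c(A = 1), c(A = -1)), list(NULL, NULL))
  g <- buildGeneGraph(m, asFluxSolution(m, c(Rin = 1, Rout = 1)),
                      currency = character(0))
  expect_equal(length(graphNodes(g)), 0L)
  expect_equal(nrow(graphEdges(g)), 0L)
})

test_that("graph invariants hold on random toy models", {
  for (seed in 1:5) {
    tg <- makeToyGEM(toyGemSpec(seed = seed, n_currency = 1))
    sol <- asFluxSolution(tg$model, tg$v_true, "truth")
    gFull <- buildReactionGraph(tg$model, sol, currency = character(0))
    gCur <- buildReactionGraph(tg$model, sol, currency = c("CUR1", "CUP1"))

    ## removing ids from the currency list only adds edges
    keyFull <- paste(gFull@edges$from, gFull@edges$to)
    keyCur <- paste(gCur@edges$from, gCur@edges$to)
    expect_true(all(keyCur %in% keyFull))

    ## edge soundness: a shared non-currency metabolite is produced by
    ## the source and consumed by the target under effective orientation
    ori <- orientActive(tg$model, sol)
    S <- ori$stoichiometry
    for (k in seq_len(nrow(gCur@edges))) {
      mets <- strsplit(gCur@edges$shared[k], ";")[[1]]
      expect_true(any(S[mets, gCur@edges$from[k]] > 0 &
                      S[mets, gCur@edges$to[k]] < 0))
    }

    ## gene-graph size bound: sum over reaction edges of |genes(a)|*|genes(b)|
    gg <- buildGeneGraph(tg$model, sol, currency = c("CUR1", "CUP1"))
    rg <- gCur@edges
    genesOf <- lapply(gprRules(tg$model), gprGenes)
    bound <- sum(mapply(function(a, b) length(genesOf[[a]]) * length(genesOf[[b]]),
                        rg$from, rg$to))
    expect_lte(nrow(gg@edges), bound)
  }
})
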