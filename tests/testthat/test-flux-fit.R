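test_that("flux constraints clamp bounds and re-normalize reversibility", {
  m <- fixtureModel()
  c1 <- applyFluxConstraints(m, data.frame(reaction_id = "R_in",
                                           lower = 10, upper = 10))
  b <- reactionBounds(c1)
  expect_equal(b$lower_bound[b$id == "R_in"], 10)
  expect_equal(b$upper_bound[b$id == "R_in"], 10)
  ## untouched elsewhere
  expect_equal(b$upper_bound[b$id == "R2"], 1000)

  expect_identical(applyFluxConstraints(m, list()), m)
  expect_identical(applyFluxConstraints(m, data.frame(reaction_id = character(),
                                                      lower = numeric(),
                                                      upper = numeric())), m)

  ## interval clamp (mean +/- SD style) is set verbatim
  c2 <- applyFluxConstraints(m, list(R_in = c(7.5, 12.5)))
  b2 <- reactionBounds(c2)
  expect_equal(b2$lower_bound[b2$id == "R_in"], 7.5)
  expect_equal(b2$upper_bound[b2$id == "R_in"], 12.5)

  ## clamping a reversible reaction to non-negative flux makes it irreversible
  c3 <- applyFluxConstraints(m, list(R4 = c(0, 5)))
  expect_false(reactionBounds(c3)$reversible[reactionBounds(c3)$id == "R4"])

  expect_error(applyFluxConstraints(m, list(NOPE = c(0, 1))), "NOPE")
  expect_error(applyFluxConstraints(m, list(R_in = c(5, 1))), "lower > upper")
})

test_that("the L1 fit matches the brute-force oracle on the funnel toy", {
  m <- funnelModel(inflow = 10)
  opts <- fitOptions(scale_data = FALSE, max_iter = 1)

  ## unique optimum: data (8, 2) are exactly attainable
  s1 <- fitFluxes(m, mapToReactions(m, funnelProfile(8, 2)), opts = opts)
  o1 <- funnelGridOracle(c(8, 2))
  expect_equal(s1@objective, 0, tolerance = 1e-6)
  expect_equal(s1@objective, o1$objective, tolerance = 1e-3)
  expect_equal(unname(fluxes(s1)[c("Ra", "Rb")]), c(8, 2), tolerance = 1e-6)

  ## degenerate optimum: data (8, 8) exceed the inflow; the tie-break
  ## selects the balanced split
  s2 <- fitFluxes(m, mapToReactions(m, funnelProfile(8, 8)), opts = opts)
  o2 <- funnelGridOracle(c(8, 8))
  expect_equal(s2@objective, 6, tolerance = 1e-6)
  expect_equal(o2$objective, 6, tolerance = 1e-10)
  expect_equal(unname(fluxes(s2)[c("Ra", "Rb")]), c(5, 5), tolerance = 1e-6)

  s3 <- fitFluxes(m, mapToReactions(m, funnelProfile(8, 8)),
                  opts = fitOptions(scale_data = FALSE, max_iter = 1,
                                    tiebreak = "least_squares"))
  expect_equal(unname(fluxes(s3)[c("Ra", "Rb")]), c(5, 5), tolerance = 1e-6)

  ## weighted case: weights steer the degenerate split
  s4 <- fitFluxes(m, mapToReactions(m, funnelProfile(8, 4, sda = 0.5, sdb = 4)),
                  opts = opts)
  o4 <- funnelGridOracle(c(8, 4), w = c(2, 0.25))
  expect_equal(s4@objective, o4$objective, tolerance = 1e-3)
  expect_equal(unname(fluxes(s4)["Ra"]), o4$va, tolerance = 1e-3)
})

test_that("noise-free toy data give a perfect fit (rho 1, objective 0)", {
  m <- fixtureModel()
  vt <- fixtureTruth()
  rd <- mapToReactions(m, makeExpressionFromFlux(m, vt, 0, 1))
  sol <- fitFluxes(m, rd, label = "toy")
  expect_equal(sol@rho, 1)
  expect_lt(sol@objective, 1e-2)
  expect_true(sol@converged)
  expect_equal(unname(fluxes(sol)), unname(vt[names(fluxes(sol))]),
               tolerance = 1e-6)
  expect_equal(fluxCorrelation(sol, rd), 1)
})

test_that("rho is non-decreasing across iterations up to tolerance", {
  m <- fixtureModel()
  vt <- fixtureTruth()
  for (seed in 1:5) {
    prof <- makeExpressionFromFlux(m, vt, 0.05, seed)
    sol <- suppressWarnings(fitFluxes(m, mapToReactions(m, prof)))
    traj <- sol@rhoTrajectory[!is.na(sol@rhoTrajectory)]
    if (length(traj) > 1) {
      expect_true(all(diff(traj) >= -fitOptions()$rho_tol),
                  label = sprintf("seed %d trajectory", seed))
    }
  }
})

test_that("solutions satisfy mass balance and bounds on random toy models", {
  for (seed in 1:8) {
    tg <- makeToyGEM(toyGemSpec(seed = seed))
    Fup <- tg$v_true[["R_upt"]]
    cm <- applyFluxConstraints(tg$model, list(R_upt = c(Fup, Fup)))
    prof <- makeExpressionFromFlux(tg$model, tg$v_true, 0.05, seed)
    sol <- suppressWarnings(fitFluxes(cm, mapToReactions(tg$model, prof)))
    v <- fluxes(sol)
    S <- as.matrix(stoichiometricMatrix(tg$model, internalOnly = TRUE))
    expect_lt(max(abs(S %*% v)), 1e-6)
    b <- reactionBounds(cm)
    expect_true(all(v >= b$lower_bound - 1e-9))
    expect_true(all(v <= b$upper_bound + 1e-9))
  }
})

test_that("the fit is invariant to a global rescaling of the data", {
  m <- fixtureModel()
  vt <- fixtureTruth()
  prof <- makeExpressionFromFlux(m, vt, 0.05, 3)
  sol1 <- suppressWarnings(fitFluxes(m, mapToReactions(m, prof)))
  pd <- prof@data; pd$mean <- pd$mean * 41
  prof2 <- new("ExpressionProfile", condition = "x", data = pd)
  sol2 <- suppressWarnings(fitFluxes(m, mapToReactions(m, prof2)))
  expect_equal(fluxes(sol2), fluxes(sol1), tolerance = 1e-6)
})

test_that("degenerate fits fail loudly", {
  m <- fixtureModel()
  rdNone <- mapToReactions(
    m, new("ExpressionProfile", condition = "x",
           data = data.frame(gene = "G1", mean = 5, sd = 1)))
  rdNone@data$has_data[] <- FALSE
  expect_error(fitFluxes(m, rdNone), "no data-carrying")

  ## uptake forced to 10 but both exits capped at 2: mass cannot balance
  bad <- makeMetabolicModel(
    data.frame(id = "A"),
    data.frame(id = c("R_in", "Ra", "Rb"),
               lower_bound = c(10, 0, 0), upper_bound = c(10, 2, 2)),
    list(c(A = 1), c(A = -1), c(A = -1)),
    list(NULL, "Ga", "Gb"))
  expect_error(fitFluxes(bad, mapToReactions(bad, funnelProfile(8, 2))),
               "infeasible")
})

test_that("flux-expression correlation follows Spearman rank convention", {
  m <- funnelModel()
  mk <- function(t) {
    sol <- asFluxSolution(m, c(R_in = 10, Ra = t[1], Rb = t[2]))
    tab <- sol@table
    tab$throughput <- c(t[3], t[1], t[2])
    methods::initialize(sol, table = tab)
  }
  rdat <- function(d) new("ReactionData", policy = "min_sum",
    data = data.frame(reaction_id = c("R_in", "Ra", "Rb"),
                      d = d, sd = 1, w = 1, has_data = TRUE))
  expect_equal(fluxCorrelation(mk(c(2, 3, 1)), rdat(c(10, 20, 30))), 1)
  expect_equal(fluxCorrelation(mk(c(2, 3, 1)), rdat(c(30, 20, 10))), -1)
  expect_equal(fluxCorrelation(mk(c(2, 3, 1)), rdat(c(10, 30, 20))), 0.5)

  few <- rdat(c(1, 2, 3)); few@data$has_data[1] <- FALSE
  few@data$d[1] <- NA
  expect_error(fluxCorrelation(mk(c(1, 2, 3)), few), "fewer than 3")
})

test_that("flux changes are classified by direction and fold change", {
  m <- fixtureModel()
  vA <- c(R_in = 8, R1 = 8, R2 = 4, R3 = 4, R4 = 3, R5 = 8, R_atp = 8)
  vB <- c(R_in = 8, R1 = 2, R2 = 1, R3 = 16, R4 = -3, R5 = 8, R_atp = 0)
  cmp <- classifyFluxChanges(asFluxSolution(m, vA, "A"),
                             asFluxSolution(m, vB, "B"),
                             fcThreshold = 2)
  tab <- cmp@table
  expect_equal(tab$log2_ratio[tab$reaction_id == "R1"], -2)
  expect_equal(tab$category[tab$reaction_id == "R1"], "lower_in_B")
  expect_equal(tab$category[tab$reaction_id == "R2"], "lower_in_B")
  expect_equal(tab$category[tab$reaction_id == "R3"], "higher_in_B")
  expect_equal(tab$category[tab$reaction_id == "R5"], "unchanged")
  expect_equal(tab$log2_ratio[tab$reaction_id == "R5"], 0)
  expect_equal(tab$category[tab$reaction_id == "R_atp"], "inactive")
  ## opposite direction: active in both with flipped sign
  expect_true(tab$opposite_direction[tab$reaction_id == "R4"])
  expect_equal(sum(tab$opposite_direction), 1L)
  ## counts partition the reactions
  expect_equal(sum(cmp@counts), nReactions(m))
})
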