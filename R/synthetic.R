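#' @include AllClasses.R utils.R flux-fit.R network-build.R network-compare.R
NULL

## Run code under a fixed seed without disturbing the caller's RNG state.
withLocalSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' The hand-specified toy metabolic model
#'
#' A six-internal-metabolite, seven-reaction network with an ATP/ADP
#' currency cycle and a branch point, small enough that every downstream
#' quantity (flux fit, graphs, rewiring) can be derived by hand:
#' \itemize{
#'   \item \code{R_in}: uptake, -> A, bounds [0, 10], no gene;
#'   \item \code{R1}: A + ATP -> B + ADP (gene G1);
#'   \item \code{R2}: B -> C (GPR "G2 or G3");
#'   \item \code{R3}: B -> D (gene G4);
#'   \item \code{R4}: C <-> D, reversible (gene G5);
#'   \item \code{R5}: D -> (sink), GPR "G6 and G7";
#'   \item \code{R_atp}: ADP -> ATP, no gene.
#' }
#' The documented ground truth \code{\link{fixtureTruth}} satisfies
#' \code{S v = 0} exactly.
#'
#' @return a \code{\link{MetabolicModel-class}} object.
#' @export
fixtureModel <- function() {
  mets <- data.frame(
    id = c("A", "B", "C", "D", "ATP", "ADP"),
    name = c("A", "B", "C", "D", "ATP", "ADP"),
    compartment = "c", boundary = FALSE, stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("R_in", "R1", "R2", "R3", "R4", "R5", "R_atp"),
    lower_bound = c(0, 0, 0, 0, -1000, 0, 0),
    upper_bound = c(10, 1000, 1000, 1000, 1000, 1000, 1000),
    stringsAsFactors = FALSE)
  stoich <- list(
    R_in = c(A = 1),
    R1 = c(A = -1, ATP = -1, B = 1, ADP = 1),
    R2 = c(B = -1, C = 1),
    R3 = c(B = -1, D = 1),
    R4 = c(C = -1, D = 1),
    R5 = c(D = -1),
    R_atp = c(ADP = -1, ATP = 1))
  gpr <- list(NULL, "G1", "G2 or G3", "G4", "G5", "G6 and G7", NULL)
  makeMetabolicModel(mets, rxns, stoich, gpr)
}

#' Ground-truth flux vector of the toy fixture
#'
#' @return named numeric vector (umol/100g/min) with \code{S v = 0}
#'   exactly: 10 units uptake, a 6/4 split over the B -> C / B -> D
#'   branch, R4 running C -> D, and a matching ATP regeneration cycle.
#' @export
fixtureTruth <- function() {
  c(R_in = 10, R1 = 10, R2 = 6, R3 = 4, R4 = 6, R5 = 10, R_atp = 10)
}

#' Wrap a raw flux vector as a FluxSolution
#'
#' Utility for constructing solutions from known (e.g. ground-truth)
#' fluxes; throughput is \code{|v|}, provenance fields are \code{NA}.
#'
#' @param model a \code{MetabolicModel}.
#' @param v named numeric flux vector covering the model's reactions.
#' @param label condition label.
#' @return a \code{FluxSolution}.
#' @export
asFluxSolution <- function(model, v, label = "") {
  rxn <- model@reactions
  i <- match(rxn$id, names(v))
  if (anyNA(i)) stop("flux vector must cover all reactions: missing ",
                     paste(rxn$id[is.na(i)], collapse = ", "))
  vv <- unname(v[i])
  tab <- data.frame(
    reaction_id = rxn$id, flux = vv, throughput = abs(vv),
    lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
    data_value = NA_real_, in_objective = FALSE, stringsAsFactors = FALSE)
  new("FluxSolution", table = tab, label = label)
}

#' Specification for a random toy metabolic model
#'
#' @param n_internal_metabolites number of internal backbone metabolites.
#' @param n_reactions total reactions (uptake + sinks + conversions +
#'   currency regeneration); must leave at least
#'   \code{n_internal_metabolites - 1} conversion reactions.
#' @param reversible_fraction fraction of conversion reactions marked
#'   reversible (in [0, 1]).
#' @param n_currency number of currency cofactor pairs coupled to random
#'   conversion reactions (each adds one regeneration reaction).
#' @param gpr_complexity maximum genes per reaction (random AND/OR
#'   structure above 1; every gene is private to its reaction).
#' @param exchange_count number of exchange reactions (>= 2: one uptake,
#'   at least one sink).
#' @param seed RNG seed fixing all randomness.
#' @return a list of class \code{ToyGemSpec}.
#' @export
toyGemSpec <- function(n_internal_metabolites = 8, n_reactions = 14,
                       reversible_fraction = 0.2, n_currency = 1,
                       gpr_complexity = 1, exchange_count = 2, seed = 1) {
  stopifnot(n_internal_metabolites >= 2, exchange_count >= 2,
            reversible_fraction >= 0, reversible_fraction <= 1,
            n_currency >= 0, gpr_complexity >= 1)
  nConv <- n_reactions - exchange_count - n_currency
  if (nConv < n_internal_metabolites - 1) {
    stop("infeasible spec: n_reactions leaves fewer conversion reactions (",
         nConv, ") than the backbone needs (", n_internal_metabolites - 1, ")")
  }
  structure(list(n_internal_metabolites = n_internal_metabolites,
                 n_reactions = n_reactions,
                 reversible_fraction = reversible_fraction,
                 n_currency = n_currency, gpr_complexity = gpr_complexity,
                 exchange_count = exchange_count, seed = seed),
            class = "ToyGemSpec")
}

#' Generate a random toy metabolic model with planted ground-truth fluxes
#'
#' Builds a connected conversion network: a backbone path from an uptake
#' exchange through all internal metabolites to a sink, plus random
#' forward branches, optional currency-cofactor coupling with
#' regeneration reactions, and one private gene set per reaction. The
#' ground truth \code{v_true} is the superposition of random positive
#' source-to-sink path flows, so \code{S v_true = 0} holds exactly by
#' construction. The same seed reproduces the identical model and fluxes.
#'
#' @param spec a \code{\link{toyGemSpec}}.
#' @return list with \code{model} (\code{MetabolicModel}) and
#'   \code{v_true} (named numeric).
#' @export
makeToyGEM <- function(spec) {
  stopifnot(inherits(spec, "ToyGemSpec"))
  withLocalSeed(spec$seed, {
    m <- spec$n_internal_metabolites
    nSink <- spec$exchange_count - 1L
    nConv <- spec$n_reactions - spec$exchange_count - spec$n_currency

    metIds <- sprintf("M%02d", seq_len(m))
    ## conversion edges i -> j (i < j): backbone first, then random branches
    edges <- cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)
    if (nConv > m * (m - 1L) / 2) {
      stop("infeasible spec: more conversion reactions than metabolite pairs")
    }
    pick1 <- function(x) x[sample.int(length(x), 1L)]
    while (nrow(edges) < nConv) {
      i <- sample.int(m - 1L, 1L)
      j <- pick1(seq.int(i + 1L, m))
      if (!any(edges[, 1] == i & edges[, 2] == j)) {
        edges <- rbind(edges, c(i, j))
      }
    }
    sinkAt <- unique(c(m, if (nSink > 1L) sample.int(m, nSink - 1L)))
    nSink <- length(sinkAt)

    rid <- c("R_upt",
             sprintf("R_snk%02d", sinkAt),
             sprintf("R_cnv%02d", seq_len(nConv)),
             if (spec$n_currency > 0) sprintf("R_reg%02d", seq_len(spec$n_currency)))
    stoich <- vector("list", length(rid))
    names(stoich) <- rid
    stoich[["R_upt"]] <- stats::setNames(1, metIds[1L])
    for (s in sinkAt) {
      stoich[[sprintf("R_snk%02d", s)]] <- stats::setNames(-1, metIds[s])
    }
    for (k in seq_len(nConv)) {
      stoich[[sprintf("R_cnv%02d", k)]] <-
        stats::setNames(c(-1, 1), metIds[edges[k, ]])
    }

    ## currency coupling: reaction consumes CURk, produces CUPk;
    ## a regeneration reaction closes the cycle
    curIds <- character()
    curUsers <- vector("list", spec$n_currency)
    if (spec$n_currency > 0) {
      for (q in seq_len(spec$n_currency)) {
        cur <- sprintf("CUR%d", q); cup <- sprintf("CUP%d", q)
        curIds <- c(curIds, cur, cup)
        users <- which(stats::runif(nConv) < 0.4)
        if (!length(users)) users <- sample.int(nConv, 1L)
        curUsers[[q]] <- users
        for (k in users) {
          rk <- sprintf("R_cnv%02d", k)
          stoich[[rk]] <- c(stoich[[rk]], stats::setNames(c(-1, 1), c(cur, cup)))
        }
        stoich[[sprintf("R_reg%02d", q)]] <- stats::setNames(c(1, -1), c(cur, cup))
      }
    }

    ## planted fluxes: superposed random source-to-sink path flows
    vTrue <- stats::setNames(numeric(length(rid)), rid)
    adj <- lapply(seq_len(m), function(i) which(edges[, 1] == i))
    for (p in seq_len(3L * m)) {
      flow <- stats::runif(1, 1, 5)
      node <- 1L
      repeat {
        if (node %in% sinkAt && (node == m || !length(adj[[node]]) ||
                                 stats::runif(1) < 0.35)) {
          vTrue[[sprintf("R_snk%02d", node)]] <-
            vTrue[[sprintf("R_snk%02d", node)]] + flow
          break
        }
        k <- adj[[node]][sample.int(length(adj[[node]]), 1L)]
        vTrue[[sprintf("R_cnv%02d", k)]] <- vTrue[[sprintf("R_cnv%02d", k)]] + flow
        node <- edges[k, 2L]
      }
      vTrue[["R_upt"]] <- vTrue[["R_upt"]] + flow
    }
    if (spec$n_currency > 0) {
      for (q in seq_len(spec$n_currency)) {
        vTrue[[sprintf("R_reg%02d", q)]] <-
          sum(vTrue[sprintf("R_cnv%02d", curUsers[[q]])])
      }
    }

    ## bounds: uptake clamped to its planted value; reversible subset
    nR <- length(rid)
    lb <- rep(0, nR); ub <- rep(1000, nR)
    ub[1L] <- vTrue[["R_upt"]]
    convIdx <- which(startsWith(rid, "R_cnv"))
    nRev <- round(spec$reversible_fraction * length(convIdx))
    if (nRev > 0) lb[convIdx[sample.int(length(convIdx), nRev)]] <- -1000

    ## private genes; random AND/OR structure above complexity 1
    geneCounter <- 0L
    gpr <- vector("list", nR)
    for (j in seq_len(nR)) {
      if (!startsWith(rid[j], "R_cnv") && !startsWith(rid[j], "R_reg")) next
      k <- sample.int(spec$gpr_complexity, 1L)
      gs <- sprintf("G%03d", geneCounter + seq_len(k))
      geneCounter <- geneCounter + k
      gpr[[j]] <- if (k == 1L) gprLeaf(gs) else {
        gprNode(sample(c("and", "or"), 1L), lapply(gs, gprLeaf))
      }
    }

    mets <- data.frame(id = c(metIds, curIds), name = c(metIds, curIds),
                       compartment = "c", boundary = FALSE,
                       stringsAsFactors = FALSE)
    model <- makeMetabolicModel(
      mets,
      data.frame(id = rid, lower_bound = lb, upper_bound = ub,
                 stringsAsFactors = FALSE),
      stoich, gpr)
    list(model = model, v_true = vTrue)
  })
}

## Recursively assign gene means so the GPR evaluates to `target` under
## the default policy (AND = min: every child gets the full target;
## OR = sum: the target is split equally). First assignment wins for
## genes shared between reactions.
assignGeneTargets <- function(tree, target, env) {
  if (is.null(tree)) return(invisible())
  if (tree$op == "leaf") {
    if (is.null(env$means[[tree$gene]])) env$means[[tree$gene]] <- target
    return(invisible())
  }
  share <- if (tree$op == "or") target / length(tree$children) else target
  for (ch in tree$children) assignGeneTargets(ch, share, env)
  invisible()
}

#' Generate an expression profile from a ground-truth flux vector
#'
#' Assigns each gene a mean such that GPR evaluation under the default
#' policy (AND = min, OR = sum) reproduces \code{|v_true|} per reaction
#' (exact when genes are private to one reaction; otherwise greedy
#' leaf-by-leaf, and the achieved value is recorded as the recovery
#' target in \code{metadata$target_d}). Means are then perturbed with
#' multiplicative gaussian noise of standard deviation
#' \code{noiseSdFrac * mean} and clamped at zero; the reported per-gene
#' SD is that noise SD, floored at \code{sdFloor}.
#'
#' @param model a \code{MetabolicModel}; every gene should appear in at
#'   least one GPR.
#' @param vTrue named ground-truth flux vector.
#' @param noiseSdFrac noise SD as a fraction of the mean (>= 0).
#' @param seed RNG seed.
#' @param condition condition label.
#' @param sdFloor floor for the reported SD.
#' @return an \code{ExpressionProfile}; \code{metadata$target_d} holds
#'   the per-reaction data values the profile encodes.
#' @export
makeExpressionFromFlux <- function(model, vTrue, noiseSdFrac = 0, seed = 1,
                                   condition = "synthetic", sdFloor = 1e-6) {
  stopifnot(noiseSdFrac >= 0)
  rxn <- model@reactions
  i <- match(rxn$id, names(vTrue))
  if (anyNA(i)) stop("vTrue must cover all reactions")
  vv <- abs(unname(vTrue[i]))
  env <- new.env(parent = emptyenv()); env$means <- list()
  for (j in seq_len(nrow(rxn))) assignGeneTargets(model@gpr[[j]], vv[j], env)
  genes <- names(env$means)
  mu <- unlist(env$means, use.names = FALSE)

  targets <- rep(NA_real_, nrow(rxn))
  mv <- stats::setNames(mu, genes)
  zv <- stats::setNames(rep(0, length(genes)), genes)
  for (j in seq_len(nrow(rxn))) {
    ev <- gprEvaluate(model@gpr[[j]], mv, zv, "min_sum")
    if (ev$ok) targets[j] <- ev$value
  }

  withLocalSeed(seed, {
    noise <- stats::rnorm(length(mu), 0, 1)
    muNoisy <- pmax(mu + noise * noiseSdFrac * mu, 0)
    prof <- new("ExpressionProfile", condition = condition,
                data = data.frame(gene = genes, mean = muNoisy,
                                  sd = pmax(noiseSdFrac * mu, sdFloor),
                                  stringsAsFactors = FALSE),
                metadata = list(target_d = stats::setNames(targets, rxn$id)))
    prof
  })
}

## Re-balance a flux vector after knocking out reactions: the closest
## (least-squares) steady-state flux with the knocked-out reactions at
## zero, bounds respected, and every exchange reaction clamped to its
## original value (the measured uptake/secretion rates are condition-
## independent inputs). Errors if no such flow exists.
rebalanceFlux <- function(model, vTrue, knockout) {
  rxn <- model@reactions
  unknown <- setdiff(knockout, rxn$id)
  if (length(unknown)) stop("unknown knockout reaction(s): ",
                            paste(unknown, collapse = ", "))
  n <- nrow(rxn)
  vt <- unname(vTrue[match(rxn$id, names(vTrue))])
  Sint <- as.matrix(stoichiometricMatrix(model, internalOnly = TRUE))
  nz <- Matrix::colSums(model@stoichiometry != 0)
  exch <- which(nz == 1L & !rxn$id %in% knockout)
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  ko <- match(knockout, rxn$id)
  lb[ko] <- 0; ub[ko] <- 0
  lb[exch] <- vt[exch]; ub[exch] <- vt[exch]
  v <- tryCatch(
    solveRidgeQP(cvec = -vt, Aeq = Sint, beq = rep(0, nrow(Sint)),
                 lower = lb, upper = ub, quad = diag(1, n), ridge = 1e-10),
    error = function(e) {
      stop("infeasible knockout: removing {",
           paste(knockout, collapse = ", "),
           "} cuts all remaining steady-state flow [",
           conditionMessage(e), "]", call. = FALSE)
    })
  if (max(abs(v)) < 1e-9) {
    stop("infeasible knockout: removing {", paste(knockout, collapse = ", "),
         "} leaves only the zero flow")
  }
  v[abs(v) < 1e-9] <- 0  # snap solver dust so zero flux is exactly zero
  stats::setNames(v, rxn$id)
}

#' Reactions whose single knockout keeps a nonzero rerouted flow
#'
#' Tries each active, gene-associated conversion reaction and keeps those
#' for which \code{\link{makeConditionPair}} can re-balance the flow.
#'
#' @param model a \code{MetabolicModel}.
#' @param vTrue named ground-truth flux vector.
#' @param zeroTol activity threshold.
#' @return character vector of knockout candidates (possibly empty).
#' @export
feasibleKnockouts <- function(model, vTrue, zeroTol = 1e-6) {
  rxn <- model@reactions
  hasGene <- !vapply(model@gpr, is.null, logical(1))
  nz <- Matrix::colSums(model@stoichiometry != 0)
  cand <- rxn$id[hasGene & nz > 1L &
                 abs(vTrue[match(rxn$id, names(vTrue))]) > zeroTol]
  keep <- vapply(cand, function(r) {
    !inherits(tryCatch(rebalanceFlux(model, vTrue, r), error = identity),
              "error")
  }, logical(1))
  cand[keep]
}

#' Generate a two-condition pair with planted differences
#'
#' Condition A's expression profile encodes the ground-truth fluxes;
#' condition B's encodes the re-balanced flow after knocking out the
#' given reactions (their genes set to zero expression) scaled by a
#' global factor. The knockout must leave a feasible nonzero steady
#' state (flow is rerouted along the remaining paths; an error names the
#' cut otherwise). The returned \code{expected} element records the
#' planted truth against which pipeline output can be scored: the
#' condition-A-specific reaction nodes and the rewired neighbours
#' (dn_raw >= 0.25), both derived from the ground-truth graphs.
#'
#' @param model a \code{MetabolicModel}.
#' @param vTrue named ground-truth flux vector.
#' @param knockout reaction ids knocked out in condition B.
#' @param scaleB global flux scale of condition B (e.g. 0.4 for a
#'   uniformly slower metabolism).
#' @param noiseSdFrac expression noise level (fraction of mean).
#' @param seed RNG seed (condition B uses \code{seed + 1}).
#' @param labels condition labels.
#' @param currency currency list used for the expected graphs.
#' @return list with \code{profile_A}, \code{profile_B}
#'   (\code{ExpressionProfile}s), \code{flux_A}, \code{flux_B} (named
#'   vectors) and \code{expected} (list: \code{a_only_nodes},
#'   \code{rewired_nodes}).
#' @export
makeConditionPair <- function(model, vTrue, knockout = character(),
                              scaleB = 1, noiseSdFrac = 0, seed = 1,
                              labels = c("A", "B"),
                              currency = defaultCurrencyMetabolites()) {
  stopifnot(scaleB > 0)
  vA <- stats::setNames(unname(vTrue[match(model@reactions$id, names(vTrue))]),
                        model@reactions$id)
  vB <- if (length(knockout)) rebalanceFlux(model, vA, knockout) else vA
  vB <- vB * scaleB

  profA <- makeExpressionFromFlux(model, vA, noiseSdFrac, seed,
                                  condition = labels[1L])
  profB <- makeExpressionFromFlux(model, vB, noiseSdFrac, seed + 1L,
                                  condition = labels[2L])
  if (length(knockout)) {
    koGenes <- unique(unlist(lapply(model@gpr[match(knockout, model@reactions$id)],
                                    gprGenes), use.names = FALSE))
    if (length(koGenes)) {
      pb <- profB@data
      pb$mean[pb$gene %in% koGenes] <- 0
      profB <- methods::initialize(profB, data = pb)
    }
  }

  gA <- buildReactionGraph(model, asFluxSolution(model, vA, labels[1L]),
                           currency = currency)
  gB <- buildReactionGraph(model, asFluxSolution(model, vB, labels[2L]),
                           currency = currency)
  ref <- mergeReference(gA, gB)
  rew <- rewiringScores(ref)
  expected <- list(
    a_only_nodes = ref@nodes$node[ref@nodes$membership == "A_only"],
    rewired_nodes = rew@table$node[rew@table$dn_raw >= 0.25])
  list(profile_A = profA, profile_B = profB, flux_A = vA, flux_B = vB,
       expected = expected)
}
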