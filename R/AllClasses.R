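#' @import methods
#' @importClassesFrom Matrix dgCMatrix
NULL

#' MetabolicModel: a genome-scale metabolic model
#'
#' Holds the stoichiometric matrix, reaction bounds and reversibility,
#' gene-protein-reaction (GPR) rules and the gene set of a metabolic model.
#' Rows of the stoichiometric matrix are metabolites (boundary species
#' included as rows but excluded from every steady-state constraint),
#' columns are reactions; entry \code{N[i, j]} is the signed stoichiometric
#' coefficient of metabolite \code{i} in reaction \code{j}.
#'
#' Reversibility is normalized from the bounds: a reaction is reversible
#' if and only if its lower bound is negative. Bounds are the operational
#' truth for all downstream flux computations; a conflicting SBML
#' \code{reversible} attribute is overridden at import.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{boundary} (logical).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound}, \code{reversible}
#'   (bounds in umol/100g/min).
#' @slot stoichiometry sparse \code{dgCMatrix}, metabolites x reactions,
#'   dimnames set to the respective ids.
#' @slot gpr list of GPR trees (see \code{\link{parseGPR}}), one per
#'   reaction, \code{NULL} for reactions without gene association.
#' @slot genes character vector of gene symbols (verbatim, case preserved).
#'
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  slots = c(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "dgCMatrix",
    gpr = "list",
    genes = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need_met <- c("id", "name", "compartment", "boundary")
  need_rxn <- c("id", "name", "lower_bound", "upper_bound", "reversible")
  if (!all(need_met %in% names(met))) {
    msg <- c(msg, "metabolites must have columns id, name, compartment, boundary")
  }
  if (!all(need_rxn %in% names(rxn))) {
    msg <- c(msg, "reactions must have columns id, name, lower_bound, upper_bound, reversible")
  }
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicate reaction ids")
  if (!identical(dim(S), c(nrow(met), nrow(rxn)))) {
    msg <- c(msg, "stoichiometry dimensions do not match metabolites x reactions")
  } else {
    if (!identical(rownames(S), met$id)) msg <- c(msg, "stoichiometry rownames must equal metabolite ids")
    if (!identical(colnames(S), rxn$id)) msg <- c(msg, "stoichiometry colnames must equal reaction ids")
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound]
    msg <- c(msg, paste0("lower_bound > upper_bound for: ", paste(bad, collapse = ", ")))
  }
  if (!identical(rxn$reversible, rxn$lower_bound < 0)) {
    msg <- c(msg, "reversible flag must equal (lower_bound < 0)")
  }
  if (length(object@gpr) != nrow(rxn)) {
    msg <- c(msg, "gpr list length must equal the number of reactions")
  } else {
    gg <- unique(unlist(lapply(object@gpr, gprGenes), use.names = FALSE))
    if (length(gg) && !all(gg %in% object@genes)) {
      msg <- c(msg, "all genes referenced in GPR rules must be listed in genes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ExpressionProfile: per-group gene expression summary
#'
#' One record per gene: the arithmetic mean and the sample standard
#' deviation of expression over all samples of one condition group
#' (e.g. lean or obese).
#'
#' @slot condition single condition label.
#' @slot data data.frame with columns \code{gene}, \code{mean}, \code{sd}.
#' @slot metadata free-form list (e.g. recovery targets set by the
#'   synthetic-data generators).
#'
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
  slots = c(condition = "character", data = "data.frame", metadata = "list"),
  prototype = prototype(condition = "unnamed", metadata = list())
)

setValidity("ExpressionProfile", function(object) {
  msg <- character()
  d <- object@data
  if (!all(c("gene", "mean", "sd") %in% names(d))) {
    return("data must have columns gene, mean, sd")
  }
  if (length(object@condition) != 1L) msg <- c(msg, "condition must be a single label")
  if (anyDuplicated(d$gene)) msg <- c(msg, "one record per gene symbol required")
  if (any(!is.finite(d$mean))) msg <- c(msg, "gene means must be finite")
  if (any(d$sd < 0 | !is.finite(d$sd))) msg <- c(msg, "gene sd must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' ReactionData: expression data mapped onto reactions
#'
#' Per-reaction data value \code{d} (expression units) obtained by
#' evaluating the GPR rule on gene means, the propagated standard
#' deviation, and the fit weight \code{w} (reciprocal dispersion).
#' Reactions without GPR or without any measured gene carry
#' \code{has_data = FALSE}.
#'
#' @slot data data.frame with columns \code{reaction_id}, \code{d},
#'   \code{sd}, \code{w}, \code{has_data}.
#' @slot policy the GPR aggregation policy used (\code{"min_sum"},
#'   \code{"min_max"} or \code{"min_mean"}).
#'
#' @exportClass ReactionData
setClass("ReactionData",
  slots = c(data = "data.frame", policy = "character")
)

setValidity("ReactionData", function(object) {
  d <- object@data
  if (!all(c("reaction_id", "d", "sd", "w", "has_data") %in% names(d))) {
    return("data must have columns reaction_id, d, sd, w, has_data")
  }
  msg <- character()
  hd <- d$has_data
  if (any(hd & (is.na(d$d) | d$d < 0))) msg <- c(msg, "d must be >= 0 where has_data")
  if (any(hd & (is.na(d$w) | d$w <= 0))) msg <- c(msg, "w must be > 0 where has_data")
  if (length(msg)) msg else TRUE
})

#' FluxSolution: a fitted steady-state flux distribution
#'
#' Signed fluxes per reaction (umol/100g/min), the throughput
#' (forward + backward component after reversible splitting) used for
#' comparison against expression data, the final weighted
#' least-absolute-deviation objective, and the trajectory of the
#' flux-expression rank correlation across fit iterations.
#'
#' @slot table data.frame with columns \code{reaction_id}, \code{flux},
#'   \code{throughput}, \code{lower_bound}, \code{upper_bound},
#'   \code{data_value}, \code{in_objective}.
#' @slot objective final weighted L1 objective value.
#' @slot rho final flux-expression correlation (dimensionless, in [-1, 1];
#'   \code{NA} when fewer than 3 data-carrying reactions).
#' @slot rhoTrajectory per-iteration correlation values.
#' @slot iterations number of fit iterations performed.
#' @slot converged whether the stopping rule was met before max_iter.
#' @slot label constraint-set / condition label.
#'
#' @exportClass FluxSolution
setClass("FluxSolution",
  slots = c(
    table = "data.frame",
    objective = "numeric",
    rho = "numeric",
    rhoTrajectory = "numeric",
    iterations = "integer",
    converged = "logical",
    label = "character"
  ),
  prototype = prototype(
    objective = NA_real_, rho = NA_real_, rhoTrajectory = numeric(),
    iterations = 0L, converged = NA, label = ""
  )
)

setValidity("FluxSolution", function(object) {
  need <- c("reaction_id", "flux", "throughput", "lower_bound",
            "upper_bound", "data_value", "in_objective")
  if (!all(need %in% names(object@table))) {
    return(paste("table must have columns", paste(need, collapse = ", ")))
  }
  TRUE
})

#' ConditionGraph: a condition-specific directed metabolic graph
#'
#' Directed graph derived from one flux solution, with either active
#' reactions or their regulating genes as nodes. Edges run from the
#' producer to the consumer of a shared non-currency metabolite under the
#' flux-assigned orientation; parallel edges are merged and annotated with
#' every shared metabolite.
#'
#' @slot nodeKind \code{"reaction"} or \code{"gene"}.
#' @slot nodeTable data.frame with columns \code{node} and \code{flux}
#'   (signed flux for reaction nodes, \code{NA} for gene nodes).
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{shared} (semicolon-joined shared metabolite ids).
#' @slot condition condition label.
#' @slot provenance list (flux solution label, currency ids, zero_tol).
#'
#' @exportClass ConditionGraph
setClass("ConditionGraph",
  slots = c(
    nodeKind = "character",
    nodeTable = "data.frame",
    edges = "data.frame",
    condition = "character",
    provenance = "list"
  ),
  prototype = prototype(condition = "unnamed", provenance = list())
)

setValidity("ConditionGraph", function(object) {
  msg <- character()
  if (!object@nodeKind %in% c("reaction", "gene")) {
    msg <- c(msg, "nodeKind must be 'reaction' or 'gene'")
  }
  if (!all(c("node", "flux") %in% names(object@nodeTable))) {
    msg <- c(msg, "nodeTable must have columns node, flux")
  }
  e <- object@edges
  if (!all(c("from", "to", "shared") %in% names(e))) {
    msg <- c(msg, "edges must have columns from, to, shared")
  } else {
    if (nrow(e)) {
      if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
      if (anyDuplicated(paste(e$from, e$to, sep = "\r"))) {
        msg <- c(msg, "duplicate (from, to) edges must be merged")
      }
      nn <- object@nodeTable$node
      if (!all(c(e$from, e$to) %in% nn)) msg <- c(msg, "edge endpoints must be nodes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceNetwork: union of two condition graphs
#'
#' The union ("central reference") network of two condition-specific
#' graphs of the same kind, with every node and edge labelled by
#' membership: present in both conditions, only in A, or only in B.
#'
#' @slot nodeKind \code{"reaction"} or \code{"gene"}.
#' @slot labelA,labelB the two condition labels.
#' @slot nodes data.frame with columns \code{node}, \code{membership}
#'   (\code{"both"}, \code{"A_only"}, \code{"B_only"}).
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{membership}.
#'
#' @exportClass ReferenceNetwork
setClass("ReferenceNetwork",
  slots = c(
    nodeKind = "character",
    labelA = "character",
    labelB = "character",
    nodes = "data.frame",
    edges = "data.frame"
  )
)

setValidity("ReferenceNetwork", function(object) {
  msg <- character()
  if (!all(object@nodes$membership %in% c("both", "A_only", "B_only"))) {
    msg <- c(msg, "node membership must be both/A_only/B_only")
  }
  if (!all(object@edges$membership %in% c("both", "A_only", "B_only"))) {
    msg <- c(msg, "edge membership must be both/A_only/B_only")
  }
  if (length(msg)) msg else TRUE
})

#' RewiringReport: per-node rewiring (Dn) scores
#'
#' For every node present in both conditions of a reference network, the
#' rewiring score dn_raw (sum over incident union edges of the two-state
#' population variance of the edge presence indicator; 0.25 per edge
#' present in exactly one condition) and its degree-corrected variant.
#' Rows are ranked by dn_raw descending, ties broken by node id.
#'
#' @slot table data.frame with columns \code{node}, \code{dn_raw},
#'   \code{dn_degree_corrected}, \code{union_degree}.
#' @slot labelA,labelB condition labels.
#'
#' @exportClass RewiringReport
setClass("RewiringReport",
  slots = c(table = "data.frame", labelA = "character", labelB = "character")
)

setValidity("RewiringReport", function(object) {
  need <- c("node", "dn_raw", "dn_degree_corrected", "union_degree")
  if (!all(need %in% names(object@table))) {
    return(paste("table must have columns", paste(need, collapse = ", ")))
  }
  if (any(object@table$dn_raw < 0)) return("dn_raw must be >= 0")
  TRUE
})

#' PathLengthDistribution: directed shortest-path length histogram
#'
#' Histogram of finite directed shortest-path lengths (>= 1) over ordered
#' node pairs, the modal length (smallest length on ties), and the number
#' of reachable ordered pairs.
#'
#' @slot histogram named integer vector, names are path lengths.
#' @slot modalLength modal length (\code{NA} for an empty histogram).
#' @slot reachablePairs number of ordered reachable pairs.
#'
#' @exportClass PathLengthDistribution
setClass("PathLengthDistribution",
  slots = c(histogram = "integer", modalLength = "numeric", reachablePairs = "integer")
)

setValidity("PathLengthDistribution", function(object) {
  if (any(object@histogram < 0)) return("histogram counts must be >= 0")
  if (sum(object@histogram) != object@reachablePairs) {
    return("histogram counts must sum to reachablePairs")
  }
  TRUE
})

#' FluxComparison: per-reaction flux change classification
#'
#' Pairwise comparison of two flux solutions on the same model:
#' opposite-direction flags for reactions active in both conditions with
#' opposite signs, log2 flux ratios (B over A), and a fold-change
#' category per reaction, with summary counts.
#'
#' @slot table data.frame with columns \code{reaction_id}, \code{flux_A},
#'   \code{flux_B}, \code{opposite_direction}, \code{log2_ratio},
#'   \code{category}.
#' @slot counts named integer vector over categories
#'   (\code{lower_in_B}, \code{higher_in_B}, \code{unchanged},
#'   \code{inactive}); sums to the number of reactions.
#' @slot labelA,labelB condition labels.
#'
#' @exportClass FluxComparison
setClass("FluxComparison",
  slots = c(table = "data.frame", counts = "integer",
            labelA = "character", labelB = "character")
)

setValidity("FluxComparison", function(object) {
  if (sum(object@counts) != nrow(object@table)) {
    return("category counts must sum to the number of reactions")
  }
  TRUE
})
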