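#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname nReactions
setMethod("nReactions", "MetabolicModel", function(object) nrow(object@reactions))

#' @rdname nReactions
setMethod("nMetabolites", "MetabolicModel", function(object) nrow(object@metabolites))

#' @rdname reactionIds
setMethod("reactionIds", "MetabolicModel", function(object) object@reactions$id)

#' @rdname reactionIds
setMethod("metaboliteIds", "MetabolicModel", function(object) object@metabolites$id)

#' @rdname reactionIds
setMethod("geneIds", "MetabolicModel", function(object) object@genes)

#' @rdname reactionIds
setMethod("stoichiometricMatrix", "MetabolicModel",
  function(object, internalOnly = FALSE) {
    S <- object@stoichiometry
    if (internalOnly) S <- S[!object@metabolites$boundary, , drop = FALSE]
    S
  })

#' @rdname reactionIds
setMethod("reactionBounds", "MetabolicModel", function(object) {
  object@reactions[c("id", "lower_bound", "upper_bound", "reversible")]
})

#' @rdname reactionIds
setMethod("gprRules", "MetabolicModel", function(object) {
  stats::setNames(object@gpr, object@reactions$id)
})

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel:", nrow(object@reactions), "reactions,",
      nrow(object@metabolites), "metabolites",
      sprintf("(%d boundary),", sum(object@metabolites$boundary)),
      length(object@genes), "genes\n")
  cat("  reversible reactions:", sum(object@reactions$reversible), "\n")
  cat("  reactions with GPR:", sum(!vapply(object@gpr, is.null, logical(1))), "\n")
})

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile '", object@condition, "': ",
      nrow(object@data), " genes\n", sep = "")
})

setMethod("show", "ReactionData", function(object) {
  cat("ReactionData (policy ", object@policy, "): ",
      sum(object@data$has_data), "/", nrow(object@data),
      " reactions with data\n", sep = "")
})

#' @rdname fluxes
setMethod("fluxes", "FluxSolution", function(object) {
  stats::setNames(object@table$flux, object@table$reaction_id)
})

#' @rdname fluxes
setMethod("throughputs", "FluxSolution", function(object) {
  stats::setNames(object@table$throughput, object@table$reaction_id)
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution '", object@label, "': ", nrow(object@table),
      " reactions\n", sep = "")
  cat("  objective:", format(object@objective, digits = 6),
      " rho:", format(object@rho, digits = 4),
      " iterations:", object@iterations,
      " converged:", object@converged, "\n")
})

#' @rdname graphNodes
setMethod("graphNodes", "ConditionGraph", function(object) object@nodeTable$node)

#' @rdname graphNodes
setMethod("graphEdges", "ConditionGraph", function(object) object@edges)

#' @rdname graphNodes
setMethod("graphNodes", "ReferenceNetwork", function(object) object@nodes$node)

#' @rdname graphNodes
setMethod("graphEdges", "ReferenceNetwork", function(object) object@edges)

setMethod("show", "ConditionGraph", function(object) {
  cat("ConditionGraph '", object@condition, "' (", object@nodeKind,
      " nodes): ", nrow(object@nodeTable), " nodes, ",
      nrow(object@edges), " edges\n", sep = "")
})

#' @rdname membershipLabels
setMethod("membershipLabels", "ReferenceNetwork", function(object, what = "nodes") {
  what <- match.arg(what, c("nodes", "edges"))
  if (what == "nodes") {
    stats::setNames(object@nodes$membership, object@nodes$node)
  } else {
    stats::setNames(object@edges$membership,
                    paste(object@edges$from, "->", object@edges$to))
  }
})

setMethod("show", "ReferenceNetwork", function(object) {
  nc <- table(factor(object@nodes$membership, c("both", "A_only", "B_only")))
  cat("ReferenceNetwork (", object@nodeKind, " nodes): ",
      object@labelA, " vs ", object@labelB, "\n", sep = "")
  cat("  nodes: both=", nc[["both"]], " A_only=", nc[["A_only"]],
      " B_only=", nc[["B_only"]], "; edges: ", nrow(object@edges), "\n", sep = "")
})

setMethod("show", "RewiringReport", function(object) {
  cat("RewiringReport (", object@labelA, " vs ", object@labelB, "): ",
      nrow(object@table), " shared nodes, ",
      sum(object@table$dn_raw > 0), " rewired\n", sep = "")
})

setMethod("show", "PathLengthDistribution", function(object) {
  cat("PathLengthDistribution:", object@reachablePairs,
      "reachable ordered pairs, modal length",
      format(object@modalLength), "\n")
  if (length(object@histogram)) print(object@histogram)
})

setMethod("show", "FluxComparison", function(object) {
  cat("FluxComparison (", object@labelB, " vs ", object@labelA, "):\n", sep = "")
  print(object@counts)
  cat("  opposite direction:", sum(object@table$opposite_direction), "\n")
})

#' @rdname asIgraph
setMethod("asIgraph", "ConditionGraph", function(object) {
  verts <- data.frame(name = object@nodeTable$node,
                      flux = object@nodeTable$flux,
                      stringsAsFactors = FALSE)
  ed <- object@edges
  igraph::graph_from_data_frame(
    d = data.frame(from = ed$from, to = ed$to, shared = ed$shared,
                   stringsAsFactors = FALSE),
    directed = TRUE, vertices = verts)
})

#' @rdname asIgraph
setMethod("asIgraph", "ReferenceNetwork", function(object) {
  verts <- data.frame(name = object@nodes$node,
                      membership = object@nodes$membership,
                      stringsAsFactors = FALSE)
  ed <- object@edges
  igraph::graph_from_data_frame(
    d = data.frame(from = ed$from, to = ed$to, membership = ed$membership,
                   stringsAsFactors = FALSE),
    directed = TRUE, vertices = verts)
})
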