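#' @include AllClasses.R
NULL

#' Number of reactions / metabolites in a model
#'
#' @param object a \code{MetabolicModel}.
#' @return integer count.
#' @export
setGeneric("nReactions", function(object) standardGeneric("nReactions"))

#' @rdname nReactions
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))

#' Model component accessors
#'
#' @param object a \code{MetabolicModel}.
#' @return \code{reactionIds}, \code{metaboliteIds} and \code{geneIds}
#'   return character vectors; \code{stoichiometricMatrix} the sparse
#'   metabolite-by-reaction matrix (internal metabolites only when
#'   \code{internalOnly = TRUE}); \code{reactionBounds} a data.frame with
#'   \code{id}, \code{lower_bound}, \code{upper_bound}, \code{reversible};
#'   \code{gprRules} the list of GPR trees named by reaction id.
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname reactionIds
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname reactionIds
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname reactionIds
#' @param internalOnly drop boundary metabolite rows (the steady-state
#'   constraint applies to internal metabolites only).
#' @export
setGeneric("stoichiometricMatrix",
  function(object, internalOnly = FALSE) standardGeneric("stoichiometricMatrix"))

#' @rdname reactionIds
#' @export
setGeneric("reactionBounds", function(object) standardGeneric("reactionBounds"))

#' @rdname reactionIds
#' @export
setGeneric("gprRules", function(object) standardGeneric("gprRules"))

#' Fluxes and throughputs of a solution
#'
#' @param object a \code{FluxSolution}.
#' @return named numeric vector over reactions. \code{fluxes} are signed;
#'   \code{throughputs} are the non-negative forward + backward components
#'   used for comparison with expression data.
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname fluxes
#' @export
setGeneric("throughputs", function(object) standardGeneric("throughputs"))

#' Graph component accessors
#'
#' @param object a \code{ConditionGraph} or \code{ReferenceNetwork}.
#' @return \code{graphNodes}: character vector of node ids;
#'   \code{graphEdges}: data.frame of directed edges.
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' @rdname graphNodes
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' Membership labels of a reference network
#'
#' @param object a \code{ReferenceNetwork}.
#' @param what \code{"nodes"} or \code{"edges"}.
#' @return named character vector of membership labels
#'   (\code{both}/\code{A_only}/\code{B_only}); for edges the names are
#'   \code{"from -> to"}.
#' @export
setGeneric("membershipLabels", function(object, what = "nodes") standardGeneric("membershipLabels"))

#' Convert a package graph to an igraph object
#'
#' @param object a \code{ConditionGraph} or \code{ReferenceNetwork}.
#' @return an \code{igraph} directed graph carrying the node and edge
#'   attributes of the object.
#' @export
setGeneric("asIgraph", function(object) standardGeneric("asIgraph"))
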