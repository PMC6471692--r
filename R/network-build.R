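#' @include AllClasses.R utils.R
NULL

#' Orient the active reactions of a flux solution
#'
#' Drops reactions with (near-)zero flux and gives every remaining
#' reaction its effective orientation: for a negative flux the
#' stoichiometric column is sign-flipped, so effective products and
#' reagents reflect the direction the flux actually runs; irreversible
#' reactions keep their declared orientation.
#'
#' @param model a \code{MetabolicModel}.
#' @param solution a \code{FluxSolution} on the model.
#' @param zeroTol activity threshold on |flux| (umol/100g/min).
#' @return list with \code{reactions} (active reaction ids),
#'   \code{flux} (their signed fluxes) and \code{stoichiometry}
#'   (effective metabolite-by-active-reaction matrix).
#' @export
orientActive <- function(model, solution, zeroTol = 1e-6) {
  v <- fluxes(solution)
  i <- match(model@reactions$id, names(v))
  if (anyNA(i)) stop("solution does not cover the model's reactions")
  v <- v[i]
  act <- which(abs(v) > zeroTol)
  S <- model@stoichiometry[, act, drop = FALSE]
  if (length(act)) {
    flip <- v[act] < 0
    if (any(flip)) S[, flip] <- -S[, flip, drop = FALSE]
  }
  list(reactions = model@reactions$id[act], flux = unname(v[act]),
       stoichiometry = S)
}

#' Build the reaction-level condition graph
#'
#' Nodes are the active reactions of the flux solution (isolated active
#' reactions are retained). For every internal, non-currency metabolite,
#' an edge runs from each reaction producing it to each reaction
#' consuming it under the flux-assigned orientation. Parallel edges over
#' several shared metabolites are merged into one edge annotated with all
#' of them. Currency names are matched against metabolite ids and names
#' case-insensitively and compartment-suffix aware (\code{ATP} matches
#' \code{ATP_c}, \code{M_atp_m}, ...); currency entries matching no model
#' metabolite are warned about and ignored.
#'
#' @param model a \code{MetabolicModel}.
#' @param solution a \code{FluxSolution}.
#' @param currency character vector of currency (recurring) metabolite
#'   base names excluded from edge construction.
#' @param zeroTol activity threshold on |flux|.
#' @return a \code{\link{ConditionGraph-class}} with reaction nodes.
#' @export
buildReactionGraph <- function(model, solution,
                               currency = defaultCurrencyMetabolites(),
                               zeroTol = 1e-6) {
  ori <- orientActive(model, solution, zeroTol)
  cm <- currencyMask(model@metabolites, currency)
  if (length(cm$unmatched)) {
    warning("currency metabolite(s) not found in model (ignored): ",
            paste(cm$unmatched, collapse = ", "))
  }
  excluded <- cm$mask | model@metabolites$boundary
  S <- ori$stoichiometry
  from <- character(); to <- character(); met <- character()
  usable <- which(!excluded)
  for (i in usable) {
    row <- S[i, ]
    prod <- which(row > 0); cons <- which(row < 0)
    if (!length(prod) || !length(cons)) next
    pairs <- expand.grid(p = prod, c = cons, KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[pairs$p != pairs$c, , drop = FALSE]
    if (!nrow(pairs)) next
    from <- c(from, ori$reactions[pairs$p])
    to <- c(to, ori$reactions[pairs$c])
    met <- c(met, rep(model@metabolites$id[i], nrow(pairs)))
  }
  edges <- mergeParallelEdges(from, to, met)
  new("ConditionGraph", nodeKind = "reaction",
      nodeTable = data.frame(node = ori$reactions, flux = ori$flux,
                             stringsAsFactors = FALSE),
      edges = edges, condition = solution@label,
      provenance = list(solution = solution@label, currency = currency,
                        zero_tol = zeroTol))
}

mergeParallelEdges <- function(from, to, met) {
  if (!length(from)) {
    return(data.frame(from = character(), to = character(),
                      shared = character(), stringsAsFactors = FALSE))
  }
  key <- edgeKey(from, to)
  ord <- order(from, to, met, method = "radix")
  from <- from[ord]; to <- to[ord]; met <- met[ord]; key <- key[ord]
  first <- !duplicated(key)
  shared <- vapply(split(met, factor(key, levels = key[first])),
                   function(m) paste(unique(m), collapse = ";"), character(1))
  data.frame(from = from[first], to = to[first], shared = unname(shared),
             stringsAsFactors = FALSE)
}

#' Build the gene-level condition graph
#'
#' Genes take the place of the reactions they regulate: the nodes are
#' all genes appearing in the GPR of any active reaction, and for every
#' reaction-level edge a -> b an edge g -> h is added for each gene g
#' regulating a and each gene h regulating b (g != h; all genes of a GPR
#' count as regulators regardless of AND/OR structure). Reactions
#' without a GPR contribute no gene nodes and bridge no gene edges.
#' Duplicates are merged, shared-metabolite annotations pooled.
#'
#' @inheritParams buildReactionGraph
#' @return a \code{\link{ConditionGraph-class}} with gene nodes.
#' @export
buildGeneGraph <- function(model, solution,
                           currency = defaultCurrencyMetabolites(),
                           zeroTol = 1e-6) {
  rg <- buildReactionGraph(model, solution, currency, zeroTol)
  rxnGenes <- stats::setNames(lapply(model@gpr, gprGenes), model@reactions$id)
  active <- rg@nodeTable$node
  nodes <- sort(unique(unlist(rxnGenes[active], use.names = FALSE)))
  from <- character(); to <- character(); met <- character()
  ed <- rg@edges
  for (k in seq_len(nrow(ed))) {
    ga <- rxnGenes[[ed$from[k]]]
    gb <- rxnGenes[[ed$to[k]]]
    if (!length(ga) || !length(gb)) next
    pairs <- expand.grid(g = ga, h = gb, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$g != pairs$h, , drop = FALSE]
    if (!nrow(pairs)) next
    mets <- strsplit(ed$shared[k], ";", fixed = TRUE)[[1L]]
    for (m in mets) {
      from <- c(from, pairs$g); to <- c(to, pairs$h)
      met <- c(met, rep(m, nrow(pairs)))
    }
  }
  edges <- mergeParallelEdges(from, to, met)
  new("ConditionGraph", nodeKind = "gene",
      nodeTable = data.frame(node = nodes, flux = rep(NA_real_, length(nodes)),
                             stringsAsFactors = FALSE),
      edges = edges, condition = solution@label,
      provenance = list(solution = solution@label, currency = currency,
                        zero_tol = zeroTol))
}
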