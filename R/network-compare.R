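#' @include AllClasses.R utils.R
NULL

#' Directed shortest-path length distribution
#'
#' Unweighted directed shortest paths from every node (BFS); the
#' histogram counts ordered node pairs at each finite length >= 1
#' (trivial length-0 pairs and unreachable pairs are excluded). The
#' modal length is the smallest length among tied maximal counts.
#'
#' @param graph a \code{ConditionGraph}.
#' @return a \code{\link{PathLengthDistribution-class}} object.
#' @export
shortestPathDistribution <- function(graph) {
  n <- nrow(graph@nodeTable)
  if (n == 0L) {
    return(new("PathLengthDistribution", histogram = integer(),
               modalLength = NA_real_, reachablePairs = 0L))
  }
  ig <- asIgraph(graph)
  D <- igraph::distances(ig, mode = "out")
  dv <- D[row(D) != col(D)]
  dv <- dv[is.finite(dv) & dv >= 1]
  if (!length(dv)) {
    return(new("PathLengthDistribution", histogram = integer(),
               modalLength = NA_real_, reachablePairs = 0L))
  }
  tb <- table(dv)
  hist <- stats::setNames(as.integer(tb), names(tb))
  lens <- as.numeric(names(hist))
  modal <- min(lens[hist == max(hist)])
  new("PathLengthDistribution", histogram = hist, modalLength = modal,
      reachablePairs = sum(hist))
}

#' Merge two condition graphs into a union reference network
#'
#' Builds the central reference network: the union of the two graphs'
#' nodes and edges, each labelled \code{both}, \code{A_only} or
#' \code{B_only} by presence in the two conditions.
#'
#' @param gA,gB \code{ConditionGraph}s of the same node kind.
#' @return a \code{\link{ReferenceNetwork-class}} object.
#' @export
mergeReference <- function(gA, gB) {
  if (!identical(gA@nodeKind, gB@nodeKind)) {
    stop("cannot merge graphs of different node kinds (",
         gA@nodeKind, " vs ", gB@nodeKind, ")")
  }
  nA <- gA@nodeTable$node; nB <- gB@nodeTable$node
  nodes <- sort(union(nA, nB))
  nodeMem <- ifelse(nodes %in% nA & nodes %in% nB, "both",
                    ifelse(nodes %in% nA, "A_only", "B_only"))
  kA <- edgeKey(gA@edges$from, gA@edges$to)
  kB <- edgeKey(gB@edges$from, gB@edges$to)
  kU <- sort(union(kA, kB))
  parts <- strsplit(kU, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[[`, character(1), 1L),
    to = vapply(parts, `[[`, character(1), 2L),
    membership = ifelse(kU %in% kA & kU %in% kB, "both",
                        ifelse(kU %in% kA, "A_only", "B_only")),
    stringsAsFactors = FALSE)
  labA <- if (nzchar(gA@condition)) gA@condition else "A"
  labB <- if (nzchar(gB@condition)) gB@condition else "B"
  new("ReferenceNetwork", nodeKind = gA@nodeKind, labelA = labA,
      labelB = labB,
      nodes = data.frame(node = nodes, membership = nodeMem,
                         stringsAsFactors = FALSE),
      edges = edges)
}

#' Node rewiring (Dn) scores on a reference network
#'
#' Quantifies, for every node present in both conditions, how much the
#' identity of its interacting neighbours changes. Incident union edges
#' (in- and out-edges pooled) each contribute the population variance of
#' their presence indicator across the two states: 0.25 when present in
#' exactly one condition, 0 when shared. \code{dn_raw} sums these
#' contributions (0.25 x size of the symmetric difference of incident
#' edge sets); \code{dn_degree_corrected} divides by the union degree.
#' Nodes present in only one condition are membership signals, not
#' rewiring signals, and receive no score. Rows are ranked by
#' \code{dn_raw} descending, ties broken by node id.
#'
#' @param ref a \code{ReferenceNetwork}.
#' @return a \code{\link{RewiringReport-class}} object.
#' @export
rewiringScores <- function(ref) {
  shared <- ref@nodes$node[ref@nodes$membership == "both"]
  ed <- ref@edges
  specific <- ed$membership != "both"
  dn <- deg <- stats::setNames(numeric(length(shared)), shared)
  for (k in seq_len(nrow(ed))) {
    for (endp in unique(c(ed$from[k], ed$to[k]))) {
      if (!endp %in% shared) next
      deg[endp] <- deg[endp] + 1
      if (specific[k]) dn[endp] <- dn[endp] + 0.25
    }
  }
  corr <- ifelse(deg > 0, dn / deg, 0)
  ord <- order(-dn, shared, method = "radix")
  tab <- data.frame(node = shared, dn_raw = unname(dn),
                    dn_degree_corrected = unname(corr),
                    union_degree = as.integer(unname(deg)),
                    stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL
  new("RewiringReport", table = tab, labelA = ref@labelA, labelB = ref@labelB)
}

#' Top rewired nodes
#'
#' @param report a \code{RewiringReport}.
#' @param k number of nodes to return (>= 1); capped at the number of
#'   ranked nodes. Ordering is deterministic: dn_raw descending, ties by
#'   node id.
#' @return data.frame of the first \code{k} ranked rows.
#' @export
topRewired <- function(report, k) {
  stopifnot(k >= 1)
  utils::head(report@table, k)
}
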