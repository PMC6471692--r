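#' @include AllClasses.R utils.R
#' @importFrom utils read.delim write.table
NULL

#' Write a flux solution as a TSV table
#'
#' Tab-separated, one row per reaction in model order, columns
#' \code{reaction_id}, \code{flux}, \code{lower_bound}, \code{upper_bound},
#' \code{data_value}, \code{in_objective}. Decimal point is '.', row order
#' is deterministic.
#'
#' @param solution a \code{FluxSolution}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFluxTable <- function(solution, path) {
  tab <- solution@table[c("reaction_id", "flux", "lower_bound",
                          "upper_bound", "data_value", "in_objective")]
  for (col in c("flux", "lower_bound", "upper_bound", "data_value")) {
    tab[[col]] <- numFormat(tab[[col]])
  }
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, dec = ".")
    TRUE
  }, error = function(e) {
    stop("cannot write flux table to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' Read a flux table written by \code{writeFluxTable}
#'
#' @param path TSV path.
#' @param label condition/constraint label to attach.
#' @return a \code{FluxSolution} (objective/rho slots are \code{NA}: a
#'   table on disk carries fluxes, not fit provenance). Throughput is
#'   reconstructed as \code{|flux|}.
#' @export
readFluxTable <- function(path, label = "") {
  if (!file.exists(path)) stop("flux table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "flux", "lower_bound", "upper_bound",
            "data_value", "in_objective")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("flux table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("flux", "lower_bound", "upper_bound", "data_value")) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab$throughput <- abs(tab$flux)
  new("FluxSolution",
      table = tab[c("reaction_id", "flux", "throughput", "lower_bound",
                    "upper_bound", "data_value", "in_objective")],
      label = label)
}

#' Read a per-group expression summary table
#'
#' Reads a TSV/CSV table with columns \code{gene}, \code{mean}, \code{sd}
#' (the per-group summaries of all samples of one condition). Duplicate
#' gene rows are collapsed by averaging, with a warning.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (\code{.csv} = comma, otherwise tab).
#' @param condition condition label for the profile.
#' @return an \code{\link{ExpressionProfile-class}} object.
#' @export
readExpressionTable <- function(path, condition = "unnamed") {
  if (!file.exists(path)) stop("expression table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "mean", "sd"), names(tab))
  if (length(miss)) stop("expression table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(is.na(tab$sd) | tab$sd < 0)) stop("negative or missing sd values")
  if (any(!is.finite(tab$mean))) stop("non-finite gene means")
  if (anyDuplicated(tab$gene)) {
    warning("duplicate gene rows collapsed by averaging: ",
            paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
    tab <- do.call(rbind, lapply(split(tab, tab$gene), function(g) {
      data.frame(gene = g$gene[1L], mean = mean(g$mean), sd = mean(g$sd),
                 stringsAsFactors = FALSE)
    }))
    tab <- tab[order(match(tab$gene, unique(tab$gene))), ]
    rownames(tab) <- NULL
  }
  if (any(tab$mean < 0)) {
    warning("negative gene means clamped to 0 (expression assumed non-negative)")
    tab$mean <- pmax(tab$mean, 0)
  }
  new("ExpressionProfile", condition = condition,
      data = tab[c("gene", "mean", "sd")])
}

#' Write an expression profile as TSV
#'
#' @param profile an \code{ExpressionProfile}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(profile, path) {
  utils::write.table(profile@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a condition graph as an edge-list TSV
#'
#' Columns \code{source}, \code{target}, \code{shared_metabolites}
#' (semicolon-joined).
#'
#' @param graph a \code{ConditionGraph}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeEdgeList <- function(graph, path) {
  ed <- graph@edges
  out <- data.frame(source = ed$from, target = ed$to,
                    shared_metabolites = ed$shared, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph in GraphML format
#'
#' Accepts a \code{ConditionGraph} or a \code{ReferenceNetwork}; node and
#' edge attributes (flux or membership) are carried into the GraphML.
#'
#' @param graph a \code{ConditionGraph} or \code{ReferenceNetwork}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGraphML <- function(graph, path) {
  ig <- asIgraph(graph)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Write a per-node table of a condition graph
#'
#' Columns \code{node}, \code{flux} (NA for gene nodes), \code{condition}.
#'
#' @param graph a \code{ConditionGraph}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNodeTable <- function(graph, path) {
  out <- data.frame(node = graph@nodeTable$node, flux = graph@nodeTable$flux,
                    condition = graph@condition, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
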