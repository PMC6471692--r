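#' @include AllClasses.R gpr.R
NULL

#' Summarize expression samples into a per-group profile
#'
#' Computes, for every gene, the arithmetic mean and the sample standard
#' deviation (n-1 denominator) over the samples of one group, matching
#' the per-group summaries used as the data side of the flux fit.
#'
#' @param sampleValues numeric matrix, genes x samples, with gene symbols
#'   as rownames.
#' @param groupMask logical (or index) vector selecting the group's
#'   columns; at least 2 samples are required (SD is undefined otherwise).
#' @param condition condition label.
#' @return an \code{\link{ExpressionProfile-class}} object.
#' @examples
#' m <- matrix(c(2, 4, 6), 1, 3, dimnames = list("G1", NULL))
#' summarizeGroup(m, c(TRUE, TRUE, TRUE), "demo")
#' @export
summarizeGroup <- function(sampleValues, groupMask, condition = "unnamed") {
  stopifnot(is.matrix(sampleValues), !is.null(rownames(sampleValues)))
  sub <- sampleValues[, groupMask, drop = FALSE]
  if (ncol(sub) < 2L) stop("group must contain at least 2 samples (SD undefined)")
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  if (any(mu < 0)) {
    warning("negative gene means clamped to 0 (expression assumed non-negative)")
    mu <- pmax(mu, 0)
  }
  new("ExpressionProfile", condition = condition,
      data = data.frame(gene = rownames(sub), mean = unname(mu),
                        sd = unname(sdv), stringsAsFactors = FALSE))
}

#' Map an expression profile onto model reactions through GPR rules
#'
#' Evaluates every reaction's GPR rule on the gene means: AND takes the
#' minimum of its children (a complex is limited by its scarcest
#' subunit), OR aggregates isoenzyme children by the chosen policy
#' (default: sum, capacities add). The standard deviation propagates as
#' the SD of the child attaining the minimum (AND), the root sum of
#' squares (OR sum), the SD of the maximal child (OR max), or the RSS
#' divided by the child count (OR mean). The fit weight is the
#' reciprocal dispersion \code{w = 1/max(sd, sdFloor)}.
#'
#' Genes absent from the profile are dropped from OR terms; an AND with
#' any absent child, an empty GPR, or an all-absent OR yields
#' \code{has_data = FALSE}. Negative gene means are clamped to 0 with a
#' warning.
#'
#' @param model a \code{MetabolicModel}.
#' @param profile an \code{ExpressionProfile}.
#' @param policy GPR aggregation policy: \code{"min_sum"} (default),
#'   \code{"min_max"} or \code{"min_mean"}.
#' @param sdFloor dispersion floor (expression units) keeping weights
#'   finite for genes with zero SD.
#' @return a \code{\link{ReactionData-class}} object.
#' @export
mapToReactions <- function(model, profile, policy = c("min_sum", "min_max", "min_mean"),
                           sdFloor = 1e-6) {
  policy <- match.arg(policy)
  pd <- profile@data
  if (any(pd$mean < 0)) {
    warning("negative gene means clamped to 0")
    pd$mean <- pmax(pd$mean, 0)
  }
  means <- stats::setNames(pd$mean, pd$gene)
  sds <- stats::setNames(pd$sd, pd$gene)
  if (!length(intersect(model@genes, pd$gene)) && length(model@genes)) {
    warning("no gene symbols shared between model and profile; no reaction carries data")
  }
  rid <- model@reactions$id
  n <- length(rid)
  d <- sd <- w <- rep(NA_real_, n)
  has <- rep(FALSE, n)
  for (j in seq_len(n)) {
    ev <- gprEvaluate(model@gpr[[j]], means, sds, policy)
    if (ev$ok) {
      has[j] <- TRUE
      d[j] <- max(ev$value, 0)
      sd[j] <- ev$sd
      w[j] <- 1 / max(ev$sd, sdFloor)
    }
  }
  new("ReactionData", policy = policy,
      data = data.frame(reaction_id = rid, d = d, sd = sd, w = w,
                        has_data = has, stringsAsFactors = FALSE))
}

#' Write reaction-level data as TSV
#'
#' @param rdata a \code{ReactionData}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeReactionData <- function(rdata, path) {
  utils::write.table(rdata@data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
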