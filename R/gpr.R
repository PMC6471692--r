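#' @include AllClasses.R
NULL

## GPR trees are lightweight recursive lists:
##   list(op = "leaf", gene = "G1")
##   list(op = "and"|"or", children = list(<tree>, ...))
## NULL stands for an empty (absent) GPR.

gprLeaf <- function(gene) structure(list(op = "leaf", gene = gene), class = "GprTree")
gprNode <- function(op, children) {
  stopifnot(op %in% c("and", "or"), length(children) >= 1L)
  if (length(children) == 1L) return(children[[1L]])
  structure(list(op = op, children = children), class = "GprTree")
}

#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses boolean gene association strings such as
#' \code{"G1 or (G2 and G3)"} into a recursive tree. Tokens are gene
#' symbols, \code{and}/\code{or} (case-insensitive) and parentheses.
#' \code{and} binds tighter than \code{or}. An empty or all-whitespace
#' string yields \code{NULL} (no gene association).
#'
#' @param rule character GPR string.
#' @return a GPR tree (\code{op} = \code{"leaf"}, \code{"and"} or
#'   \code{"or"}) or \code{NULL} for an empty rule.
#' @examples
#' parseGPR("G1 or G2 and G3")
#' @export
parseGPR <- function(rule) {
  if (is.null(rule) || length(rule) == 0L) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  s <- trimws(rule)
  if (!nzchar(s)) return(NULL)
  toks <- gprTokenize(s)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gprParseOr(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR syntax error at token ", st$pos, " ('",
         st$toks[[st$pos]]$text, "') in rule: ", rule)
  }
  tree
}

gprTokenize <- function(s) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(s, i, n), regexpr("^[^()[:space:]]+", substr(s, i, n)))
    if (!length(m)) stop("GPR syntax error at position ", i)
    word <- m[[1L]]
    lw <- tolower(word)
    type <- if (lw == "and") "and" else if (lw == "or") "or" else "gene"
    toks[[length(toks) + 1L]] <- list(type = type, text = word, pos = i)
    i <- i + nchar(word)
  }
  toks
}

gprPeek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]]$type else NA_character_

gprParseOr <- function(st) {
  children <- list(gprParseAnd(st))
  while (identical(gprPeek(st), "or")) {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gprParseAnd(st)
  }
  gprNode("or", children)
}

gprParseAnd <- function(st) {
  children <- list(gprParseAtom(st))
  while (identical(gprPeek(st), "and")) {
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gprParseAtom(st)
  }
  gprNode("and", children)
}

gprParseAtom <- function(st) {
  tp <- gprPeek(st)
  if (is.na(tp)) stop("GPR syntax error: unexpected end of rule")
  tok <- st$toks[[st$pos]]
  if (tp == "(") {
    st$pos <- st$pos + 1L
    inner <- gprParseOr(st)
    if (!identical(gprPeek(st), ")")) {
      stop("GPR syntax error: unbalanced parentheses (opened at position ",
           tok$pos, ")")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tp == "gene") {
    st$pos <- st$pos + 1L
    return(gprLeaf(tok$text))
  }
  stop("GPR syntax error at position ", tok$pos, ": unexpected '", tok$text, "'")
}

#' Serialize a GPR tree back to a rule string
#'
#' Inverse of \code{\link{parseGPR}} up to whitespace and redundant
#' parentheses: re-parsing the serialized string yields an identical tree.
#'
#' @param tree a GPR tree or \code{NULL}.
#' @return character rule string (\code{""} for \code{NULL}).
#' @export
gprToString <- function(tree) {
  if (is.null(tree)) return("")
  switch(tree$op,
    leaf = tree$gene,
    and = paste(vapply(tree$children, function(ch) {
      s <- gprToString(ch)
      if (!is.null(ch$op) && ch$op == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    or = paste(vapply(tree$children, gprToString, character(1)),
               collapse = " or "),
    stop("invalid GPR node op: ", tree$op)
  )
}

#' Genes referenced by a GPR tree
#'
#' @param tree a GPR tree or \code{NULL}.
#' @return character vector of unique gene symbols (in first-appearance
#'   order; empty for \code{NULL}).
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "leaf") return(tree$gene)
  unique(unlist(lapply(tree$children, gprGenes), use.names = FALSE))
}

## Evaluate a GPR tree on gene means under an aggregation policy.
## Returns list(value, sd, ok):
##   AND -> min of children (sd of the child attaining the minimum);
##   OR  -> sum / max / mean of available children (sd propagated as
##          root-sum-of-squares, sd of the max child, or rms/k);
## genes absent from the profile are dropped from OR terms; an AND with
## any absent child is unavailable (ok = FALSE).
gprEvaluate <- function(tree, means, sds, policy = c("min_sum", "min_max", "min_mean")) {
  policy <- match.arg(policy)
  if (is.null(tree)) return(list(value = NA_real_, sd = NA_real_, ok = FALSE))
  if (tree$op == "leaf") {
    g <- tree$gene
    if (!g %in% names(means)) return(list(value = NA_real_, sd = NA_real_, ok = FALSE))
    return(list(value = unname(means[[g]]), sd = unname(sds[[g]]), ok = TRUE))
  }
  kids <- lapply(tree$children, gprEvaluate, means = means, sds = sds, policy = policy)
  if (tree$op == "and") {
    if (!all(vapply(kids, `[[`, logical(1), "ok"))) {
      return(list(value = NA_real_, sd = NA_real_, ok = FALSE))
    }
    vals <- vapply(kids, `[[`, numeric(1), "value")
    i <- which.min(vals)
    return(list(value = vals[i], sd = kids[[i]]$sd, ok = TRUE))
  }
  ## OR: drop unavailable children
  kids <- kids[vapply(kids, `[[`, logical(1), "ok")]
  if (!length(kids)) return(list(value = NA_real_, sd = NA_real_, ok = FALSE))
  vals <- vapply(kids, `[[`, numeric(1), "value")
  sds2 <- vapply(kids, `[[`, numeric(1), "sd")
  switch(substring(policy, 5L),
    sum = list(value = sum(vals), sd = sqrt(sum(sds2^2)), ok = TRUE),
    max = {
      i <- which.max(vals)
      list(value = vals[i], sd = sds2[i], ok = TRUE)
    },
    mean = list(value = mean(vals), sd = sqrt(sum(sds2^2)) / length(vals), ok = TRUE)
  )
}
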