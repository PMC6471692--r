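#' @include AllClasses.R
#' @importFrom Matrix sparseMatrix
NULL

#' Construct a MetabolicModel from components
#'
#' Low-level constructor used by the SBML reader and the toy-model
#' generators. Reversibility is normalized to \code{lower_bound < 0}.
#'
#' @param metabolites data.frame with columns \code{id} and optionally
#'   \code{name}, \code{compartment}, \code{boundary}.
#' @param reactions data.frame with columns \code{id} and optionally
#'   \code{name}, \code{lower_bound}, \code{upper_bound}.
#' @param stoichiometry named list, one entry per reaction (in reaction
#'   order): named numeric vector of signed coefficients per metabolite id
#'   (negative = consumed, positive = produced).
#' @param gpr list of GPR trees or rule strings (parsed if character),
#'   one per reaction; \code{NULL} entries mean no gene association.
#' @param defaultBound bound magnitude used when \code{lower_bound} /
#'   \code{upper_bound} columns are absent (umol/100g/min).
#' @return a validated \code{MetabolicModel}.
#' @export
makeMetabolicModel <- function(metabolites, reactions, stoichiometry,
                               gpr = NULL, defaultBound = 1000) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(metabolites$boundary)) metabolites$boundary <- FALSE
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lower_bound)) reactions$lower_bound <- 0
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- defaultBound
  reactions$reversible <- reactions$lower_bound < 0
  metabolites <- metabolites[c("id", "name", "compartment", "boundary")]
  reactions <- reactions[c("id", "name", "lower_bound", "upper_bound", "reversible")]

  if (is.null(gpr)) gpr <- vector("list", nrow(reactions))
  gpr <- lapply(gpr, function(g) if (is.character(g)) parseGPR(g) else g)
  stopifnot(length(gpr) == nrow(reactions),
            length(stoichiometry) == nrow(reactions))

  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(stoichiometry)) {
    sj <- stoichiometry[[j]]
    if (!length(sj)) next
    mi <- match(names(sj), metabolites$id)
    if (anyNA(mi)) {
      stop("reaction '", reactions$id[j], "' references unknown metabolite(s): ",
           paste(names(sj)[is.na(mi)], collapse = ", "))
    }
    keep <- sj != 0
    ii <- c(ii, mi[keep]); jj <- c(jj, rep.int(j, sum(keep))); xx <- c(xx, sj[keep])
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(metabolites), nrow(reactions)),
                            dimnames = list(metabolites$id, reactions$id))
  genes <- unique(unlist(lapply(gpr, gprGenes), use.names = FALSE))
  if (is.null(genes)) genes <- character()
  new("MetabolicModel", metabolites = metabolites, reactions = reactions,
      stoichiometry = methods::as(S, "CsparseMatrix"), gpr = gpr, genes = genes)
}

#' Default currency (recurring) metabolite list
#'
#' Ubiquitous cofactors excluded from graph construction so that shared-
#' metabolite edges reflect carbon/backbone chemistry rather than cofactor
#' turnover. Matching against model metabolites is compartment-suffix
#' aware and case-insensitive (see \code{\link{buildReactionGraph}}).
#'
#' @return character vector of currency metabolite base names.
#' @export
defaultCurrencyMetabolites <- function() {
  c("H2O", "CO2", "O2", "ATP", "ADP", "AMP", "Pi", "PPi",
    "NADH", "NAD+", "NADPH", "NADP+", "FADH2", "FAD", "H+", "CoA")
}

## Match currency names against model metabolites, compartment-suffix
## aware: metabolite id (optionally prefixed "M_"/"m_", optionally
## suffixed "_<compartment>") or metabolite name matches the currency
## base name case-insensitively.
## Returns list(mask = logical over metabolites, unmatched = character).
currencyMask <- function(metabolites, currency) {
  ids <- tolower(metabolites$id)
  base <- sub("^m_", "", ids)
  base_nc <- sub("_[a-z0-9]+$", "", base)
  nms <- tolower(metabolites$name)
  mask <- rep(FALSE, nrow(metabolites))
  unmatched <- character()
  for (cur in currency) {
    cl <- tolower(cur)
    hit <- ids == cl | base == cl | base_nc == cl | nms == cl
    if (!any(hit)) unmatched <- c(unmatched, cur) else mask <- mask | hit
  }
  list(mask = mask, unmatched = unmatched)
}

## Deterministic ordered-pair key for edges.
edgeKey <- function(from, to) paste(from, to, sep = "\r")

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

## Format numbers for text outputs: full double precision (so values
## survive a write-read round trip bit-exactly), no scientific notation.
numFormat <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    if (isTRUE(as.numeric(s) == v)) s else sprintf("%.17e", v)
  }, character(1))
}
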