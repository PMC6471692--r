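#' @include AllClasses.R utils.R
#' @importFrom xml2 read_xml xml_find_all xml_find_first xml_attrs xml_text xml_name
NULL

## Namespace-agnostic attribute lookup: matches the local attribute name
## whether or not it carries a namespace prefix (fbc:lowerFluxBound etc.).
xAttr <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(a)) == name)
  if (length(hit)) unname(a[hit[1L]]) else NA_character_
}

xChildren <- function(node, localname) {
  xml2::xml_find_all(node, sprintf("./*[local-name()='%s']", localname))
}

xDescendants <- function(node, path) {
  xml2::xml_find_all(node, paste0("./", paste(
    sprintf("*[local-name()='%s']", path), collapse = "/")))
}

#' Read an SBML metabolic model
#'
#' Imports SBML Level 2 or Level 3 models, with or without the FBC
#' extension, optionally gzip-compressed (\code{.xml.gz}). Flux bounds are
#' taken from FBC bound parameters when present, else from kinetic-law
#' parameters named \code{LOWER_BOUND}/\code{UPPER_BOUND}, else set to
#' \code{[0, defaultBound]} (\code{[-defaultBound, defaultBound]} when the
#' SBML \code{reversible} attribute is true). Gene associations are read
#' from \code{fbc:geneProductAssociation} elements or, failing that, from
#' \code{GENE_ASSOCIATION} notes. After import, the reversible flag is
#' normalized to \code{lower_bound < 0}: bounds are the operational truth
#' for flux fitting, overriding a conflicting SBML attribute.
#'
#' @param path SBML file path (plain or gzipped XML).
#' @param defaultBound bound magnitude for reactions without explicit
#'   bounds (umol/100g/min).
#' @return a \code{\link{MetabolicModel-class}} object.
#' @export
readSBMLModel <- function(path, defaultBound = 1000) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "rb")
      on.exit(close(con), add = TRUE)
      xml2::read_xml(paste(readLines(con, warn = FALSE), collapse = "\n"))
    } else {
      xml2::read_xml(path)
    }
  }, error = function(e) stop("invalid SBML in '", path, "': ", conditionMessage(e)))

  model <- xml2::xml_find_first(doc, "./*[local-name()='model']")
  if (inherits(model, "xml_missing")) stop("invalid SBML: no <model> element in ", path)

  ## species
  sp <- xDescendants(model, c("listOfSpecies", "species"))
  if (!length(sp)) stop("invalid SBML: no species in <listOfSpecies>")
  metabolites <- data.frame(
    id = vapply(sp, xAttr, character(1), "id"),
    name = vapply(sp, function(n) {
      nm <- xAttr(n, "name"); if (is.na(nm)) xAttr(n, "id") else nm
    }, character(1)),
    compartment = vapply(sp, function(n) {
      cp <- xAttr(n, "compartment"); if (is.na(cp)) "c" else cp
    }, character(1)),
    boundary = vapply(sp, function(n) {
      identical(xAttr(n, "boundaryCondition"), "true")
    }, logical(1)),
    stringsAsFactors = FALSE
  )
  if (anyNA(metabolites$id)) stop("invalid SBML: species without id")

  ## global parameters (FBC bound values live here in L3)
  par <- xDescendants(model, c("listOfParameters", "parameter"))
  parVal <- stats::setNames(
    vapply(par, function(n) as.numeric(xAttr(n, "value")), numeric(1)),
    vapply(par, xAttr, character(1), "id"))

  ## fbc gene products: id -> label
  gp <- xml2::xml_find_all(model, ".//*[local-name()='geneProduct']")
  gpLabel <- stats::setNames(
    vapply(gp, function(n) {
      lb <- xAttr(n, "label")
      if (is.na(lb)) sub("^G_", "", xAttr(n, "id")) else lb
    }, character(1)),
    vapply(gp, xAttr, character(1), "id"))

  rx <- xDescendants(model, c("listOfReactions", "reaction"))
  if (!length(rx)) stop("invalid SBML: no reactions in <listOfReactions>")

  n <- length(rx)
  rid <- character(n); rname <- character(n)
  lb <- numeric(n); ub <- numeric(n)
  stoich <- vector("list", n); gpr <- vector("list", n)

  for (j in seq_len(n)) {
    node <- rx[[j]]
    rid[j] <- xAttr(node, "id")
    if (is.na(rid[j])) stop("invalid SBML: reaction #", j, " without id")
    nm <- xAttr(node, "name")
    rname[j] <- if (is.na(nm)) rid[j] else nm
    revAttr <- identical(xAttr(node, "reversible"), "true")

    coef <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (ref in xDescendants(node, c(side, "speciesReference"))) {
        spid <- xAttr(ref, "species")
        if (is.na(spid) || !spid %in% metabolites$id) {
          stop("invalid SBML: reaction '", rid[j],
               "' references unknown species '", spid, "'")
        }
        st <- xAttr(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        coef[spid] <- (if (spid %in% names(coef)) coef[[spid]] else 0) + sgn * st
      }
    }
    stoich[[j]] <- coef

    ## bounds: fbc attributes > kinetic-law parameters > defaults
    lbRef <- xAttr(node, "lowerFluxBound")
    ubRef <- xAttr(node, "upperFluxBound")
    lj <- uj <- NA_real_
    if (!is.na(lbRef)) lj <- if (lbRef %in% names(parVal)) parVal[[lbRef]] else as.numeric(lbRef)
    if (!is.na(ubRef)) uj <- if (ubRef %in% names(parVal)) parVal[[ubRef]] else as.numeric(ubRef)
    if (is.na(lj) || is.na(uj)) {
      kl <- xml2::xml_find_all(node,
        "./*[local-name()='kineticLaw']//*[local-name()='parameter' or local-name()='localParameter']")
      for (p in kl) {
        pid <- xAttr(p, "id"); if (is.na(pid)) pid <- xAttr(p, "name")
        v <- as.numeric(xAttr(p, "value"))
        if (identical(pid, "LOWER_BOUND") && is.na(lj)) lj <- v
        if (identical(pid, "UPPER_BOUND") && is.na(uj)) uj <- v
      }
    }
    if (is.na(lj)) lj <- if (revAttr) -defaultBound else 0
    if (is.na(uj)) uj <- defaultBound
    lb[j] <- lj; ub[j] <- uj

    ## GPR: fbc geneProductAssociation, else GENE_ASSOCIATION note
    gpa <- xml2::xml_find_first(node, "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_find_all(gpa, "./*")
      if (length(kids)) gpr[[j]] <- fbcAssocToTree(kids[[1L]], gpLabel, rid[j])
    } else {
      notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexpr("GENE[_ ]ASSOCIATION:[^\n\r<]*", txt))
        if (length(m)) {
          rule <- trimws(sub("^GENE[_ ]ASSOCIATION:", "", m[[1L]]))
          gpr[[j]] <- tryCatch(parseGPR(rule), error = function(e) {
            stop("GPR syntax error in reaction '", rid[j], "': ",
                 conditionMessage(e))
          })
        }
      }
    }
  }

  makeMetabolicModel(
    metabolites = metabolites,
    reactions = data.frame(id = rid, name = rname, lower_bound = lb,
                           upper_bound = ub, stringsAsFactors = FALSE),
    stoichiometry = stoich, gpr = gpr, defaultBound = defaultBound
  )
}

fbcAssocToTree <- function(node, gpLabel, rid) {
  nm <- sub("^.*:", "", xml2::xml_name(node))
  if (nm == "geneProductRef") {
    ref <- xAttr(node, "geneProduct")
    label <- if (!is.na(ref) && ref %in% names(gpLabel)) gpLabel[[ref]] else sub("^G_", "", ref)
    return(gprLeaf(label))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_find_all(node, "./*"), fbcAssocToTree,
                   gpLabel = gpLabel, rid = rid)
    if (!length(kids)) stop("invalid SBML: empty fbc:", nm, " in reaction '", rid, "'")
    return(gprNode(nm, kids))
  }
  stop("invalid SBML: unsupported gene association element <", nm,
       "> in reaction '", rid, "'")
}

#' Write a model as SBML Level 3 (FBC version 2)
#'
#' Serializes a \code{MetabolicModel} to SBML L3V1 with FBC flux-bound
#' parameters and nested gene product associations. Writing to a path
#' ending in \code{.gz} produces a gzip-compressed file. The output
#' round-trips through \code{\link{readSBMLModel}}.
#'
#' @param model a \code{MetabolicModel}.
#' @param path output file path.
#' @param modelId SBML model id.
#' @return invisibly, \code{path}.
#' @export
writeSBMLModel <- function(model, path, modelId = "model") {
  met <- model@metabolites
  rxn <- model@reactions
  S <- model@stoichiometry
  genes <- sort(model@genes)
  geneId <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

  L <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\" ",
           "level=\"3\" version=\"1\" fbc:required=\"false\">"),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", xmlEscape(modelId)),
    "    <listOfCompartments>")
  for (cp in unique(met$compartment)) {
    L <- c(L, sprintf("      <compartment id=\"%s\" constant=\"true\"/>", xmlEscape(cp)))
  }
  L <- c(L, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(met))) {
    L <- c(L, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "boundaryCondition=\"%s\" hasOnlySubstanceUnits=\"false\" constant=\"false\"/>"),
      xmlEscape(met$id[i]), xmlEscape(met$name[i]), xmlEscape(met$compartment[i]),
      if (met$boundary[i]) "true" else "false"))
  }
  L <- c(L, "    </listOfSpecies>", "    <listOfParameters>")
  for (j in seq_len(nrow(rxn))) {
    L <- c(L, sprintf("      <parameter id=\"%s_lb\" value=\"%s\" constant=\"true\"/>",
                      xmlEscape(rxn$id[j]), numFormat(rxn$lower_bound[j])),
              sprintf("      <parameter id=\"%s_ub\" value=\"%s\" constant=\"true\"/>",
                      xmlEscape(rxn$id[j]), numFormat(rxn$upper_bound[j])))
  }
  L <- c(L, "    </listOfParameters>")
  if (length(genes)) {
    L <- c(L, "    <fbc:listOfGeneProducts>")
    for (g in genes) {
      L <- c(L, sprintf("      <fbc:geneProduct fbc:id=\"%s\" fbc:label=\"%s\"/>",
                        xmlEscape(geneId(g)), xmlEscape(g)))
    }
    L <- c(L, "    </fbc:listOfGeneProducts>")
  }
  L <- c(L, "    <listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    L <- c(L, sprintf(
      paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"%s_lb\" fbc:upperFluxBound=\"%s_ub\">"),
      xmlEscape(rxn$id[j]), xmlEscape(rxn$name[j]),
      if (rxn$reversible[j]) "true" else "false",
      xmlEscape(rxn$id[j]), xmlEscape(rxn$id[j])))
    coef <- S[, j]
    cons <- which(coef < 0); prod <- which(coef > 0)
    if (length(cons)) {
      L <- c(L, "        <listOfReactants>")
      for (i in cons) L <- c(L, sprintf(
        "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
        xmlEscape(met$id[i]), numFormat(-coef[i])))
      L <- c(L, "        </listOfReactants>")
    }
    if (length(prod)) {
      L <- c(L, "        <listOfProducts>")
      for (i in prod) L <- c(L, sprintf(
        "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
        xmlEscape(met$id[i]), numFormat(coef[i])))
      L <- c(L, "        </listOfProducts>")
    }
    tree <- model@gpr[[j]]
    if (!is.null(tree)) {
      L <- c(L, "        <fbc:geneProductAssociation>",
             fbcTreeToXml(tree, geneId, indent = "          "),
             "        </fbc:geneProductAssociation>")
    }
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>", "  </model>", "</sbml>")

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(L, con)
  invisible(path)
}

fbcTreeToXml <- function(tree, geneId, indent) {
  if (tree$op == "leaf") {
    return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                   indent, xmlEscape(geneId(tree$gene))))
  }
  inner <- unlist(lapply(tree$children, fbcTreeToXml, geneId = geneId,
                         indent = paste0(indent, "  ")))
  c(sprintf("%s<fbc:%s>", indent, tree$op), inner,
    sprintf("%s</fbc:%s>", indent, tree$op))
}
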