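#' @include AllClasses.R flux-fit.R network-build.R network-compare.R tables.R
NULL

#' Read constraint sets from a YAML file
#'
#' Expected layout: a mapping of time-point labels to mappings of
#' reaction id to \code{[lower, upper]} (umol/100g/min), e.g.
#' \preformatted{tp4:
#'   R_glc: [-3.2, -3.2]
#'   R_tag: [0.9, 0.9]}
#'
#' @param path YAML file path.
#' @return named list of constraint data.frames (columns
#'   \code{reaction_id}, \code{lower}, \code{upper}).
#' @export
readConstraintSets <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(set) {
    data.frame(
      reaction_id = names(set),
      lower = vapply(set, function(x) as.numeric(x[[1L]]), numeric(1)),
      upper = vapply(set, function(x) as.numeric(x[[2L]]), numeric(1)),
      stringsAsFactors = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' For every condition x constraint set: applies the measured-flux
#' clamps, fits the fluxes to the condition's expression data, and
#' builds the requested condition graphs. For every constraint set (when
#' exactly two conditions are configured): merges the two condition
#' graphs into a reference network, computes rewiring scores and
#' shortest-path distributions, and classifies per-reaction flux
#' changes. All artifacts are written under \code{out_dir}
#' (\code{<condition>_<timepoint>/} per run,
#' \code{compare_<timepoint>/} per comparison) and listed, with md5
#' hashes and the correlation trajectories, in \code{manifest.json}.
#' The pipeline is deterministic: identical inputs produce
#' byte-identical outputs.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{model} (path or \code{MetabolicModel}); \code{expression}
#'   (named list: condition label to path or \code{ExpressionProfile});
#'   \code{constraints} (named list: time-point label to constraint
#'   data.frame / named list, or a YAML path); optional \code{currency}
#'   (character vector or YAML path; default
#'   \code{\link{defaultCurrencyMetabolites}}), \code{fit}
#'   (\code{\link{fitOptions}}), \code{gpr_policy}, \code{graph_kinds}
#'   (subset of \code{c("reaction", "gene")}), \code{top_k} (default 20),
#'   \code{fc_threshold} (default 2), \code{zero_tol}; and
#'   \code{out_dir}.
#' @return the manifest, invisibly (also written as JSON).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir),
            !is.null(config$model), !is.null(config$expression),
            !is.null(config$constraints))

  model <- config$model
  if (is.character(model)) model <- readSBMLModel(model)
  profiles <- lapply(names(config$expression), function(lab) {
    p <- config$expression[[lab]]
    if (is.character(p)) readExpressionTable(p, condition = lab) else p
  })
  names(profiles) <- names(config$expression)
  if (anyDuplicated(names(profiles))) stop("condition labels must be unique")

  constraints <- config$constraints
  if (is.character(constraints)) constraints <- readConstraintSets(constraints)
  currency <- config$currency
  if (is.null(currency)) currency <- defaultCurrencyMetabolites()
  if (is.character(currency) && length(currency) == 1L && file.exists(currency)) {
    currency <- unlist(yaml::read_yaml(currency), use.names = FALSE)
  }
  opts <- if (is.null(config$fit)) fitOptions() else config$fit
  policy <- if (is.null(config$gpr_policy)) "min_sum" else config$gpr_policy
  kinds <- if (is.null(config$graph_kinds)) c("reaction", "gene") else config$graph_kinds
  topK <- if (is.null(config$top_k)) 20L else as.integer(config$top_k)
  fcThr <- if (is.null(config$fc_threshold)) 2 else config$fc_threshold
  zeroTol <- if (is.null(config$zero_tol)) 1e-6 else config$zero_tol

  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  rhoTraj <- list()
  logLines <- character()
  say <- function(...) {
    logLines <<- c(logLines, paste0(...))
  }
  addArtifact <- function(path) {
    rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", outDir), "/?"),
               "", path)
    artifacts[[length(artifacts) + 1L]] <<- list(
      path = rel, md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, label, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed for '", label, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  solutions <- list()
  graphs <- list()
  for (cond in names(profiles)) {
    rdata <- stage("map_to_reactions", cond,
                   mapToReactions(model, profiles[[cond]], policy = policy))
    for (tp in names(constraints)) {
      runLab <- paste0(cond, "_", tp)
      runDir <- file.path(outDir, runLab)
      dir.create(runDir, showWarnings = FALSE)
      cmodel <- stage("apply_constraints", runLab,
                      applyFluxConstraints(model, constraints[[tp]]))
      sol <- stage("fit_fluxes", runLab,
                   fitFluxes(cmodel, rdata, opts = opts, label = runLab))
      solutions[[runLab]] <- sol
      rhoTraj[[runLab]] <- sol@rhoTrajectory
      say("fit ", runLab, ": rho=", format(sol@rho, digits = 4),
          " iterations=", sol@iterations, " converged=", sol@converged)
      fp <- file.path(runDir, "flux.tsv")
      writeFluxTable(sol, fp); addArtifact(fp)
      for (kind in kinds) {
        g <- stage(paste0("build_", kind, "_graph"), runLab,
                   withCallingHandlers({
                     if (kind == "reaction") {
                       buildReactionGraph(cmodel, sol, currency, zeroTol)
                     } else {
                       buildGeneGraph(cmodel, sol, currency, zeroTol)
                     }
                   }, warning = function(w) {
                     say("warning (", runLab, "/", kind, "): ",
                         conditionMessage(w))
                     invokeRestart("muffleWarning")
                   }))
        graphs[[paste0(runLab, ".", kind)]] <- g
        ep <- file.path(runDir, paste0(kind, ".edges.tsv"))
        writeEdgeList(g, ep); addArtifact(ep)
        np <- file.path(runDir, paste0(kind, ".nodes.tsv"))
        writeNodeTable(g, np); addArtifact(np)
        gp <- file.path(runDir, paste0(kind, ".graphml"))
        writeGraphML(g, gp); addArtifact(gp)
      }
    }
  }

  comparisons <- list()
  if (length(profiles) == 2L) {
    condA <- names(profiles)[1L]; condB <- names(profiles)[2L]
    for (tp in names(constraints)) {
      cmpDir <- file.path(outDir, paste0("compare_", tp))
      dir.create(cmpDir, showWarnings = FALSE)
      labA <- paste0(condA, "_", tp); labB <- paste0(condB, "_", tp)
      report <- list(timepoint = tp, condition_A = condA, condition_B = condB)
      for (kind in kinds) {
        ref <- stage("merge_reference", tp,
                     mergeReference(graphs[[paste0(labA, ".", kind)]],
                                    graphs[[paste0(labB, ".", kind)]]))
        rew <- rewiringScores(ref)
        top <- topRewired(rew, topK)
        distA <- shortestPathDistribution(graphs[[paste0(labA, ".", kind)]])
        distB <- shortestPathDistribution(graphs[[paste0(labB, ".", kind)]])
        memb <- table(factor(ref@nodes$membership,
                             c("both", "A_only", "B_only")))
        report[[kind]] <- list(
          node_membership = as.list(memb),
          top_rewired = top,
          path_histogram_A = as.list(distA@histogram),
          path_histogram_B = as.list(distB@histogram),
          modal_length_A = distA@modalLength,
          modal_length_B = distB@modalLength)
        rp <- file.path(cmpDir, paste0(kind, ".reference.graphml"))
        refIg <- asIgraph(ref)
        dn <- rew@table$dn_raw[match(ref@nodes$node, rew@table$node)]
        refIg <- igraph::set_vertex_attr(refIg, "dn_raw",
                                         value = ifelse(is.na(dn), 0, dn))
        igraph::write_graph(refIg, rp, format = "graphml")
        addArtifact(rp)
        tp2 <- file.path(cmpDir, paste0(kind, ".rewiring.tsv"))
        utils::write.table(rew@table, tp2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        addArtifact(tp2)
      }
      fcmp <- stage("classify_flux_changes", tp,
                    classifyFluxChanges(solutions[[labA]], solutions[[labB]],
                                        fcThreshold = fcThr,
                                        activeTol = opts$active_tol))
      report$flux_changes <- list(
        counts = as.list(fcmp@counts),
        opposite_direction = fcmp@table$reaction_id[fcmp@table$opposite_direction])
      fp <- file.path(cmpDir, "flux_changes.tsv")
      utils::write.table(fcmp@table, fp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      addArtifact(fp)
      rp <- file.path(cmpDir, "report.json")
      jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      addArtifact(rp)
      comparisons[[tp]] <- report
    }
  } else if (length(profiles) != 2L) {
    say("skipping comparisons: ", length(profiles),
        " condition(s) configured (pairwise comparison needs exactly 2)")
  }

  manifest <- list(conditions = names(profiles),
                   timepoints = names(constraints),
                   rho_trajectories = rhoTraj,
                   artifacts = artifacts,
                   log = logLines)
  mp <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(manifest)
}
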