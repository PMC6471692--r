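#' @include AllClasses.R solver.R
NULL

#' Options controlling the data-driven flux fit
#'
#' @param rho_tol convergence tolerance: iteration stops once both the
#'   change in the flux-expression correlation and the deviation of the
#'   data rescaling factor from 1 fall below this value.
#' @param max_iter maximum number of rescale-and-refit cycles.
#' @param steady_tol maximum tolerated steady-state residual
#'   \code{max |S v|} (umol/100g/min).
#' @param lp_tol tolerance for bound compliance checks.
#' @param active_tol flux magnitude below which a reaction counts as
#'   inactive (umol/100g/min).
#' @param tiebreak selection among optimal flux distributions:
#'   \code{"throughput"} minimizes total throughput (parsimonious flux),
#'   \code{"least_squares"} minimizes the squared deviation from the
#'   scaled data.
#' @param correlation \code{"spearman"} (rank agreement, scale-free;
#'   default) or \code{"pearson"}. Before ranking, throughputs are
#'   snapped to the \code{active_tol} grid so solver-precision jitter
#'   cannot break genuine ties.
#' @param scale_data rescale the expression-derived data onto the flux
#'   scale (once initially, then iteratively by weighted regression
#'   through the origin). Disable to fit the data values verbatim in a
#'   single pass.
#' @param tiebreak_mu weight of the tie-break term relative to the
#'   (unit-scaled) data-fit objective. The lexicographic selection is
#'   realized as a small-penalty composite: because the fit term has
#'   unit-scale slopes, a penalty this small only discriminates along
#'   degenerate optimal faces (and removes futile two-way flux through
#'   reversible reactions).
#' @param ridge magnitude of the strictly-convex stabilizer added to the
#'   (unit-scaled) linear objective; makes the optimum unique (the
#'   minimum-norm point of any remaining degenerate face).
#' @return a list of class \code{FitOptions}.
#' @export
fitOptions <- function(rho_tol = 1e-4, max_iter = 25L, steady_tol = 1e-6,
                       lp_tol = 1e-9, active_tol = 1e-6,
                       tiebreak = c("throughput", "least_squares"),
                       correlation = c("spearman", "pearson"),
                       scale_data = TRUE, tiebreak_mu = 1e-4, ridge = 1e-6) {
  tiebreak <- match.arg(tiebreak)
  correlation <- match.arg(correlation)
  stopifnot(rho_tol > 0, max_iter >= 1, steady_tol > 0, lp_tol > 0,
            active_tol > 0, ridge > 0, tiebreak_mu > 0)
  structure(list(rho_tol = rho_tol, max_iter = as.integer(max_iter),
                 steady_tol = steady_tol, lp_tol = lp_tol,
                 active_tol = active_tol, tiebreak = tiebreak,
                 correlation = correlation, scale_data = scale_data,
                 tiebreak_mu = tiebreak_mu, ridge = ridge),
            class = "FitOptions")
}

#' Clamp reaction bounds to measured exchange fluxes
#'
#' Returns a copy of the model in which the listed reactions' bounds are
#' replaced by the measured values (point clamps \code{[v, v]} or
#' intervals such as \code{[mean - SD, mean + SD]}); all other bounds are
#' untouched. Reversibility flags are re-normalized from the new bounds.
#'
#' @param model a \code{MetabolicModel}.
#' @param constraints data.frame with columns \code{reaction_id},
#'   \code{lower}, \code{upper}, or a named list
#'   \code{list(R_in = c(10, 10), ...)} (umol/100g/min).
#' @return the constrained \code{MetabolicModel}.
#' @export
applyFluxConstraints <- function(model, constraints) {
  cons <- normalizeConstraints(constraints)
  if (!nrow(cons)) return(model)
  unknown <- setdiff(cons$reaction_id, model@reactions$id)
  if (length(unknown)) {
    stop("constraints reference unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  bad <- cons$lower > cons$upper
  if (any(bad)) {
    stop("constraint lower > upper for: ",
         paste(cons$reaction_id[bad], collapse = ", "))
  }
  rxn <- model@reactions
  i <- match(cons$reaction_id, rxn$id)
  rxn$lower_bound[i] <- cons$lower
  rxn$upper_bound[i] <- cons$upper
  rxn$reversible <- rxn$lower_bound < 0
  methods::initialize(model, reactions = rxn)
}

normalizeConstraints <- function(constraints) {
  if (is.data.frame(constraints)) {
    if (!nrow(constraints)) {
      return(data.frame(reaction_id = character(), lower = numeric(),
                        upper = numeric(), stringsAsFactors = FALSE))
    }
    stopifnot(all(c("reaction_id", "lower", "upper") %in% names(constraints)))
    return(constraints[c("reaction_id", "lower", "upper")])
  }
  if (is.list(constraints)) {
    if (!length(constraints)) {
      return(data.frame(reaction_id = character(), lower = numeric(),
                        upper = numeric(), stringsAsFactors = FALSE))
    }
    return(data.frame(
      reaction_id = names(constraints),
      lower = vapply(constraints, function(x) as.numeric(x[[1L]]), numeric(1)),
      upper = vapply(constraints, function(x) as.numeric(x[[2L]]), numeric(1)),
      stringsAsFactors = FALSE))
  }
  stop("constraints must be a data.frame or a named list")
}

## Variable layout of the fit program:
##   x = [ f_1..f_n | b_(reversible reactions) | r_(data reactions) ]
## v_j = f_j - b_j (b_j = 0 for irreversible), throughput t_j = f_j + b_j.
buildFitLayout <- function(model) {
  rxn <- model@reactions
  n <- nrow(rxn)
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  revIdx <- which(lb < 0)
  fidx <- seq_len(n)
  bidx <- rep(NA_integer_, n)
  bidx[revIdx] <- n + seq_along(revIdx)
  flo <- pmax(0, lb); fhi <- pmax(0, ub)
  blo <- pmax(0, -ub)[revIdx]; bhi <- (-lb)[revIdx]
  list(n = n, fidx = fidx, bidx = bidx, revIdx = revIdx,
       lower = c(flo, blo), upper = c(fhi, bhi), nvb = n + length(revIdx))
}

#' Fit steady-state fluxes to expression-derived reaction data
#'
#' Computes the flux distribution whose throughput pattern best agrees
#' with the expression-derived data values, replacing an a priori
#' objective function with a data-driven one. The procedure:
#' \enumerate{
#'   \item split every reversible reaction into non-negative forward and
#'     backward components; the throughput \code{t = f + b} is the
#'     quantity compared against the data;
#'   \item scale the data once onto the flux scale (median of feasible
#'     throughput-range midpoints over median data value);
#'   \item solve the weighted least-absolute-deviation program: minimize
#'     \code{sum w |t - d|} over data-carrying reactions subject to
#'     \code{S v = 0} (internal metabolites) and the flux bounds;
#'   \item compute the rank correlation between throughput and data, then
#'     rescale the data by the weighted regression of throughput on data
#'     through the origin, and refit, until both the correlation change
#'     and the rescaling factor stabilize (or \code{max_iter});
#'   \item select among optimal flux distributions by the tie-break
#'     criterion (minimum total throughput by default), realized as a
#'     small composite penalty on every solve (see
#'     \code{\link{fitOptions}}), which also suppresses futile
#'     forward-plus-backward flux through reversible reactions.
#' }
#'
#' The rescale map can have several fixed points: above the feasible flow
#' scale, reversible reactions can chase inflated targets with futile
#' two-way flux. The iteration is therefore restarted from a short ladder
#' of initial scales and the run with the best final correlation (ties:
#' smallest relative misfit) is kept.
#'
#' @param model a \code{MetabolicModel} (constraints already applied).
#' @param data a \code{ReactionData} from \code{\link{mapToReactions}}.
#' @param opts a \code{\link{fitOptions}} list.
#' @param label condition/constraint-set label stored on the solution.
#' @return a \code{\link{FluxSolution-class}} object.
#' @export
fitFluxes <- function(model, data, opts = fitOptions(), label = "") {
  stopifnot(is(data, "ReactionData"))
  rd <- data@data
  rxn <- model@reactions
  if (!identical(rd$reaction_id, rxn$id)) {
    i <- match(rxn$id, rd$reaction_id)
    if (anyNA(i)) stop("ReactionData does not cover the model's reactions")
    rd <- rd[i, ]
  }
  dataIdx <- which(rd$has_data)
  if (!length(dataIdx)) stop("no data-carrying reactions: nothing to fit")

  bad <- rxn$lower_bound > rxn$upper_bound
  if (any(bad)) {
    stop("infeasible bounds (lower > upper) for: ",
         paste(rxn$id[bad], collapse = ", "))
  }

  lay <- buildFitLayout(model)
  nD <- length(dataIdx)
  nvar <- lay$nvb + nD
  ridx <- lay$nvb + seq_len(nD)

  Sint <- as.matrix(stoichiometricMatrix(model, internalOnly = TRUE))
  Aeq <- matrix(0, nrow(Sint), nvar)
  if (nrow(Sint)) {
    Aeq[, lay$fidx] <- Sint
    if (length(lay$revIdx)) Aeq[, lay$bidx[lay$revIdx]] <- -Sint[, lay$revIdx, drop = FALSE]
  }
  beq <- rep(0, nrow(Sint))

  lower <- c(lay$lower, rep(0, nD))
  upper <- c(lay$upper, rep(Inf, nD))

  ## throughput row per data reaction
  Tmat <- matrix(0, nD, nvar)
  for (k in seq_len(nD)) {
    j <- dataIdx[k]
    Tmat[k, lay$fidx[j]] <- 1
    if (!is.na(lay$bidx[j])) Tmat[k, lay$bidx[j]] <- 1
  }

  wRaw <- rd$w[dataIdx]
  ## cap the weight dynamic range: reciprocal-dispersion weights from a
  ## floored SD are effectively infinite-precision claims; a 1e4 spread
  ## keeps low-dispersion reactions dominant while the program stays
  ## numerically solvable
  wCap <- pmin(wRaw, 1e4 * stats::median(wRaw))
  wInt <- wCap / mean(wCap)
  d0 <- rd$d[dataIdx]

  ## initial data scaling onto the flux scale; computed over reactions
  ## with positive data so that silenced genes (d = 0) cannot drive the
  ## scale
  s <- 1
  if (isTRUE(opts$scale_data)) {
    lb <- rxn$lower_bound[dataIdx]; ub <- rxn$upper_bound[dataIdx]
    tlo <- ifelse(lb >= 0, lb, 0)
    thi <- ifelse(lb >= 0, ub, pmax(ub, -lb))
    mid <- (tlo + thi) / 2
    pos <- d0 > max(d0, 0) * 1e-9 & d0 > 0
    if (any(pos)) {
      medd <- stats::median(d0[pos])
      if (is.finite(medd) && medd > 0) s <- stats::median(mid[pos]) / medd
    }
    if (!is.finite(s) || s <= 0) s <- 1
  }
  dhat <- d0 * s

  ## inequality rows for residuals: r >= t - dhat and r >= dhat - t
  Rsel <- matrix(0, nD, nvar)
  Rsel[cbind(seq_len(nD), ridx)] <- 1
  AineqBase <- rbind(Rsel - Tmat, Rsel + Tmat)

  cvec1 <- rep(0, nvar)
  cvec1[ridx] <- wInt

  ## one composite solve: weighted L1 data fit + small tie-break penalty
  ## (minimum total throughput, or least-squares deviation) + ridge
  mu <- opts$tiebreak_mu
  penLin <- rep(0, nvar)
  penLin[seq_len(lay$nvb)] <- mu
  penQuad <- NULL
  if (opts$tiebreak == "least_squares") {
    penQuad <- 2 * mu * crossprod(Tmat * sqrt(wInt))
  }
  solveFit <- function(dhat) {
    bineq <- c(-dhat, dhat)
    cv <- cvec1
    if (opts$tiebreak == "throughput") {
      cv <- cv + penLin
    } else {
      cv <- cv - as.numeric(2 * mu * t(Tmat) %*% (wInt * dhat))
    }
    tryCatch(
      solveRidgeQP(cv, Aeq, beq, lower, upper, AineqBase, bineq,
                   quad = penQuad, ridge = opts$ridge),
      error = function(e) stop(infeasibilityMessage(model, conditionMessage(e)),
                               call. = FALSE))
  }

  rhoOf <- function(tD) {
    if (nD < 3L) return(NA_real_)
    tSnap <- round(tD / opts$active_tol) * opts$active_tol
    suppressWarnings(stats::cor(tSnap, d0, method = opts$correlation))
  }

  ## rescale-and-refit to a fixed point of the scaling factor; the factor
  ## contracts geometrically, so it is stabilized far below rho_tol to
  ## land on the fixed point rather than short of it
  facTol <- min(opts$rho_tol, 1e-9)
  runFrom <- function(dhat) {
    rhoTraj <- numeric(0)
    converged <- FALSE
    iter <- 0L
    x <- NULL
    for (k in seq_len(opts$max_iter)) {
      iter <- k
      x <- solveFit(dhat)
      tD <- as.numeric(Tmat %*% x)
      rho <- rhoOf(tD)
      rhoTraj <- c(rhoTraj, rho)
      den <- sum(wInt * dhat^2)
      fac <- if (den > 0) sum(wInt * tD * dhat) / den else 1
      if (!is.finite(fac) || fac <= 0) fac <- 1
      if (k > 1L) {
        dr <- abs(rho - rhoTraj[k - 1L])
        rhoStable <- if (is.na(dr)) TRUE else dr < opts$rho_tol
        if (rhoStable && abs(fac - 1) < facTol) {
          converged <- TRUE
          break
        }
      }
      if (k < opts$max_iter) dhat <- dhat * fac
    }
    tD <- as.numeric(Tmat %*% x)
    objRel <- sum(wInt * abs(tD - dhat)) / max(sum(wInt * dhat), 1e-12)
    list(x = x, dhat = dhat, rhoTraj = rhoTraj, iter = iter,
         converged = converged, rho = rhoTraj[length(rhoTraj)],
         objRel = objRel)
  }

  ## the fixed-point map can be trapped above the feasible flow scale
  ## (reversible reactions can chase inflated targets with futile two-way
  ## flux); restart from smaller initial scales and keep the run with the
  ## best final correlation (ties: smallest relative misfit)
  starts <- if (isTRUE(opts$scale_data)) s * c(1, 0.1, 0.01) else s
  best <- NULL
  for (s0 in starts) {
    run <- runFrom(d0 * s0)
    if (is.null(best)) { best <- run; next }
    ## a later start must improve materially; effective ties keep the
    ## run from the canonical initial scale
    rNew <- if (is.na(run$rho)) -Inf else run$rho
    rBest <- if (is.na(best$rho)) -Inf else best$rho
    if (rNew > rBest + opts$rho_tol ||
        (rNew >= rBest - opts$rho_tol && run$objRel < best$objRel - 1e-6)) {
      best <- run
    }
  }
  x <- best$x
  dhat <- best$dhat
  rhoTraj <- best$rhoTraj
  iter <- best$iter
  converged <- best$converged

  f <- x[lay$fidx]
  b <- rep(0, lay$n); b[lay$revIdx] <- x[lay$bidx[lay$revIdx]]
  v <- f - b
  t <- f + b
  tD <- t[dataIdx]

  futile <- pmin(f, b) > opts$active_tol
  if (any(futile)) {
    warning("residual two-way flux above active_tol in: ",
            paste(rxn$id[futile], collapse = ", "))
  }

  resid <- max(0, if (nrow(Sint)) max(abs(Sint %*% v)) else 0)
  if (resid > opts$steady_tol) {
    stop("steady-state residual ", format(resid), " exceeds steady_tol")
  }
  tol <- max(opts$lp_tol, 1e-9)
  if (any(v < rxn$lower_bound - tol) || any(v > rxn$upper_bound + tol)) {
    stop("flux bound violation beyond lp_tol")
  }

  objective <- sum(wRaw * abs(tD - dhat))
  dcol <- rep(NA_real_, lay$n); dcol[dataIdx] <- dhat
  tab <- data.frame(
    reaction_id = rxn$id, flux = v, throughput = t,
    lower_bound = rxn$lower_bound, upper_bound = rxn$upper_bound,
    data_value = dcol, in_objective = rd$has_data,
    stringsAsFactors = FALSE)

  new("FluxSolution", table = tab, objective = objective,
      rho = rhoTraj[length(rhoTraj)], rhoTrajectory = rhoTraj,
      iterations = iter, converged = converged, label = label)
}

infeasibilityMessage <- function(model, why) {
  rxn <- model@reactions
  bad <- which(rxn$lower_bound > rxn$upper_bound)
  detail <- if (length(bad)) {
    paste0("; conflicting bounds (lower > upper) on: ",
           paste(rxn$id[bad], collapse = ", "))
  } else ""
  paste0("infeasible constraint system (no flux satisfies S v = 0 under ",
         "the bounds)", detail, " [solver: ", why, "]")
}

#' Rank correlation between fitted throughput and expression data
#'
#' @param solution a \code{FluxSolution}.
#' @param data a \code{ReactionData} on the same model.
#' @param method \code{"spearman"} (average ranks on ties) or
#'   \code{"pearson"}.
#' @param activeTol throughputs are snapped to this grid before ranking
#'   so solver-precision jitter cannot break genuine ties.
#' @return correlation coefficient (dimensionless, in [-1, 1]).
#' @export
fluxCorrelation <- function(solution, data, method = c("spearman", "pearson"),
                            activeTol = 1e-6) {
  method <- match.arg(method)
  rd <- data@data
  tab <- solution@table
  i <- match(tab$reaction_id, rd$reaction_id)
  if (anyNA(i)) stop("solution and data cover different reactions")
  rd <- rd[i, ]
  sel <- rd$has_data
  if (sum(sel) < 3L) {
    stop("correlation undefined: fewer than 3 data-carrying reactions")
  }
  t <- round(tab$throughput[sel] / activeTol) * activeTol
  stats::cor(t, rd$d[sel], method = method)
}

#' Classify per-reaction flux changes between two conditions
#'
#' Flags reversible reactions running in opposite directions in the two
#' conditions (both active, opposite signs) and classifies each reaction
#' by the log2 ratio of absolute flux in condition B over condition A:
#' \code{lower_in_B} when \code{log2(|vB|/|vA|) <= -log2(fcThreshold)},
#' \code{higher_in_B} when \code{>= +log2(fcThreshold)}, otherwise
#' \code{unchanged}; reactions inactive in either condition are
#' \code{inactive}.
#'
#' @param solA,solB \code{FluxSolution}s on the same model.
#' @param fcThreshold fold-change threshold (dimensionless, default 2).
#' @param activeTol activity threshold on |flux| (umol/100g/min).
#' @return a \code{\link{FluxComparison-class}} object.
#' @export
classifyFluxChanges <- function(solA, solB, fcThreshold = 2, activeTol = 1e-6) {
  ta <- solA@table; tb <- solB@table
  if (!identical(ta$reaction_id, tb$reaction_id)) {
    stop("the two solutions cover different reaction sets")
  }
  va <- ta$flux; vb <- tb$flux
  activeA <- abs(va) > activeTol
  activeB <- abs(vb) > activeTol
  both <- activeA & activeB
  opposite <- both & (sign(va) * sign(vb) < 0)
  l2 <- rep(NA_real_, length(va))
  l2[both] <- log2(abs(vb[both]) / abs(va[both]))
  thr <- log2(fcThreshold)
  category <- rep("inactive", length(va))
  category[both] <- "unchanged"
  category[both & l2 <= -thr] <- "lower_in_B"
  category[both & l2 >= thr] <- "higher_in_B"
  counts <- table(factor(category,
    levels = c("lower_in_B", "higher_in_B", "unchanged", "inactive")))
  tab <- data.frame(
    reaction_id = ta$reaction_id, flux_A = va, flux_B = vb,
    opposite_direction = opposite, log2_ratio = l2, category = category,
    stringsAsFactors = FALSE)
  new("FluxComparison", table = tab,
      counts = stats::setNames(as.integer(counts), names(counts)),
      labelA = solA@label, labelB = solB@label)
}
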