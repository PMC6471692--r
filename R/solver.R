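#' @include AllClasses.R
NULL

## Internal convex-program backend for the flux fit.
##
## Solves  min  cvec'x + 0.5 x' (quad + ridge I) x
##         s.t. Aeq x = beq,  Aineq x >= bineq,  lower <= x <= upper
##
## The ridge term makes the program strictly convex, so the optimum is
## unique and deterministic; on a degenerate optimal face of the
## underlying linear objective it selects the minimum-norm point.
## Before calling the solver the problem is normalized to unit scale
## (variables divided by the characteristic bound/rhs magnitude, the
## objective by its largest coefficient): the Goldfarb-Idnani method is
## otherwise unreliable when bounds and data span several orders of
## magnitude. Linearly dependent equality rows (conserved-moiety rows of
## a stoichiometric matrix) are removed by QR.
solveRidgeQP <- function(cvec, Aeq = NULL, beq = NULL,
                         lower, upper, Aineq = NULL, bineq = NULL,
                         quad = NULL, ridge = 1e-8) {
  nv <- length(cvec)
  stopifnot(length(lower) == nv, length(upper) == nv)
  big <- 1e9
  lower <- pmax(lower, -big)
  upper <- pmin(upper, big)

  ## unit-scale normalization: x = sigma * y
  finite <- c(abs(lower[lower > -big + 1]), abs(upper[upper < big - 1]),
              if (!is.null(beq)) abs(beq), if (!is.null(bineq)) abs(bineq))
  sigma <- max(1, finite)
  lower <- lower / sigma
  upper <- pmin(upper / sigma, big)
  if (!is.null(beq)) beq <- beq / sigma
  if (!is.null(bineq)) bineq <- bineq / sigma
  cvec <- cvec * sigma
  if (!is.null(quad)) quad <- quad * sigma^2
  objScale <- max(1, abs(cvec), if (!is.null(quad)) abs(quad))
  cvec <- cvec / objScale
  if (!is.null(quad)) quad <- quad / objScale

  dvec <- -cvec

  cols <- list(); rhs <- numeric(); meq <- 0L
  if (!is.null(Aeq) && nrow(Aeq)) {
    Aeq <- as.matrix(Aeq)
    qrA <- qr(t(Aeq))
    keep <- sort(qrA$pivot[seq_len(qrA$rank)])
    Aeq <- Aeq[keep, , drop = FALSE]
    beq <- beq[keep]
    cols[[length(cols) + 1L]] <- t(Aeq)
    rhs <- c(rhs, beq)
    meq <- nrow(Aeq)
  }
  ## box constraints (skip rows that are vacuous at |big|)
  finL <- which(lower > -big + 1)
  if (length(finL)) {
    M <- matrix(0, nv, length(finL))
    M[cbind(finL, seq_along(finL))] <- 1
    cols[[length(cols) + 1L]] <- M
    rhs <- c(rhs, lower[finL])
  }
  finU <- which(upper < big - 1)
  if (length(finU)) {
    M <- matrix(0, nv, length(finU))
    M[cbind(finU, seq_along(finU))] <- -1
    cols[[length(cols) + 1L]] <- M
    rhs <- c(rhs, -upper[finU])
  }
  if (!is.null(Aineq) && nrow(Aineq)) {
    cols[[length(cols) + 1L]] <- t(as.matrix(Aineq))
    rhs <- c(rhs, bineq)
  }
  Amat <- do.call(cbind, cols)

  ## deterministic retry ladder: the Goldfarb-Idnani method can fail on
  ## valid problems when the ridge is very small relative to the linear
  ## term; raising it trades a little tie-break sharpness for a solve
  res <- NULL
  for (mult in c(1, 10, 100, 1e3, 1e4)) {
    Dmat <- diag(ridge * mult, nv)
    if (!is.null(quad)) Dmat <- Dmat + quad
    res <- tryCatch(quadprog::solve.QP(Dmat, dvec, Amat, rhs, meq = meq),
                    error = function(e) e)
    if (!inherits(res, "error")) break
  }
  if (inherits(res, "error")) {
    stop("optimization failed: ", conditionMessage(res), call. = FALSE)
  }
  res$solution * sigma
}
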