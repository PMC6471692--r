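## Independent oracles and small builders used across the suite.

## Two-exit funnel: uptake clamped to `inflow`, two sinks Ra/Rb draining
## the single internal metabolite, one private gene each.
funnelModel <- function(inflow = 10, ub = 1000) {
  makeMetabolicModel(
    data.frame(id = "A"),
    data.frame(id = c("R_in", "Ra", "Rb"),
               lower_bound = c(inflow, 0, 0),
               upper_bound = c(inflow, ub, ub)),
    list(c(A = 1), c(A = -1), c(A = -1)),
    list(NULL, "Ga", "Gb"))
}

funnelProfile <- function(da, db, sda = 1, sdb = 1) {
  new("ExpressionProfile", condition = "test",
      data = data.frame(gene = c("Ga", "Gb"), mean = c(da, db),
                        sd = c(sda, sdb), stringsAsFactors = FALSE))
}

## Brute-force oracle for the funnel fit: one free dimension
## (va in [0, inflow], vb = inflow - va); dense grid + local refinement.
funnelGridOracle <- function(d, w = c(1, 1), inflow = 10, step = 0.01) {
  obj <- function(va) w[1] * abs(va - d[1]) + w[2] * abs((inflow - va) - d[2])
  grid <- seq(0, inflow, by = step)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  fine <- seq(max(0, grid[i] - step), min(inflow, grid[i] + step), by = step / 100)
  fvals <- vapply(fine, obj, numeric(1))
  j <- which.min(fvals)
  list(objective = fvals[j], va = fine[j])
}

## Floyd-Warshall all-pairs shortest paths (independent of igraph).
floydWarshall <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges$from[k], edges$to[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

## Random directed ConditionGraph on `n` reaction nodes, edge prob `p`.
randomConditionGraph <- function(n, p, seed, label = "rand") {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- runif(nrow(pairs)) < p
  ed <- pairs[keep, , drop = FALSE]
  ed$shared <- rep("m", nrow(ed))
  rownames(ed) <- NULL
  new("ConditionGraph", nodeKind = "reaction",
      nodeTable = data.frame(node = nodes, flux = 1, stringsAsFactors = FALSE),
      edges = ed, condition = label, provenance = list())
}

## Spearman on throughputs snapped to the activity-tolerance grid
## (the package's tie convention).
snappedSpearman <- function(t, d, tol = 1e-6) {
  stats::cor(round(t / tol) * tol, d, method = "spearman")
}

expectNoMatchWarning <- function(expr) suppressWarnings(expr)
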