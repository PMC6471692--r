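# fluxrewire

Condition-specific metabolic network analysis from group-level gene
expression: an objective-free, data-driven flux fit on a genome-scale
metabolic model (GEM), condition-specific directed graphs built from
the fitted fluxes, and differential network topology between two
conditions (e.g. lean vs obese patient groups).

## The problem and the method

Flux balance analysis predicts a steady-state flux vector `v`
(`N v = 0`, `lb ≤ v ≤ ub`, where `N[i, j]` is the stoichiometric
coefficient of metabolite `i` in reaction `j`) by maximizing an assumed
cellular objective. For differentiated human cells there is no
defensible single objective. `fluxrewire` replaces it with the data:
per-gene expression means and SDs of a patient group are mapped onto
reactions through gene-protein-reaction (GPR) rules (AND = min over
complex subunits, OR = sum over isoenzymes), and the package solves the
weighted least-absolute-deviation program

```
min Σ_j  w_j | t_j − d̂_j |    s.t.  N_int v = 0,  lb ≤ v ≤ ub
```

where `t_j` is the reaction's throughput (forward + backward flux after
reversible splitting), `d̂_j` the expression-derived data value scaled
onto the flux scale, and `w_j = 1/max(sd_j, 1e-6)` the reciprocal
dispersion. The data scale is refined by repeated cycles of refitting
and rescaling until the flux–expression rank correlation stabilizes.
Clinically measured exchange rates (glucose uptake, triacylglycerol
extraction, in µmol·100g⁻¹·min⁻¹) clamp the corresponding reaction
bounds.

Each fitted solution becomes a directed graph: active reactions
(|v| > tolerance) are oriented by their flux sign, and an edge runs
from the reaction producing a shared non-currency metabolite to the
reaction consuming it (currency cofactors — ATP, H2O, NADH, … — are
excluded so paths trace backbone chemistry). A gene-level graph
replaces reactions by their regulating genes. Two conditions are then
compared on the union ("reference") network: node/edge membership
(common vs condition-specific), per-node rewiring scores (`dn_raw` =
0.25 × the symmetric difference of incident edge sets, with a
degree-corrected variant), shortest-path length distributions, and
per-reaction flux fold-change classification.

Seeded generators (`fixtureModel()`, `makeToyGEM()`,
`makeExpressionFromFlux()`, `makeConditionPair()`) produce toy GEMs
with exactly balanced planted fluxes, expression profiles that encode
them, and two-condition pairs with planted knockouts, so the whole
pipeline is testable without any downloads.

## Worked example

```r
library(fluxrewire)

model <- fixtureModel()      # 7-reaction toy GEM with GPRs and an ATP cycle
truth <- fixtureTruth()      # balanced ground-truth fluxes

## expression profile that encodes the ground truth, with 5% noise
prof <- makeExpressionFromFlux(model, truth, noiseSdFrac = 0.05,
                               seed = 7, condition = "lean")

## clamp the measured uptake and fit
clamped <- applyFluxConstraints(model, list(R_in = c(10, 10)))
sol <- fitFluxes(clamped, mapToReactions(model, prof), label = "lean_tp4")
sol
#> FluxSolution 'lean_tp4': 7 reactions
#>   objective: 5.75467  rho: 0.9487  iterations: 16  converged: TRUE
round(fluxes(sol), 3)
#>   R_in     R1     R2     R3     R4     R5  R_atp
#> 10.000 10.000  5.632  4.368  5.632 10.000 10.000
```

`rho` is the Spearman correlation between fitted throughput and the
expression-derived data (0.95 here: 5% gene noise slightly reorders the
branch reactions); the fluxes recover the planted 6/4 branch split as
5.6/4.4 under that noise. Building and comparing graphs:

```r
g <- buildReactionGraph(model, sol, currency = c("ATP", "ADP"))
shortestPathDistribution(g)
#> PathLengthDistribution: 13 reachable ordered pairs, modal length 1
#> 1 2 3
#> 6 5 2

## plant a knockout of the B -> D branch in condition B and compare
pair <- makeConditionPair(model, truth, knockout = "R3",
                          currency = c("ATP", "ADP"))
ref <- mergeReference(
  buildReactionGraph(model, asFluxSolution(model, pair$flux_A, "lean"),
                     currency = c("ATP", "ADP")),
  buildReactionGraph(model, asFluxSolution(model, pair$flux_B, "obese"),
                     currency = c("ATP", "ADP")))
ref
#> ReferenceNetwork (reaction nodes): lean vs obese
#>   nodes: both=6 A_only=1 B_only=0; edges: 6
topRewired(rewiringScores(ref), 3)
#>   node dn_raw dn_degree_corrected union_degree
#> 1   R1   0.25          0.08333333            3
#> 2   R5   0.25          0.12500000            2
#> 3   R2   0.00          0.00000000            2
```

The knocked-out reaction `R3` is the single lean-specific node, and its
two former neighbours `R1` and `R5` are the top rewired nodes — exactly
the planted difference. `runPipeline()` drives the same steps for a
conditions × time-points design from one configuration list (or YAML
file) and writes flux tables, edge lists, GraphML, comparison reports
and a hashed manifest.

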