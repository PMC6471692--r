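---
title: "Expression-driven flux fitting and differential network topology with fluxrewire"
author: "fluxrewire maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-driven flux fitting and differential network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxrewire)
```

# The problem

A genome-scale metabolic model (GEM) describes a cell's metabolism as a
stoichiometric matrix $N$ whose entry $N_{ij}$ is the signed coefficient
of metabolite $i$ in reaction $j$, together with flux bounds,
reversibility, and gene-protein-reaction (GPR) rules linking reactions
to the genes encoding their enzymes. Classical flux balance analysis
(FBA) predicts a steady-state flux vector $v$ ($N v = 0$,
$lb \le v \le ub$) by maximizing a stated cellular objective such as
biomass. For differentiated human cells (here: the adipocyte) no single
objective is defensible. `fluxrewire` instead fits the fluxes to
condition-specific transcriptomics: per-gene means and standard
deviations summarized over all samples of a patient group are mapped
onto reactions through the GPR rules, and the flux pattern that best
agrees with those data — under mass balance, bounds, and clinically
measured exchange-rate clamps — is taken as the condition's metabolic
state. The fitted fluxes are then turned into condition-specific
directed graphs (reaction-level and gene-level), and two conditions are
compared by network topology: node/edge membership in the union
("reference") network, per-node rewiring scores, shortest-path length
distributions, and per-reaction flux fold changes.

# The data-driven flux fit

## GPR evaluation

Every reaction's GPR rule is evaluated on the gene means:

* **AND** (enzyme complex) takes the **minimum** of its children — a
  complex is limited by its scarcest subunit. The propagated SD is the
  SD of the child attaining the minimum.
* **OR** (isoenzymes) **sums** its children by default — independent
  enzyme pools add capacity. The SD propagates as the root sum of
  squares. `min_max` (competing readings: only the strongest isoform
  matters) and `min_mean` are available through `gpr_policy` because the
  aggregation convention is genuinely open; the default is the common
  choice in transcriptome-constrained GEM work.

Genes absent from a profile drop out of OR terms; an AND with any
absent child marks the reaction as carrying no data. Reactions without
GPR (exchanges, spontaneous reactions) never enter the fit objective.
The fit weight of a reaction is the reciprocal dispersion
$w_j = 1/\max(sd_j, 10^{-6})$: reactions measured consistently across
patients constrain the fit more.

## The optimization

Reversible reactions are split into non-negative forward and backward
components; the **throughput** $t_j = v_j^+ + v_j^-$ is the quantity
compared against the data (catalytic usage is unsigned). With scaled
data $\hat d$, the core program is the weighted least-absolute-deviation
fit

$$\min_v \sum_{j \in \mathcal{D}} w_j\,|t_j - \hat d_j|
\quad \text{s.t.} \quad N_{\mathrm{int}} v = 0,\; lb \le v \le ub,$$

which is linear, deterministic, and uses the SDs exactly where the data
provide them. Expression and flux live on different scales, so the data
are first scaled onto the flux scale (median feasible-throughput
midpoint over median positive data value) and then iteratively
rescaled by the weighted regression of fitted throughput on data
through the origin; after each solve the Spearman rank correlation
$\rho$ between throughput and data is recorded. The iteration stops
when $\rho$ stops changing (tolerance `rho_tol`, default $10^{-4}$)
*and* the rescale factor has stabilized at 1 (the factor contracts
geometrically, so it is stabilized to $10^{-9}$; stopping on $\rho$
alone halts short of the fixed point because a scalar rescale rarely
changes ranks). Spearman is the default reading of "correlation"
because rank agreement is scale-free; Pearson is available.

Two realizations of this procedure deserve explanation:

* **Tie-breaking.** The L1 optimum can be a face, not a point. The
  lexicographic selection (among optimal fits, the most parsimonious
  flux) is realized as a small composite penalty, `tiebreak_mu`
  ($10^{-4}$) times total throughput (or, with
  `tiebreak = "least_squares"`, times the squared deviation), added to
  every solve. Because the unit-normalized fit term has slopes of order
  1, a penalty of $10^{-4}$ only discriminates *along* degenerate
  optimal faces; it also removes futile forward-plus-backward flux
  through reversible reactions at every iterate. An explicit two-stage
  solve (re-optimizing subject to the stage-one optimum as a
  constraint) creates a numerically razor-thin feasible region and is
  deliberately avoided.
* **Multiple fixed points of the rescaling.** If the data scale lands
  above the feasible flow (bounds hold total flow down), reversible
  reactions can chase the inflated targets with futile two-way flux,
  trapping the rescale factor at a spurious fixed point. The iteration
  is therefore restarted from initial scales $s \times (1, 0.1, 0.01)$
  and the run with the best final correlation is kept (ties go to the
  canonical scale). Correlation is the procedure's stated objective, so
  it is also the selection criterion among fixed points.

## Numerical realization

The linear program is solved as a ridge-stabilized quadratic program
(`quadprog`): the fit objective plus $\tfrac{1}{2}\,\rho_r\|x\|^2$ with
`ridge` $= 10^{-6}$ on the unit-normalized problem. The ridge makes the
optimum unique and deterministic — on a degenerate optimal face it
selects the minimum-norm point, which is exactly the reproducible
behaviour wanted from the tie-break — while being far too small to move
the solution off an L1 kink. Three further numerical choices matter:

* problems are normalized to unit scale (variables by the largest
  bound/target magnitude, the objective by its largest coefficient)
  before the solve; the Goldfarb-Idnani method is unreliable when
  bounds and data span several orders of magnitude;
* if the solver still fails, the ridge is raised deterministically
  ($\times 10 \dots \times 10^4$) until it succeeds — a documented
  trade of tie-break sharpness for a solution;
* raw weights are capped at $10^4 \times$ their median: the SD floor
  makes zero-dispersion genes claim effectively infinite precision, and
  a $10^6$ weight spread breaks the solver without changing which
  reactions dominate.

Fitted solutions are checked against `steady_tol` ($10^{-6}$, maximum
$|N_{\mathrm{int}} v|$) and `lp_tol` ($10^{-9}$, bound compliance);
violations are errors, not warnings. Throughputs are snapped to the
`active_tol` ($10^{-6}$) grid before rank correlation so that
solver-precision jitter cannot break genuine ties. All tolerances are
in the model's flux units (the shipped generators use
µmol·100g⁻¹·min⁻¹, following clinical adipose-tissue fluxomics).

Measured exchange rates (e.g. glucose uptake and triacylglycerol
extraction at a clinical time point) enter as bound clamps via
`applyFluxConstraints()` — either point values $[v, v]$ or intervals
such as $[\mu - \sigma, \mu + \sigma]$; both are supported because
either reading of "set to the experimentally measured values" is
defensible. Those values are user inputs, never defaults: they come
from a clinical study, not from this package.

# Condition-specific graphs

Given a fitted solution, reactions with $|v| \le$ `zero_tol`
($10^{-6}$) are removed and every remaining reaction is oriented by the
sign of its flux (a negative flux swaps reagents and products). In the
**reaction graph**, nodes are the active reactions and an edge $a \to b$
exists when some internal, non-currency metabolite is a product of $a$
and a reagent of $b$ under that orientation; parallel edges are merged
and annotated with all shared metabolites; isolated active reactions
are retained as nodes (node-presence comparisons would otherwise be
distorted). In the **gene graph**, genes replace the reactions they
regulate: for every reaction edge $a \to b$, edges $g \to h$ are added
for all $g$ regulating $a$ and $h$ regulating $b$ ($g \ne h$); all
genes of a GPR count as regulators regardless of AND/OR structure, and
reactions without GPR bridge nothing.

Currency (recurring) metabolites — ubiquitous cofactors such as ATP or
H2O — are excluded so that edges trace backbone chemistry rather than
cofactor turnover. The exact published list is not recoverable, so the
default (`defaultCurrencyMetabolites()`: H2O, CO2, O2, ATP, ADP, AMP,
Pi, PPi, NADH, NAD+, NADPH, NADP+, FADH2, FAD, H+, CoA) is declared,
versioned configuration, matched case-insensitively and
compartment-suffix aware (`ATP` matches `M_atp_c`); unknown entries
warn and are ignored. Removing an entry from the list can only add
edges, a property the test suite asserts.

# Differential topology

`mergeReference()` builds the union reference network with per-node and
per-edge membership (`both` / `A_only` / `B_only`). The rewiring score
of a node present in both conditions pools its incident union edges
(in- and out-); each edge contributes the two-state population variance
of its presence indicator — $0.25$ if present in exactly one condition,
$0$ otherwise — so `dn_raw` $= 0.25 \times$ the symmetric difference of
incident edge sets, with a degree-corrected variant dividing by union
degree. This is a reimplementation of the published description of the
DyNet rewiring metric ("changes in the identity of interacting
neighbours"); agreement with that tool's implementation is not claimed,
and the formula above is this package's contract. One-condition nodes
are membership signals, not rewiring signals, and receive no score.
Ranking is by `dn_raw` descending with lexicographic ties, making
`topRewired()` deterministic.

Shortest-path distributions are computed on the directed graph with
unit edge weights over *ordered reachable pairs* (length $\ge 1$;
unreachable pairs are excluded rather than set to infinity) — whether
the original figures counted ordered pairs is unstated, so this is the
declared convention. The modal length takes the smallest length on
tied counts.

Flux fold-change classification compares two solutions per reaction:
reactions active in both conditions ($|v| >$ `active_tol`) with
opposite signs are flagged `opposite_direction`; otherwise the log2
ratio $\log_2 |v_B| / |v_A|$ sorts reactions into `lower_in_B`,
`higher_in_B` or `unchanged` at a configurable fold-change threshold
(default 2); reactions inactive in either condition are `inactive`.

# The synthetic-data generators

Real inputs at full scale (a 1,800-gene adipocyte GEM, microarray
cohorts, clinical fluxomics) are not redistributable at desk scale, so
the package ships generators that emulate all three inputs and define
the package's validation conditions:

* `fixtureModel()` — a hand-built 6-metabolite, 7-reaction network
  (uptake, a branch point, a reversible bridge, an AND complex, an OR
  isoenzyme pair, an ATP/ADP currency cycle) with a documented balanced
  ground truth, small enough that every downstream quantity is derived
  by hand in the tests.
* `makeToyGEM()` — seeded random GEMs: a backbone path from uptake to
  sink over `n_internal_metabolites` (default 8) internal metabolites,
  random forward branches up to `n_reactions` (default 14), a fraction
  (default 0.2) of reversible conversions, currency-cofactor coupling
  with regeneration, and one private gene set per reaction. The ground
  truth superposes random source-to-sink path flows (each U(1, 5)
  µmol·100g⁻¹·min⁻¹), so $N v = 0$ holds exactly by construction, and
  the uptake bound is clamped to the planted inflow, mirroring how
  measured exchange rates anchor the real analysis.
* `makeExpressionFromFlux()` — gene means chosen so the GPR map returns
  $|v_{\mathrm{true}}|$ (split equally across OR branches, copied
  across AND members), then perturbed with multiplicative gaussian
  noise (`noiseSdFrac` of the mean; microarray-like, a lognormal
  alternative was considered and rejected as indistinguishable at the
  noise levels used), the noise SD reported as the per-gene SD.
* `makeConditionPair()` — plants condition contrasts: reaction
  knockouts (expression of their genes set to zero, so the loss must
  propagate through the fit — this tests the pipeline end to end, not
  just the graph code) with the remaining flow re-balanced by a
  least-squares steady-state projection holding exchanges fixed, and/or
  a global scale factor for condition B (e.g. 0.4 for a uniformly
  slower metabolism).

Validation runs 20 seeded replicates at 5% (end-to-end recovery) and
10% (rank recovery) noise — sizes chosen so the full suite documents
the behaviour in seconds while every replicate still exercises a
distinct random topology. What passing these tests shows is that the
machinery is correct under the generator's assumptions: private genes
per reaction, multiplicative noise, exactly balanced ground truths, and
planted differences that remain feasible. What they do not show is
robustness to the pathologies of real data — cross-reaction gene
sharing at scale, probe-level noise structure, systematic annotation
error, or model curation gaps — which is why the acceptance quantities
are properties of the method, not reproductions of clinical numbers.

# Known limitations

* The LP relaxation does not impose $v^+ \cdot v^- = 0$; the throughput
  penalty removes futile two-way flux at optimum, and residual two-way
  flux above `active_tol` triggers a warning rather than an error.
* Reactions whose (capped) weight is far below the tie-break penalty
  are effectively governed by parsimony, not by their data — by design
  for very noisy genes.
* The rewiring score is the declared two-state formula; multi-state
  variance analysis and any claim of numerical agreement with external
  tools are out of scope.
* Gene identifiers are verbatim strings; probe-to-symbol conversion and
  expression normalization happen upstream.

# Session info

```{r}
sessionInfo()
```
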