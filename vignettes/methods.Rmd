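---
title: "Methods: the gene-bank allocation model and its implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gene-bank allocation model and its implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoplan)
```

## The planning problem

A network of gene banks stores frozen semen doses of livestock breeds as a
backup against the erosion of on-farm genetic diversity. Each bank `g` has a
fixed annual maintenance cost `F` (EUR/year), a per-dose storage cost `mc`
(EUR/dose/year, liquid nitrogen and handling), a cryotank capacity `cp`
(doses), and sits in a region whose farm zones are a round-trip distance `d`
(km) away; banks are `D[g,j]` km apart from each other. Collecting a breed
requires `r` donor animals, charged at a bank- and species-specific fee per
animal: `cf` when teams visit farm zones, `cc` when animals are brought to a
collection centre (which sits at the region's bank, so the within-region
travel distance is zero in that mode). Collection journeys move `k` doses per
trip at `tc` EUR/km.

The package treats allocation as a capacitated facility-location model.
Decision variables are the doses `SF[b,g,j]` and `SP[b,g,j]` that bank `g`
collects of breed `b` in region `j` (farm zones vs collection point), their
per-bank totals `SB[b,g]`, and a binary conservation indicator `y[b]`. Since
every bank is identified with its regional vicinity, bank ids double as
region ids. Availability flags `e[b,j]` restrict the *source region* `j` — a
breed can only be collected where it is native — while any bank may travel to
an available region and store the doses at home.

Two objectives are treated separately, never as a weighted compromise:

* **cost minimization** for a fixed recollection demand (every breed's
  current network-wide holdings must be recollected), and
* **diversity maximization** — the number of conserved breeds — under a
  budget, where each conserved breed's total must lie in `[mu, M]` for its
  species (semicontinuity). The dose-sum reading of diversity is available
  as `diversity_measure = "total_doses"`, but the breed count is the default
  because it is the quantity the diversity-cost curves are defined on.

The semicontinuous requirement is linearized with the standard indicator
pair `mu*y <= sum_g SB[b,g] <= M*y`. Under the recollection rule the
quantities are predetermined, so the pair is trivially satisfied and no dose
bounds are imposed on the demand — current holdings routinely exceed `M`
(a single cattle breed can hold several thousand doses against a collection
maximum of 585), and recollecting them in full is the only reading under
which centralizing the network in one bank roughly doubles its cost, as the
single-bank scenarios show. A `clamp_demand` option caps demand at `M` for
users who prefer the collection-limit reading.

## Cost identities and the campaign ambiguity

Costs decompose per bank as `C = MC + VC`, `VC = CC + TC`, with
`MC = T*(F + mc * stored doses)`, travel
`TC = (doses/k) * tc * (d_j + D[g,j])` for farm collection (the `d` of the
*source* region) and `(doses/k) * tc * D[g,j]` for centre pickup. Trips are
fractional — the travel model is linear and no integer rounding is applied.
Inter-bank distances are used as tabulated, not doubled; a schematic reading
in which both legs of a cross-region journey are counted can be emulated by
doubling `D` in the input.

The collection charge admits two readings. Read literally per dose,
`r * cf * doses` prices a single cattle dose at roughly 2,500 EUR — several
times the cost of maintaining an entire bank for a year once multiplied by a
breed's holdings, and irreconcilable with conservation budgets of a few tens
of thousands of EUR that are meant to cover dozens of breeds. The package
therefore defaults to **campaign costing**: the donor-animal charge `r * cf`
(or `r * cc`) is incurred once per (breed, bank, region, mode) campaign with
positive doses; on the bundled network this puts the minimal cost of
conserving one breed in the hundreds-to-thousands of EUR, the scale on which
the budget range is meaningful. The literal per-dose mode is retained behind
`costing_mode = "per_dose"` for fidelity comparisons. All monetary values are
stored in EUR — the bank table's fixed costs are converted from thousands on
ingestion — so no unit mixing can occur inside the cost identities.

Fixed costs `F` are charged for every bank in the network regardless of use:
the cost model contains no closure decision, and a network that reallocates
its collections still maintains its buildings. `fixed_cost_rule =
"active_only"` switches to charging only storing banks (relevant when
interpreting single-bank centralization as actually closing the others); the
optimizer then still minimizes variable cost and the rule is applied in
pricing. Budget constraints compare against **variable spend only**
(campaigns, travel, per-dose storage): the network's fixed costs
(1.267 M EUR/year) exceed the entire tabulated budget range (600–118,800
EUR), so a budget that included `F` could never be satisfied; this is the
only reading under which the diversity-cost curves are defined.

## The solver

No mixed-integer programming library is assumed. The package solves the
model exactly by exploiting its structure:

* **Uncapacitated cost minimization** decomposes per breed: with linear
  per-dose costs, moving a breed's fixed demand between banks can only help
  if the whole demand moves, and under campaign costing splitting adds
  charges; each breed therefore takes its cheapest (bank, region, mode)
  triple. Candidates are scanned in lexicographic (bank, region, mode)
  order, so exact ties resolve deterministically to the first bank id and
  farm before point — solver output is reproducible even when allocations
  are degenerate.
* **Capacitated cost minimization** is a fixed-charge transportation
  problem. A transportation LP whose arc costs amortize the campaign charge
  over the breed's full demand provides lower bounds — the amortized cost
  `(FC + U*dem)/dem * x` under-estimates the true `FC + U*x` for `x <= dem`
  and is tight at full demand. A branch-and-bound then fixes campaign
  activations: closing an arc removes it; opening one charges its smallest
  campaign fee as a constant and re-prices the arc accordingly (again tight
  at full demand). Every node's LP flow is repaired into a feasible
  assignment so good incumbents appear immediately; node bounds that remain
  open when the node budget (`node_limit`, default 400) is exhausted are
  reported as the achieved optimality gap, and `"optimal"` status is claimed
  only when the gap is within `mip_gap` (default 1e-6).
* The transportation LP itself is solved by successive shortest augmenting
  paths with the bipartite residual graph contracted onto the bank nodes
  (Bellman-Ford over at most 11 nodes per augmentation, since contracted
  edges can be negative). Warm starts from a parent node's flow make
  branch-and-bound children cheap. Per-dose costing has no fixed charges, so
  there the LP optimum is returned directly and splits are legitimate.
* **Diversity maximization** without capacities reduces to taking breeds in
  increasing order of their minimal conservation cost (campaign + travel +
  storage for `mu` doses at the cheapest triple) until the budget is
  exhausted — optimal for a cardinality objective. With capacities a
  capacity-aware greedy is used and the uncapacitated optimum bounds the
  gap. The dose-sum variant is a fixed-charge knapsack; it is solved by a
  bounded greedy and reports `"feasible"` with its LP gap unless the bound
  is attained.

Correctness is cross-checked two ways in the test suite: an exhaustive
enumeration oracle prices every single-triple assignment of tiny instances
(at most 4 banks, 5 breeds) through the independent cost engine and must
agree with the solver to 1e-6 relative; and the transportation LP is
compared against a dense-simplex reference on random small instances. Every
solver solution is additionally re-priced by the cost engine and must
reproduce the objective.

## The synthetic inventory

The breed-level survey matrix behind the bundled network is not public, so
the package reconstructs a statistically consistent stand-in. The generator
is a pure function of its configuration, including the seed:

1. A bank × species seed matrix encodes soft concentration targets (sheep
   predominantly in B1/B6/B9, pigs in B7) and restricts species with few
   breeds to the largest banks so that every positive cell can receive at
   least one breed. **Iterative proportional fitting** calibrates this
   matrix to both marginals: the per-bank dose totals and the species dose
   shares.
2. Breed counts per species are apportioned from the dose shares by largest
   remainder to hit 489 breeds exactly. (Deriving counts from a typical
   per-breed holding near the collection maximum `M` is not viable: real
   holdings exceed `M` many-fold, and such a rule would imply thousands of
   breeds.)
3. Each breed gets a primary bank sampled proportional to its species'
   calibrated cell masses (after deterministic coverage of every positive
   cell); 10% of breeds are stored in 2–5 banks. Cell masses are split
   across their breeds by gamma weights (shape 0.5), giving the strongly
   skewed per-breed holdings — from tens to thousands of doses — that real
   collections show.
4. Availability is set to exactly the storing banks' regions (`e = 1` iff
   `A > 0`): a stored breed is assumed native to that region.

The published species shares (55% cattle, 25% sheep, 9% pig, 4% poultry, and
goat plus horse "around 3%") sum to 96%, and no sum-to-one allocation is
consistent with all of them at rounding precision. The four precisely
reported shares are kept exact and the residual 7% is split evenly between
goat and horse, the two categories reported only loosely; the default
configuration documents this choice.

What the generator does **not** emulate: real breed names, transboundary
breeds (the same breed held in several countries is treated as distinct per
record), genetic relatedness or within-breed diversity, and any correlation
between a breed's holdings and its endangerment. Passing tests on synthetic
inventories therefore demonstrate calibration to the published aggregates
and correctness of the optimization, not fidelity to any particular real
breed's situation.

## Scenarios and the diversity-cost curve

* `S0` prices the current configuration: each bank recollects its own
  holdings from its own region, choosing farm vs centre mode per record to
  minimize cost (a deliberately favorable baseline, which makes reported
  savings conservative). No cross-bank optimization occurs.
* `SUC` solves least-cost recollection with unlimited capacity, `SC50` with
  the tabulated tank capacities (which equal twice the current holdings, so
  reallocation replaces current stocks; a flag switches to residual
  capacity), and `single:<bank>` forces all storage into one bank.
* The budget sweep evaluates the diversity maximum at `n` budgets
  `B_i = B0 + i (BMax - B0)/n` (the endpoint convention that makes
  `B_n = BMax`), by default 100 points over 600–118,800 EUR, and reports raw
  optima — monotonicity of `D(B)` is a property the tests assert, not one
  the sweep enforces. Marginal costs are incremental budget per incremental
  breed between consecutive informative points. Species-restricted sweeps
  run on the species sub-inventory with all banks available.

## Sizes, tolerances and limitations

The full network instantiates, in matrix form, 124,261 variables (two
collection variable families of 489 × 11 × 11, stored doses 489 × 11, 489
indicators, five cost variables per bank) and 12,280 constraint rows
(stored-dose definitions and indicator links per breed × bank, the
semicontinuous pair and demand balance per breed, five cost rows per bank);
availability restrictions enter as variable bounds and are not counted as
rows. Counting conventions for such tallies vary by modeling system; this
one is reported transparently by `count_model_size()` and is structural —
independent of cost values.

Default tolerances: relative optimality gap 1e-6; feasibility slack 1e-7
doses in the flow solver; validation treats distance asymmetries above 1e-9
as errors. Degenerate inputs are handled explicitly: empty allocations price
to the fixed-cost floor, zero-dose records incur no campaign, budget points
below the cheapest breed yield zero diversity, and infeasible configurations
(capacity below total demand, a breed with no available region) are reported
as such rather than repaired.

The test suite and the acceptance script run the full 489-breed network for
the scenario comparisons (a few seconds per uncapacitated solve, several
seconds for the capacitated branch-and-bound) and use 2–4-bank instances
where exhaustive enumeration is the reference; five generator seeds back the
stochastic scenario summaries. Known limitations: multi-year horizons are a
single linear factor `T` (no discounting); collection failure rates,
breed-specific weights and extinction risk are out of scope; and the
capacitated diversity maximization and dose-sum diversity are solved to a
reported bound rather than proven optimality.
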