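# cryoplan

Planning tools for *ex situ* conservation of livestock genetic resources:
where should semen doses of several hundred European breeds be collected and
cryogenically stored, given a network of gene banks that differ in fixed
maintenance costs, per-dose storage costs, tank capacities, collection fees
and geography?

The package is aimed at conservation planners and agricultural economists
working with gene-bank networks. It treats the question as a capacitated
facility-location problem: banks play the role of facilities, the farm zones
around each bank are the demand regions, and each breed's doses must be
collected — at farm zones or at a collection centre — and stored somewhere in
the network.

## The model

For banks *g* and breeds *b*, continuous variables SF<sub>b,g,j</sub> and
SP<sub>b,g,j</sub> give the doses of breed *b* that bank *g* collects in
region *j* at farm zones and at the collection point respectively, and
SB<sub>b,g</sub> = Σ<sub>j</sub>(SF + SP) is what bank *g* stores. Costs per
bank decompose as

* maintenance  MC<sub>g</sub> = T·(F<sub>g</sub> + mc<sub>g</sub>·Σ<sub>b</sub> SB<sub>b,g</sub>),
* collection  CC<sub>g</sub> = Σ<sub>b</sub> r·cf<sub>g,s(b)</sub> (farm) or r·cc<sub>g,s(b)</sub> (centre), charged once per collection campaign,
* travel  TC<sub>g</sub> = (doses/k)·tc·(d<sub>j</sub> + D<sub>g,j</sub>) with fractional trips,

and C<sub>g</sub> = MC<sub>g</sub> + CC<sub>g</sub> + TC<sub>g</sub>. Two
objectives are supported: minimizing Σ<sub>g</sub> C<sub>g</sub> for a fixed
recollection demand, and maximizing the number of conserved breeds under a
budget, where each breed's stored total is semicontinuous — zero or within
[μ<sub>b</sub>, M<sub>b</sub>] — via an indicator variable y<sub>b</sub> with
μ<sub>b</sub>·y<sub>b</sub> ≤ Σ<sub>g</sub> SB<sub>b,g</sub> ≤ M<sub>b</sub>·y<sub>b</sub>.
Availability flags e<sub>b,j</sub> restrict the regions a breed can be
collected from; capacity and budget constraints are optional.

No MILP solver is required: the package ships an exact structured solver
(per-breed decomposition when capacities are off; a transportation linear
program embedded in a fixed-charge branch-and-bound when they bind), an
independent cost engine used to re-price every solution, and a brute-force
enumeration oracle for verifying the solver on tiny instances.

Because the underlying breed-level survey matrix is not public, the package
also includes a seeded synthetic-inventory generator calibrated by iterative
proportional fitting to the network's published per-bank dose totals and
species dose shares; the bundled `inventory.csv` is such a synthetic
reconstruction.

## Worked example

```r
library(cryoplan)
inst <- example_instance(seed = 1)
inst
#> <gb_instance> 11 banks, 6 species, 489 breeds (596 inventory records)
#>   stored doses: 1,646,844 | horizon T = 1 year(s) | budget TB = unbounded

compare_scenarios(inst, c("S0", "SUC", "single:B7"))
#>    scenario  status total_cost pct_vs_S0
#> 1        S0 optimal    3514894       0.0
#> 2       SUC optimal    2756783     -21.6
#> 3 single:B7 optimal   10802164     207.3
```

`S0` prices the current configuration (every bank recollects its own
holdings from its own region, 3.51 M EUR/year here). `SUC` lets any bank
collect in any available region with unlimited tank capacity and cuts the
bill by 21.6%, mostly by consolidating duplicate collections and routing
collection campaigns through banks with cheaper fees and shorter journeys.
Forcing the whole network into the single largest bank (`single:B7`) triples
the cost (+207%) because no one bank is cheap for every species and all
doses must then travel.

A budget sweep traces the diversity-cost frontier — how many breeds can be
conserved at minimum dose levels as the variable-cost budget grows:

```r
sw <- run_sweep(inst, sweep_config(n = 10))
head(sw[, 1:4], 3)
#>   i budget diversity cost_used
#> 1 1  12420        26  12116.83
#> 2 2  24240        41  23526.43
#> 3 3  36060        57  35781.46
marginal_costs(sw)   # here ~739-788 EUR per additional breed
```

A command-line wrapper with `generate`, `solve`, `sweep`, `report` and
`validate` subcommands is installed under `exec/cryoplan`.

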