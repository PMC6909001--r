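# fluxcom

Constraint-based analysis of multi-species microbial communities in R:
flux balance and flux variability analysis, model curation diagnostics,
GapFind/GapFill mixed-integer programs, a bilevel community model with a
shared extracellular metabolite pool, gap-fill-driven discovery of
inter-species metabolite exchanges, viral auxiliary-metabolic-gene (AMG)
augmentation with flux-shift reporting, and robustness analysis under
alternative community objectives.

The package is written for microbial-ecology and systems-biology groups who
work with small, curated communities — the motivating system is the bovine
rumen, where a polysaccharide degrader, a starch/protein consumer and a
hydrogenotrophic methanogen exchange sugars, acids, hydrogen and CO2 — and
who want every stage of such an analysis reproducible and testable on
synthetic communities with planted ground truth.

## The models

**Member models.** Each member is a genome-scale (here: toy-scale) metabolic
model analysed by flux balance analysis:

```
max  v_biomass
s.t. sum_j S_ij v_j = 0        for every metabolite i
     LB_j <= v_j <= UB_j       for every reaction j
```

with fluxes in mmol/gDCW/hr and biomass flux in 1/hr. Flux variability
analysis (FVA) minimises and maximises each `v_j` over the same polytope,
optionally with the objective pinned at (a fraction of) a threshold value.

**Community model.** Members are coupled through a shared metabolite pool
(compartment `[u]`) in a bilevel program in the OptCom style: each member k
is an inner problem maximising its own biomass, with its uptake and export
of every shared metabolite i fixed to outer allocation variables
`r_uptake[i,k]`, `r_export[i,k] >= 0`. The outer problem optimises a
community-level objective subject to the pool mass balance

```
sum_k r_export[i,k] + pool_in[i] = sum_k r_uptake[i,k] + pool_out[i]
```

where `pool_in` is the community uptake from the environment (capped by the
diet) and `pool_out` the community release. The bilevel program is solved as
a single-level MILP by replacing each inner LP with its KKT conditions
(complementary slackness linearised with big-M binaries); a collapsed
single-LP "joint" mode is available as a cross-check. All LPs/MILPs are
solved with HiGHS (through `reticulate` and `scipy.optimize.milp`).

**Gap analysis and interaction discovery.** GapFind is a MILP that marks
every metabolite the network can produce (and, run on `-S`, consume); the
rest are *problem metabolites*. GapFill searches a reaction database — the
other community members, or a universal database — for a
minimum-cardinality addition restoring each problem metabolite, enumerating
ties by integer cuts. Every candidate fill is then classified: transporter
fills are screened against a transporter-evidence knowledgebase, other
fills against a taxonomic-relatedness configuration, and every fill against
a thermodynamically-infeasible-cycle check; an uptake transporter with
evidence whose substrate another member demonstrably exports becomes a
**de novo inter-species interaction** (metabolite, donor, receiver).

## Worked example

`make_toy3()` builds a deterministic three-guild community — degrader `X`,
consumer `Y`, methanogen `Z` — with planted truth: one infeasible cycle and
a dead-end branch in X, four problem metabolites, a capacity bottleneck in
Z with a viral bypass, and one cross-feed (X exports acetate; Y's acetate
transporter is withheld).

```r
library(fluxcom)
toy <- make_toy3()
print(toy$members$X)
#> <metabolic_model> X: 18 metabolites, 21 reactions (6 exchange), biomass = BIO_X

fba(toy$members$X)$objective_value      # degrader alone on 10 glucose
#> [1] 20

gapfind(toy$members$Y)$no_production    # the planted gap in the consumer
#> [1] "ac[c]"

cm   <- build_community(toy$members, toy$shared, toy$diet)
ints <- discover_interactions(cm, toy$kb, toy$tax, toy$db_universal)
ints[, c("metabolite", "donor", "receiver", "status", "source")]
#>   metabolite donor receiver              status    source
#> 1         x1  <NA>        X       accepted_fill universal
#> 2         x2  <NA>        X       accepted_fill universal
#> 3         ac     X        Y de_novo_interaction         X
#> 4         vb  <NA>        Z            rejected universal
#> 5         vb  <NA>        Z       accepted_fill universal

sol <- solve_optcom(bundle_community(toy))   # cross-feed incorporated
print(sol)
#> <community_solution> status optimal, growth = 25
#> member biomass: X= 0 Y=20 Z= 5
```

Reading the output: the acetate gap in Y is best filled by a transporter
for which Y has knowledgebase evidence and whose substrate X exports — a de
novo X -> Y interaction; the x1/x2 gaps are ordinary network fixes, and the
vitamin transporter for Z is rejected for lack of transporter evidence
(the biosynthetic route is accepted instead). With the cross-feed bridged,
the community grows at 25 1/hr on 10 glucose: the growth optimum is
degenerate in how X and Y split the sugar (this solution has X fermenting
everything for Y and Z), which is why downstream logic uses objective
values and FVA ranges, never one particular flux vector. Pool residuals are
zero for every shared metabolite. Applying the viral AMG sets relaxes Z's
methanogenesis bottleneck and raises the community optimum to 30, while the
acetate interaction becomes unnecessary (Y gains an internal route) — the
record shows up as *lost* in `diff_interactions()`.

## Native model dialect

Models round-trip through a JSON dialect (SBML level 2 is read-only, since
it cannot carry member tags and taxon lists losslessly):

```json
{
  "id": "X",
  "biomass_reaction_id": "BIO_X",
  "metabolites": [
    {"id": "glc[c]", "name": "glc[c]", "formula": "C6H12O6",
     "charge": 0, "compartment": "c"}
  ],
  "reactions": [
    {"id": "GLY", "stoichiometry": {"glc[c]": -1, "triose[c]": 2},
     "lb": 0, "ub": 1000, "reversible": false, "genes": [],
     "subsystem": null, "is_exchange": false, "is_transport": false,
     "is_biomass": false}
  ]
}
```

Conventions: metabolite ids are compartment-suffixed (`[c]` cytosol, `[e]`
member extracellular, `[u]` shared pool); an exchange reaction `EX_x: x ->`
has positive flux for secretion and negative for uptake; a reaction is
reversible iff its lower bound is negative; 1000 mmol/gDCW/hr is both the
default bound magnitude and the big-M constant. Reaction databases and the
transporter knowledgebase are TSV; diet, taxonomy and pipeline
configurations are YAML.
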