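---
title: "Community metabolic modeling with fluxcom: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community metabolic modeling with fluxcom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxcom)
```

## The problem

Small anaerobic communities — the motivating case is the rumen, with a
fiber-degrading firmicute, a starch/protein-degrading bacteroidete and a
hydrogenotrophic methanogen — are held together by metabolite exchange:
sugars and acids flow from degraders to consumers, hydrogen and CO2 to the
methanogen, methane out. `fluxcom` models each member as a constraint-based
metabolic network, couples them through a shared extracellular pool, and
uses the machinery of gap analysis to *propose* exchanges that the curated
models alone do not contain, each proposal backed by an explicit evidence
trail.

## Member-level analysis

A member model is a stoichiometric matrix $S$ with flux bounds. FBA solves
$\max v_{biomass}$ subject to $Sv = 0$, $LB \le v \le UB$; FVA reports
$[\min v_j, \max v_j]$ per reaction, optionally with the objective pinned.
Two numerical conventions hold everywhere:

* bounds default to $\pm 1000$ mmol/gDCW/hr; the same constant is the big-M
  of every mixed-integer construction. One constant means one place where
  "effectively unbounded" is defined.
* the solver (HiGHS, reached through `scipy.optimize.milp` via
  `reticulate`) runs with primal, dual and integrality tolerances of 1e-9
  and a zero MIP gap. The integrality tolerance matters: with HiGHS's
  default 1e-6, a gating binary at $y = 10^{-6}$ times big-M 1000 leaks
  exactly the 1e-3 production threshold used by the gap programs, and a
  "cardinality-zero gap fill" appears out of round-off. Reporting
  tolerances are 1e-6 throughout.

Degenerate optima are embraced, not fought: FBA returns *an* optimal
vertex, and all cross-stage logic (interaction discovery, flux-shift
reports, robustness statistics) consumes only objective values and FVA
ranges. The worked example in the README shows a growth optimum where the
degrader keeps none of the sugar for itself — an equally optimal sibling of
the "fair split" solution.

## Curation diagnostics

`check_balance()` does exact integer element/charge accounting per reaction
(exchange and biomass pseudo-reactions are excluded; unknown formulas make
a reaction *unbalanceable*, not imbalanced), and `suggest_proton_fix()`
returns the signed proton count when hydrogen and charge disagree by the
same integer. `find_unbounded()` closes every exchange and flags reactions
whose FVA range still reaches $0.999 \times 1000$ — the operational
signature of a thermodynamically infeasible cycle, the 0.999 absorbing
solver round-off near the artificial bound. `group_loops()` intersects the
unbounded set with supports of an *exact rational* null-space basis of the
internal stoichiometric matrix; the basis is computed by Gauss–Jordan
elimination on numerator/denominator pairs because floating-point null
bases produce spurious supports that would merge unrelated cycles. Repair
is deliberately not automatic: `constrain_loop_representatives()` applies
the curator's choice (default: turn off the lexicographically first member
of each group; a whitelist protects loops one decides to keep, the usual
fate of nucleotide-degradation cycles).

## Gap programs

GapFind maximises the number of metabolites shown producible in one flux
distribution, with production-coupling binaries $w_{ij}$ enforcing
$\varepsilon \le S_{ij} v_j \le M w_{ij}$ on producing terms and
$\varepsilon = 10^{-3}$, $M = 1000$. Producibility uses the
accumulation-relaxed balance $Sv \ge 0$ with all exchanges open; the
consumption pass runs the identical program on $-S$. GapFill minimises the
number of database reactions (binaries gating their bounds) needed to push
the target's net production to $\varepsilon$, under the *same* relaxed
balance — this shared semantics is what makes "applying a returned fill
removes its gap" an exact invariant rather than an empirical hope.
Alternate optima are enumerated with integer cuts; ties are returned in
lexicographic order via a second solve that fixes the cardinality and
minimises a rank objective, so reruns are reproducible. When a candidate
transporter references an extracellular metabolite the model lacks, an
open exchange is created alongside (community-pool context; config
toggle `allow_exchange`), and it does not count toward cardinality.
Per-metabolite filling is the default mode; root gaps (no structural
producer at all) are distinguished from downstream ones in the report.

## The bilevel community model

Members are coupled only through the pool: member $k$'s exchange flux of
shared metabolite $i$ is split as $v_{EX,ik} = r_{export,ik} -
r_{uptake,ik}$ with both allocations outer variables $\ge 0$, and each pool
metabolite carries the balance *member exports + community uptake = member
uptakes + community release*, with the diet capping community uptake only —
member bounds are never diet-constrained. Each inner problem maximises its
member's biomass given the allocations. The single-level reformulation
replaces each inner LP by its KKT system; because allocations enter only
inner right-hand sides, stationarity rows are allocation-free and the
problem stays a MILP. Complementary slackness uses the tightest available
primal big-M (the bound gap $UB_j - LB_j$) and a dual big-M of 1000;
solutions are flagged if any dual presses against that cap, and every
returned solution is re-verified by fixing the allocations and re-solving
each member's LP (`check_inner_optimality()`). A `"joint"` mode solves the
pooled LP without inner optimality — the cross-check used in the tests,
where the two provably coincide on the fixtures (no conflicting inner
degrees of freedom).

One modelling consequence is worth knowing: the outer problem can steer a
member only through shared-pool allocations. An objective over a member's
private exchange flux is inner-controlled and typically optimises to zero;
this is why the sugar objective of the fixture community works through a
pooled sugar, and why metabolites one wants community objectives to "see"
must be shared. Community growth is reported as the unweighted sum of
member biomass fluxes (each per gDCW of that member); an abundance-weighted
variant is available through objective weights since no canonical weights
exist for the motivating system.

## Interaction discovery and AMG analysis

For every member and problem metabolite, fills are sought in each other
member's reaction set and in the universal database. Checks run
cheapest-first and in a fixed order: transport plausibility (knowledgebase
evidence at least *ortholog*; a transporter without evidence is rejected
outright), taxonomic likelihood for non-transport fills (rank of the
entry's taxa in the member's configured relatedness list, threshold
inclusive), then a cycle check by tentative addition (any new unbounded
reaction rejects the candidate). An uptake transporter with evidence
becomes a de novo interaction when at least one other member's standalone
FVA shows export of the metabolite above $\varepsilon$; all qualifying
donors are recorded, flagged ambiguous when several. Export-direction
transporter fills with evidence are accepted fixes, not interactions — the
record key is (metabolite, donor, receiver), and duplicates across source
databases collapse onto the first record found.

AMG reaction sets are an input contract (provenance and an e-value below
1e-34 as metadata; alignment itself is out of scope, being unreproducible
at desk scale against a moving target database). `apply_amg()` adds
reactions with duplicate detection in both orientations, and
`flux_shift()` compares FVA envelopes across the objective contexts:
since augmentation only enlarges the flux polytope, every range is weakly
wider — a theorem the tests exercise on random augmentations — and
"significant" follows the standard-deviation rule (SD of minima or maxima
across the context simulations above 1), with an absolute-delta fallback
(1e-3) for single-context runs.

## Objectives and robustness

Five community objectives are standard: growth (max), SCFA production
(max pooled export), feed utilisation (max pooled uptake), methane + CO2
release (min pooled export), and small-sugar production (max pooled
export). Membership of the SCFA/feed/gas/sugar sets is configuration;
the generator emits defaults matching its guild template. All five runs
share one diet so differences are attributable to the objective alone.
`robustness_stats()` computes the per-reaction SD of FVA minima and maxima
across the runs using the *population* formula (n in the denominator: the
five objectives are the whole condition set, not a sample; a sample-SD
switch exists), reports both columns separately plus a pooled view, and
`density_summary()` draws the Gaussian-kernel density with Silverman's
rule-of-thumb bandwidth (grid widened to 4 bandwidths so the density
integrates to 1 within 1e-3).

## The synthetic generator

`make_toy3()` is a fixed three-guild fixture with real chemistry where
balance matters (glucose fermentation
`glc + 2 h2o -> 2 ac + 2 co2 + 4 h2`, methanogenesis
`co2 + 4 h2 -> ch4 + 2 h2o`) and unknown formulas for lumped metabolites.
Its planted features and hand-solved values anchor the tests: degrader
growth 20 1/hr at 10 glucose uptake, community growth 25 (the fermentative
route is worth 3 biomass units per glucose against 2 for direct growth,
capped by the methanogen's bottleneck at 5), 30 after the viral bypass.
`generate_community()` draws seeded random communities of linear catabolic
chains with planted dead-ends, cross-feeds (receiver transporter withheld
and recorded in the knowledgebase), reversible 3-cycles and AMG bypasses;
the same spec and seed reproduce the bundle byte-for-byte, and gaps sit
only on branches whose removal does not zero biomass, so gap tests are
decoupled from growth tests.

What the generator does *not* emulate: genome-scale topology (cofactor
hubs, alternative routes in the hundreds), realistic biomass compositions,
growth-associated maintenance, or noisy annotations. Passing the planted
truth therefore shows the algorithms are implemented correctly, not that
their biological error rates on real reconstructions are zero — on real
models, gap classification inherits every bias of the knowledgebase and
taxonomy configuration it is given.

## Problem sizes used in verification

The shipped test-suite and acceptance script run: LP-oracle equivalence on
50 random networks of at most 6 reactions against exhaustive vertex
enumeration; GapFill minimality against brute-force subset search on 30
random databases of at most 15 entries; planted-truth recovery on 50
seeded communities (10 of them also with an emptied knowledgebase); 100
random augmentations for range monotonicity; and the full TOY3 pipeline
under all five objectives. These sizes were chosen so the whole suite
verifies every claim in minutes on one CPU while still exercising each
combinatorial mechanism (alternate optima, ties, infeasible fills,
ambiguous donors) at least once.

## Known limitations

* The KKT reformulation's dual big-M (1000) is a modelling assumption;
  pathological models with shadow prices near the cap would be flagged but
  not re-solved with a larger cap automatically.
* GapFind's accumulation-relaxed balance follows the classical
  construction; metabolites producible only in tightly coupled cycles are
  counted produced (cycles are the loop report's job, not GapFind's).
* SBML support is level 2 read-only, with COBRA-style notes for formulas
  and bounds in kinetic-law parameters; level 3/FBC is out of scope.
* The pipeline incorporates discovered *transport* fills before community
  simulation; non-transport accepted fills are reported but left to the
  curator, mirroring how such fixes are adopted in practice.
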