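---
title: "Methods: abundance-weighted community FBA for weaning-diet screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abundance-weighted community FBA for weaning-diet screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weanflux)
```

## The question the package answers

During weaning, complementary foods change the mix of carbohydrates,
fibres and proteins that escape small-intestinal absorption and reach
the colon. Colonic genera ferment these substrates into short-chain
fatty acids (SCFAs: acetate, propionate, butyrate) and, from undigested
amino acids, branched-chain fatty acids (BCFAs: isobutyrate,
isovalerate). `weanflux` predicts how a food–breastmilk combination
shifts community SCFA/BCFA production relative to breastmilk alone,
using constraint-based metabolic modelling: no kinetics, no time
courses, only stoichiometry, flux bounds and an optimality principle.

## Model and assumptions

**Steady state.** Each genus is represented by a metabolic
reconstruction: a stoichiometric matrix (metabolites × reactions) with
flux bounds in mmol/(gDW·h) and a biomass pseudo-reaction normalised so
that unit flux produces 1 g dry weight — its flux is the growth rate
μ in 1/h. Flux vectors must satisfy S·v = 0: intracellular metabolites
and the shared lumen neither accumulate nor drain. This idealises the
colon as a chemostat-like compartment at the microbial exponential
phase; it cannot represent substrate depletion over a feeding cycle.

**Abundance weighting.** Relative abundance aᵢ (from genus-collapsed
amplicon data) is equated with relative biomass. Taxon fluxes are per
gDW of that taxon, so community-level balances weight each taxon's
exchange fluxes by aᵢ: the lumen row for metabolite m reads
Σᵢ aᵢ·vᵢ^(ex,m) − v^(diet,m) = 0, where the diet exchange column
exports from the lumen (negative flux = supply, bounded below by the
medium). The community growth rate is μ_c = Σᵢ aᵢμᵢ, an identity, never
a fitted quantity.

**Cooperative trade-off.** Maximising μ_c alone funnels all growth into
the most efficient taxon. The trade-off computes μ_c^max first, then
minimises Σᵢμᵢ² subject to all FBA constraints plus
Σᵢ aᵢμᵢ ≥ α·μ_c^max. With no other binding constraint the minimiser is
μᵢ = α·μ_c^max·aᵢ/(aᵀa) — growth proportional to abundance, which is
the biological motivation for the squared (L2) objective; an L1 variant
is exposed via `solverConfig(tradeoffNorm = "l1")` for sensitivity
analyses. The optimal α for a diet is selected by scanning a descending
grid (default 1.0, 0.9, …, 0.1) and keeping the largest α that
maximises the number of taxa growing above the negligible-growth
threshold (10⁻⁶ /h); the scan stops early once every taxon grows, and
the whole trace is retained in the solution object. The grid step and
the max-growing-taxa rule are package choices: they bound runtime and
make "optimal trade-off" reproducible and deterministic.

## Diet pipeline

The order is fixed: build → convert → absorption → secretions →
completion.

| step | parameter | default | why |
|---|---|---|---|
| caloric mixing | total energy | 608 kcal/day | daily requirement of a ~7.6 kg 6-month-old |
| | milk fraction | 0.85 (pairs: 2 × 0.075 food) | breastmilk still dominates energy intake at 6 months |
| unit conversion | divisor | 24 | tables arrive in mmol/day; solvers need mmol/h |
| absorption | factor | 0.2 | fraction of absorbable compounds escaping the small intestine |
| host secretions | mucin, glycocholate, taurocholate | 1 mmol/h each | host-derived substrates present regardless of diet |
| completion | growth floor | 0.01 /h | food tables omit vitamins/cofactors; every genus must be viable |

Food masses follow from calories: grams = fraction × energy /
energy-density, and compound fluxes are mass-weighted sums of the
composition tables; recomputed energy is asserted equal to the design
total within 10⁻⁶ kcal. Absorption multiplies only flagged compounds
(the absorbable set is configuration, derived by default from the food
table's flags). Host secretions are added after absorption; the two
steps commute because the package rejects secretion compounds that
appear in the absorbed set. Completion solves, per taxon, an LP
minimising total supplemental flux such that the taxon *alone* reaches
the floor growth rate, then adds the element-wise maximum of the
per-taxon supplement vectors. Per-taxon-then-union keeps the LP small
and makes supplements independent of community composition; a joint
formulation could be smaller in total flux but would couple supplements
to abundances. Supplement vectors are inflated by a 10⁻⁴ relative
safety factor so solver rounding can never leave the floor infeasible;
the post-condition is re-verified by single-taxon FBA before the medium
is accepted.

## Screening

Community production of metabolite m is v_tot^m = Σᵢ aᵢ·vᵢ^m. By
default only positive (secreting) exchanges contribute
(`aggregate = "producers"`): with cross-feeding, a consumer's negative
exchange would silently offset a producer's output in the plain sum;
the net mode is available as a switch. Panels are summed (SCFA:
acetate + propionate + butyrate; BCFA: isobutyrate + isovalerate),
compared with the milk-only control as 100·(combo − control)/control,
and classified increase / decrease / no-change with a ±1 % band — the
band is a package choice; the underlying percent values are stored at
full precision. Results are ordered by absolute total SCFA flux.
Combinations whose control flux is zero get `NA` rather than a number.
A zero-variation second control (infant formula at caloric fraction 1)
is supported as just another food item.

## Abundance handling

Genera below 1 % relative abundance are removed before assembly: they
contribute little to community totals but enlarge the model and are the
typical locus of numerical instability (near-zero growth rates that
break the trade-off). After filtering, the profile is renormalised to
sum to 1 so that the retained community is treated as the whole
community; whether to renormalise is genuinely open (the retained mass
is ~95 % in realistic tables), so `renormalize = FALSE` is exposed for
sensitivity runs. Renormalisation preserves abundance ratios, and
downstream results are invariant to the raw abundance scale.

## The solver

All programmes are solved by a built-in dense primal-dual
interior-point method (Mehrotra predictor-corrector on the normal
equations) for problems of the form min q'x + ½x'·diag(h)·x subject to
Ax = b, l ≤ x ≤ u. Design points:

- **Diagonal Hessian only.** Every programme in the package is an LP or
  a separable QP (the trade-off objective is diagonal in the biomass
  columns), which keeps the reduced system dense m × m.
- **Proximal ridge.** A 10⁻¹⁰ ridge is added to the Hessian. It bounds
  the conditioning of the normal equations and makes flat LP optima
  unique, so solutions are deterministic without randomised pivoting.
  A retry ladder (10⁻⁸, 10⁻⁶) handles trajectories that stall on badly
  scaled degenerate faces.
- **Feasibility restoration.** After the barrier phase the iterate is
  projected onto Ax = b along variables away from their bounds, which
  removes the residual that interior-point methods leave on rows whose
  natural scale (e.g. vitamin fluxes, ~10⁻⁴ mmol/h) is far below the
  bound spans (~10³).
- **Status semantics.** `optimal` requires primal feasibility below
  10⁻⁷ (relative to the right-hand side) with complementarity resolved;
  `infeasible` is declared on a large stagnant primal residual;
  anything between is `numerically-unstable` and is propagated, flagged,
  into solutions and screen results rather than hidden.
- **Flux degeneracy.** Growth rates are unique under the strictly
  convex step-2 objective, but fluxes need not be; an optional
  minimal-total-flux polish (L1, on by default) re-solves with growth
  rates pinned, making reported fluxes deterministic.

The test suite cross-checks the solver against brute-force vertex
enumeration on random toy communities, `boot::simplex`,
`pracma::quadprog`, and the closed-form trade-off allocation; mass
balance is verified to max|S·v| ≤ 10⁻⁶ and the growth identity to
10⁻⁸.

## The synthetic-data generator

Real inputs for this analysis are large curated resources: genus pan
reconstructions pooled from strain models, food composition databases,
and a cohort genus table. The generator stands in for all three with
known ground truth:

- **Taxa** are fermentation archetypes: per substrate, a biomass yield
  (gDW/mmol) and fixed product stoichiometry; optional cofactor
  requirements (mmol/gDW) enter the biomass reaction. The default
  community has 10 modeled genera named after typical infant colonic
  genera, with abundances spanning >10 % to 1.5 %, plus a sub-1 % genus
  without a reconstruction so the filter has work to do. Two
  low-abundance genera require B vitamins absent from all foods, making
  every food-derived diet cofactor-deficient until completion.
- **Foods** follow group templates (fruits and vegetables rich in
  non-absorbable fibres, cereals in resistant starch and xylan, animal
  proteins in amino acids) with ±5 % seeded jitter; breastmilk carries
  lactose, oligosaccharides, protein and lipid, and infant formula
  matches breastmilk per kcal exactly, so it is a built-in no-change
  control.
- **Ground truth** is derived from the archetype stoichiometry alone,
  without solving any LP/QP: substrates are exclusive to (or shared
  with identical parameters among) substrate-limited taxa, so at the
  optimal trade-off the community converts each substrate supply
  completely and metabolite totals are linear in the completed diet
  fluxes; cofactor-limited taxa contribute the constant production
  implied by minimal completion. The generator classifies every
  single-food and pair combination analytically, and the acceptance
  suite requires the full pipeline to reproduce 100 % of those
  directions.

What passing these tests shows — and what it does not: the pipeline
implements the stated mathematics exactly on models whose optima are
analytically known. Real reconstructions have thousands of reactions,
redundant pathways, genuine flux degeneracy and cross-feeding; the
synthetic scenario keeps cross-feeding off by default (a flag enables
an acetate-consuming butyrogen) precisely so its ground truth stays
analytic. Quantitative agreement with laboratory measurements is a
separate question the package does not claim to answer.

## Numerical choices and degenerate inputs

- Default reaction bounds are ±1000 mmol/(gDW·h), the conventional
  stand-in for "unbounded"; all variables are kept in finite boxes.
- Pan-model pooling deduplicates reactions by identifier *and*
  stoichiometry, widens bounds of duplicates to the interval hull, and
  takes the first strain's biomass reaction (a deterministic convention;
  there is no canonical merge of differing biomass compositions). The
  same identifier with different stoichiometry is an error, not a
  silent rename.
- Unit conversion refuses to run twice (per-day → per-hour is tracked
  in the object); classification refuses undefined relative variations.
- Problem sizes: the default scenario community has ~60 reaction
  columns plus 17 lumen exchanges; a full 80-combination screen (12
  singles, 66 pairs, 2 controls) solves in well under a minute on one
  CPU, and the test suite's brute-force oracles are restricted to toys
  with ≤ 16 columns so vertex enumeration stays exact and fast.

## Known limitations

Steady-state FBA cannot capture depletion dynamics or pH effects;
abundance-as-biomass is an approximation; the trade-off grid is
discrete; medium completion is per-taxon minimal rather than jointly
minimal; and synthetic archetypes compress genus metabolism into a few
reactions. The screening verdicts are therefore comparative, not
absolute predictions of colonic concentrations.
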