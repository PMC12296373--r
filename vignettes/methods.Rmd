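---
title: "Pooled community metabolic modelling: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled community metabolic modelling: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocomm)
```

## The model

A GEM here is a bounded stoichiometric network with one biomass
pseudo-reaction; flux balance analysis (FBA) maximises the biomass flux
subject to steady state (`S v = 0`) and bounds, and flux variability
analysis (FVA) brackets each reaction's attainable flux, optionally
while holding biomass at a fraction of its optimum. Exchange reactions
are single-metabolite reactions with coefficient −1; negative flux is
uptake. A medium is a map from exchange ids to maximal uptake rates
(mmol/gDW/h); applying a medium sets each listed exchange's lower bound
to −uptake and *closes unlisted exchanges*, so a medium fully specifies
the environment. With no medium the model's own bounds stand — the
permissive default for exploratory use, since published cohort
simulations rarely state their diet.

### Pooling related models

`merge_models()` joins a group of GEMs into one: the union of their
reactions keyed by reaction id (first occurrence wins; conflicting
duplicate definitions are counted and warned about, which presumes a
shared reaction namespace as in curated model collections) and a new
biomass reaction whose coefficients are the unweighted arithmetic mean
of the members' biomass coefficient vectors over a common metabolite
basis, absent entries counting as zero. All member biomass reactions are
removed; the merged biomass gets bounds [0, 1000] and becomes the sole
objective. We deliberately do *not* weight the biomass average by
abundance: the averaging formula is an unweighted mean, and weighting
would entangle model structure with per-sample composition; abundance
enters later, in the community coupling.

Groupings come from four sources: a taxonomic rank column
(`group_by_rank()`), a similarity matrix thresholded at 0.6
(`group_by_distance()`; single-linkage connected components by default
— the minimal closure that turns "pairs above threshold merge" into a
partition, with complete linkage exposed for stricter groups), explicit
merge sets (`group_manual()`), and a size-preserving random null
(`random_grouping()`). Merging is defined once, globally, by the
scheme; per-sample behaviour arises naturally because each sample's
community only instantiates the groups present in it.

### Community coupling and growth

`build_community()` embeds each member with `"__taxon"`-suffixed ids,
rewires member exchanges into transfer reactions against a shared pool
(`<met>_m`), and opens the pool through medium-governed pool exchanges.
Member fluxes are per gram of member biomass; the pool side of each
transfer is multiplied by the member's relative abundance, so pool
balances are per gram of community. Two consequences worth knowing:

* the natural community objective is `G = Σ a_i μ_i`;
* a member's pool access scales like `U/a_i` — a rare member can draw a
  large per-gram share of a community-level allowance.

`cooperative_tradeoff()` maximises `G`, then minimises `Σ μ_i²` subject
to `G ≥ fraction · G*`. The L2 stage is strictly convex in the member
growths, so the reported growth vector is unique and deterministic; for
a single member and `fraction < 1` it settles exactly on the constraint
(`μ = fraction · G*`), which is the direct consequence of the stated
two-stage program. `community_fba_sum()` is a deliberately simple
single-level surrogate for nested multi-objective community
formulations: maximise the unweighted `Σ μ_i` with the same L2
tie-break. Full bilevel optimisation is out of scope.

Knockouts rebuild the community without the member; by default the
survivors' abundances are renormalised (keeping `Σ a_i = 1`), with
`renormalize = FALSE` available. Renormalisation has a side effect the
screen's users should know: a surviving member's pool coupling changes
from `a_i` to its renormalised share, so a formerly advantaged member
can *lose* growth when a minor competitor disappears. The knockout
fixtures in the tests document both the clean competition signal (minor
member freed by removing the dominant competitor) and this rebound.

## Solvers

No LP package is available in the target environment, so FBA/FVA run on
an internal dense two-phase simplex: Dantzig pricing with a maintained
reduced-cost row, Bland's rule after 500 iterations (termination
guarantee), explicit upper-bound rows, artificial variables driven out
of the basis after phase 1. All bounds must be finite (the generators
cap free fluxes at ±1000). Requested tolerances are 1e-9; tests assert
1e-6. The L2 stages are quadratic programs solved with `quadprog`; the
non-growth flux directions receive a 1e-8 ridge to meet its
strict-convexity requirement, with a one-off 1e-7 constraint relaxation
retry absorbing LP-rounding infeasibility. On the toy scale this
package targets (tens of reactions per model, hundreds per community)
the solver is exact to well below the asserted tolerances; it is not
intended for genome-scale inputs with thousands of reactions.

## Evaluation choices

Correlations pool `(sample, unit)` pairs across samples into one
Pearson coefficient by default (`growth_correlation()`), matching the
usual "correlation across samples" reporting; a per-sample mode exists.
Reference construction mirrors the two-step wording it implements:
duplicate `(sample, unit)` replication entries are averaged unweighted,
then higher-level references are abundance-weighted means.
`williams_test()` implements the 1959 t2 statistic for two dependent
correlations sharing one variable, with `n − 3` degrees of freedom; the
test suite checks it against an independently written determinant-form
evaluation to 1e-10.

Redundancy metrics use reaction-id sets with biomass reactions excluded
(their ids are artifacts of merging) and community suffixes stripped.
Metabolite-set or flux-space similarity is out of scope; reaction sets
were chosen because merging operates on reactions.

For blocked-metabolite interaction detection, a metabolite is *blocked*
for a model when the medium does not supply it and the model cannot
produce it, yet the model could take it up if an exchange bound were
opened — the minimal reading under which a partner's secretion creates
a de novo interaction. `detect_interactions()` draws `A → B` whenever A
can secrete a metabolite blocked for B, weighting edges by metabolite
count; `merge_graphs()` consolidates per-sample graphs into per-label
consensus graphs with occurrence weights in (0, 1].

## The synthetic world

The generators state a small but structured world:

* `make_toy_gem()` builds linear pathways whose FBA optimum is exactly
  `Σ uptake × yield`; byproducts are stoichiometrically coupled to
  biomass (one unit per unit growth) so cross-feeding fixtures are
  deterministic.
* `make_related_family()` plants exact reaction-set overlap: members
  share a `core_size` chain and carry `variant_size` private reactions,
  so pairwise Jaccard distance is `1 − core/(core + 2·variant)` by
  construction, and each member's optimum is `uptake × yield_member`.
* `make_cohort()` (defaults: 20 samples, 5 families × 3 genera,
  planted correlation 0.8, replication noise 0) gives each family its
  own substrate and a family-characteristic yield drawn from
  U(0.2, 0.9) with ±10% within-family jitter — families are
  metabolically coherent, and merging across families forces
  co-production of two biomass precursors, which is what makes the
  random-grouping null measurably worse. The cohort medium caps each
  family substrate at 1 mmol/(g community)/h, deliberately limiting, so
  growth predictions respond to the abundance vector. Abundances are
  flat-Dirichlet; replication rates are
  `ρ·z(achievable growth) + sqrt(1 − ρ²)·N(0,1)` per (sample, taxon).

What a green test on this world establishes — and what it does not: the
pipeline recovers planted structure, structured grouping beats the
random null, and all exact claims (merging arithmetic, closed-form
optima, interaction signs) hold to stated tolerances. It does not
establish that pooling improves accuracy on real cohorts, where model
redundancy, diet, and replication-rate noise are all messier.

One stated-world limitation deserves emphasis. Replication rates are
planted against per-taxon *achievable* growth, independent of the
abundance vector, while the simulated predictions depend on abundances
through the limiting medium. Perturbing abundances with Gaussian noise
(`sensitivity_analysis()`, defaults 0.1/0.7/1.5 on the fraction scale
with five replicates, per the standard protocol) therefore does not
degrade the prediction–reference correlation here; it can even raise it,
by flattening abundance-driven prediction variance that is orthogonal to
the static reference. In a real cohort replication rates covary with the
sample context and noise is genuinely destructive; emulating that would
require planting replication on realized per-sample growth, which we
chose not to retrofit. The package's sensitivity machinery is
nevertheless fully exercised: for an abundance-proportional pipeline the
mean correlation falls monotonically with noise, as the tests show.

## Numerical conventions

* Solver feasibility/optimality: 1e-9 requested, 1e-6 asserted.
* Blocked-reaction calls and interaction capability calls: 1e-6 flux
  tolerance; blocked-exchange detection uses `fraction_of_optimum = 0`
  (capability, not growth-coupled flux).
* Knockout screen edge threshold: |Δμ| > 1e-6.
* Abundance cutoff for community membership: 1e-4 (relative), applied
  after normalisation, then renormalised.
* All randomness flows through per-call integer seeds; child seeds are
  derived with a fixed LCG-style mix kept below 2^31, and generators
  restore the caller's RNG state.

## Known limitations

Dense linear algebra limits model size; gene–protein–reaction rules and
compartments beyond the cytosol/extracellular/pool triple are not
modelled; SBML support covers the constraint-based subset (fbc bounds
and objective), not the full standard; the bilevel community
formulation is approximated by the summed-growth surrogate; and the
synthetic cohort is a caricature designed for exactness, not realism.
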