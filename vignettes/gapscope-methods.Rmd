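---
title: "Topological gap-filling of metabolic networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological gap-filling of metabolic networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapscope)
```

## The problem

Draft genome-scale metabolic networks reconstructed from incomplete or poorly
annotated sequence data miss reactions, so compounds the organism demonstrably
makes (biomass components, measured metabolites) cannot be produced *in
silico* from the growth medium. Gap-filling selects reactions from a reference
database whose addition restores producibility. `gapscope` implements the
purely topological variant of this problem: stoichiometric balance is ignored
and producibility is a reachability notion on the bipartite
reaction–metabolite graph. This makes the method robust to the cofactor and
stoichiometry errors that plague large reaction databases, at the price of
over-approximating what a flux-balance model would accept — which is why the
package pairs the solver with an LP validation layer.

## Producibility: forward scope

A network is a set of reactions $r$ with reactant sets $reac(r)$ and product
sets $prod(r)$; a reversible reaction contributes both directions. Given seed
metabolites $S$ (the growth medium), the *forward scope* is the least fixed
point of

$$M_0 = S, \qquad
  M_{i+1} = M_i \cup \mathit{prod}(\{\, r : reac(r) \subseteq M_i \,\}).$$

A reaction fires only when **all** its reactants are already reachable — an
AND/OR reachability, not plain graph connectivity. Two consequences matter in
practice:

* a reaction with no reactants fires unconditionally (the universal
  quantification is vacuous);
* a cycle none of whose members is independently produced contributes
  nothing: self-sustaining loops, which flux-balance analysis happily uses,
  are rejected. The bundled `semantics_network()` exhibits both directions of this
  disagreement (a metabolite producible only through a cycle is
  FBA-producible but not scope-producible; a branch whose stoichiometric
  coefficient is unbalanced is scope-producible but FBA-blocked).

`compute_scope()` runs a counting queue (each reaction tracks how many
reactants are still missing), which is linear in the total reactant degree;
the result is independent of iteration order, and a naive sweep-to-fixpoint
oracle confirms this in the test suite.

## The completion problem

Given a draft $R_{draft}$, a database $R_{db}$, seeds and targets, the solver
finds all sets $R_{fill} \subseteq R_{db}$ of minimum cardinality such that
every *reconstructable* target is in the scope of the seeds over
$R_{draft} \cup R_{fill}$. Because scope is monotone in the reaction set, the
targets producible with the whole database added form the unique maximal
achievable target set; `reconstructable_split()` resolves this before
minimization, and unreconstructable targets are reported, not failed on.
A reversible database reaction costs 1 and grants both directions: the
objective counts reactions, and reversibility is declared per reaction in
SBML.

Alongside the enumeration the solver reports the union (reactions in at least
one minimal completion — the headline output handed to manual curation) and
the intersection (reactions in every minimal completion; these are
indispensable to any parsimonious repair, and removing such a reaction from
draft ∪ database provably breaks some target).

### Solving strategy

The contract is exactness, not a particular solving technology. The solver:

1. **prunes** database reactions that can never fire even with the whole
   database active, or whose products cannot reach any target through the
   producer graph — neither kind can appear in a minimal completion;
2. **peels off forced reactions**: $r$ belongs to every completion iff
   dropping $r$ from the candidate pool (the most permissive context, by
   monotonicity) loses a reconstructable target. Forced reactions are granted
   and the reduction is iterated to a fixed point;
3. **searches the residual pool** by iterative deepening, enumerating all
   $k$-subsets at the first size $k$ that covers the targets.

On degraded-network instances the forced set absorbs the broken essential
routes and the residual pool holds only interchangeable alternatives, so the
exhaustive stage stays small. Every solver answer (counts, members, union,
intersection) is checked against a brute-force subset-search oracle on
hundreds of random instances in the acceptance suite; `solver_options()`
exposes an enumeration cap (which truncates only the reported list — union
and intersection stay exact) and a wall-clock budget that aborts with a typed
timeout error.

## Flux validation

`build_flux_model()` wraps a network with bounds
($[-1000, 1000]$ reversible, $[0, 1000]$ irreversible, the community
convention — classification is invariant under uniform scaling of these) and
one import exchange per seed. `fba_max()` maximizes the objective flux under
steady-state mass balance on non-boundary metabolites. `classify_reactions()`
runs flux variability analysis over the region with the biomass flux held at
or above a floor `delta` (default 1 flux unit): a reaction is *blocked* when
its flux interval is $\{0\}$, *essential* when the interval excludes 0, and
*alternative* otherwise. The floor — rather than pinning biomass at its
optimum — encodes "non-zero biomass production"; essentiality by this
definition coincides with knock-out lethality (forcing the flux to zero drops
the achievable biomass below `delta`), which the tests assert exactly. An
explicit LP tolerance of `1e-6` makes the classification reproducible in the
face of solver rounding.

The LP core is a dense two-phase primal simplex compiled with Rcpp (Dantzig
pricing with a Bland fallback against cycling). These stoichiometric LPs are
small, sparse-integer and well-conditioned; the implementation is
cross-checked against an independent LP solver on small models in the test
suite. Infeasible programs are reported as optimum 0 with a flag, since
"cannot run at all" is a meaningful verdict for a degraded network.

## The degradation benchmark

The harness reproduces, at configurable scale, the experimental design used
to evaluate topological gap-filling on a model organism:

1. `random_biomass()` zeroes each biomass reactant independently with
   probability `zero_prob` (Bernoulli draws; a draw that would empty the
   biomass is repeated);
2. reactions are classified against that biomass, and `degrade()` removes
   the same fraction from each class (essential / alternative / blocked),
   uniformly without replacement; per-class counts are rounded half away
   from zero and the largest class is adjusted by single reactions so the
   global fraction is exact. Classification is recomputed per random biomass
   before removal, since the classes are only defined relative to a biomass.
   Optionally the draw is repeated until the degraded network is
   FBA-nonfunctional (bounded at 100 retries);
3. the degraded network is gap-filled from the reference (the pre-degradation
   network serves as database), the **union** of minimal completions is added
   back, and `evaluate_completion()` measures: FBA functionality, recovery of
   removed essential reactions, the 3×3 class-drift matrix, and an outcome
   category (functional / all essentials recovered / one missed / several
   missed).

A structural theorem anchors the evaluation: any FBA-functional filled
network necessarily contains every reference-essential reaction, because
essential means "no biomass without it". The suite asserts this on every run.

### Scale

The default preset is one reference network × four removal fractions
(10–40%) × three degradation seeds on the bundled 100-reaction
`benchmark_model()` (13 essential / 61 alternative / 26 blocked at the
default biomass). These sizes keep a full benchmark pass within seconds
while exercising every code path; they are the package's smoke-test
conditions. Genome-scale grids — thousands of degraded networks drawn from
curated reconstructions, completed against a repository-scale reaction
database — are presets of the same functions (`fractions`, `rng_seeds`, and
the model argument), not a different code path. Results at desk scale are
property checks — stratified
counts within ±1 per class, the essential-recovery theorem, determinism —
and are not expected to reproduce percentages measured on genome-scale
networks, where minimal completions must choose among thousands of
alternative routes.

## Synthetic fixtures: what they emulate, and what not

`toy_instance()` is a hand-transcribed toy whose enumeration output (five
minimal completions of size 3, union of six reactions, intersection of one)
is pinned behaviorally by the test suite; `semantics_network()` pins the
scope-vs-FBA semantics. `planted_instance()` builds layered chains with a
known forced cut and an interchangeable bundle, plus distractors that are
either never firable (orphan reactant) or redundant (duplicate of a surviving
draft reaction) in equal proportion — exercising both pruning paths of the
solver. `benchmark_model()` wires an essential backbone, two-route
alternative branches and a blocked compartment.

None of these emulate real biochemistry: coefficients are unit, there are no
cofactors or compartments, and alternative routes are short. Passing tests
on them demonstrates algorithmic correctness (exactness of enumeration,
classification, stratification), not biological fidelity of any particular
completion.

## Numerical and design choices

* **Identifier matching** is exact string equality; database reactions whose
  id and definition both match a draft reaction are deduplicated silently,
  and any id shared with a *different* definition is a construction error.
* **Seeds/targets absent from every reaction** are kept as isolated
  metabolites; such a target is simply reported unreconstructable.
* **SBML subset**: Level 2/3, species `id`/`name`/`boundaryCondition`,
  reaction `reversible`, coefficients defaulting to 1 when the
  `stoichiometry` attribute is missing. An absent `reversible` attribute
  means reversible, the Level 2 default. The writer emits deterministic
  Level 2 v4 that the reader inverts exactly; golden checksums freeze the
  serialized form of the toy fixtures.
* **Ordering**: solutions are sorted lexicographically by their sorted
  reaction ids, so repeated runs are byte-identical.
* **Boundary metabolites** affect only the mass balance of the flux layer;
  scope ignores them, as the topological semantics has no boundary concept.
* **Randomness** is always funneled through an explicit integer seed and the
  RNG state of the caller is restored afterwards.

## Limitations

Scope-based producibility over-approximates flux-based producibility on
unbalanced stoichiometry and under-approximates it on self-sustaining cycles;
both directions are exhibited by `semantics_network()` and discussed above. The
practical remedy for cycle-locked pathways (cofactor loops, photosynthetic
electron chains) is to add a cycle member to the seeds. Cardinality-minimal
enumeration deliberately misses longer alternative routes; restoring *all*
routes is out of scope, as are weighted completions, gene–protein–reaction
associations, compartments and identifier cross-referencing between
databases.
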