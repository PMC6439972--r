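---
title: "Predicting multi-strand RNA complexes as constrained maximum-weight cliques"
author: "RNAComplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multi-strand RNA complexes as constrained maximum-weight cliques}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNAComplexes)
```

## The problem

RNAs assemble into complexes — ribosomal subunits, snoRNA--rRNA pairs,
riboswitch--trigger duplexes — held together by canonical base pairs
(Watson--Crick A-U and G-C, plus the G-U wobble). The secondary structure
of such a complex is the set of those pairs: pairs internal to each strand
(its secondary structure, possibly pseudoknotted) and pairs between
strands (interaction sites, possibly crossing one another). Predicting the
joint structure of more than two strands directly is hard, and tools that
concatenate the strands in some order can miss structures that the chosen
order forbids.

RNAComplexes takes a different route. Many mature tools already predict
single-strand secondary structures and pairwise interaction sites, with
sub-optimal alternatives. We treat those predictions as *candidates* and
ask: which combination of one structure per strand plus any number of
interaction sites forms the most stable, conflict-free complex? Both the
candidates and the question are agnostic to strand order, and pseudoknots
or crossing interactions survive as long as some candidate describes them.

## The graph model

Every candidate becomes a vertex of a *compatibility graph*:

* a **structure vertex** holds the base pairs of one candidate secondary
  structure of one strand (an always-present *empty structure* with no
  pairs guarantees that each strand can be left unfolded);
* an **interaction vertex** holds the base pairs of one candidate
  interaction site between two strands (non-crossing within the site;
  crossing arises between sites).

Two vertices are joined by an edge — are *compatible* — unless some
nucleotide position is paired in both of them, or they are both structures
of the same strand. Nothing else is forbidden: interleaved but
position-disjoint pair sets remain compatible, which is precisely how
pseudoknots and crossing interactions enter complexes. We deliberately
treat even a shared pair with the *same* partner as a conflict: merging
two candidates that re-predict the same pair would double-count its
energy, and such duplicates only arise from redundant inputs (duplicated
candidates are collapsed at graph build anyway).

An RNA complex is then a *constrained clique*: a set of pairwise
compatible vertices with exactly one structure vertex per strand, carrying
at least one base pair in total. The all-empty selection (a *weak*
clique) is excluded — it is not a complex. Each vertex carries a weight
derived from its free energy, and we search for maximum-weight constrained
cliques; the clique archive doubles as a pool of ranked sub-optimal
complexes, which matters because the native structure is often near, not
at, the free-energy minimum.

## Free energies and weights

Candidates may come from heterogeneous tools, so the package re-scores
every candidate with one of two models (Turner 2004 parameters, shipped as
a plain-text resource so energies are reproducible bit-exactly):

* **Nearest-neighbor model** for pseudoknot-free structures: loop
  decomposition into stacks, hairpin loops, bulges, internal loops,
  multiloops and the exterior loop, with terminal AU/GU penalties at helix
  ends. Dangling ends, coaxial stacking and loop terminal-mismatch bonuses
  are *not* modelled; on stems closed by loops of three and on bulges the
  model reproduces a reference evaluator exactly, while structures rich in
  larger hairpin loops or internal loops can deviate by a few tenths of a
  kcal/mol per loop.
* **Stacking-energy sum** for pseudoknotted structures, where the loop
  decomposition does not apply: the sum of stacking terms over adjacent
  pairs, isolated pairs contributing nothing.
* **Duplex model** for interactions: duplex initiation (+4.10 kcal/mol),
  stacks between consecutive pairs, bulge/internal-loop penalties for
  gaps, terminal AU/GU penalties at both duplex ends.

The solver maximizes total weight with `weight = max(0, -energy)`.
Clamping at zero makes the maximization well-posed: a destabilizing
candidate (positive free energy) is never preferred over leaving the
strand unstructured, yet it remains available for sub-optimal complexes.
A complex's energy is the plain sum of its members' energies — an
approximation that ignores inter-member loop context, shared by design
with the additive weight.

## The search heuristic

Finding maximum-weight cliques is NP-hard, so the package uses a breakout
local search specialized to the constraints, implemented in C++ for the
inner loop:

1. **Initial clique**: one random interaction vertex plus, per strand, a
   random compatible structure vertex (the empty structure guarantees
   feasibility).
2. **Descent**: repeatedly apply the best strictly-improving move until a
   local optimum. Moves preserve the constraints by construction: *add* an
   interaction vertex compatible with everything in the clique (the set
   `PA`), or *replace* a clique member by an outside vertex of the same
   kind that is compatible with everything else (the pair set `OM` —
   same-kind pairs are exactly what keeps one structure per strand).
3. **Perturbation**: at a local optimum, apply `L = ceiling(0.1 |V|)`
   weakly degrading moves — adds, replaces, or *removes* of interaction
   vertices — chosen greedily by least degradation among non-tabu moves. A
   degrading replace must retain at least `alphaS` of the clique weight; a
   removal may only take out a vertex worth at most `(1 - alphaR)` of it.
   Vertices leaving the clique are tabu for `phi` iterations. After `T`
   consecutive non-improving descents a **restart** fires instead: a
   random outside interaction is forced in, incompatible structures are
   repaired (empty fallback), incompatible interactions dropped.
4. Every distinct valid clique seen anywhere — descent, perturbation,
   restart — is archived. After all restarts the archive is deduplicated
   and energy-ranked.

Any move that would produce a weak clique is never offered.

Defaults (`solverConfig()`): 500 iterations per restart (one iteration =
one descent plus one perturbation), 5 restarts, `lFrac = 0.1`, `T = 10`,
`alphaS = alphaR = 0.5`, `phi = 7`, `p0 = 1` (perturbations are always
directed; setting `p0 < 1` mixes in uniformly random moves). All
randomness flows from one integer seed through a dedicated xorshift64*
generator, so runs are bit-reproducible across platforms and independent
of R's RNG state.

Numerical/design choices worth knowing:

* Ties among equal-delta moves are broken uniformly at random (seeded).
* The non-improvement counter resets after a restart, so restarts are
  followed by a fresh intensification phase rather than an immediate
  second restart.
* Weight comparisons use an absolute 1e-12 guard; archived weights are
  re-summed exactly from the member weights.
* Graphs with no interaction candidate are rejected with a diagnostic: the
  object of study is a complex, and silently returning single-strand
  foldings would misrepresent the result.
* Tabu tenure counts solver iterations, not individual perturbation moves.

## Ranking, symmetry, evaluation

Strands with character-identical sequences are interchangeable labels, so
one complex can reappear relabelled. `dedupAndRank()` canonicalizes each
archived complex — the lexicographically minimal serialization of its pair
set over all within-class strand permutations (exact up to a class size of
6, identity fallback with a warning beyond) — keeps the lowest-energy
representative per canonical form, sorts by total free energy (ties by
canonical key, for determinism) and truncates to `maxSolutions`
(default 10).

`confusionCounts()` scores a prediction against a reference complex at
base-pair level. The negative universe is all unordered position pairs
across the complex, `N(N-1)/2`, the most inclusive convention (the
alternative — only canonically pairable position pairs — would shrink TN
and raise MCC slightly; the choice is documented here because MCC depends
on it). Sensitivity, PPV, F1 and MCC follow the standard formulas with
zero-denominator cases returning 0 so that means over many runs never
propagate NaN. Both pair sets are canonicalized under strand symmetry
first, so a symmetric relabelling is not penalized.

Because the returned list is ranked by *energy* while the exhaustive
oracle naturally ranks by *weight*, comparisons between the two (tests,
acceptance script) rank the oracle's enumeration by energy as well. The
two orders differ exactly when weight-0 (clamped) members create weight
ties that energy resolves; comparing like-for-like keeps the check
meaningful.

## The synthetic test bed

`generateInstance()` builds random instances that exercise every layer
without external tools: random sequences; helix-based structure candidates
(stems of 4--6 pairs with hairpin loops of at least 3, pseudoknotted
two-helix candidates with the configured probability); duplex-shaped
interaction candidates. Canonicity is guaranteed by *fill-in*: pair
positions fix the sequence letters as they are placed, so the energy
models never reject a generated candidate. The `overlapProb` knob anchors
candidates on already-used positions, injecting the shared-nucleotide
conflicts that make the clique search non-trivial; `duplicateStrands`
copies strand 1 onto strand 2 and mirrors its candidates to exercise
symmetry deduplication.

With `plantOptimum = TRUE` the instance contains a known unique optimum:
per strand a pure-GC stem (strongly stabilizing), plus one strong GC
duplex, all position-disjoint; every decoy candidate is both weight-0
(too short to be stable) and anchored on a planted position, so nothing
can extend or beat the plant. The constrained optimum therefore equals
the plant *by construction*, which `bruteForceOptimum()` — an independent
exhaustive enumeration over (structures per strand) x (interaction
subsets), guarded at 2e6 combinations — re-confirms in the tests.

What the generator does **not** emulate: thermodynamically realistic
sequence--structure co-distributions, tool-specific candidate noise,
modified nucleotides, non-canonical pairs, or candidate sets hundreds
deep. Passing the synthetic suite therefore shows the machinery is
correct — compatibility, energies, search, ranking, symmetry — not that
predictions on biological complexes reach any particular accuracy; that
depends on the quality of the candidate inputs supplied.

## Problem sizes used by the tests

The test suite and the acceptance script run at sizes chosen to make the
exhaustive oracle exact and the suite brisk: 3 strands of 20--40 nt, up to
4 non-empty structure candidates per strand, 2 interaction candidates per
pair (at most 8 total), overlap probability 0.3; 100 instances for the
optimality comparison, 1000 (mixed 2- and 3-strand) for constraint
integrity, 50 planted instances at 10 restarts, 200-move traces for the
set-maintenance equivalence. Graphs this size have about 20 vertices and
at most a few tens of thousands of enumerable constrained cliques.

## A small worked example

```{r example}
ss <- StrandSet(c(A = "GGGAAACCCACGCGC", B = "GCGCGUAAGGGAAACCC"))
st <- list(parseDotBracket("(((...)))......", "A", ss),
           parseDotBracket("........(((...)))", "B", ss))
it <- list(interactionVertex("A", "B", cbind(9:14, 5:0)))
preds <- predictComplexes(ss, st, it, solverConfig(seed = 7))
preds[[1]]
renderDotBracket(vertexPairs(preds[[1]]), ss)
```

The rank-1 complex folds both stems and hybridizes the 6-bp duplex; its
energy is the sum of the three member energies.

## Known limitations

* Energies are additive over members; inter-member multiloop context,
  dangles and coaxial stacking are ignored, so reported complex energies
  are comparative scores, not calorimetric predictions.
* The stacking-sum model underestimates the destabilization of
  pseudoknotted structures (no loop penalties), slightly favoring
  pseudoknotted candidates with many stacks.
* Symmetry canonicalization is exact only up to 6 identical strands per
  class (factorial growth beyond).
* Prediction quality is bounded by the candidate sets: a pair present in
  no candidate can never appear in a predicted complex.
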