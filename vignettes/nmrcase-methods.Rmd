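---
title: "Constitution generation from 2D NMR data and the statistical environment filter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitution generation from 2D NMR data and the statistical environment filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrcase)
```

## The problem

Computer-assisted structure elucidation (CASE) starts from the observation
that 2D NMR experiments report *through-bond relationships* between atoms,
not structures. HSQC fixes how many protons each carbon carries; COSY cross
peaks arise from vicinal H–H coupling, so the two H-bearing heavy atoms must
be directly bonded; HMBC cross peaks arise from 2- and 3-bond H→C (or H→N)
coupling, so the two heavy atoms are one *or* two bonds apart — an ambiguity
that is the central difficulty of the whole field; 1,1-ADEQUATE resolves it
for protonated carbons by reporting one-bond C–C connectivity directly.

Given a molecular formula and these constraints, the set of chemically
possible constitutions (molecular graphs without stereochemistry) is finite
and can be enumerated exhaustively. For saturated molecules the set is often
a single structure; for unsaturated and proton-poor molecules — condensed
heterocycles especially — it can run to thousands or hundreds of thousands.
`nmrcase` implements both the exhaustive generator and a *statistical
filter* that removes candidates containing atom environments never seen in a
reference corpus of known molecules, shrinking the candidate list without
ever discarding a structure whose local chemistry is precedented.

## From correlations to path constraints

`compile_constraints()` translates each correlation into the set of
heavy-atom bond-path lengths it permits:

| experiment     | allowed heavy-atom path lengths |
|----------------|---------------------------------|
| COSY           | {1}                             |
| ¹³C-HMBC       | {1, 2}                          |
| ¹⁵N-HMBC       | {1, 2}                          |
| 1,1-ADEQUATE   | {1}                             |

Multiple correlations on the same unordered atom pair are intersected.
Because every experiment's allowed set contains length 1, an empty
intersection cannot arise from these four experiment types; the
"contradictory correlations" guard in the compiler exists for future
correlation types with disjoint length sets. A `--allow-4bond` flag widens
HMBC to {1, 2, 3} for the occasional 4-bond correlation.

A constraint is *satisfied* when **some simple path** of an allowed length
joins the two atoms, not when the shortest path length is allowed. The
distinction matters in rings: in cyclopropane two carbons are simultaneously
in a 1-bond and a 2-bond relationship, and a 2-bond HMBC peak between them is
perfectly explained even though the shortest path has length 1. Requiring
the shortest path to be allowed would over-constrain cyclic molecules, so
the any-path dialect is the package default (and the only implemented
semantics). Paths may run through NMR-silent heteroatoms: an H–C–O–C–H
COSY relationship does not exist, but an HMBC path through oxygen does.

Exchangeable protons (OH, NH on unobserved atoms) carry no reliable
correlation information and are out of scope: H counts are declared only on
observed C/N atoms, and leftover formula hydrogens are distributed over the
silent heteroatoms by the generator.

## The generator

`enumerate_constitutions()` assigns a bond order (0–3) to every heavy-atom
pair depth-first in a fixed lexicographic order, with constraint
propagation:

* `{1}`-constraints become **mandatory edges** (order ≥ 1); if an atom's
  required adjacencies exceed its free valence the run aborts before any
  search.
* Remaining valence is tracked per atom and checked **exactly** the moment
  an atom's last pair is assigned.
* Hybridizations map to multiple-bond patterns — sp³: no multiple bonds;
  sp²: exactly one double; sp: one triple or two cumulated doubles — and are
  pruned as soon as a partial assignment violates them. An `open` atom (or a
  run with `open_types = TRUE`, the "no atom types defined" mode) admits any
  valence-legal pattern, which is exactly the union of the three
  hybridization patterns, so open-type runs need no outer enumeration loop.
* A capacity bound (`remaining valence ≤ max bond order × remaining pairs`)
  prunes branches that can no longer consume an atom's valence.

Leaves are checked for connectivity, minimum ring size, and the full
constraint set, then deduplicated by canonical key. Because membership of
the result set is decided per isomorphism class, the output is independent
of atom input order and of the pair ordering heuristics.

Silent heteroatoms (O, S, halogens) are divalent/monovalent per the fixed
valence table (C=4, N=3, O=2, S=2, halogens=1) but carry **no
multiple-bond-pattern restriction**: a silent O may accept a double bond, so
carbonyl groups are expressible even though O's hybridization is never an
input. Restricting silent O to single bonds would exclude ketones, esters
and lactones — the very motifs the filter literature discusses — which is
why the package treats the hybridization machinery as applying to observed
C/N only. Neutral molecules only are generated; the valence model for
charged atoms (`sum of bond orders + H + |charge| = standard valence`)
exists in the data model and codecs but the generator does not place
charges.

`brute_force_enumerate()` is the independent correctness oracle: the same
pair loop with *only* valence pruning, every other check applied at the
leaves, no mandatory edges, no pattern propagation. It is exponentially
slower and refuses more than 7 heavy atoms, but any discrepancy between the
two routes on the same input is a bug by definition, and the test suite
asserts key-set equality on seeded batches of toy problems.

### Canonical keys and Kekulé normalization

Deduplication needs a string invariant under labeled-graph isomorphism.
The key is computed from a canonical vertex labeling (BLISS, via igraph) of
a bond-subdivided graph: each bond becomes an auxiliary vertex colored by
its order, each atom a vertex colored by (element, charge, H count), which
reduces edge-colored to vertex-colored canonical labeling. Before keying,
six-membered C/N rings whose ring bonds alternate single/double are flagged
aromatic and their bonds rendered with a dedicated order token, so the two
Kekulé forms of a benzenoid or pyridine-type ring collapse to one key. The
same normalization feeds the environment keys below, for the same reason: a
Kekulé choice must not split one chemical environment into two dictionary
entries. Full Hückel aromaticity perception (5-membered heteroaromatics,
fused edge cases) is deliberately out of scope; those rings are handled in
whichever Kekulé form they arrive, consistently on both the corpus and the
candidate side, because both sides pass through the same OpenBabel
kekulization and the same keying code. Atom ids (the NMR shift labels) are
ignored by the key: two shift assignments of the same graph are one
constitution, and the result counts reflect that.

## The statistical filter

The filter re-casts "a force-field parameterization would fail on this
substructure" as a dictionary test on **one-sphere (radius-1) atom
environments**: the key of an atom is its element, formal charge, H count
and the sorted multiset of (neighbor element, bond order) pairs — e.g. the
central carbon of acetic acid is `CH0(C:1,O:1,O:2)`. `build_reference()`
counts every atom of every corpus molecule; `filter_candidates()` keeps a
candidate iff every one of its keys is present (count ≥ `min_count`,
default 1: pure presence/absence, matching a binary parameterization
success/failure). No ranking of survivors is performed, by design.

Two properties follow directly from this construction and are asserted as
seeded property tests:

* **Safety** — a candidate all of whose environments occur in the reference
  can never be removed; in particular the true structure survives whenever
  the corpus covers its chemistry. This is the filter's headline guarantee.
* **Monotonicity / idempotence** — growing the corpus can only grow the kept
  set, and refiltering a kept set removes nothing.

The radius-1 recast is intentionally more local than the multi-atom
substructures (e.g. a fused oxet-2-one) one might diagnose by eye in removed
candidates: a rare four-atom motif is invisible to the dictionary unless one
of its constituent one-sphere environments is itself unseen. In practice
strained or exotic motifs do contain unseen one-sphere environments, and
`summarize_missing()` tabulates which missing keys drove the exclusions so
the user can recognise the offending substructure.

## The forward model and what the synthetic data covers

`forward_correlations()` inverts the constraint semantics: COSY peaks for
every bonded pair of protonated observed atoms, HMBC/¹⁵N-HMBC peaks for
every C/N and protonated atom joined by a simple path of heavy-atom length 1
or 2, ADEQUATE peaks for bonded carbon pairs with a protonated member. With
`dropout = 0` the compiled constraints are satisfied by the source structure
*by construction*, which closes the package's central test loop: every toy
structure must be a member of the candidate set generated from its own
correlations. Dropout removes correlations independently with a fixed seed,
modelling sparse spectra; losing constraints can only grow the candidate
set, which the tests witness from the data side.

`make_toy_structures()` grows random connected valence-legal molecules
(spanning tree, occasional ring closure, occasional bond-order upgrades) of
2–7 heavy atoms with C-rich element weights; `make_reference_corpus()` uses
the same machinery with heteroatom-richer weights as a desk-scale stand-in
for a large corpus of known compounds. What the synthetic data does **not**
emulate: realistic chemical-shift values (shifts are carried but never
interpreted), peak intensities and artifacts beyond dropout, molecules
beyond 7 heavy atoms, and the empirical environment distribution of real
compound databases. Passing tests therefore demonstrate the combinatorial
and logical guarantees (completeness, soundness, safety, monotonicity) at
desk scale — not that the filter's *reduction percentages* on real
natural-product data are reproduced, which depend on corpus and molecule
class.

## Numerical and design choices

* **Problem sizes.** Tests and the acceptance script use 20 problems for
  oracle equivalence, 50 for round-trip completeness, 500 (structure,
  corpus) safety trials and 100 anti-monotonicity trials, at 2–6 heavy
  atoms; these sizes give the brute-force oracle headroom while exercising
  every code path, and complete in a few minutes on one CPU.
* **Valence table** fixed at C=4, N=3, O=2, S=2, halogens=1; neutral
  molecules only. Amide-style N is therefore trivalent; protonated or
  N-oxide nitrogens are out of scope of generation (the codecs accept them).
* **`min_ring_size` default 3**: every chemically expressible ring is
  allowed, and rarity is the filter's job, not the generator's. The same
  logic admits heteroatom–heteroatom bonds by default (peroxide natural
  products exist), with `forbid_hetero_hetero` as the stricter flag.
* **`max_results` default 10⁶** with an explicit truncation flag in the run
  metadata — results are never silently dropped.
* **Determinism.** All randomness (toy generation, corpora, dropout) is
  seed-scoped and restores the caller's RNG state; generation itself is
  deterministic, and file outputs are canonical SMILES sorted lexically so
  reruns diff clean.
* **Ties and degenerate inputs.** Zero-correlation inputs are legal
  (unconstrained enumeration); a single heavy atom with full-valence H (CH₄)
  is legal; an empty reference corpus is refused rather than silently
  eliminating every candidate.

## Limitations

Stereochemistry, tautomer enumeration, chemical-shift prediction and any
ranking of surviving candidates are out of scope. The generator is exact
but exponential: it is built for the constraint densities real 2D NMR data
provides, and the package's own validated envelope is ≤ 7 heavy atoms
(the oracle limit); larger runs work but are unverified against the oracle
and can be slow in open-type mode. Aromaticity normalization covers
six-membered benzenoid/pyridine rings only.
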