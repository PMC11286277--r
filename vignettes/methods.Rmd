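---
title: "Methods: similarity-tree search spaces and embedding evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-tree search spaces and embedding evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open when it was designed, and what its tests do and
do not demonstrate.

## 1. Fragmentation model

A molecule is decomposed by cutting every **acyclic single bond with at
least one endpoint in a ring**. This severs ring-substituent bonds and
direct ring-ring linkers (the biphenyl bond) but never opens a ring; fused
ring systems stay intact, and a molecule without ring atoms is its own
single fragment with zero attachment points. Each cut leaves a dummy-atom
attachment marker on both sides. Markers are isotope-indexed `[1*]`,
`[2*]`, ... within each fragment, numbered by canonical atom rank, so that:

* a topology table `(fragment, slot, fragment, slot)` records exactly how
  the molecule reassembles, making `assemble(decompose(x)) == x` an exact
  canonical-SMILES identity (asserted on a 50-molecule fixture set), and
* the same chemical fragment obtained from different molecules has the same
  canonical marker-bearing SMILES, which is the fragment's identity for
  de-duplication.

Reassembly resolves marker pairs into single bonds and refuses to return a
structure that fails valence sanitization. When a fragment is substituted
for another with the same number of attachment points, the slot pairing is
the identity mapping; for symmetric fragments any mapping gives the same
molecule, for asymmetric ones it is an arbitrary but deterministic choice.
Stereochemistry is preserved where the toolkit keeps it through cutting;
fragments that lose stereo assignments are accepted as-is.

A known openness of the fragmentation literature is whether linker-linker
bonds (acyclic bonds between two non-ring atoms) should also be cut; only
the ring-incident rule is implemented here, because it is the rule the
embedding model needs: every fragment then contains either a ring system or
a terminal substituent, and attachment counts are stable under substitution.

## 2. Fragment similarity and its two terms

Pairwise fragment similarity is

```
A_sim(i, j) = max( Tan_MCS(f_i, f_j), Lev(f_i, f_j) )
```

* `Tan_MCS` is `|MCS| / (|f_i| + |f_j| - |MCS|)` over heavy atoms, with the
  maximum common substructure required to match elements, bond orders, and
  ring bonds only to ring bonds. Attachment markers are stripped before
  matching (they are placeholders, not atoms). The MCS search gets a 1 s
  budget per pair; on timeout the best bound found so far is used. Dummy
  atoms never count as heavy atoms, so `|f|` is the true heavy-atom count.
* `Lev` is a string **similarity**: `1 - d_edit / max(len)` over the
  canonical marker-bearing fragment SMILES, defined as 1 when both strings
  are empty. Normalization is forced by the `max(...)`: a raw edit
  *distance* is unbounded and dimensionally incomparable with a Tanimoto
  similarity in `[0, 1]`. The strings include the attachment markers
  because they are part of the fragment's identity.

Molecule-level similarity (the SIM objective) is Tanimoto on circular
radius-2, 2048-bit fingerprints.

## 3. The similarity tree and path codes

The tree is built greedily. Step 1 repeatedly extracts the globally most
similar unpaired fragment pair into a two-leaf subtree (`ceiling(n/2)`
groups; an odd leftover becomes a subtree with only a left leaf). Step 2
pairs subtrees round by round — tree-to-tree similarity is the maximum
`A_sim` over cross-tree fragment pairs — halving (by ceiling) the forest
each round until one tree remains. Every internal node is virtual; the
root-to-leaf path with left = 0 / right = 1 is the fragment's **path code**,
right-padded with 0 to `d = ceiling(log2 n)` bits (`d = 1` for a one-leaf
tree). Eight fragments therefore give a tree of four node levels (root =
level 1) with 3-bit codes; depth counted in edges equals the code length.
Because pairing is greedy-by-similarity, leaves sharing long code prefixes
are similar — this is what makes rear-position bit flips "small" moves.

The procedure as stated leaves several ties and orientations undefined; the
package fixes them deterministically:

* among equal similarities, the smallest (row, column) index pair wins;
* within a pair, the lower-index item goes left (and the odd leftover is a
  left-only leaf);
* when two subtrees merge, the one containing the lower-index fragment of
  the best cross pair goes left.

Decoding is total: the walk consumes bits, diverts to the existing child
when the requested one is absent, and stops at the first leaf reached.
During embedding decode, the walk is additionally restricted to subtrees
containing at least one leaf with the required attachment-point count, so a
decoded slot is always chemically substitutable; if no compatible leaf
exists anywhere the slot keeps its original fragment.

Expansion rebuilds the tree from scratch on the enlarged fragment set
(incremental insertion would disturb the greedy pairing structure); the
pairwise similarity computation is the cost that matters, and entries for
already-known pairs are reused from the matrix cache inside one session.

## 4. Embeddings and the evolutionary loop

A lead with `m` fragments is embedded as the concatenation of its fragment
codes (`m * d` bits, slot order = decomposition order). `m` is fixed for
the whole run: mutation replaces fragments but never changes their number,
because the fixed-length embedding is what the bit-flip operators act on.

* **Initial population.** `2M` distinct perturbations of the lead embedding
  (flip count uniform on `[1, 0.25 * m * d]`; the window widens
  automatically when `m * d` is too small to offer `2M` distinct
  neighbors), decoded, scored, reduced to `M` by non-dominated sorting plus
  crowding distance. A space whose embedding is too short to supply `2M`
  distinct bit vectors at all is refused as degenerate.
* **Mutation.** Uniform: every bit flips with probability `p`. Positional:
  bit `i` of each fragment code flips with probability `p + q*i`
  (1-based, validated to stay within `[0, 1]` at `i = d`). The positional
  operator is drawn with probability `1 - cos(pi/2 * Iter/Itermax)`, the
  uniform one with `cos(pi/2 * Iter/Itermax)`: early iterations favor
  uniform flips (which can hit front positions and jump between distant
  subtrees), late iterations favor rear-position refinement. Parents are
  chosen by binary tournament on (front rank, crowding distance); one
  offspring per selected parent, `M` per iteration.
* **Selection.** Elitist: parents and valid offspring are pooled and the
  best `M` survive by front rank, the split front ordered by descending
  crowding distance (ties keep index order). Invalid decodes (failed
  assembly) are reported as values and never reach scoring; the parent pool
  guarantees at least `M` valid candidates.
* **Samples and budget extension.** Offspring meeting every configured
  threshold `delta_p - Iter * eta_p` (clipped at the property's domain
  minimum) join the sample set. If the run reaches `Itermax` with fewer
  than `k` samples, `Itermax` grows by `Itermax0 / 2` up to a hard cap of
  `4 * Itermax0`.
* **Expansion.** Every `E` iterations, the generator receives the lead and
  the `k` most recent samples and proposes up to `gen_n` molecules; their
  fragments join the space, the tree is rebuilt, and every population
  member is re-encoded against the new tree (codes can lengthen when `n`
  crosses a power of two).

All randomness flows from one seed set at the start of
`run_optimization()`; two runs with the same seed are bit-identical.

### Default hyperparameters

| parameter | default | meaning / rationale |
|---|---|---|
| `M` | 20 | population size; desk-scale runs converge well below this cost |
| `N` | 20 | donor molecules seeding the space — the one concrete value used in the case study the design follows |
| `k` | 10 | minimum sample count before the budget stops extending |
| `Itermax0` | 50 | initial iteration budget |
| `p`, `q` | 0.05, 0.05 | flip-rate base and slope; keeps `p + q*d <= 1` for trees up to ~19 bits deep and yields per-code expected flips near 1 |
| `E` | 5 | expansion period (iterations) |
| `eta_p` | 0.001 | per-iteration threshold decay; `delta_p` defaults to the success threshold |
| initial flips | <= 25 % of bits | large enough to spread the first population, small enough to stay lead-like |

`SIM` is always appended to the objective list: staying near the lead is
part of every task definition, not an optional extra.

## 5. Property oracles

QED, Crippen logP and the Ertl synthetic-accessibility score are computed
by RDKit (the SA score via the toolkit's contributed implementation).
Penalized logP is `logP - SA_raw - max(0, largest_ring - 6)`; its
*improvement* over the lead (`PLogP_imp`) is the reported objective since
raw PLogP is unbounded. SA is exposed to the optimizer as the normalized,
higher-is-better `(10 - SA_raw) / 9`, which maps the raw 1-10 scale onto
`[0, 1]` to match the direction and range of the other bounded objectives
(the threshold `SA >= 0.7` then means "raw score at most 3.7").

DRD2 and GSK3B activity scorers are **synthetic surrogates**: fixed,
smooth, deterministic functions of cheap descriptors (aromatic rings, basic
amines, aromatic nitrogens, H-bond donors, molecular weight, sp3 fraction)
squashed through a logistic to `(0, 1)`. They exist so the multi-objective
machinery, the task predicates and the sample thresholds can be exercised
honestly end to end; their values carry no pharmacological meaning, and a
trained predictor can replace them through `register_scorer()` without
touching any other code.

Task success is conjunctive and inclusive (`>=`) over the configured
thresholds; the built-in tasks use QED >= 0.85 / PLogP_imp >= 3 / SIM >= 0.3
(Task I), QED >= 0.8 / DRD2 >= 0.4 / SIM >= 0.3 (Task II), and QED >= 0.7 /
GSK3B >= 0.4 / SA >= 0.7 / SIM >= 0.2 (Task III). The success rate over a
set of leads is the percentage with at least one succeeding molecule.

## 6. The synthetic fixture library

`make_fixture_library()` enumerates ring scaffolds (benzene, pyridine,
cyclohexane, thiophene, furan, piperidine, pyrimidine, cyclopentane)
decorated with one or two small substituents (methyl through acetyl),
assembled by the package's own fragment machinery, deterministically for a
given seed. It emulates the *shape* of a drug-like reference library — ring
cores with substituent diversity, every molecule decomposable into at least
two fragments — at a scale where exhaustive oracles are feasible.

It does **not** emulate: screening-library scale (tens of molecules, not
hundreds of thousands), scaffold diversity beyond eight cores, charged or
stereochemically annotated molecules, or realistic property distributions.
Consequently, passing tests demonstrate the correctness of the machinery
(roundtrips, invariants, schedules, selection, recovery of enumerable
optima) — not that the optimizer reproduces benchmark success rates on real
libraries with trained predictors.

## 7. Numerical and degenerate-input choices

* Similarities are clamped to `[0, 1]` by construction; no floating-point
  tolerance is applied to the `max()` in `A_sim` (ties fall through to the
  deterministic index tie-break).
* Crowding distance normalizes each objective by its front range;
  zero-range objectives contribute nothing (avoiding 0/0), and fronts of
  one or two points are all-infinite.
* An empty intermediate library is a warning at filter time and an error at
  selection time (with the advice to relax thresholds).
* One-fragment trees use `d = 1` by convention so embeddings are never
  zero-length; the degenerate-space error at population initialization is
  the intended failure mode for leads whose space cannot support `2M`
  distinct embeddings.
* Sample thresholds clip at the property's domain minimum, so unbounded
  properties (PLogP) decay forever while bounded ones stop at 0.

## 8. Test problem sizes

The suite exercises: 50-molecule decompose/assemble roundtrips; trees of 1
to 11 leaves against a repeated-argmax oracle and hand-traced 5-fragment
groupings; 100 random objective sets (up to 20 points, 2-3 objectives)
against an O(n^2) dominance oracle; 10,000-trial flip-rate checks for both
mutation operators against their closed forms (3 sigma); and ten seeded
end-to-end runs on a 16-fragment toy space whose optimum is proved
reachable by exhaustive enumeration of all slot-compatible assemblies,
requiring at least nine recoveries within 50 iterations. These sizes were
chosen so every expected value is computable by an independent oracle while
keeping the whole suite in the tens of seconds.

## 9. Known limitations

* The fragment count `m` of the lead is fixed; edits that change the number
  of fragments (growing a new substituent site) are out of reach of the
  embedding representation.
* Slot-to-slot marker pairing under substitution is deterministic but
  arbitrary for asymmetric multi-attachment fragments; both orientations
  are chemically valid, only one is explored per code.
* The default generator recombines known fragments; it cannot invent
  genuinely novel fragments the way a trained generative model can, so
  space growth stalls once the sample pool's fragment vocabulary is
  exhausted.
* MCS under a per-pair timeout makes the similarity matrix formally
  best-effort on very large fragments; at fixture scale the search is
  always exact.
* The persistent RDKit worker is one process per R session; parallel
  optimization of many leads should use separate R processes.
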