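# fragopt

Fragment-based multi-objective lead optimization over adaptive
similarity-tree search spaces.

## The problem

In lead optimization a medicinal chemist wants molecules that improve several
properties at once — drug-likeness (QED), penalized lipophilicity (PLogP),
predicted target activity, synthetic accessibility (SA) — while staying
structurally close to a given *lead* molecule (fingerprint Tanimoto
similarity, SIM). The chemical space of possible edits is vast and discrete;
fragment-based search makes it tractable, but a fixed, global fragment
vocabulary wastes most of its entries on fragments irrelevant to any one
lead.

`fragopt` gives every lead its **own** fragment search space and lets that
space grow during the search:

1. **Molecule-specific search space.** Reference molecules passing the
   task's property thresholds are ranked by similarity to the lead; the top
   *N* are decomposed by cutting every acyclic single bond incident to a
   ring atom, leaving attachment-marked fragments. The pooled fragments are
   organized in a **binary similarity tree**: fragments are paired greedily
   by the similarity `A_sim(i,j) = max(Tan_MCS(f_i, f_j), Lev(f_i, f_j))`
   (maximum-common-substructure Tanimoto vs. normalized string Levenshtein
   similarity of the fragment SMILES), then the subtrees are paired
   repeatedly — tree-to-tree similarity is the best cross-tree fragment pair
   — until one tree remains. Root-to-leaf paths (left = 0, right = 1) give
   every fragment a binary **path code** of length `d = ceiling(log2 n)`;
   fragments with long common code prefixes are similar.
2. **Evolutionary optimization.** A molecule with *m* fragments is embedded
   as the `m x d`-bit concatenation of its fragment codes. The population of
   *M* embeddings evolves by bit-flip mutation under two operators — uniform
   (every bit at the same rate) and positional (bit *i* of a code flips with
   probability `p + q*i`, favoring rear positions, i.e. small moves between
   similar fragments). The operators are scheduled by the weights
   `w1 = 1 - cos(pi/2 * Iter/Itermax)` (positional) and
   `w2 = cos(pi/2 * Iter/Itermax)` (uniform), so the search moves from
   coarse jumps to local refinement. Decoded offspring are scored on all
   objectives and survivors are chosen by non-dominated (Pareto) sorting
   with crowding distance. Molecules passing the decaying thresholds
   `delta_p - Iter * eta_p` are collected as **samples**; the iteration
   budget extends itself until at least *k* samples exist.
3. **Adaptive expansion.** Every *E* iterations a pluggable generator
   proposes new molecules from the lead and the most recent samples (the
   default recombines attachment-compatible fragments of those molecules; a
   neural generator can be registered behind the same interface). Their
   fragments join the space and the tree is rebuilt — the search space only
   ever grows.

All chemistry primitives (SMILES canonicalization, fragmentation,
reassembly, MCS, Morgan fingerprints, QED / Crippen logP / SA scoring) are
delegated to RDKit through a persistent Python worker that the package
starts on first use and talks to over a local socket. DRD2 and GSK3B ship as
deterministic *synthetic surrogates* behind the scorer registry, so the full
pipeline runs without trained activity models; real predictors drop in via
`register_scorer()`.

## Worked example

```r
library(fragopt)

lib  <- make_fixture_library(6, 8, seed = 0)   # 76 synthetic drug-like molecules
lead <- "Cc1ccncc1"

cfg <- task_config(objectives = c("QED", "SIM"),
                   success    = c(QED = 0.62, SIM = 0.35),
                   delta      = c(QED = 0.5,  SIM = 0.2),
                   M = 10, N = 10, k = 3, Itermax0 = 20, seed = 1)

res <- run_optimization(lead, lib, cfg)
print(res)
#> Optimization of Cc1ccncc1
#>   iterations: 20  population: 10
#>   samples: 6  successes: 1
#>   search space: 11 -> 11 fragments
#>   best (by objective sum): Cc1ccncc1

head(res$population[order(-res$population$QED), c("smiles", "QED", "SIM")], 1)
#>               smiles      QED SIM
#>  c1cc(-c2ccncc2)ccn1 0.631773 0.5
```

The run found one molecule meeting both success thresholds: a bipyridyl
analogue with QED 0.632 (lead: 0.537) at SIM 0.5 to the lead. `res$samples`
holds the threshold-passing molecules collected along the way,
`res$history` the per-iteration operator weights, best/mean objectives and
space size, and `res$space$size_history` the growth of the fragment library
(`space_growth_percent()` turns it into a percentage).

The similarity tree itself is inspectable:

```r
tree <- build_tree(fixture_fragments(8))
print(tree)
#> Fragment similarity tree: 8 fragment(s), code length 3 , 4 node level(s)
#>         smiles code n_attachments
#> 1        [1*]C  110             1
#> 2 [1*]c1ccccc1  000             1
#> ...
```

A shell interface wraps the same functions
(`Rscript inst/cli/fragopt.R optimize --config run.yaml`), with subcommands
`build-space`, `optimize`, `evaluate` (success rate over result folders) and
`fixtures`; see `?cli_main`.

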