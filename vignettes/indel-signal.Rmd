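---
title: "Indels between quartet blocks as phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indels between quartet blocks as phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapquartet)
```

## The model

`gapquartet` infers phylogenies from insertions and deletions without
computing alignments. The underlying object is the *quartet block*: one
spaced word — defined by a binary pattern $P \in \{0,1\}^{\ell}$ with $w$
match positions — occurring in four different input sequences. A block is a
local, gap-free four-way alignment of length-$\ell$ segments. Within a
block no gaps are possible by construction, so indel information must come
from *between* blocks: for a pair of blocks $(B_1, B_2)$ involving the same
four sequences, with $B_1$ strictly left of $B_2$ everywhere, the
inter-block distance in sequence $\iota$ is

$$D_\iota = k_2 - k_1 - \ell_1,$$

the length of the segment separating the blocks. If both blocks are true
homologies, then $D_i \neq D_j$ implies at least one indel on the path
between $i$ and $j$ since their last common ancestor, while $D_i = D_j$
requires none.

Treating the distance as a character and $D_\iota$ as its state, small
parsimony on a quartet tree gives the support classes:

* $D_i = D_j \neq D_k = D_l$: topology $ij|kl$ costs one indel, both
  alternatives cost two — the pair **strongly** supports $ij|kl$;
* $D_i = D_j$ with $D_k \neq D_l$ both unequal to $D_i$: all three
  topologies cost two indels, but under any model in which an indel occurs
  on each branch independently with probability $p < 0.5$, $ij|kl$ has the
  higher likelihood — the pair **weakly** supports $ij|kl$;
* all other distance multisets (all equal, three equal, all distinct) do
  not discriminate between topologies and the pair is discarded.

`classify_support()` implements exactly this case analysis;
`min_indel_events()` is the corresponding two-internal-node Fitch
computation, and the two are consistent by construction (the test suite
verifies the equivalence exhaustively over all $5^4$ distance vectors with
entries in $\{0,\dots,4\}$).

### Assumptions

The signal is only as good as the homology of the blocks. The score filter
(below) makes random reference blocks rare but not impossible, and the
second block is deliberately unfiltered — its support comes from
uniqueness within a small window. Distances are compared by exact integer
equality: two indels of equal length on the two sides of a cherry cancel,
and an indel pair on one lineage that happens to restore the original
distance is invisible. Both effects bias towards *missing* signal rather
than inventing it, which is the right direction for a method meant as
complementary evidence.

## Parameters

* **Reference pattern** (`default_pattern()`): length $\ell = 110$ with
  $w = 10$ match positions, hence 100 don't-care positions. Only length and
  weight are fixed by convention; the mask layout (match positions every 12
  positions) is a deterministic choice made for reproducibility — the
  package does not optimise patterns, and users can supply any mask
  starting with `1`.
* **Substitution matrix** (`default_score_matrix()`): the symmetric
  nucleotide matrix used by the filtered spaced-word-match family
  (A/A = 91, C/C = G/G = 100, T/T = 91; transitions −31, transversions
  −114 to −125). Positive diagonal and negative off-diagonal entries make
  homologous don't-care columns score positive and background negative. A
  plain-text reader (`read_score_matrix()`) allows exact substitution.
* **Score threshold**: the three non-anchor occurrences must score
  *strictly above zero* against the anchor (`min_score = 0`,
  configurable).
* **Second-block pattern**: `1111111`, i.e. exact 7-mer matches; no score
  is computed for the second block because a common unique 7-mer in four
  500 nt windows is already unlikely by chance.
* **Window** `L = 500` nt to the right of the reference block, anchored at
  the first position after the block, clipped at the sequence end;
  candidate occurrences must fit entirely inside the window.
* **Sampling**: up to `max_blocks` (default $10^6$) reference blocks;
  words are visited in seeded random order, one quartet drawn per eligible
  word by default (random anchor, three random other sequences, bounded
  retries when the filter fails). All randomness flows through a single
  seed, so runs are byte-reproducible.

## Numerical and design choices

Several points are underdetermined by the verbal description of the method;
the package fixes them as follows.

* **Coordinates** are 1-based and closed throughout, matching R string
  semantics and `ape`/`Biostrings` conventions. The distance
  $D = k_2 - k_1 - \ell_1$ is invariant under the coordinate convention.
* **Choice of the second block**: candidate words must occur exactly once
  in *each* of the four windows; candidates are ordered by start position
  in the anchor taxon with ties broken lexicographically, and the first is
  taken. Uniqueness is only required of the second block's word — the
  reference block is already protected by its score filter.
* **Character encoding**: within a column, the first distance seen in
  ascending taxon order becomes `0`, the next new value `1`, then `2`;
  uninvolved taxa are `-` (missing). The symbols are arbitrary labels —
  only equality matters — so this canonical assignment changes nothing
  except making output deterministic. Missing cells receive the full state
  set in the Fitch pass (standard missing-data treatment), so they never
  contribute changes.
* **Weak columns** are included in the character matrix by default
  (every informative pair is one column); because a weak column has state
  multiset $\{x,x,y,z\}$, it costs exactly 2 on *every* tree and is
  parsimony-uninformative — including it cannot change the optimum, a
  property the test suite asserts. `strong_only = TRUE` reproduces the
  strong-pairs-only regime for both tree methods.
* **Parsimony search**: exhaustive enumeration of all unrooted topologies
  up to 8 taxa (10395 trees); beyond that, seeded random-order stepwise
  addition followed by nearest-neighbour-interchange hill climbing with
  multiple restarts. NNI with restarts was chosen over
  tree-bisection-reconnection because at the problem sizes this package
  targets it reaches the exhaustive optimum in every test case while being
  considerably simpler; ties between equally parsimonious trees are broken
  by a canonical Newick ordering (`canonical_newick()`), the deterministic
  analogue of "take the first reported tree".
* **Quartet amalgamation** is self-contained rather than delegating to an
  external max-cut program: each quartet $ab|cd$ votes for cuts separating
  its cherries ("good" cross pairs) and against cuts splitting a cherry
  ("bad" within pairs); the cut maximising the weighted good/bad ratio
  (violation-free cuts with support rank highest) is applied recursively,
  with the off-side contracted to a placeholder leaf so rooted triplet
  information survives the recursion. On a conflict-free covering quartet
  set this provably returns a tree displaying every quartet (verified on
  random trees); under conflict, weighted majority wins. Cuts are
  enumerated exhaustively up to 14 taxa and found by seeded local search
  above. The quartet list can be exported (`export_quartets()`) for users
  who prefer an external amalgamation tool.
* **Degenerate inputs**: windows containing non-ACGT symbols produce no
  spaced word (the score would be undefined); sequences shorter than the
  pattern contribute nothing; an empty informative-pair set is an error at
  tree-building time rather than a silent star tree. Only the forward
  strand is scanned — reverse complements would create block pairs whose
  distances mix coordinate systems, and the method's own description never
  invokes them.

## The synthetic-data generator

`simulate_sequences()` evolves a uniform-random root sequence along a tree
with branch lengths in expected substitutions per site: Jukes–Cantor
substitutions (each site substituted with the exact JC probability
$\tfrac{3}{4}(1 - e^{-4t/3})$), and indels as a Poisson process with
`indel_rate` events per site per unit branch length, equiprobable
insertion/deletion, uniform positions and geometric lengths (default mean
5 nt). The default `indel_rate = 0.1` makes indels about one tenth as
frequent as substitutions, a ratio in the range reported for nuclear DNA;
the 8-taxon recovery experiments use a balanced tree with 0.02
substitutions/site per branch and a 50 kb root, which yields on the order
of a hundred indels per branch — enough that block pairs regularly span an
indel, without degrading block discovery.

What the generator emulates: point substitutions, length-changing indels,
and the resulting equal/unequal inter-block distances — i.e. exactly the
features the method consumes. What it does not emulate: rearrangements,
duplications, GC bias, rate heterogeneity, or realistic repeat structure.
A green recovery test therefore establishes that the pipeline correctly
extracts and amalgamates indel signal under its own model assumptions; it
says nothing about robustness to repeats or segmental duplication, which
on real genomes are handled only indirectly (repeats defeat the
uniqueness requirement of the second block and the score filter of the
first).

Every simulated indel is written to an event log (branch, position,
length, type), which the tests use to assert causality: with events
confined to a single internal branch, every informative pair must support
the cherry that branch separates, and a planted indel strictly between
two blocks shifts the affected distances by exactly its length.

## Limitations

* Short or highly divergent sequences yield few reference blocks, and the
  method degrades with them (few informative pairs, low coverage) — it is
  designed as an *additional* source of evidence, not a replacement for
  substitution-based inference.
* Indel lengths are ignored: a pair only records which sequences changed,
  not by how much. Modelling lengths (or a probabilistic indel model
  replacing the parsimony step) is future work.
* Block pairs are restricted to quartets; blocks spanning more sequences
  would carry more information per pair but need a different support
  calculus.
* The desk-scale in-memory index is not meant for gigabase genomes.
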