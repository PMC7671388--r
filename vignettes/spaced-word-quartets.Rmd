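---
title: "Alignment-free phylogeny from spaced-word quartet blocks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free phylogeny from spaced-word quartet blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaq)
```

## The problem and the approach

Estimating a phylogeny for a set of genomes normally starts from a multiple
sequence alignment, which becomes impractical at whole-genome scale. `spaq`
reconstructs an unrooted tree *topology* directly from unaligned DNA, in
four stages:

1. **Spaced words.** A binary pattern $P \in \{0,1\}^\ell$ with $w$ match
   positions (`1`) and $\ell - w$ don't-care positions (`0`) defines a
   spaced word: the nucleotides observed at the match positions of a
   length-$\ell$ window. Both strands of every input genome are scanned
   and every window indexed by its spaced word.
2. **Quartet P-blocks.** Four occurrences of the same spaced word in four
   *different* taxa form a gap-free $4 \times \ell$ micro-alignment. A
   block is accepted as *homologous* when some anchor row has a positive
   substitution score against each of the other three rows, summed over
   all $\ell$ columns with the fixed scoring matrix `default_matrix()`
   (positive diagonal, strongly negative transversions, mildly negative
   transitions). Blocks are sampled randomly, each accepted occurrence is
   removed, and sampling stops at the cap $M$ or when anchors repeatedly
   fail.
3. **Quartet maximum likelihood.** For each block the three unrooted
   4-leaf topologies are evaluated under GTR+$\Gamma$ by Felsenstein
   pruning; the best topology is kept unless the top-two log-likelihood
   gap is below a tie tolerance, in which case the block is
   *inconclusive* and discarded.
4. **Supertree.** The conclusive quartet topologies are amalgamated with
   a MaxCut-style recursion: the taxon set is repeatedly bipartitioned by
   a cut minimizing a good/bad edge ratio, every cut becoming a split of
   the output tree.

The package also ships a sequence-evolution simulator and Robinson–Foulds
(RF) utilities, so the whole pipeline is testable end-to-end against known
ground truth without any external data.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| pattern length $\ell$ | 110 | nt | long don't-care context separates homologous from background matches |
| weight $w$ | 10 | match positions | low weight keeps the match count high; raise (e.g. 12) for very large data sets |
| block cap $M$ | $10^6$ | blocks | run-time control; a few hundred blocks suffice for small taxon sets |
| tie tolerance | $10^{-3}$ | log-likelihood | below this gap a block is inconclusive; the fraction of inconclusive blocks rises as sequences get more similar |
| $\Gamma$ categories | 4 | — | standard discrete-gamma resolution |
| $\alpha$ bounds | $[0.02, 100]$ | shape | optimized per block, start 1.0 |
| branch-length bounds | $[10^{-8}, 10]$ | subst./site | optimized per topology, starts 0.05 then 0.5 |

The pattern itself is drawn by hill-climbing the *overlap complexity*
$\mathrm{OC}(P) = \sum_{s \ne 0} 2^{\sigma(s)}$, where $\sigma(s)$ counts
match positions overlapping under relative shift $s$. The literature
defines OC only up to this family; we adopt exactly this form and compute
$\sigma$ from pairwise differences of match positions. Patterns are
canonical (first symbol `1`), since a leading `0` only shifts coordinates.
OC optimization is a preprocessing nicety — accuracy is driven by the
homology filter and the likelihood stage — so the default budget is
10,000 accepted-or-rejected swaps.

## Likelihood details

Blocks enter the likelihood as site-pattern counts over the $4^4$ ordered
nucleotide quadruples. The rate matrix is the reversible
$Q_{xy} = s_{xy}\pi_y$, normalized to one expected substitution per site,
and diagonalized through the $\sqrt{\pi}$ symmetrization (real spectrum
guaranteed). Transition matrices $P(t) = U e^{\Lambda t} U^{-1}$ feed a
4-leaf pruning kernel written in C++; rate heterogeneity is the
equal-weight discrete $\Gamma$ with category means (Yang's mean method),
renormalized to mean 1.

Three deliberate modeling choices:

* **Base frequencies are empirical** per block (zero frequencies are
  floored at $10^{-6}$ and renormalized). 110 columns do not support
  three extra free parameters.
* **Exchangeabilities are fixed at 1 by default** (`params_policy =
  "fixed"`), again because five free rates are barely identifiable on 110
  sites; `params_policy = "gtr"` optimizes them for users who want the
  full model.
* **All $\ell$ columns are used by default**, including the $w$ match
  columns that are constant by construction (`columns = "dontcare"`
  restricts to the don't-care columns). No ascertainment-bias correction
  is applied for the invariant match columns; this biases branch lengths
  downward slightly but is topology-neutral in practice, and the selected
  quantity is the topology only.

Optimization is cyclic coordinate-wise bounded maximization (golden
section via `optimize()`), cycling branch lengths then $\alpha$ until the
cycle improves the log-likelihood by less than $10^{-6}$, capped at 25
cycles; non-convergence triggers one restart from 0.5 and, failing that,
the block is marked inconclusive with a warning. With four distinct
sequences the likelihood surface of a 4-leaf tree is benign and the
coordinate scheme is robust; speed is dominated by the C++ kernel, not the
optimizer.

Ties: an all-identical block has exactly equal likelihoods for all three
topologies, and closely related taxa produce many near-ties. The tie
tolerance ($10^{-3}$ log-units) formalizes "no single best topology"; the
pipeline reports the inconclusive fraction, which is itself a useful
divergence diagnostic.

## Supertree design

Each quartet $ab|cd$ embedded in the current taxon set $A$ contributes six
edges to a multigraph: *good* edges $(a,b)$, $(c,d)$ and *bad* edges on
the four cross pairs. `find_cut()` minimizes
$(\mathrm{good_{cut}}+1)/(\mathrm{bad_{cut}}+1)$ over all single-taxon
splits plus 50 hill-climbed random bipartitions; the $+1$ pseudo-count
regularizes the ratio when no bad edge is cut. The recursion turns each
cut into a split and descends into both sides.

Two design points where the obvious simplification fails, discovered and
fixed during development:

* **Spanning quartets are not dropped.** A quartet with three taxa inside
  $A$ contributes its induced triplet (one good, two bad edges); with two
  taxa inside it contributes one good (siblings) or one bad (cross pair)
  edge. Without these constraints the attachment position of the parent
  edge inside a 4-taxon subset is undetermined: on data with 98% correct
  quartets the dropped-quartet variant still returned RF 4 trees. For the
  same reason three-taxon subsets are resolved by the same machinery
  rather than emitted as stars.
* **One vote per subset.** Random sampling covers closely related taxa
  far more often (they share more spaced words), and raw multiplicities
  demonstrably mislead the ratio cut. The pipeline therefore collapses
  the conclusive blocks to a single majority topology per 4-taxon subset
  (`majority_quartets()`; tied subsets are dropped) before amalgamation.
  `build_supertree()` still accepts weighted/multiset input directly.

When a recursion level has no quartet information at all, the set becomes
a multifurcation instead of an arbitrary split. Taxa that appear in no
quartet are attached at the root with a warning. The output carries no
branch lengths: the method estimates topology only.

## The simulator, and what a green test establishes

`random_tree()` grows a topology by attaching each new leaf to a uniformly
chosen edge; branch lengths are i.i.d. `Uniform(0.01, 0.03)` by default,
which yields average leaf-to-leaf distances near 0.1 substitutions/site
for 8–16 taxa — the divergence regime of congeneric mammalian genomes,
and the regime in which the end-to-end acceptance test operates.
`evolve()` draws the root from the stationary frequencies and applies
$P(t)$ branch-wise (JC by default, arbitrary GTR+$\Gamma$ optionally);
indels are optional point events with geometric lengths, off by default.

The simulator emulates neutral substitution along a clock-free tree, and
nothing else: no gene duplication or loss, no horizontal transfer, no
rearrangements, no compositional heterogeneity across lineages, no
repeats. A green end-to-end test therefore establishes that the sampling,
likelihood and amalgamation machinery recover a tree when homology is
honest and signal is present; it does not certify performance on real
genomes, where repeat-induced false homologies and transfer events are
the dominant failure modes.

## Numerical and degenerate-input choices

* Occurrence keys are base-4 integers in a double (exact up to $w = 26$);
  bucket order is therefore lexicographic.
* Windows overlapping any non-`ACGT` character are skipped whole, with a
  per-record warning (ambiguity codes are not N-masked).
* Coordinates are 0-based internally; all user-facing reports are
  1-based. Reverse-strand occurrences live on the reverse-complemented
  record with their own coordinates.
* Site likelihoods are floored at $10^{-300}$ before the log.
* The sampler abandons an anchor after 50 failed (negative-score) probes
  and terminates after a consecutive-failure streak equal to the number
  of remaining occurrences (capped at $10^5$).
* RF normalization divides by the number of nontrivial splits actually
  present in the two trees, so multifurcating comparisons stay in
  $[0, 1]$.
* `find_cut` side labels are arbitrary; consumers must treat the
  bipartition as unordered.

## Known limitations

* The supertree stage is a heuristic; with heavily conflicting quartets
  it can return a suboptimal cut (mitigated by restarts and majority
  voting, not eliminated).
* Single-process only; the block loop is embarrassingly parallel but the
  contract here is seed-determinism.
* The low-memory chunked index mode for very large genomes is not
  implemented (future flag).
* No protein mode, no distance-matrix output, no bootstrap support
  values.
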