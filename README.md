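# spaq — alignment-free phylogeny from spaced-word quartet blocks

`spaq` reconstructs an unrooted phylogenetic tree **topology** for a set
of genomes directly from unaligned FASTA sequences. It is aimed at users
who need a fast whole-genome tree — bacterial isolates, assembled
eukaryote genomes, simulated benchmarks — without computing a multiple
alignment.

## Method in brief

A binary pattern P ∈ {0,1}^ℓ (default ℓ = 110, weight w = 10) defines a
*spaced word*: the nucleotides at the w match positions of an ℓ-window.
The pipeline:

1. enumerates spaced-word occurrences on both strands of every genome and
   buckets them by spaced word;
2. randomly samples up to M (default 10⁶) **quartet P-blocks** — gap-free
   4 × ℓ micro-alignments of the same spaced word in four different taxa
   — keeping a block only if an anchor row scores positively against the
   other three rows under a fixed nucleotide substitution score matrix
   (s(A,A)=91, s(C,C)=s(G,G)=100, s(T,T)=91, transitions −31,
   transversions −114…−125);
3. selects, for every block, the maximum-likelihood quartet topology
   among the three possible splits ab|cd under GTR+Γ (Felsenstein
   pruning, 4 discrete Γ categories, empirical base frequencies),
   discarding *inconclusive* blocks whose top two log-likelihoods tie
   within 10⁻³;
4. amalgamates the conclusive quartets into a supertree by recursive
   MaxCut partitioning: each quartet ab|cd contributes "good" edges
   (a,b), (c,d) and "bad" edges across, and each recursion level removes
   the bipartition minimizing (good_cut + 1)/(bad_cut + 1).

Accuracy is checked with the Robinson–Foulds (RF) metric against known
trees; the package includes a sequence-evolution simulator
(`random_tree()`, `evolve()`) so the full pipeline is verifiable
end-to-end without external data. See the methods vignette
(`vignettes/spaced-word-quartets.Rmd`) for models, assumptions and design
rationale.

## Worked example

Simulate eight ~0.1-substitutions/site-diverged 100 kb genomes along a
known tree, then recover the tree:

```r
library(spaq)

tr   <- random_tree(8, seed = 101)                       # ground truth
seqs <- evolve(tr, sim_config(n_taxa = 8, sequence_length = 100000,
                              seed = 202))
run  <- run_pipeline(seqs, run_config(max_blocks = 300, seed = 7),
                     quiet = FALSE)
#> pattern (l=110, w=10): 1000000000001000001000010000...
#> 1598256 spaced-word occurrences in 504504 buckets
#> 300 homologous P-blocks sampled
#> 279 conclusive / 21 inconclusive quartet topologies
#> 63 distinct quartet subsets after majority vote

run$newick
#> [1] "(t5,(t7,(t2,t6)),((t3,t8),(t1,t4)));"

rf_distance(run$tree, tr)
#> $absolute
#> [1] 0
#> $normalized
#> [1] 0
```

Reading the report: 1.6 M windows were indexed (8 genomes × 100 kb × two
strands); of 300 sampled homologous blocks, 279 gave a single best
quartet topology (the 7% inconclusive fraction is typical at this
divergence — it grows as genomes get more similar). The majority vote
covered 63 of the C(8,4) = 70 quartet subsets, and the amalgamated
topology matches the generating tree exactly (RF = 0).

Input can equally be FASTA files: `run_pipeline(c(tax1 = "tax1.fa", ...))`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/spaq.R", package = "spaq"))')
Rscript $CLI run --seed 1 -M 1000 -o tree.nwk genome1.fa genome2.fa genome3.fa genome4.fa
Rscript $CLI simulate -n 8 -L 100000 --seed 1 -o simdir
Rscript $CLI rf tree.nwk simdir/guide_tree.nwk
Rscript $CLI pattern -l 110 -w 10 --seed 1
```

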