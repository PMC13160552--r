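# wtfkit

Tools for studying how multi-copy **poison-antidote spore-killer gene
families** — the fission-yeast *wtf* family is the archetype — diversify
through duplication, gene conversion and recombination, and for modelling
why recombination (not duplication) creates new meiotic drivers.

A *wtf*-type driver is a single gene expressing two isoforms: a short
poison to which all spores of a tetrad are exposed, and a long antidote
made only in spores inheriting the gene, so non-carrier spores die and
the driver is over-transmitted. A newly duplicated copy cannot drive —
its poison is already detoxified by the fixed ancestral antidote — but a
recombinant coupling a novel poison to its matching antidote can sweep.
`wtfkit` packages the full comparative-genomic and population-genetic
analysis around that idea, for researchers working on selfish genetic
elements, gene-family evolution, or recombination detection generally.

## What is inside

* **Annotation** — seeded local-alignment search for family members in
  assemblies (`find_family_members`, extreme-value E-values with the
  familiar `1e-5` cutoff semantics), exon-structure transfer from
  reference models, pseudogene calling, poison-start (exon-2-ATG /
  intron-1-ATG) detection, flank-identity locus assignment into a
  presence/absence matrix, solo-LTR flagging.
* **Exon networks** — coverage-aware pairwise identity, thresholded
  similarity graph (edges at identity >= 0.50), connected-component
  clusters and singletons, identity heatmap tables.
* **Recombination** — the pairwise homoplasy index (PHI) test with
  permutation p-values (statistic = mean refined incompatibility, i.e.
  minimum homoplasies any tree requires per site pair, over
  informative-site pairs within a 100 bp window); a triplet
  maximum-descent breakpoint scan with exact DP p-values; four-gamete
  minimum-recombination counts (Rmin) with Hudson-Kaplan thinning and
  per-region rate comparisons.
* **Phylogenetic grouping** — p/JC69/K2P distances, neighbor joining,
  anchor-clade group assignment, normalized Colless ladder-likeness.
* **Chimeras and isoforms** — exon-swap chimera construction, long/short
  isoform CDS derivation, engineered poison-start insertion (reversible),
  PY-motif scanning, poison-vs-antidote C-terminal segment comparison.
* **Family simulator** — forward-time evolution of a multi-locus family
  along a random strain genealogy with mutation, duplication, conversion
  and pseudogenization channels, full ground-truth event logging, true
  alignments, and emitted FASTA/GFF3.
* **Drive dynamics** — the deterministic recursion
  `p' = p / (1 - c p (1 - p))` for a poison-antidote driver in a haploid
  outcrossing population, Wright-Fisher simulation of
  novel-driver / duplicate / recombinant scenarios, and Monte-Carlo
  fixation probabilities.

## Worked example

Simulate a 10-strain family with two ~2.25 kb loci and an active
conversion channel, then ask whether the recombination machinery sees it:

```r
library(wtfkit)

anc2k <- ancestor_model(c(450, 240, 255, 270, 300, 483),
                        c(50, 50, 50, 50, 52))
params <- family_sim_params(n_strains = 10, n_loci = 2, mu = 2.5e-4,
                            conv_rate = 7.5e-3, anc = anc2k, seed = 42)
sim <- simulate_family(params)
sum(sim$truth$kind == "conversion")
#> [1] 11

aln <- pooled_alignment(sim, c("L01", "L02"))   # 20 genes x 2250 columns
phi_test(aln, permutations = 1000, seed = 1)
#> <PhiResult: statistic 0.0204 over 472 informative sites, p = 0.000999 (1000 permutations)>

rmin(aln)$rmin
#> [1] 24

# matched clonal control: conversion off, infinite-sites mutation
nul <- make_clonal_null(params)
phi_test(pooled_alignment(nul, c("L01", "L02")), permutations = 1000, seed = 1)
#> <PhiResult: statistic 0.0000 over 556 informative sites, p = 1 (0 permutations)>
```

The 11 logged conversion events leave a strong signal (PHI p ~ 0.001 and
at least 24 recombination events by the four-gamete bound), while the
conversion-free control is exactly homoplasy-free (statistic 0, p = 1).

On the population side, a duplicate with the ancestral specificity is
exactly neutral, while a recombinant with a novel poison drives:

```r
p <- 0.05
for (g in 1:5) { p <- next_gen_deterministic(p, c = 1); print(p) }
#> 0.0525, 0.0552, 0.0583, 0.0617, 0.0655  (strictly increasing toward 1)

estimate_fixation_prob(list(N = 1000, c = 1, p0 = 0.01,
                            generations = 20000, seed = 7),
                       "recombinant_novel_specificity",
                       replicates = 200)$estimate
#> [1] 0.39        # vs 0.01 for a neutral allele at the same p0
```

See the methods vignette (`vignettes/wtf-family-methods.Rmd`) for the
models, parameter choices and limitations.

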