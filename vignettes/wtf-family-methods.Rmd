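---
title: "Models and methods for poison-antidote driver family analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for poison-antidote driver family analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtfkit)
```

## The system

Spore killers of the fission-yeast *wtf* type are single-gene
poison-antidote meiotic drivers. One gene expresses two isoforms from
alternative starts: a short isoform (the poison) to which every spore of a
tetrad is exposed, and a long isoform (the antidote) expressed only in
spores that inherit the gene. Spores lacking the driver die with some
efficiency, so a heterozygote transmits the driver to more than half of its
surviving spores. The family is multi-copy and turns over quickly:
strains differ in copy number, loci gain and lose members, many members are
pseudogenes, and non-allelic gene conversion shuffles sequence between
members. A duplicate of an existing driver cannot spread — its poison is
already covered by the fixed ancestral antidote — whereas a recombinant
that couples a novel poison with its matching antidote can.

`wtfkit` implements this analysis stack end to end: discovery and
annotation of family members in assemblies, exon similarity networks,
flank-based locus assignment, recombination-signal statistics, distance
trees and tree-shape summaries, chimera/isoform construction, a
forward-time family simulator with ground-truth logging, and the drive
population model. Everything below documents the modelling choices and
their rationale; no empirical claim is made here beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## Drive dynamics

The haploid life cycle is simplified to obligate random outcrossing every
generation. Let $p$ be the driver frequency and $c \in [0,1]$ the killing
efficiency (the probability that a poison-exposed spore lacking the
antidote dies). Enumerating the three mating classes of a tetrad of four
spores — driver x driver (all spores rescued), driver x non-driver (two
driver spores rescued, two non-driver spores each die with probability
$c$), non-driver x non-driver (no poison) — gives the expected
next-generation frequency

$$p' = \frac{p}{1 - c\,p\,(1-p)}.$$

`next_gen_deterministic()` is verified against that enumeration in the
test suite rather than trusted from the algebra. The finite-population
counterpart `simulate_wf()` binomially resamples $N$ haploids from the
post-killing pool each generation. Three scenarios are exposed:

* `novel_driver` / `recombinant_novel_specificity`: the poison is covered
  by nothing already fixed, so the recursion applies. The two names are
  kept separate because they answer different questions (invasion of a
  brand-new driver vs. of a recombination product).
* `duplicate_same_specificity`: the fixed ancestral antidote covers the
  duplicate's poison, every spore survives, and the allele is exactly
  neutral — duplication alone cannot drive.

Assumptions, all deliberate simplifications: no fitness cost of carriage
(knocking out individual family members does not measurably change
vegetative growth, so the cost defaults to zero); killing acts per spore
independently; survival multiplies across distinct poisons
(independence); no selfing or mating-type structure; no aneuploid-spore
rescue. `spore_survival()` implements the general multi-locus rescue rule
for arbitrary genotypes, and is what the scenario maps reduce to.

## The family simulator

`simulate_family()` evolves a genome of `n_loci` loci, each initially an
identical copy of one ancestor gene embedded in locus-specific random
flanks, along a random coalescent-shaped strain genealogy (`ape::rcoal`
topology, rescaled to integer generations). Per gene and generation,
four independent event channels fire:

* **mutation** — binomial per-site substitution at `mu`;
* **duplication** — with probability `dup_rate` the gene is copied to a
  brand-new locus with fresh random flanks;
* **conversion** — with probability `conv_rate` the gene receives a tract
  from a uniformly chosen co-resident member; tract length is geometric
  with mean `tract_len_mean`, placement uniform, truncated at gene ends;
* **pseudogenization** — with probability `pseudo_rate` a random in-frame
  codon in the body of the CDS (codons 2 through just short of the final
  10%) is set to TAA. The placement window keeps the disruption
  unambiguous for the caller, which deliberately ignores stops in the
  final 10% of codons.

Genes are gap-free (indel evolution is out of scope because alignment
inference is), so every member shares the ancestor's coordinate system:
the per-locus "true alignments" and the pooled paralog alignment are just
sequences stacked, and conversion breakpoints are exact column indices in
the truth log. Under `infinite_sites = TRUE` a single family-wide
used-site mask forbids any column from mutating twice anywhere in the
family, which makes clonal output (`make_clonal_null()`, conversion off)
exactly homoplasy-free — the matched negative control for every
recombination statistic. Flanks mutate at `mu` but are not logged; they
exist to make flank-based locus assignment testable. Duplication always
founds a new locus, so within-strain copy number per locus is 0/1 — tandem
expansion within a locus is not modelled.

The default conditions (5 strains, 8 loci, 200 generations, `mu = 1e-4`,
`dup_rate = 5e-4`, `conv_rate = 1e-3`, `pseudo_rate = 5e-4`, mean tract
300 bp, 1 kb flanks, six-exon ~1.3 kb ancestor) give strains a few percent
sequence divergence, a handful of duplication/conversion/pseudogenization
events per history, and are the reference setting for the annotation
recovery checks. The recombination power analyses use a ~2.25 kb six-exon
ancestor at `mu = 2.5e-4` (about 10% divergence between loci, in the range
of real paralog divergence) with 10 strains x 2 loci pooled into a 20-taxon
alignment, and `conv_rate = 7.5e-3`, which yields on the order of 10
logged conversion events per history. The clonal null for the acceptance
checks uses 20 strains x 1 locus at the same scale. Problem sizes
throughout (replicate counts of 100-500, populations of $10^3$-$10^4$)
are chosen so the whole suite runs on a laptop in minutes while leaving
Monte-Carlo error well inside the stated tolerances.

What the simulator does *not* emulate about real data: indels and
alignment error, selection on sequence content, transposon/LTR targeting
of insertions, within-locus tandem duplication, structural variation in
the flanks, and sequencing/assembly artefacts. Tests passing on simulated
data therefore validate the statistical machinery and the pipeline
contracts, not robustness to those real-data complications.

## Sequence identity and the exon network

All identity computations use one definition: global alignment with free
end gaps (match +1, mismatch -1, gap -2 per position) and
**coverage-aware identity** = matches / (aligned columns + unaligned
terminal overhang), i.e. matches over the full alignment length with
internal gaps counting as mismatches. The denominator choice matters:
with free end gaps, a score-optimal alignment of two unrelated sequences
is a short, high-identity sub-overlap, and an identity computed only over
aligned columns averages about 0.7 for random 150-mers — which would put
unrelated exons above the 0.5 clustering threshold and merge the whole
network into one blob. With the full-length denominator, random pairs
score ~0.03, sequences a few substitutions apart score >0.9, and the 0.5
threshold separates homologous from unrelated exons as intended.

`build_exon_graph()` scores all pairs and draws an edge at identity
`>= threshold` (the boundary is inclusive; a strictness flag switches to
`>`), and `extract_clusters()` reports connected components with at least
two members as clusters, the rest as singletons. "Cluster" is read as
"component with more than one member": singletons are the stated
complement, so a strict more-than-two reading would leave two-member
components unaccounted for; `min_size` exposes the choice. Components are
ordered by size then lexicographically smallest member, making output
deterministic under input reordering.

## Family-member discovery and annotation

`find_family_members()` is a self-contained seeded search: exact-match
k-mer seeds (default length 11) on both strands, seeds clustered by
implied gene start, then gapped local alignment (match +1, mismatch -2,
gap open -5, extend -2 — standard nucleotide-search-like scoring) of the
query against each seeded window. Significance is an extreme-value
E-value $E = K m n e^{-\lambda S}$: $\lambda$ solves
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ for the ungapped scheme, and
$K$ is fitted once per scoring scheme from the mean maximal local score of
random sequence pairs via $E[S_{max}] \approx (\ln(Kmn) + \gamma)/\lambda$
(cached; its own fixed RNG stream, so user seeds are untouched). The
familiar threshold semantics ($E \le 10^{-5}$) are preserved even though
absolute E-values from external search tools cannot be matched
bit-for-bit. Overlapping hits from different queries are merged when they
overlap at least half of the shorter interval.

`transfer_exon_structure()` picks the reference model with the highest
gene-sequence identity to the candidate (ties broken by reference order
and flagged), maps exon boundaries through the pairwise alignment, nudges
boundaries that land opposite gaps to the nearest aligned position
(flagged), and rejects candidates below a 0.5 identity floor.
`call_pseudogene()` uses three disruption rules — premature stop before
the final 10% of codons, spliced length not divisible by 3, missing start
codon — because no published criterion set exists for this family; the
three rules are the package's own documented definition.
`detect_poison_starts()` looks for an in-frame ATG in the first 30 nt of
exon 2 (in frame means its spliced position is a codon start of the
long-isoform frame) and for an ATG in the last 30 nt of intron 1 whose
retained tail length is congruent to the exon-2 phase mod 3, so that
translation through the tail reads exon 2 in the long-isoform frame. The
30 nt window is a documented choice ("near the start of exon 2" has no
published number) and is configurable.

`assign_loci()` identifies loci by synteny: 1 kb flanks on each side,
an edge between genes of different strains when both flanks align at
identity >= 0.8, connected components as loci. Genes near contig ends
fall back to single-flank mode and are flagged. `flag_solo_ltr()` asks
for a library hit within 500 bp of either gene end at identity >= 0.7
covering >= 80% of the LTR; the coverage floor stops short spurious
high-identity sub-matches from counting as an LTR.

## Recombination statistics

**Refined incompatibility / PHI.** For a site pair, the refined
incompatibility is the minimum number of homoplasies any tree requires to
fit both sites jointly — computed exactly as the cycle rank of the
partition intersection graph (vertices = states of each site, edges =
observed joint states), and verified in the tests against exhaustive
parsimony over all topologies. The PHI statistic is the mean score over
parsimony-informative pairs within 100 bp of each other (distance on the
ungapped consensus; the window is the published default, configurable).
Gap/N taxa are dropped per site pair; pairs with fewer than four complete
taxa score 0. Significance is by permuting site contents over the
observed positions. The test is one-sided low: recombination makes
nearby sites *more* compatible than random pairs, so
$p = (1 + \#\{\text{perm} \le \text{obs}\})/(1 + n_{perm})$. When every
informative pair is compatible the permutation distribution is degenerate
at 0 and $p = 1$ exactly — the behaviour the clonal-null control checks.

**Triplet breakpoint scan.** For an ordered triplet (P, Q, C),
informative sites are the columns where C matches exactly one parent;
coding P-matches +1 and Q-matches -1 gives a walk whose maximum descent
(drop from the running maximum) is large when C switches from P-derived
to Q-derived sequence. The exact p-value — the probability that a random
arrangement of the m up- and n down-steps reaches a descent at least as
deep — is computed by dynamic programming over (ups used, downs used,
current drop), exact in floating point and verified against full
enumeration for all m, n <= 6. Multiple testing across triplets uses
Dunn-Sidak (Bonferroni available). The breakpoint interval spans the
maximal-descent run, from the column where the running maximum was last
attained to the trough column.

**Rmin.** Sites with exactly two states enter pairwise four-gamete tests;
incompatible pairs define open intervals, thinned Hudson-Kaplan style
(sort by right endpoint, greedily keep disjoint intervals) to the lower
bound on the number of recombination events. A regression-based
population-scaled recombination rate ($\rho = 4N_e r$) estimator is
deliberately out of scope — it would hinge on an externally trained
regressor — so all between-group and between-region comparisons in
`compare_regions()` use per-bp Rmin. That preserves comparative claims
(which region or group recombines more) but not absolute rates.

## Trees and groups

Group assignment consumes tree *structure*, not support values, so
maximum-likelihood inference is replaced by neighbor joining on
pairwise-deletion p/JC69/K2P distances, with saturated distances capped
and flagged and negative NJ branch lengths clamped to zero. Trees are
midpoint-rooted when a root is needed (the family has no outgroup within
a single species). `assign_groups()` maps each gene to the group whose
anchor set's smallest enclosing clade contains it — anchors must be user
supplied, since group boundaries in this family are defined by
inspection, and exact published memberships cannot be guaranteed.
Ladder-likeness, a qualitative claim about driver phylogenies, is made
testable as the normalized Colless index (caterpillar = 1, balanced = 0).

## Chimeras and isoforms

`build_chimera()` joins exons 1..k of parent A (with A's introns) to
exons k+1..end of parent B, the junction at the exon/intron boundary
after A's exon k, so the junction intron is B's — mirroring last-exon
swap constructs. Intra-exon breakpoints belong to the simulator's
`inject_single_crossover()` instead. `derive_isoforms()` returns the
long-isoform CDS from the exon-1 ATG and the short-isoform CDS from the
exon-2 ATG if present, else the intron-1 ATG (retained tail included, in
frame), else marks the gene antidote-only; exon-2 starts take priority
when both exist. `insert_poison_start()` recreates the
engineered-poison construct: an ATG inserted at the 5' end of exon 2 on
the first codon boundary of the reading frame (0-2 nt of original exon 2
may precede it), shifting downstream coordinates by exactly 3 and
reversible byte-identically by `remove_poison_start()`.
`compare_poison_antidote()` reports identity of the protein segments
encoded downstream of exon k between each poison and each antidote — a
sequence-level proxy for detoxification specificity only; no functional
rescue is claimed or predicted.

## Numerical and degenerate-input conventions

Coordinates are 1-based inclusive everywhere; only the BED writer
converts (0-based half-open). `N` is tolerated in genomes; statistics
drop gap/N taxa site-wise. Alignments need >= 2 taxa, PHI/Rmin >= 4,
triplets >= 3. Fewer than 2 informative sites, or no informative pair
inside the PHI window, returns a not-testable flag with p = 1 rather than
an error. Monomorphic or fully compatible alignments give Rmin 0.
All stochastic functions are reproducible from explicit seeds; the
simulator guarantees bit-identical output for identical parameters and
seed.

## Known limitations

* Absolute recombination rates are not estimated; only Rmin-based
  comparisons are supported.
* Group anchors are user input; the package cannot reproduce
  by-eye group boundaries without them.
* The simulator's truth log records stop-gains it introduces, but point
  mutations can also create stops; pseudogene-call comparisons against
  the truth log are therefore one-directional (every logged disruption
  must be called).
* The drive model ignores population structure, selfing, linkage and
  costs; it addresses the qualitative fate of duplicates vs.
  recombinants, not quantitative allele-frequency prediction.
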