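---
title: "Host specificity and co-diversification statistics for honeybee gut symbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host specificity and co-diversification statistics for honeybee gut symbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apisym)
```

## The scientific problem

The gut microbiota of the five widespread honeybee species — *Apis mellifera*,
*A. cerana*, *A. dorsata* and the dwarf honeybees *A. florea* and
*A. andreniformis* — is dominated by a small set of bacterial genera whose
members differ strikingly in how tightly they track their host. Two competing
evolutionary narratives explain such host specificity: strict
co-diversification, in which symbiont lineages split when their hosts split
and the phylogenies mirror each other, and a more fluid history of symbiont
gains, losses and host switches, in which specificity arises ecologically
rather than from shared descent.

`apisym` implements the statistical machinery needed to distinguish these
narratives from shotgun-metagenomic profiles of individual bee guts:
detection and strain-level rules operating on coverage and allele-frequency
profiles, host-specificity indices, community-level beta-diversity and
phylosymbiosis tests, a node-by-node co-phylogeny scan with a second-order
permutation null, and functional profiling of gene content. Because the raw
metagenomes of any particular study are not needed to verify the statistics,
the package ships a seeded synthetic-data generator whose outputs exercise
every analysis stage.

## The synthetic-data generator

### Host tree

`default_host_tree()` returns the accepted Apis topology
`((A_florea, A_andreniformis), (A_dorsata, (A_mellifera, A_cerana)))` as an
ultrametric tree of depth 1. Real branch lengths from a dated mitochondrial
phylogeny can be substituted by reading any five-taxon Newick file; depth-1
scaling was chosen so that simulation rates are expressed per host-tree
depth, which keeps parameter choices interpretable.

### Symbiont trees

`simulate_symbiont_tree()` runs a continuous-time Gillespie simulation of
symbiont lineages inside the host tree's branches:

* at a host split, a lineage follows both daughters with probability
  `cospec_prob` (co-speciation), otherwise one daughter chosen uniformly;
* each lineage duplicates (rate `dup_rate`), dies (rate `loss_rate`) or
  switches host (rate `switch_rate`) with exponential waiting times;
* a switch *copies* the lineage into a uniformly chosen host branch alive at
  that moment — the donor is retained — because invasion without donor loss
  matches the observed coexistence of related clades in multiple hosts. A
  `switch_moves` flag gives the move variant. The target is uniform among
  contemporaneous branches since no sympatry structure is assumed.
* surviving lineages at a host tip each contribute `tips_per_lineage` MAG
  tips attached as a star of length `tip_jitter`, mimicking repeated genome
  recovery of one bacterial species from several samples; this is what lets
  simulated clades reach the 7-tip testability threshold of the scan.

Branch lengths are host-time spans multiplied by `rate_scale` and, when
`rate_noise > 0`, by per-branch lognormal factors (mean 1). The default
`rate_scale = 0.4` puts root-to-tip symbiont divergence at 0.4 substitutions
per site, the magnitude observed for genus-level core-genome trees whose
within-genus divergence is comparable to the divergence of the Apis genus;
it also keeps tip-tip distances of an undisturbed clade below the scan's
depth filter of 1. No nucleotide-level sequence evolution is simulated: the
trees carry branch lengths directly, which is all the downstream statistics
consume.

Limits worth knowing: with `cospec_prob = 1` and all rates zero the symbiont
tree is an exact copy of the host topology (the package tests assert
Robinson–Foulds distance 0); with `switch_rate = 0` every internal node's
host set is a complete host-tree clade; high switch rates (`switch_rate = 5`)
produce exponential lineage growth (the process is supercritical), so such
settings are intended for mixing-behaviour checks, not for large-scale
scans.

### Communities, strains, genes

`simulate_community()` draws species presence per sample as Bernoulli with
host-specific prevalence, and lognormal abundances given presence. The
default archetypes (`default_archetypes()`) mirror the empirically observed
structure: a core of generalists present in ~90% of samples of every host,
specialists private to single hosts, and patchy intermediates — the three
regimes the specificity classification must separate.

`simulate_allele_profiles()` generates the strain-level evidence: `n_strains`
haplotypes over `n_variant_positions` of a `genome_length`-bp genome, with
each sample mixing its allowed strains with Dirichlet weights and observing
them through multinomial read sampling at Poisson coverage (default mean
20x, a typical well-covered species in a gut metagenome). With
`host_partition = TRUE` strains are private to hosts, producing the
within-host strain sharing that popANI + PERMANOVA should detect; with
`FALSE` all samples draw from one pool and no host signal exists. Dirichlet
concentration 0.8 gives uneven mixtures in which minor strains routinely
fall near the 0.05 frequency threshold, exercising the allele-set logic.

`simulate_gene_table()` draws per-gene read counts from a negative binomial
whose log-mean carries per-(gene, host) normal shifts of standard deviation
`host_effect`; the covered fraction of a gene saturates as
`1 - exp(-reads * read_length / length)`, the expectation under random read
placement. `host_effect = 0` yields exchangeable samples, used to check that
the downstream PERMANOVA holds its nominal size.

All generators are bit-reproducible given their seed.

## Detection and strain-level rules

* **Species presence**: breadth ≥ 0.5 of the genome covered. The rule is a
  deliberate echo of the practice of requiring half the genome rather than a
  read-count threshold, which is robust to coverage spikes from conserved
  regions.
* **SNVs**: a site is a variant when covered ≥ 5x with ≥ 2 alleles at
  frequency ≥ 0.05; sites with coverage < 1x, or in regions flagged by a
  read-identity mask (supplied as a `read_ani` column, threshold 0.92, since
  mapping is upstream of this package), are excluded from numerator and
  denominator alike. Percent variable sites is 100 × SNVs / covered length.
* **popANI**: a pair of samples is compared for a species only when both
  have mean coverage ≥ 5x and breadth ≥ 0.5. At each position covered ≥ 5x
  in both, the allele sets (frequency ≥ 0.05) are intersected; a
  substitution is counted only when the sets are disjoint, so a single
  shared minor allele prevents a substitution. The dissimilarity is
  substitutions / compared positions. The denominator counts *all* jointly
  well-covered positions, polymorphic or not: a shared fixed allele can
  never be a substitution, so this reading keeps the ratio well defined; a
  `denominator = "multiallelic"` flag restricts to positions where the union
  of allele sets is polymorphic, for sensitivity analysis. Breadth is
  computed after the read-identity mask.
* **Strain matrices**: a species is analyzable when ≥ 5 eligible samples
  span ≥ 2 host species; ineligible pairs are `NA`, distinguishable from a
  true dissimilarity of 0.
* **ANI clustering**: average-linkage agglomerative clustering on 1 − ANI
  cut at 0.05 (the 95% species boundary), with cluster representatives
  chosen by the dRep-style score completeness − 5 × contamination (the N50
  term is dropped because assembly contiguity is not modelled), ties broken
  lexicographically.

## Specificity indices and classification

Rohde's index is computed in its prevalence-rank form: hosts are ranked by
descending prevalence with strictly consecutive ranks (ties broken by host
name for determinism) and `S = sum(p_j / r_j) / sum(p_j)`. The index is 1
exactly when one host is occupied and reaches its minimum
`(sum_{j=1..H} 1/j)/H` ≈ 0.457 for a uniform five-host generalist. The
original reference's exact tie-handling is not printed anywhere accessible,
so the consecutive-rank variant — which preserves both limiting behaviours
and scale invariance — was adopted; an intensity-weighted variant is not
implemented.

Classification: species detected in one host are `species_specific`; shared
species are `strain_specific` when the popANI matrix clusters by host
(PERMANOVA p < 0.01) and `non_specific` otherwise. Shared species without
analyzable strain data are reported `non_specific` with an `untested` flag
rather than dropped, so category totals stay well defined.

## Community statistics

Beta diversity follows the Baselga partition: `beta_sor = beta_sim +
beta_sne` (asserted to 1e-12 in the tests), with the Sorensen turnover
component `beta_sim` — insensitive to richness differences — used for
phylosymbiosis, and Jaccard analogues available.

PERMANOVA is the one-way Anderson decomposition of squared distances with
free permutation of sample labels (no strata: the sampling design offers no
stated blocking). On Euclidean distances of univariate data the pseudo-F
equals the classical ANOVA F to machine precision, which the tests use as an
exact oracle, and an independent cross-check against `vegan::adonis2` is
included. The reported effect size is the sample-size-adjusted
`omega^2 = (SS_between − df_effect · MS_within) / (SS_total + MS_within)`,
which is centred at zero under the null where R² is positively biased.
An all-zero distance matrix (possible for popANI when every pair shares
alleles everywhere) is returned as a degenerate result with p = 1 rather
than an error, so simulation sweeps never crash on uninformative draws.

The Mantel test uses Spearman correlation of lower-triangle distances by
default (Pearson behind a flag) and permutes one matrix's labels. With ≤ 6
labels all permutations are enumerated: the five-host subsets used below
have a permutation space of only 120, and enumeration removes Monte-Carlo
noise from the headline q-values. Enumeration includes the identity, so the
smallest attainable p is the number of automorphisms of the host distance
matrix divided by 120 — 4/120 ≈ 0.033 for the default host tree, because
the two cherries can each be swapped without changing any distance.

The phylosymbiosis test draws one sample per host per iteration (avoiding
pseudo-replication from unequal sampling), Mantel-tests the induced 5×5
community matrix against host divergence, and Benjamini–Hochberg-adjusts
the `n_iter` p-values of one run; the headline number is mean q ± sd. When
community turnover is constructed as a strictly increasing function of host
divergence every iteration attains r = 1 and the enumeration minimum p, so
mean q ≈ 0.033 < 0.05; under independence q-values concentrate near 1.

PCoA is classical metric scaling; negative eigenvalues are reported, never
silently dropped, so non-Euclidean inputs (popANI, turnover) are visible to
the caller.

## The co-phylogeny scan

`hommola_test()` implements the cospeciation test of Hommola and colleagues:
over all unordered pairs of host–symbiont links, the Pearson correlation
between host and symbiont patristic distances, with a null built by
independently permuting the host side and the symbiont side of the
association. Both-side permutation is the original procedure and the
default; host-only shuffling is behind a flag. Pairs with zero variance on
either side (e.g. all links in one host) are degenerate: r is undefined and
p = 1, a deliberate choice so that label-shuffled replicates never crash a
scan. p-values carry the +1 correction and can never fall below
1/(n_perm + 1); with the default 100 permutations the floor is 1/101 ≈
0.0099, which is why strict-tier significance (p < 0.01) requires the
observed r to beat every permutation.

`node_scan()` applies the test to every internal node whose subtree has ≥ 7
non-outgroup MAG tips from ≥ 3 host species and maximum tip-tip patristic
distance ≤ 1 (deeper subtrees span divergence where saturation makes the
distances uninformative). Tiers are relaxed (p < 0.05), medium (p < 0.05
and r > 0.75) and strict (p < 0.01 and r > 0.75); they are nested by
construction. Outgroup tips never enter the links (their hosts are outside
the focal phylogeny), and a node whose subtree contains any outgroup tip is
reported but excluded from the significant count, mirroring the practice of
discarding significance driven by rooting taxa. Significant nodes are
counted including nested ones (a significant node and its significant child
both count); the filters and per-node Hommola streams are derived from the
master seed per node id, so results are independent of traversal order.

`second_order_test()` addresses the fact that 100-permutation p-values over
many correlated nodes invite false discoveries: it shuffles the host
assignments of the non-outgroup tips (topology untouched), re-applies the
filters, re-runs the whole scan, and repeats `n_shuffles` times. Shuffling
tip-host assignments rather than host-tree labels was chosen because the
host tree has only five labels, making tip-level shuffling the richer and
better-behaved null; it is also the approach of the framework this test
follows. The empirical p is +1-corrected, so a pure co-speciation
simulation whose observed count beats all 100 shuffles reports exactly
1/101.

## Functional profiling

Gene detection requires strictly more than 5 mapped reads and strictly more
than 90% of bases covered. Abundance is RPKM =
reads / ((length/1000) · (library/10⁶)); KO and CAZyme family values are
sums of constituent detected genes' RPKM. The genus-level CAZyme
contribution excludes the GT and AA classes (glycosyl transferases and
auxiliary activities, which are not glycan-degrading), restricts to genera
with prevalence > 0.05 in the host under consideration, and normalizes
host-wise means to proportions. The robust Aitchison distance is the
Euclidean distance between robust-clr rows, where the clr is centred over
each sample's positive entries only and zeros stay 0 after centring — no
matrix completion is attempted; the plain variant is simple, reproducible
and sufficient for testing, and zero-handling beyond it is deliberately out
of scope.

## Numerical choices and degenerate inputs

* Frequencies per site must sum to 1 within 1e-6 (renormalized) or an error
  is raised; positions are 1-based.
* Permutation p-values use the +1 correction throughout; exact enumerations
  include the identity permutation.
* Ties in Rohde ranks, cluster representatives and allele sets are broken
  deterministically (host-name order, lexicographic MAG id, fixed
  nucleotide order).
* Degenerate inputs return flagged results rather than errors wherever a
  scan or sweep might encounter them (zero-variance Hommola/Mantel pairs,
  all-zero distance matrices); hard errors are reserved for precondition
  violations (all-zero prevalence, empty catalogs, extinct simulations).

## Problem sizes used in validation

The automated checks simulate at sizes chosen to make the statistical
contrasts decisive while remaining desk-scale: co-diversification recovery
uses five-host trees with 2 MAG tips per surviving lineage and 100-shuffle
second-order tests over 20 seeds; PERMANOVA calibration uses 1000 null
replicates of 20 samples with 199 permutations; strain-pipeline recovery
uses 50 seeds of 12 samples × 600 positions with 999-permutation PERMANOVA;
phylosymbiosis calibration uses 1000 subsampling iterations (exact
120-permutation Mantel) and 20 independent-community replicates of 200
iterations. Headline numbers of any particular field study (e.g. counts of
significant nodes out of hundreds tested on real MAG collections) depend on
the deposited metagenomes and are outside what synthetic validation can or
should reproduce.

## Known limitations

* The symbiont simulator models tree shape, not sequences; rate noise is a
  crude stand-in for among-lineage rate variation, and no assembly or
  binning artifacts (chimeras, incomplete MAGs) are emulated. Passing tests
  therefore demonstrate correctness of the statistics, not robustness to
  upstream bioinformatic error.
* The Hommola scan tests nodes that overlap (parent and child share tips),
  so per-node p-values are dependent; the second-order test is the intended
  control for this, not per-node FDR.
* Free permutation in PERMANOVA ignores possible colony- or location-level
  structure; with strong blocking the test would be anti-conservative.
* The popANI denominator choice (all covered vs multiallelic positions)
  changes absolute values but not the within/between-host contrast that the
  classification consumes; both are available.
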