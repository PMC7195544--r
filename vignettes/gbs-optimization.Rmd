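---
title: "Optimizing GBS assemblies and filters for phylogenetics"
author: "gbsphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing GBS assemblies and filters for phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsphylo)
```

## The problem

Genotyping-by-Sequencing (GBS) reduces a genome to thousands of short
restriction-site tags — here fixed at 64 bp — and reads them at modest,
highly variable depth across many individuals. For phylogenetics in groups
with little sequence divergence, the interesting questions are not about any
single locus but about the robustness of the pipeline itself:

* Do a reference-free assembly (tags paired at Hamming distance one) and a
  reference-based assembly (tags mapped to a genome) yield the same SNP
  matrix, and the same tree?
* How do the standard SNP filters — missing data, minor allele frequency
  (MAF), heterozygosity, depth, physical linkage — trade marker count
  against tree stability, and where are the safe settings?

`gbsphylo` implements both assembly routes, the genotype caller, the filter
suite with threshold sweeps, a neighbor-joining (NJ) tree engine with
bootstrap, Robinson–Foulds (RF) concordance reports, and a fully seeded
simulator with known truth, so every claim in this vignette is checked by
the package's own tests.

## The two discovery routes

**De novo.** Reads are demultiplexed by in-line barcode (longest-prefix
match over a prefix-free key), trimmed to 64 bp, and collapsed into tags
with per-sample read counts. Two tags differing at exactly one position
form a candidate biallelic SNP. The pairing is computed by masking each of
the 64 positions in turn and hashing, which is exactly equivalent to the
all-pairs Hamming scan (a property the test suite asserts against a
crossproduct-based brute-force oracle on instances up to 2,000 tags).

A network error filter then curates pairs: a pair whose rarer tag carries
less than a fraction `etr` (default 0.03) of the pair's combined reads is
treated as a sequencing-error artifact, and unless `allow_complex = TRUE`,
any tag left in more than one pair has all its pairs removed, so only
reciprocal one-to-one networks survive. Both rules are deliberately simple
and inspectable; the report attribute counts what each rule removed. Note
that at moderate depths the two rules interact: low-count error tags that
clear the ratio test give true tags extra partners, and the reciprocity
rule then discards the true pair as well. That is the designed, conservative
behavior; experiments that target a *different* stage of the pipeline (for
example the MAF analysis below) therefore bypass the network filter so that
one rule's effect is measured at a time.

**Reference-based.** Tags are searched on both strands of every contig for
ungapped placements with at most 3 mismatches; a tag is kept only if it has
a unique placement at its minimal mismatch count. Ties make the tag a
multimapper and discard it, mirroring the standard practice of dropping
ambiguous alignments. Candidate sites are reference positions where placed
tags disagree with the reference or each other; positions showing three or
more alleles are discarded and counted. The mismatch ceiling and
strand policy are this package's documented choices — reduced-representation
reads of 64 bp leave little room for more divergence without gapped
alignment, which is out of scope.

## Genotype likelihoods and GQ

Given the two allele depths \(a, b\) at a site with total \(d = a + b\) and
base-error rate \(e\) (default 0.01), the caller evaluates the binomial
diploid likelihoods

\[
L(AA) = \binom{d}{b} e^{b} (1-e)^{a},\qquad
L(AB) = \binom{d}{b} 0.5^{d},\qquad
L(BB) = \binom{d}{b} e^{a} (1-e)^{b},
\]

calls the maximizer, and reports the genotype quality
\(GQ = 10\log_{10}(L_\mathrm{best}/L_\mathrm{second})\), capped at 99.
Exact ties resolve toward the heterozygote, then toward homozygous-A, with
GQ 0 — deterministic and conservative. GQ is reported to 0.01 Phred and the
VCF writer declares GQ as a Float, so the matrix → VCF → matrix round trip
is exact. Calls below `min_depth` (default 1) are missing; the likelihoods
are evaluated in log space so high depths cannot underflow. Swapping the two
depths flips homozygote codes and leaves GQ unchanged, a symmetry asserted
exactly in the tests.

## The filter suite

Every rule is an independent, idempotent transformation of a
`genotype_matrix`; `apply_filters()` runs them in an explicit, logged order
and returns a per-rule report. Boundary semantics are fixed once and
unit-tested:

| rule | keep/drop decision | default |
|---|---|---|
| sample missingness | drop sample iff missing fraction **>** threshold | 0.90 |
| site missingness | keep site iff missing fraction **≤** threshold | 0.50 |
| MAF | keep iff folded MAF **≥** threshold | 0.02 |
| heterozygosity | keep iff observed het **≥** min (and ≤ optional max) | 0.01 |
| depth floor | mask call iff depth **<** threshold (mean or value) | mean |
| depth ceiling | mask call iff depth **>** value | off |
| invariant | drop iff all non-missing calls identical and homozygous | on |
| linkage | drop site iff **<** 128 bp from last retained site on contig | 128 |

Design notes:

* MAF is folded (`min(p, 1-p)`) so it never depends on which allele is
  labeled reference; de novo sites are oriented by observed major allele,
  so an unfolded definition would be orientation-sensitive.
* The default order applies the depth mask *before* the site-missingness
  filter: depth masking creates missingness that the downstream rules
  should see. Order interacts with results, which is why it is a logged
  parameter rather than a hidden constant.
* Linkage pruning is greedy left-to-right per contig (position ties broken
  toward fewer missing calls, then lower site id). Greedy thinning on a
  line yields a maximum spaced subset, so the surviving count is monotone
  in the input — the property the sweep tests rely on. By construction no
  surviving pair is closer than the threshold, so no manual second pass is
  ever needed. Only positioned (reference-source) sites are pruned; de novo
  sites, which live on synthetic per-pair contigs, pass through with a
  warning.
* All filters are idempotent except `depth_mode = "floor_mean"`: its
  threshold is recomputed from the data, and masking the below-mean calls
  raises the mean of the remainder, so a second application can mask more.
  The fixed-value depth modes are idempotent and tested as such.
* Sites with zero non-missing calls are removed by the frequency-based
  filters and counted separately — they carry no evidence either way.

`sweep_filter()` re-runs the whole chain with one rule's threshold swept
over a grid (defaults mirror the exploration ranges that motivated the
toolkit: MAF 0.01–0.06, missingness 0.1–0.9, link distance 0–256), and can
build an NJ tree per threshold to report RF distance against the base
setting — turning "did the tree change?" into a number.
`depth_simulation()` sweeps a floor and a ceiling around the dataset mean
depth and flags the plateau (first step changing the count by less than
1%).

## Trees and concordance

The internal tree engine is classical neighbor joining on allele-sharing
distances (`|g_i - g_j| / 2` averaged over co-called sites; heterozygotes
contribute 0.5). Two details are pinned down for reproducibility: ties in
the Q-criterion resolve toward the lexicographically smallest pair of
representative taxon labels, and negative branch lengths are clamped to
zero with the deficit recorded. On additive matrices NJ is exact — the
output path metric reproduces the input to numerical precision — and the
suite verifies this on random instances, cross-checking the topology
against an independent NJ implementation.

NJ is deliberately a desk-scale engine: for publication-grade inference the
package exports the filtered supermatrix as relaxed PHYLIP, NEXUS or FASTA
(heterozygotes as IUPAC codes, missing as `?`/`N`) for external ML or
quartet-based tools. The package's claims are about *concordance*, which is
measured the same way whatever the engine: `rf_distance()` compares
canonical bipartition sets (trees of any multifurcation degree), and
`concordance_suite()` restricts matrices to shared samples, bootstraps each
(site resampling, seeded, bit-reproducible), and tabulates RF, normalized
RF and the number of shared clades with support ≥ 80 in both trees.

When comparing a data-derived tree against a truth tree containing hard
polytomies (identical samples within species), collapse the data tree's
zero-length branches first (`collapse_zero_branches()`); the arbitrary
resolution of indistinguishable samples is not topology signal.

## The simulator

`simulate_gbs()` generates the entire study design with known truth: a
species tree (random Yule or user-supplied, scaled to height 1), a
synthetic reference of non-overlapping 64-bp windows spaced 200 bp apart
(so ordinary neighbors are never linked at the 128-bp rule and linkage
pruning can be tested against injected pairs only), one infinite-sites
mutation per variable locus placed on a branch with probability
proportional to its length, species-fixed diploid genotypes, and barcoded
reads with per-sample, per-locus depth variation, base errors and locus
dropout.

Default parameters emulate the data regime the toolkit targets: mean depth
7 with negative-binomial dispersion 1.5 (GBS depth skew), 1% per-base
error, 10% locus dropout, 64-bp tags. Two modeling choices deserve
explanation:

* **Depth is zero-truncated negative binomial.** A locus that is present in
  a sample's library yields at least one read; absence is a library-level
  event governed by `missing_rate`. This separation makes `missing_rate`
  the single source of missing data, so an error-free, dropout-free run
  recovers the truth matrix at every cell — the baseline every acceptance
  check builds on. `mean_depth` parameterizes the untruncated law.
* **Species-fixed genotypes by default.** With no within-species
  polymorphism, tree recovery is exact and testable (all samples of a
  species are genetically identical, so the true sample-level tree is the
  species tree with zero-length polytomies). `polymorphism_rate` optionally
  makes a fraction of loci segregate within the derived clade. There is no
  incomplete lineage sorting: the simulator validates the pipeline, not
  coalescent theory.

Errors are injected in the tag portion of each read only; barcode-error
chemistry is out of scope (a mis-barcoded read would simply be discarded at
demultiplexing). Reads are conserved: the FASTQ always contains exactly as
many reads as depths were drawn.

`inject_linked_pairs()` appends pairs of sites at a chosen sub-threshold
spacing on fresh contigs and records which member a correct 128-bp pruning
must remove, giving the linkage rule an exact target.

What passing simulator-based tests does **not** show: performance on real
GBS libraries with restriction-site biology (enzyme-motif tag spacing, PCR
duplicates, allele dropout correlated with divergence), within-species
coalescent variation, paralogous collapse, or reference genomes from
distant relatives where most tags fail to align. Those effects are exactly
why the filter sweeps exist; the simulation establishes correctness of the
machinery, not field performance.

## Problem sizes used by the tests

The shipped test and acceptance runs use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: the
concordance experiment uses 8 species × 3 samples, 500 loci at depth 20 on
a balanced ultrametric tree (each internal branch then expects ~30
mutations, so 100% bootstrap support for true clades is the correct
outcome, not luck); the error-regime experiments use 200–300 loci at the
default depth 7 over ten seeds; oracle-equivalence checks run on hundreds
of random 30 × 300 matrices and tag sets up to 2,000 sequences. A balanced
tree is used rather than a random one so that the support expectation is a
property of the design, not of a lucky draw of branch lengths.

## Numerical and degenerate-input policy

* Likelihoods in log space; GQ capped at 99 and reported to 0.01.
* NJ rejects `NA`/`NaN`/negative distances and errors on sample pairs with
  zero co-called sites, naming the pair.
* The VCF writer sorts unsorted input (with a message) rather than erroring;
  the reader skips non-biallelic records with a warning and a count.
* Zero-length collapse tolerance is 1e-10 — far below any branch supported
  by even a single site, far above float noise.
* Empty matrices error on export; empty tag sets and empty pair sets are
  legal intermediate values.

## Known limitations

Single-end, fixed-length tags only; no gapped alignment or indels; no
base-quality-aware likelihoods; LD pruning is physical distance only (no
r²); NJ/bootstrap is the only internal inference engine. These boundaries
are deliberate — each omitted piece has a mature external tool, reachable
through the exporters.
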