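---
title: "Methods: context-specific DMR calling and allele-dosage association"
author: "dmrdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific DMR calling and allele-dosage association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrdose)
```

## The problem

In plants, cytosine methylation occurs in three sequence contexts — CG,
CHG and CHH (H = A, C or T) — maintained by distinct pathways, and is a
candidate regulator of gene expression under stress.  `dmrdose`
implements the analysis chain used to ask, for a pair of potato
(*Solanum tuberosum*) cultivars profiled by whole-genome bisulfite
sequencing before and after heat stress, three questions:

1. Where do the two genotypes differ in methylation (constitutive DMRs),
   and where does heat change methylation within a genotype (induced
   DMRs)?
2. Do those differentially methylated regions (DMRs) coincide with
   differentially expressed genes (DEGs), and if methylation regulated
   expression, do hypermethylated DMRs sit preferentially on
   downregulated genes?
3. Is methylation state associated with *genetic* divergence instead —
   specifically, with the per-region sum of alternative-allele dosages
   called from tetraploid genotypes?

The package consumes Bismark genome-wide cytosine reports (CX files),
GFF3/BED annotations, a differential-expression table and a VCF with
tetraploid genotypes, and is exercised end to end on synthetic data in
which every downstream answer is planted as ground truth.

All internal coordinates are 0-based half-open; conversion to and from
the 1-based formats (CX, GFF3, VCF) happens only at the I/O boundary.

## Weighted methylation levels and profiles

The methylation level of any set of cytosines is the coverage-weighted
level
$$\mathrm{wml} = \frac{\sum_i m_i}{\sum_i (m_i + u_i)},$$
where $m_i$ and $u_i$ are the methylated and unmethylated read counts of
cytosine $i$ — never a mean of per-site proportions, so a site covered by
two reads cannot outvote one covered by fifty.  The same rule applies to
200 bp genome bins (`bin_methylation()`), 500 kb chromosome-density
windows (`chromosome_density()`), and metagene profiles
(`metagene_profile()`), where read counts are pooled across features and
replicates *before* division.  A consequence worth knowing: pooling
replicates then computing the level equals computing it on the
concatenated records, and a bin with zero covered cytosines is
*undefined* (`NA`), not zero.

Metagene profiles split a 2 kb upstream flank, the feature body rescaled
to a fixed number of proportional bins (a cytosine at relative body
position $r$ lands in bin $\lfloor r \cdot n_\mathrm{body}\rfloor$), and
a 2 kb downstream flank; minus-strand features are reversed so bin 0 is
always the 5' end.  Defaults are 100 flank bins (20 bp each) and 100
body bins; both are free parameters since display conventions vary.
Symmetric CG sites on opposite strands are deliberately *not* pooled:
CX reports list each strand's cytosine separately and every record is
kept as its own observation.

## DMR calling

DMRs between a reference and a comparison group are called per context
with a noise-filter chain:

1. **Pool replicates** by summing read counts per position and strand.
   No per-replicate dispersion model is fitted; significance is assessed
   on pooled counts, which matches the pooled-count testing of the
   established DMR callers this chain follows.
2. **Smooth proportions** at each cytosine $x$ with a Gaussian kernel,
   $$\hat p(x) = \frac{\sum_i K\!\left(\frac{x - x_i}{h}\right) m_i}
                      {\sum_i K\!\left(\frac{x - x_i}{h}\right) t_i},$$
   with $t_i$ the total reads at $x_i$ and weights truncated at
   $3\sigma$.  Counts, not proportions, are smoothed, so deep sites
   weigh more.  The bandwidth $h$ is the kernel standard deviation,
   default 10 bp.  This default is set by the geometry of the size
   thresholds below: the smallest reportable DMRs are 25 bp (CHH) and
   50 bp (CG/CHG), and a kernel must keep most of its mass inside such a
   region for the region's proportion difference to survive smoothing.
   At $h = 10$ bp a centred site in a 50 bp region keeps ~99% of the
   kernel mass inside; at $h = 100$ bp it would keep ~38%, smoothing a
   0.6 difference down to ~0.23 — below the CG threshold — and making
   minimum-size DMRs structurally undetectable.
3. **Candidate regions** are maximal runs of consecutive cytosines whose
   smoothed difference (comparison − reference) is $\ge$ the context's
   minimum proportion difference (hyper) or $\le$ its negative (hypo).
   Ties at the threshold are included: a *minimum* proportion of
   difference reads as an inclusive bound.  A region spans its first to
   last cytosine, half-open.
4. **Test** each candidate with a two-sided Fisher's exact test on the
   pooled 2×2 table `[[meth_cmp, unmeth_cmp], [meth_ref, unmeth_ref]]`
   (all-zero tables get $p = 1$ by convention), and **adjust** across
   all candidates of one context and comparison with Benjamini–Hochberg
   (the field's default reading of an unqualified "FDR").
5. **Filter**: $q < 0.05$; span $\ge$ 50/50/25 bp for CG/CHG/CHH;
   absolute pooled proportion difference $\ge$ 0.40/0.30/0.10; mean
   reads per cytosine $\ge 8$; and at least 4 cytosines.  Mean coverage
   is defined symmetrically as total reads of both groups divided by
   (cytosines × 2 groups), since the published threshold does not say
   "per group".  `min_cytosines = 4` is a guard against single-cytosine
   "regions" and is configurable.
6. **Merge** same-context, same-direction DMRs on one chromosome whose
   gap is under 200 bp.  Merged statistics are *recomputed* from the
   pooled counts (Fisher + BH over the merged set) rather than taking a
   min/max of the parts, so reported p- and q-values stay meaningful.

Direction is reported for the comparison group relative to the reference
group: `hyper` means more methylated in the comparison cultivar.
Exchanging the two groups provably flips every direction and leaves
intervals and p-values unchanged, which the test suite asserts exactly.

## DMR–gene association and the DMR-DEG taxonomy

Genes get three windows relative to the direction of transcription:
2 kb upstream of the TSS, the gene body, and 2 kb downstream of the TES,
clipped at position 0.  Every (DMR, gene, window) pair with $\ge$ 1 bp of
overlap is a link; a DMR straddling a TSS therefore links to two windows
of the same gene, and counts once per window in the region-stratified
tables — region panels are only disjoint for fully contained DMRs, and
per-window counting is the one consistent reading.  For the multi-DMR
taxonomy the same DMR is deduplicated (it is one DMR): a DEG with one
linked DMR is `single`, with several all-same-direction DMRs
`unidirectional_multi`, otherwise `bidirectional_multi`.

DEG status is strict on both axes: `up` iff FDR < 0.05 *and*
log2FC > 1; `down` iff FDR < 0.05 and log2FC < −1; a gene at exactly
log2FC 1 or exactly FDR 0.05 is `ns`.  Status is always recomputed from
the numeric columns at read time; the stored status column of an input
table carries no authority.  `ns` genes are excluded from the DMR-DEG
count table but retained in the link set, because the dosage summary is
also produced for *all* DMR-associated genes.

## Allele-dosage association

In an autotetraploid, each biallelic site carries 0–4 copies of the
alternative allele (the dosage).  SNPs are filtered to biallelic
single-base records with QUAL ≥ 30, per-sample depth within [10, 50]
(both bounds inclusive — "between 10 and 50" is ambiguous, and the
inclusive per-sample reading is the stricter reproducible one), and a
dosage-based allele frequency strictly inside (0.1, 0.9).  The frequency
denominator is $4 \times$ the number of genotyped samples: after
variant calling, dosages are the only allele-frequency information
available, and both tails are excluded so that a "minor" allele
frequency above 0.1 is enforced whichever allele is minor.  Missing
tetraploid genotypes (`./././.`) are carried as missing and excluded
from sums — never imputed as zero, which would bias dosage totals
downward for the worse-genotyped cultivar.

Each DMR's dosage is the per-cultivar sum over the filtered SNPs located
*within the DMR interval itself* — not the surrounding gene window, even
when the DMR lies in a flank.  The relation of the two sums
(comparison < / > / = reference) is tabulated by genomic region and
methylation direction, for DMR-DEGs only and for all DMR-associated
genes, and optionally restricted to the deamination-type transition
classes C>T, T>C, G>A, A>G (the classes attributable to deamination of
methylated cytosines, with the reverse complements covering reference
genomes that carry the alternative allele).  DMRs containing no filtered
SNP keep relation `equal` (0 = 0) and stay in the summary; `n_snps` is
reported so they can be excluded in sensitivity analyses.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` generate a complete, seed-exact
dataset: a random multi-chromosome genome (default 2 × 500 kb, GC
content 40%), non-overlapping stranded genes on the chromosome arms,
repeats concentrated in a pericentromeric middle third, per-replicate CX
reports for two cultivars × two time points, a tetraploid two-sample
VCF, a DE table, and a truth object.

The methylation model is piecewise-constant: 1 kb segments draw a
baseline level per context — CG from a bimodal mixture (70% in
0.60–0.95, 30% near zero), CHG from a wider bimodal mixture reaching
0.80, CHH from a zero-skewed band within 0.01–0.17 — so the global bin
distributions reproduce the canonical ordering of medians
CG > CHG > CHH.  Planted DMRs override the baseline with a crisp
low/high level pair whose gap is the planted effect (default 1.5× the
context's minimum proportion difference over 2× its minimum size);
the pair is drawn inside the context's typical band, so a planted CHH
DMR moves within the near-zero CHH regime rather than at implausible
mid-range levels.  Constitutive DMRs differ between cultivars at both
time points and are placed inside a random gene's windows so the
association stages have signal; induced DMRs (CHH-biased, in one
cultivar) differ only after heat.  Planted regions are additionally
required to contain at least 8 cytosines of their own context spread
across the interval: a "DMR" whose interval holds two or three
informative sites encodes no recoverable signal for any caller, so such
placements are rejected rather than counted against sensitivity.
Observed counts are Binomial(depth, level) with depth ~ Poisson(30)
independently per sample; DMR placement, DEG status and dosage coupling
are drawn independently of each other, so the direction × regulation
table is unbiased by construction — matching the null expectation the
analysis is designed to test.

Variants are background SNPs (≈1 per 2 kb, with QUAL/depth drawn so the
standard filters remove a known fraction, and a few missing genotypes)
plus 1 + Pois(1) filter-passing SNPs inside each constitutive DMR.  With
probability `dosage_coupling_prob` (default 0.8) a DMR realises the
negative methylation–dosage coupling: every planted SNP in it favours
the cultivar that is *hypo*methylated there with the strictly larger
dosage.  At coupling 0.5 there is no association — the null case.

What the generator does **not** emulate: read-level data (FASTQ),
bisulfite conversion errors, per-cytosine stochastic methylation within
a region, linkage between SNPs, repeat-family structure, and biological
replicate heterogeneity beyond sampling noise.  Passing tests therefore
demonstrate that the chain recovers planted truth under sampling noise
at realistic depth — not that it is robust to alignment artefacts or
dispersion between biological replicates.

## Numerical choices and problem sizes

* Smoothing weights use the unnormalised Gaussian kernel (constants
  cancel in the ratio) truncated at 3σ, evaluated by a two-pointer sweep
  in C++; positions must be strictly increasing and the smoothed value
  is `NA` where the windowed total coverage is zero.
* Fisher tests use `stats::fisher.test`; the suite cross-checks them
  against a full hypergeometric enumeration with the same
  $\le p_\mathrm{obs}(1 + 10^{-7})$ tie rule, to 1e-10.  BH uses
  `stats::p.adjust`, cross-checked against an independent step-up
  implementation.
* Merging chains sorted intervals with a running end, which equals the
  exhaustive merge-to-fixpoint closure; the suite verifies this on
  random interval sets.
* The test and acceptance workloads use 1 Mb genomes (2 × 500 kb) at
  depth 30 with 3 replicates per group — large enough that each planted
  context has dozens of DMR-scale regions, small enough to run many
  seeded replicates in one sitting.  Recovery is scored at ≥ 50%
  reciprocal overlap with matching context and direction.

## Known limitations

* No beta-binomial / dispersion modelling: replicates are pooled, so a
  single aberrant replicate can create or mask signal; the published
  chain this follows shares the limitation.
* The smoothing bandwidth trades sensitivity at minimum size against
  locality; 10 bp suits the published size thresholds but users
  targeting broad, diffuse methylation drift should raise it along with
  the size thresholds.
* Dosage association is correlational and unphased; with one WGS sample
  per cultivar the per-cultivar dosage sum is a point estimate with no
  sampling variance attached.
* The MAF filter is applied to the samples present in the VCF (here the
  two cultivars); whether the original filter ran before or after
  restricting to these samples is unknowable from the publication, and
  with more samples the two orders differ.
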