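# dmrdose

Context-specific differential DNA methylation, gene expression, and
tetraploid allele-dosage association.

`dmrdose` is an R package for epigenomic comparisons between two groups
of whole-genome bisulfite sequencing (WGBS) samples — typically two
plant genotypes, or one genotype before and after a stress treatment.
It was built around a potato (*Solanum tuberosum*) heat-stress study
design: two tetraploid cultivars, three replicates each, profiled before
and after heat, plus RNA-seq differential expression and whole-genome
sequencing variants.  It answers three questions: where the methylomes
differ (DMRs, per CG/CHG/CHH context), whether those differences sit on
differentially expressed genes (DMR-DEGs), and whether methylation
direction is associated with alternative-allele dosage inside the DMRs.

## The method

**Weighted methylation.** Every level is coverage-weighted:
`wml = sum(meth) / sum(meth + unmeth)` over the cytosines of a bin,
window or metagene segment — never a mean of per-site proportions.

**DMR calling** (per context, comparison vs reference group):

1. pool replicate read counts per cytosine;
2. smooth methylation proportions with a Gaussian kernel
   (`p(x) = Σ K((x−xᵢ)/h)·methᵢ / Σ K((x−xᵢ)/h)·totalᵢ`, h = 10 bp,
   truncated at 3σ);
3. take maximal runs of cytosines whose smoothed difference exceeds the
   context threshold (hyper) or its negative (hypo);
4. Fisher's exact test on each run's pooled 2×2 count table,
   Benjamini–Hochberg adjustment across all runs;
5. filter: FDR < 0.05, span ≥ 50/50/25 bp and |Δ proportion| ≥
   0.40/0.30/0.10 for CG/CHG/CHH, mean coverage per cytosine ≥ 8,
   ≥ 4 cytosines;
6. merge same-direction DMRs separated by < 200 bp, recomputing the
   statistics from the merged pooled counts.

**Association.** Genes get 2 kb upstream / gene body / 2 kb downstream
windows (strand-aware); every overlapping (DMR, gene, window) pair is a
link.  DEGs are strict: FDR < 0.05 and |log2FC| > 1.  Links are
tabulated by context × region × methylation direction × regulation, and
genes are classified single / unidirectional-multi / bidirectional-multi
by their distinct linked DMRs.

**Dosage.** SNPs (biallelic, QUAL ≥ 30, depth 10–50, dosage-based allele
frequency in (0.1, 0.9)) carry a 0–4 alternative-allele dosage per
tetraploid sample.  Each DMR's per-cultivar dosage is the sum over SNPs
inside it; the summary counts DMRs by region × direction × relation
(comparison cultivar lower / higher / equal), optionally restricted to
deamination-type SNPs (C>T, T>C, G>A, A>G).

A seed-reproducible synthetic-data generator (`simulate_dataset()`)
plants DMRs, DEGs and a methylation–dosage coupling as ground truth and
writes the same file formats the readers consume (Bismark CX reports,
GFF3, VCF, TSV), so the whole chain is testable end to end.  See the
methods vignette (`vignettes/methylation-dosage-methods.Rmd`) for the
model, parameter rationale and limitations.

## Worked example

Simulate a two-cultivar dataset (2 × 500 kb genome, depth 30, three
replicates, 12 planted constitutive DMRs) and run the constitutive
analysis:

```r
library(dmrdose)

cfg <- sim_config(rng_seed = 42)
ds  <- simulate_dataset(cfg, timepoints = "before")
res <- run_constitutive(ds$methylomes, ds$genome$genes, ds$de_table, ds$snps)
res
#> dmrdose analysis run
#>   comparison: AA vs CA (constitutive)
#>   DMRs: 11; DMR-gene links: 12
#>     CG: 2 hyper / 2 hypo
#>     CHG: 2 hyper / 1 hypo
#>     CHH: 3 hyper / 1 hypo
```

Eleven DMRs are called: e.g. 2 hyper CG means two regions where cultivar
AA (the comparison group) is CG-hypermethylated relative to cultivar CA.
Checking them against the planted truth:

```r
planted <- ds$truth$dmrs[ds$truth$dmrs$type == "constitutive", ]
rec <- dmr_recovery(res$dmrs, planted)
sprintf("recovered %d of %d planted DMRs", rec$n_recovered, rec$n_planted)
#> [1] "recovered 11 of 12 planted DMRs"

head(res$dmrs[, c("chrom","start","end","context","direction","n_cytosines","prop_diff","q_value")])
#>   chrom  start    end context direction n_cytosines  prop_diff       q_value
#> 1  chr1  90700  90757      CG     hyper           6  0.5899195  4.793407e-88
#> 2  chr1 370629 370694      CG     hyper          12  0.6013232 6.292952e-199
#> 3  chr2  64745  64815      CG      hypo           6 -0.5854556  2.525769e-93
#> 4  chr2 445606 445688      CG      hypo          14 -0.5877571 4.928918e-207
#> 5  chr1 432795 432886     CHG     hyper           9  0.4932405 5.576457e-128
#> 6  chr2  62984  63063     CHG      hypo           9 -0.4660255  2.159944e-84
```

`prop_diff` is the pooled AA − CA methylation proportion inside the DMR:
the calls sit at the planted effect sizes (±0.6 CG, ±0.45 CHG).  The
dosage association summary (here aggregated over regions) shows the
planted negative coupling — hypomethylated-in-AA DMRs tend to carry the
*higher* AA dosage, hypermethylated ones the lower:

```r
aggregate(count ~ direction + relation, res$dosage_summary_all, sum)
#>   direction   relation count
#> 1     hyper cmp_gt_ref     2
#> 2      hypo cmp_gt_ref     2
#> 3     hyper cmp_lt_ref     5
#> 4      hypo cmp_lt_ref     0
#> 5     hyper      equal     1
#> 6      hypo      equal     2
```

`report(res, "out/")` writes all tables as TSV (plus DMRs as BED6) with
a run manifest.  Real data enters through `read_cx_report()`,
`read_annotations()`, `read_de_table()` and `read_vcf_tetraploid()`;
`run_induced()` runs the before-vs-after comparison within one cultivar.

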