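Package: dmrdose
Title: Differential DNA Methylation, Gene Expression and Tetraploid Allele
    Dosage Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls context-specific (CG, CHG, CHH) differentially methylated
    regions (DMRs) between two sample groups from Bismark genome-wide cytosine
    reports using Gaussian-kernel smoothed methylation proportions, Fisher's
    exact tests on pooled read counts, Benjamini-Hochberg FDR control and
    gap-based merging.  Computes weighted methylation levels in fixed-width
    genome bins and metagene profiles around genes and repeats.  Links DMRs to
    genes within 2 kb flanking windows, classifies DMR-associated
    differentially expressed genes by context, region, methylation direction
    and regulation, and associates per-DMR alternative-allele dosage sums from
    tetraploid genotypes with methylation direction, including the
    deamination-type SNP subset.  Ships a seed-reproducible synthetic-data
    generator that plants DMRs, differentially expressed genes and a
    methylation-dosage coupling as ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    rlang,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
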