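RELATIONS <- c("cmp_lt_ref", "cmp_gt_ref", "equal")

#' SNP filtering parameters
#'
#' Defaults follow the published variant filters: biallelic SNPs only,
#' minor allele frequency above 0.1, QUAL >= 30 and per-sample read depth
#' between 10 and 50 (both bounds inclusive).  Allele frequency is
#' computed from the tetraploid dosages across all genotyped samples,
#' `sum(dosage) / (4 * n_genotyped)`, and both tails are excluded
#' (frequency must lie strictly inside `(min_maf, 1 - min_maf)`).
#'
#' @param min_maf,min_qual,min_depth,max_depth,biallelic_only overrides.
#' @return a list of class `snp_filter_params`.
#' @export
snp_filter_params <- function(min_maf = 0.1, min_qual = 30,
                              min_depth = 10, max_depth = 50,
                              biallelic_only = TRUE) {
  stopifnot(min_maf > 0, min_maf < 0.5, min_depth <= max_depth)
  structure(list(min_maf = min_maf, min_qual = min_qual,
                 min_depth = min_depth, max_depth = max_depth,
                 biallelic_only = biallelic_only),
            class = "snp_filter_params")
}

snp_samples <- function(snps) {
  s <- attr(snps, "samples")
  if (!is.null(s)) return(s)
  sub("^dosage_", "", grep("^dosage_", names(snps), value = TRUE))
}

#' Filter tetraploid SNP records
#'
#' Retains biallelic single-base SNPs with `qual >= min_qual`, every
#' sample's read depth within `[min_depth, max_depth]`, and dosage-based
#' alternative-allele frequency strictly inside
#' `(min_maf, 1 - min_maf)`.  Records with missing genotype in every
#' sample are dropped and counted (reported via a message).
#'
#' @param snps a SNP `data.frame` from [read_vcf_tetraploid()].
#' @param params a [snp_filter_params()] object.
#' @return the surviving SNP rows (samples attribute preserved).
#' @export
filter_snps <- function(snps, params = snp_filter_params()) {
  samples <- snp_samples(snps)
  if (length(samples) == 0) stop("no dosage_<sample> columns in SNP table")
  dose <- as.matrix(snps[, paste0("dosage_", samples), drop = FALSE])
  depth <- as.matrix(snps[, paste0("depth_", samples), drop = FALSE])

  all_missing <- rowSums(!is.na(dose)) == 0
  if (any(all_missing)) {
    message(sum(all_missing), " SNP(s) dropped: genotype missing in all samples")
  }
  keep <- !all_missing

  if (params$biallelic_only) {
    keep <- keep & !grepl(",", snps$alt, fixed = TRUE) &
      nchar(snps$ref) == 1L & nchar(snps$alt) == 1L &
      snps$ref %in% c("A", "C", "G", "T") & snps$alt %in% c("A", "C", "G", "T") &
      snps$ref != snps$alt
  }
  keep <- keep & !is.na(snps$qual) & snps$qual >= params$min_qual
  depth_ok <- rowSums(is.na(depth) | depth < params$min_depth |
                        depth > params$max_depth) == 0
  keep <- keep & depth_ok

  n_genotyped <- rowSums(!is.na(dose))
  freq <- rowSums(dose, na.rm = TRUE) / (4 * pmax(n_genotyped, 1L))
  keep <- keep & freq > params$min_maf & freq < 1 - params$min_maf

  out <- snps[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' SNPs inside a half-open genomic interval
#'
#' A SNP at 1-based position `p` occupies the 0-based point `p - 1`; it is
#' inside `[start, end)` iff `start <= p - 1 < end`.  A SNP whose 1-based
#' position equals the interval's exclusive end coordinate is therefore
#' excluded; one at the start is included.
#'
#' @param snps a SNP `data.frame`.
#' @param chrom,start,end the interval (0-based half-open).
#' @return the contained SNP rows.
#' @export
snps_in_interval <- function(snps, chrom, start, end) {
  keep <- snps$chrom == chrom & (snps$pos - 1L) >= start & (snps$pos - 1L) < end
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- snp_samples(snps)
  out
}

#' Per-DMR alternative-allele dosage sums and relation
#'
#' For each DMR, sums the alternative-allele dosages of all filtered SNPs
#' located within the DMR interval itself (not the surrounding gene
#' window), separately for the reference and comparison cultivars, and
#' classifies the relation of the sums: `cmp_lt_ref`, `cmp_gt_ref` or
#' `equal`.  A DMR containing no SNP has sums 0 = 0 and relation `equal`
#' (`n_snps` lets such DMRs be excluded in sensitivity analyses).  SNPs
#' with a missing dosage in any involved sample are skipped.
#'
#' @param dmrs a DMR `data.frame` with `dmr_id` (added as row index if
#'   absent), `chrom`, `start`, `end`, `direction`.
#' @param snps a filtered SNP `data.frame`.
#' @param ref_samples,cmp_samples sample name(s) of the reference and
#'   comparison cultivars; multi-sample cultivars are summed.
#' @return a `data.frame`: `dmr_id`, `chrom`, `start`, `end`, `context`,
#'   `direction`, `n_snps`, `dosage_ref`, `dosage_cmp`, `relation`.
#' @export
dmr_dosage <- function(dmrs, snps, ref_samples, cmp_samples) {
  if (!"dmr_id" %in% names(dmrs)) {
    dmrs$dmr_id <- if (nrow(dmrs)) paste0("dmr_", seq_len(nrow(dmrs))) else character()
  }
  ref_cols <- paste0("dosage_", ref_samples)
  cmp_cols <- paste0("dosage_", cmp_samples)
  missing_cols <- setdiff(c(ref_cols, cmp_cols), names(snps))
  if (length(missing_cols)) stop("SNP table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  n <- nrow(dmrs)
  dosage_ref <- integer(n); dosage_cmp <- integer(n); n_snps <- integer(n)
  for (i in seq_len(n)) {
    inside <- snps_in_interval(snps, dmrs$chrom[i], dmrs$start[i], dmrs$end[i])
    if (nrow(inside)) {
      complete <- rowSums(is.na(inside[, c(ref_cols, cmp_cols), drop = FALSE])) == 0
      inside <- inside[complete, , drop = FALSE]
    }
    n_snps[i] <- nrow(inside)
    dosage_ref[i] <- sum(as.matrix(inside[, ref_cols, drop = FALSE]))
    dosage_cmp[i] <- sum(as.matrix(inside[, cmp_cols, drop = FALSE]))
  }
  relation <- rep("equal", n)
  relation[dosage_cmp < dosage_ref] <- "cmp_lt_ref"
  relation[dosage_cmp > dosage_ref] <- "cmp_gt_ref"
  data.frame(
    dmr_id = dmrs$dmr_id, chrom = dmrs$chrom, start = dmrs$start,
    end = dmrs$end,
    context = if ("context" %in% names(dmrs)) dmrs$context else NA_character_,
    direction = dmrs$direction,
    n_snps = n_snps, dosage_ref = dosage_ref, dosage_cmp = dosage_cmp,
    relation = relation, stringsAsFactors = FALSE
  )
}

#' Deamination-type SNP subset
#'
#' Restricts to the transition classes attributable to (methyl)cytosine
#' deamination: C>T and T>C, plus their reverse complements G>A and A>G
#' (covering sites where the reference genome carries the alternative
#' allele relative to the studied cultivars).
#'
#' @param snps a SNP `data.frame`.
#' @return the subset of rows.
#' @export
deamination_subset <- function(snps) {
  pairs <- paste(snps$ref, snps$alt, sep = ">")
  keep <- pairs %in% c("C>T", "T>C", "G>A", "A>G")
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- snp_samples(snps)
  out
}

#' Dosage-association summary by region, direction and relation
#'
#' Counts DMRs into the region (upstream / gene body / downstream) x
#' methylation direction (hyper / hypo) x dosage relation (comparison
#' cultivar lower / higher / equal) cells, once per (gene, window) link in
#' the selected gene set: either only DMR-DEGs (`"deg_only"`) or all
#' DMR-associated genes (`"all_genes"`).
#'
#' @param dmr_dosages output of [dmr_dosage()].
#' @param links output of [link_dmrs_to_genes()].
#' @param degs a DEG `data.frame` with `gene_id` and `status`.
#' @param gene_set `"deg_only"` or `"all_genes"`.
#' @return a tidy `data.frame`: `region`, `direction`, `relation`,
#'   `count` (18 rows, zeros included).
#' @export
dosage_association_summary <- function(dmr_dosages, links, degs,
                                       gene_set = c("deg_only", "all_genes")) {
  gene_set <- match.arg(gene_set)
  grid <- expand.grid(region = REGIONS, direction = DIRECTIONS,
                      relation = RELATIONS, stringsAsFactors = FALSE)
  lk <- links
  if (gene_set == "deg_only") {
    status <- degs$status[match(lk$gene_id, degs$gene_id)]
    lk <- lk[!is.na(status) & status %in% REGULATIONS, , drop = FALSE]
  }
  relation <- dmr_dosages$relation[match(lk$dmr_id, dmr_dosages$dmr_id)]
  lk <- lk[!is.na(relation), , drop = FALSE]
  relation <- relation[!is.na(relation)]
  if (nrow(lk) == 0) {
    grid$count <- 0L
    return(grid)
  }
  tab <- as.data.frame(table(region = lk$region, direction = lk$direction,
                             relation = relation), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  out <- merge(grid, tab, all.x = TRUE, sort = FALSE)
  out$count[is.na(out$count)] <- 0L
  out <- out[order(match(out$region, REGIONS), match(out$direction, DIRECTIONS),
                   match(out$relation, RELATIONS)), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("region", "direction", "relation", "count")]
}
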