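#' Constitutive cultivar-vs-cultivar analysis
#'
#' The full baseline (pre-stress) comparison between two cultivars: calls
#' DMRs per methylation context from the before-stress replicate tracks,
#' links them to genes within 2 kb windows, tabulates DMR-DEG counts and
#' the single / unidirectional / bidirectional multi-DMR classes, and —
#' when SNPs are supplied — filters them, sums per-DMR alternative-allele
#' dosages and builds the dosage-association summaries for both gene sets
#' (DMR-DEGs only; all DMR-associated genes) and the deamination-type SNP
#' subset.  Deterministic given its inputs.
#'
#' @param methylomes nested list `methylomes[[cultivar]][["before"]]` of
#'   replicate cytosine record `data.frame`s (as produced by
#'   [simulate_methylome()], or assembled from [read_cx_report()] calls).
#' @param genes gene annotation `data.frame`.
#' @param de_table DE results with `gene_id`, `log2fc`, `fdr` (status is
#'   recomputed with [classify_deg()]).
#' @param snps optional SNP `data.frame` from [read_vcf_tetraploid()].
#' @param cultivar_ref,cultivar_cmp reference and comparison cultivar
#'   labels (DMR direction is `cultivar_cmp` relative to `cultivar_ref`).
#' @param contexts methylation contexts to analyse.
#' @param params optional named list of [dmr_params()] per context.
#' @param flank_bp gene flanking window (default 2000).
#' @param snp_params a [snp_filter_params()].
#' @return a list of class `dmrdose_run`: `dmrs`, `dmr_counts`, `links`,
#'   `deg_counts`, `multi_classes`, and (with SNPs) `dmr_dosages`,
#'   `dosage_summary_deg`, `dosage_summary_all`,
#'   `dosage_summary_deamination_deg`, `dosage_summary_deamination_all`.
#' @export
run_constitutive <- function(methylomes, genes, de_table, snps = NULL,
                             cultivar_ref = "CA", cultivar_cmp = "AA",
                             contexts = CONTEXTS, params = NULL,
                             flank_bp = 2000, snp_params = snp_filter_params()) {
  for (cv in c(cultivar_ref, cultivar_cmp)) {
    if (is.null(methylomes[[cv]][["before"]])) {
      stop("missing before-stress methylome for cultivar ", cv)
    }
  }
  ref_tracks <- methylomes[[cultivar_ref]][["before"]]
  cmp_tracks <- methylomes[[cultivar_cmp]][["before"]]
  params_used <- lapply(contexts, function(ctx) {
    if (!is.null(params) && !is.null(params[[ctx]])) params[[ctx]] else dmr_params(ctx)
  })
  names(params_used) <- contexts
  dmrs <- call_dmrs_all_contexts(ref_tracks, cmp_tracks, contexts, params)
  de_table$status <- classify_deg(de_table$log2fc, de_table$fdr)
  links <- link_dmrs_to_genes(dmrs, genes, flank_bp)
  res <- list(
    cultivar_ref = cultivar_ref, cultivar_cmp = cultivar_cmp,
    params = c(params_used, list(flank_bp = flank_bp, snp_params = snp_params)),
    dmrs = dmrs,
    dmr_counts = dmr_count_summary(dmrs),
    links = links,
    deg_counts = dmr_deg_counts(links, de_table),
    multi_classes = multi_dmr_classes(links, de_table),
    de_table = de_table
  )
  if (!is.null(snps)) {
    ref_s <- grep(cultivar_ref, snp_samples(snps), value = TRUE, fixed = TRUE)
    cmp_s <- grep(cultivar_cmp, snp_samples(snps), value = TRUE, fixed = TRUE)
    if (!length(ref_s) || !length(cmp_s)) {
      stop("SNP samples do not match cultivar labels")
    }
    filtered <- filter_snps(snps, snp_params)
    res$dmr_dosages <- dmr_dosage(dmrs, filtered, ref_s, cmp_s)
    res$dosage_summary_deg <- dosage_association_summary(
      res$dmr_dosages, links, de_table, "deg_only")
    res$dosage_summary_all <- dosage_association_summary(
      res$dmr_dosages, links, de_table, "all_genes")
    deam <- deamination_subset(filtered)
    deam_dosages <- dmr_dosage(dmrs, deam, ref_s, cmp_s)
    res$dosage_summary_deamination_deg <- dosage_association_summary(
      deam_dosages, links, de_table, "deg_only")
    res$dosage_summary_deamination_all <- dosage_association_summary(
      deam_dosages, links, de_table, "all_genes")
  }
  class(res) <- "dmrdose_run"
  res
}

#' Heat-induced before-vs-after analysis for one cultivar
#'
#' Calls DMRs between the before-stress (reference) and after-stress
#' (comparison) samples of one cultivar — `direction = "hyper"` means more
#' methylated after heat — and overlaps them with that cultivar's heat
#' DEGs within 2 kb windows.
#'
#' @param methylomes nested list with `[[cultivar]][["before"]]` and
#'   `[[cultivar]][["after"]]` replicate tracks.
#' @param cultivar which cultivar to analyse.
#' @inheritParams run_constitutive
#' @return a list of class `dmrdose_run`: `dmrs`, `dmr_counts`, `links`,
#'   `deg_counts`.
#' @export
run_induced <- function(methylomes, cultivar, genes, de_table,
                        contexts = CONTEXTS, params = NULL, flank_bp = 2000) {
  for (tp in c("before", "after")) {
    if (is.null(methylomes[[cultivar]][[tp]])) {
      stop("missing ", tp, " methylome for cultivar ", cultivar)
    }
  }
  params_used <- lapply(contexts, function(ctx) {
    if (!is.null(params) && !is.null(params[[ctx]])) params[[ctx]] else dmr_params(ctx)
  })
  names(params_used) <- contexts
  dmrs <- call_dmrs_all_contexts(methylomes[[cultivar]][["before"]],
                                 methylomes[[cultivar]][["after"]],
                                 contexts, params)
  de_table$status <- classify_deg(de_table$log2fc, de_table$fdr)
  links <- link_dmrs_to_genes(dmrs, genes, flank_bp)
  res <- list(cultivar = cultivar,
              params = c(params_used, list(flank_bp = flank_bp)),
              dmrs = dmrs,
              dmr_counts = dmr_count_summary(dmrs), links = links,
              deg_counts = dmr_deg_counts(links, de_table),
              de_table = de_table)
  class(res) <- "dmrdose_run"
  res
}

call_dmrs_all_contexts <- function(ref_tracks, cmp_tracks, contexts, params) {
  # pool replicates once per group; call_dmrs' own pooling is then a no-op
  ref_pooled <- pool_replicates(ref_tracks)
  cmp_pooled <- pool_replicates(cmp_tracks)
  per_ctx <- lapply(contexts, function(ctx) {
    p <- if (!is.null(params) && !is.null(params[[ctx]])) params[[ctx]] else dmr_params(ctx)
    call_dmrs(ref_pooled[ref_pooled$context == ctx, , drop = FALSE],
              cmp_pooled[cmp_pooled$context == ctx, , drop = FALSE], ctx, p)
  })
  dmrs <- do.call(rbind, per_ctx)
  if (nrow(dmrs)) dmrs$dmr_id <- paste0("dmr_", seq_len(nrow(dmrs)))
  dmrs
}

#' DMR counts by context and direction
#'
#' The hyper/hypo x CG/CHG/CHH count summary of a DMR set (the shape of a
#' DMR-count summary table), zeros included.
#'
#' @param dmrs a DMR `data.frame`.
#' @return a `data.frame` with `context`, `direction`, `count`.
#' @export
dmr_count_summary <- function(dmrs) {
  grid <- expand.grid(context = CONTEXTS, direction = DIRECTIONS,
                      stringsAsFactors = FALSE)
  grid$count <- vapply(seq_len(nrow(grid)), function(i) {
    sum(dmrs$context == grid$context[i] & dmrs$direction == grid$direction[i])
  }, integer(1))
  grid[order(match(grid$context, CONTEXTS), match(grid$direction, DIRECTIONS)), ,
       drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Write the tables and metadata of an analysis run
#'
#' Emits the result tables of [run_constitutive()] / [run_induced()] as
#' tidy TSVs in a run directory (full headers even when empty), the DMRs
#' additionally as BED6+, plus a machine-readable run manifest
#' (`run_manifest.json`) with package version, timestamp-free
#' configuration hash and row counts, so reruns of an identical
#' configuration produce byte-identical tables.
#'
#' @param results a `dmrdose_run` object.
#' @param dir output directory (created if needed).
#' @param seed optional seed to record in the manifest.
#' @return invisibly, the named vector of written paths.
#' @export
report <- function(results, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("dmrs", "dmr_counts", "links", "deg_counts", "multi_classes",
              "dmr_dosages", "dosage_summary_deg", "dosage_summary_all",
              "dosage_summary_deamination_deg", "dosage_summary_deamination_all")
  paths <- character()
  for (tb in tables) {
    if (is.null(results[[tb]])) next
    p <- file.path(dir, paste0(tb, ".tsv"))
    data.table::fwrite(results[[tb]], p, sep = "\t", quote = FALSE)
    paths[tb] <- p
  }
  if (!is.null(results$dmrs) && nrow(results$dmrs)) {
    paths["dmrs_bed"] <- file.path(dir, "dmrs.bed")
    write_dmrs(results$dmrs, bed_path = paths[["dmrs_bed"]])
  }
  manifest <- list(
    package = "dmrdose",
    version = as.character(utils::packageVersion("dmrdose")),
    seed = seed,
    config_hash = rlang::hash(results[c("cultivar_ref", "cultivar_cmp",
                                        "cultivar", "params")]),
    n_dmrs = if (is.null(results$dmrs)) 0L else nrow(results$dmrs),
    n_links = if (is.null(results$links)) 0L else nrow(results$links)
  )
  paths["manifest"] <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(paths)
}

#' @export
print.dmrdose_run <- function(x, ...) {
  cat("dmrdose analysis run\n")
  if (!is.null(x$cultivar_cmp)) {
    cat(sprintf("  comparison: %s vs %s (constitutive)\n",
                x$cultivar_cmp, x$cultivar_ref))
  } else {
    cat(sprintf("  comparison: %s after vs before heat (induced)\n", x$cultivar))
  }
  cat(sprintf("  DMRs: %d; DMR-gene links: %d\n",
              nrow(x$dmrs), nrow(x$links)))
  cm <- x$dmr_counts
  for (ctx in unique(cm$context)) {
    cat(sprintf("    %s: %d hyper / %d hypo\n", ctx,
                cm$count[cm$context == ctx & cm$direction == "hyper"],
                cm$count[cm$context == ctx & cm$direction == "hypo"]))
  }
  invisible(x)
}
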