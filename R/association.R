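REGIONS <- c("upstream", "gene_body", "downstream")
DIRECTIONS <- c("hyper", "hypo")
REGULATIONS <- c("up", "down")

#' Classify a gene's differential-expression status
#'
#' A gene is `up` if `fdr < fdr_threshold` and `log2fc > fc_threshold`,
#' `down` if `fdr < fdr_threshold` and `log2fc < -fc_threshold`, otherwise
#' `ns`.  All inequalities are strict: a gene at exactly log2FC 1 or
#' exactly FDR 0.05 is not significant.
#'
#' @param log2fc,fdr numeric vectors (recycled together).
#' @param fc_threshold absolute log2 fold-change threshold (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return character vector of `"up"`, `"down"`, `"ns"`.
#' @export
classify_deg <- function(log2fc, fdr, fc_threshold = 1, fdr_threshold = 0.05) {
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) stop("fdr must lie in [0,1]")
  status <- rep("ns", length(log2fc))
  sig <- !is.na(fdr) & !is.na(log2fc) & fdr < fdr_threshold
  status[sig & log2fc > fc_threshold] <- "up"
  status[sig & log2fc < -fc_threshold] <- "down"
  status
}

#' Upstream, gene-body and downstream windows of genes
#'
#' For a plus-strand gene `[start, end)` the windows are upstream
#' `[start - flank_bp, start)`, body `[start, end)` and downstream
#' `[end, end + flank_bp)`; for minus-strand genes upstream and downstream
#' are exchanged (windows are named relative to the direction of
#' transcription).  Windows are clipped at position 0; a window that is
#' empty after clipping is dropped.  Unstranded genes are treated as
#' plus-strand.
#'
#' @param genes a gene `data.frame` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @param flank_bp flank width in bp (default 2000).
#' @return a long `data.frame`: `gene_id`, `region`, `chrom`, `start`,
#'   `end`.
#' @export
gene_windows <- function(genes, flank_bp = 2000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  strand <- if ("strand" %in% names(genes)) genes$strand else rep("+", nrow(genes))
  minus <- !is.na(strand) & strand == "-"
  up <- data.frame(gene_id = genes$gene_id, region = "upstream",
                   chrom = genes$chrom,
                   start = ifelse(minus, genes$end, genes$start - flank_bp),
                   end = ifelse(minus, genes$end + flank_bp, genes$start),
                   stringsAsFactors = FALSE)
  body <- data.frame(gene_id = genes$gene_id, region = "gene_body",
                     chrom = genes$chrom, start = genes$start, end = genes$end,
                     stringsAsFactors = FALSE)
  dn <- data.frame(gene_id = genes$gene_id, region = "downstream",
                   chrom = genes$chrom,
                   start = ifelse(minus, genes$start - flank_bp, genes$end),
                   end = ifelse(minus, genes$start, genes$end + flank_bp),
                   stringsAsFactors = FALSE)
  out <- rbind(up, body, dn)
  out$start <- pmax(out$start, 0)
  out <- out[out$start < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link DMRs to genes through 2 kb flanking windows
#'
#' A link exists for every (DMR, gene, window) triple with at least 1 bp
#' of overlap between the DMR interval and the gene's upstream, body or
#' downstream window.  One DMR may therefore link to several windows of
#' one gene (e.g. straddling the TSS) and to several genes.
#'
#' @param dmrs a DMR `data.frame` ([call_dmrs()] output); a `dmr_id`
#'   column is added if absent (row index).
#' @param genes a gene `data.frame` (see [gene_windows()]).
#' @param flank_bp flank width in bp.
#' @return a `data.frame` of links: `gene_id`, `dmr_id`, `region`,
#'   `context`, `direction`.
#' @export
link_dmrs_to_genes <- function(dmrs, genes, flank_bp = 2000) {
  if (!"dmr_id" %in% names(dmrs)) {
    dmrs$dmr_id <- if (nrow(dmrs)) paste0("dmr_", seq_len(nrow(dmrs))) else character()
  }
  empty <- data.frame(gene_id = character(), dmr_id = character(),
                      region = character(), context = character(),
                      direction = character(), stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0 || nrow(genes) == 0) return(empty)
  win <- gene_windows(genes, flank_bp)
  if (nrow(win) == 0) return(empty)
  dmr_gr <- GenomicRanges::GRanges(
    dmrs$chrom, IRanges::IRanges(start = dmrs$start + 1L, end = dmrs$end))
  win_gr <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(start = win$start + 1L, end = win$end))
  hits <- GenomicRanges::findOverlaps(dmr_gr, win_gr, minoverlap = 1L)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    gene_id = win$gene_id[si],
    dmr_id = dmrs$dmr_id[qi],
    region = win$region[si],
    context = dmrs$context[qi],
    direction = dmrs$direction[qi],
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(out$gene_id, out$dmr_id, match(out$region, REGIONS)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DMR-DEG counts by context, region, direction and regulation
#'
#' Counts the (DMR, gene, window) links whose gene is a differentially
#' expressed gene (`up` or `down`; `ns` genes are excluded) into the full
#' 36-cell table context (CG/CHG/CHH) x region (upstream/gene body/
#' downstream) x methylation direction (hyper/hypo) x regulation
#' (up/down).  Every qualifying link contributes exactly one count, so the
#' table total equals the number of DEG-restricted links.
#'
#' @param links output of [link_dmrs_to_genes()].
#' @param degs a DEG `data.frame` with `gene_id` and `status`.
#' @return a tidy `data.frame` with `context`, `region`, `direction`,
#'   `regulation`, `count` (36 rows, zeros included).
#' @export
dmr_deg_counts <- function(links, degs) {
  grid <- expand.grid(context = CONTEXTS, region = REGIONS,
                      direction = DIRECTIONS, regulation = REGULATIONS,
                      stringsAsFactors = FALSE)
  status <- degs$status[match(links$gene_id, degs$gene_id)]
  keep <- !is.na(status) & status %in% REGULATIONS
  if (!any(keep)) {
    grid$count <- 0L
    return(grid)
  }
  obs <- data.frame(context = links$context[keep], region = links$region[keep],
                    direction = links$direction[keep], regulation = status[keep],
                    stringsAsFactors = FALSE)
  tab <- as.data.frame(table(context = obs$context, region = obs$region,
                             direction = obs$direction, regulation = obs$regulation),
                       stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  out <- merge(grid, tab, all.x = TRUE, sort = FALSE)
  out$count[is.na(out$count)] <- 0L
  out <- out[order(match(out$context, CONTEXTS), match(out$region, REGIONS),
                   match(out$direction, DIRECTIONS),
                   match(out$regulation, REGULATIONS)), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("context", "region", "direction", "regulation", "count")]
}

#' Single / unidirectional / bidirectional multi-DMR classification
#'
#' For every DEG gene with at least one linked DMR, counts the *distinct*
#' DMRs linked across all windows and contexts (a DMR overlapping two
#' windows of one gene is one DMR) and classifies the gene as `single`
#' (one DMR), `unidirectional_multi` (two or more, all hyper- or all
#' hypomethylated) or `bidirectional_multi` (two or more with both
#' directions present).
#'
#' @param links output of [link_dmrs_to_genes()].
#' @param degs a DEG `data.frame` with `gene_id` and `status`.
#' @return a `data.frame`: `gene_id`, `status`, `n_dmrs`, `klass`.
#' @export
multi_dmr_classes <- function(links, degs) {
  status <- degs$status[match(links$gene_id, degs$gene_id)]
  keep <- !is.na(status) & status %in% REGULATIONS
  lk <- links[keep, , drop = FALSE]
  if (nrow(lk) == 0) {
    return(data.frame(gene_id = character(), status = character(),
                      n_dmrs = integer(), klass = character(),
                      stringsAsFactors = FALSE))
  }
  per_dmr <- unique(lk[, c("gene_id", "dmr_id", "direction")])
  split_by_gene <- split(per_dmr$direction, per_dmr$gene_id)
  gene_ids <- names(split_by_gene)
  n_dmrs <- lengths(split_by_gene)
  klass <- vapply(split_by_gene, function(dirs) {
    if (length(dirs) == 1L) "single"
    else if (length(unique(dirs)) == 1L) "unidirectional_multi"
    else "bidirectional_multi"
  }, character(1))
  data.frame(
    gene_id = gene_ids,
    status = degs$status[match(gene_ids, degs$gene_id)],
    n_dmrs = as.integer(n_dmrs),
    klass = unname(klass),
    stringsAsFactors = FALSE
  )
}
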