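#' Configuration for the synthetic two-cultivar methylome dataset
#'
#' Describes a small multi-chromosome genome with genes and
#' pericentromeric repeats, bimodal CG/CHG and near-zero CHH methylation,
#' planted constitutive DMRs (cultivar vs cultivar at both time points),
#' planted heat-induced CHH-biased DMRs (before vs after in one cultivar),
#' planted differentially expressed genes, and a negative methylation
#' direction / allele dosage coupling.
#'
#' Defaults emulate the study conditions: per-cytosine depth ~30x, three
#' replicates per group, CG levels mostly in the 0.60-0.95 band with a
#' near-zero mode (bimodal), CHG spanning roughly 0.02-0.80, CHH between
#' 0.01 and 0.17 and skewed toward zero; planted constitutive DMRs at 1.5x
#' the context's minimum proportion difference and 2x its minimum size;
#' induced DMRs biased to the CHH context in the comparison cultivar; and
#' a dosage coupling probability of 0.8 (a hypomethylated-in-comparison
#' DMR receives the higher comparison-cultivar dosage with that
#' probability).
#'
#' @param n_chromosomes,chrom_length_bp genome shape (>= 10 kb per
#'   chromosome).
#' @param n_genes,n_repeats total feature counts across the genome.
#' @param read_depth_mean Poisson mean per-cytosine read depth per sample.
#' @param n_replicates replicates per cultivar x time point.
#' @param base_probs base composition of the random genome (named A/C/G/T).
#' @param segment_bp width of the piecewise-constant baseline methylation
#'   segments.
#' @param n_constitutive_dmrs,constitutive_context_mix count and context
#'   probabilities of planted constitutive DMRs.
#' @param n_induced_dmrs,induced_context_mix,induced_cultivar planted
#'   heat-induced DMRs (CHH-biased by default) and the cultivar carrying
#'   them.
#' @param dmr_length_multiplier,dmr_effect_multiplier planted DMR length /
#'   effect as multiples of the context's minimum size and proportion
#'   difference.
#' @param deg_fraction fraction of genes planted as DEGs (half up, half
#'   down).
#' @param log2fc_range absolute log2 fold-change range of planted DEGs.
#' @param snp_per_bp background SNP density (per bp); planted DMRs
#'   additionally receive 1 + Pois(1) SNPs each.
#' @param dosage_coupling_prob probability that a constitutive DMR
#'   realises the negative methylation-dosage coupling.
#' @param cultivar_ref,cultivar_cmp cultivar labels; DMR direction and
#'   dosage relations are reported for `cultivar_cmp` relative to
#'   `cultivar_ref`.
#' @param rng_seed integer seed; all generator stages derive their RNG
#'   streams from it, so a fixed seed reproduces the dataset exactly.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length_bp = 500000,
                       n_genes = 60, n_repeats = 30,
                       read_depth_mean = 30, n_replicates = 3,
                       base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       segment_bp = 1000,
                       n_constitutive_dmrs = 12,
                       constitutive_context_mix = c(CG = 1, CHG = 1, CHH = 1) / 3,
                       n_induced_dmrs = 10,
                       induced_context_mix = c(CG = 0.15, CHG = 0.15, CHH = 0.7),
                       induced_cultivar = "AA",
                       dmr_length_multiplier = 2,
                       dmr_effect_multiplier = 1.5,
                       deg_fraction = 0.3,
                       log2fc_range = c(1.5, 4),
                       snp_per_bp = 1 / 2000,
                       dosage_coupling_prob = 0.8,
                       cultivar_ref = "CA", cultivar_cmp = "AA",
                       rng_seed = 1) {
  stopifnot(chrom_length_bp >= 10000, n_chromosomes >= 1,
            abs(sum(base_probs) - 1) < 1e-8,
            deg_fraction >= 0, deg_fraction <= 1,
            dosage_coupling_prob >= 0, dosage_coupling_prob <= 1,
            cultivar_ref != cultivar_cmp)
  structure(as.list(environment()), class = "sim_config")
}

sim_seed <- function(config, offset) {
  (config$rng_seed * 1000L + offset) %% .Machine$integer.max
}

#' Generate a random genome with gene and repeat annotations
#'
#' Random base composition; non-overlapping genes with random strands
#' placed outside the middle third of each chromosome; non-overlapping
#' repeats concentrated in the middle ("pericentromeric") third.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param config a [sim_config()].
#' @return a list with `seqs` (named character vector, one string per
#'   chromosome), `genes` and `repeats` (annotation `data.frame`s with
#'   0-based half-open coordinates).
#' @export
generate_genome <- function(config) {
  set.seed(sim_seed(config, 1L))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  len <- config$chrom_length_bp
  seqs <- vapply(chroms, function(ch) {
    paste(sample(names(config$base_probs), len, replace = TRUE,
                 prob = config$base_probs), collapse = "")
  }, character(1))
  genes <- place_features(chroms, len, config$n_genes,
                          len_range = c(1000, 3000), zone = "arms",
                          prefix = "gene", stranded = TRUE)
  reps <- place_features(chroms, len, config$n_repeats,
                         len_range = c(200, 1500), zone = "centro",
                         prefix = "repeat", stranded = FALSE)
  names(genes)[1] <- "gene_id"
  names(reps)[1] <- "repeat_id"
  list(seqs = seqs, genes = genes, repeats = reps)
}

# Greedy non-overlapping placement; errors out when the features cannot be
# packed (too many rejections).
place_features <- function(chroms, chrom_len, n, len_range, zone, prefix,
                           stranded) {
  if (n == 0) {
    return(data.frame(id = character(), chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  placed <- vector("list", n)
  occupied <- lapply(chroms, function(x) matrix(numeric(0), ncol = 2))
  names(occupied) <- chroms
  tries <- 0L
  i <- 1L
  while (i <= n) {
    if (tries > 200L * n) stop("infeasible feature packing: ", prefix)
    tries <- tries + 1L
    ch <- sample(chroms, 1L)
    w <- sample(len_range[1]:len_range[2], 1L)
    third <- chrom_len %/% 3L
    lo_hi <- if (zone == "centro") c(third, 2L * third - w) else c(0L, chrom_len - w)
    if (lo_hi[2] <= lo_hi[1]) next
    s <- sample(lo_hi[1]:lo_hi[2], 1L)
    if (zone == "arms" && s < 2L * third && (s + w) > third) next  # keep genes on the arms
    occ <- occupied[[ch]]
    if (nrow(occ) && any(s < occ[, 2] + 200 & (s + w) + 200 > occ[, 1])) next
    occupied[[ch]] <- rbind(occ, c(s, s + w))
    placed[[i]] <- data.frame(
      id = paste0(prefix, "_", i), chrom = ch, start = s, end = s + w,
      strand = if (stranded) sample(c("+", "-"), 1L) else "*",
      stringsAsFactors = FALSE)
    i <- i + 1L
  }
  out <- do.call(rbind, placed)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Enumerate cytosine sites of a genome sequence
#'
#' Every C on the plus strand and every G (a cytosine on the minus strand)
#' yields one record, classified as CG, CHG or CHH from its strand-local
#' trinucleotide.  Sites too close to a chromosome end to resolve their
#' context are skipped.
#'
#' @param seqs named character vector of chromosome sequences.
#' @return a `data.frame`: `chrom`, `pos` (1-based), `strand`, `context`,
#'   `tri`.
#' @export
cytosine_sites <- function(seqs) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- lapply(names(seqs), function(ch) {
    chars <- strsplit(seqs[[ch]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    # plus strand: C at i, context from i+1, i+2
    ip <- which(chars == "C")
    ip <- ip[ip <= n - 2L]
    b1p <- chars[ip + 1L]; b2p <- chars[ip + 2L]
    ctx_p <- ifelse(b1p == "G", "CG", ifelse(b2p == "G", "CHG", "CHH"))
    tri_p <- paste0("C", b1p, b2p)
    # minus strand: G at i is a C on the reverse strand; its downstream
    # bases (5'->3' on the minus strand) are i-1, i-2 complemented
    im <- which(chars == "G")
    im <- im[im >= 3L]
    b1m <- unname(comp[chars[im - 1L]]); b2m <- unname(comp[chars[im - 2L]])
    ctx_m <- ifelse(b1m == "G", "CG", ifelse(b2m == "G", "CHG", "CHH"))
    tri_m <- paste0("C", b1m, b2m)
    df <- data.frame(
      chrom = ch, pos = c(ip, im), strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(ctx_p, ctx_m), tri = c(tri_p, tri_m), stringsAsFactors = FALSE)
    df[order(df$pos), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plant the simulation truth: DMRs and DEG statuses
#'
#' Draws piecewise-constant baseline methylation levels per context for
#' `segment_bp` segments, then plants constitutive DMRs (placed inside a
#' random host gene's upstream / body / downstream 2 kb window so the
#' association stages have signal) and induced DMRs (placed anywhere),
#' each with crisp boundaries, a context-scaled length and effect, and a
#' feasible low/high level pair.  DEG statuses are drawn independently of
#' DMR placement (no planted direction x regulation coupling).
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @return a list of class `sim_truth` with `segments` (baseline levels),
#'   `dmrs` (planted DMRs with per-cultivar levels), `degs` (planted
#'   statuses); [simulate_variants()] later adds the realised dosage
#'   coupling.
#' @export
plant_truth <- function(config, genome) {
  set.seed(sim_seed(config, 2L))
  chroms <- names(genome$seqs)
  seg_bp <- config$segment_bp
  n_seg <- ceiling(config$chrom_length_bp / seg_bp)
  draw_levels <- function(context, n) {
    switch(context,
      CG = ifelse(stats::runif(n) < 0.7, stats::runif(n, 0.60, 0.95),
                  stats::runif(n, 0, 0.10)),
      CHG = ifelse(stats::runif(n) < 0.55, stats::runif(n, 0.40, 0.80),
                   stats::runif(n, 0.02, 0.10)),
      CHH = 0.01 + 0.16 * stats::rbeta(n, 1, 4))
  }
  segments <- lapply(chroms, function(ch) {
    lv <- lapply(CONTEXTS, draw_levels, n = n_seg)
    names(lv) <- CONTEXTS
    lv
  })
  names(segments) <- chroms

  min_size <- c(CG = 50, CHG = 50, CHH = 25)
  min_diff <- c(CG = 0.40, CHG = 0.30, CHH = 0.10)
  windows <- gene_windows(genome$genes, flank_bp = 2000)

  # a planted DMR must hold observable signal: enough cytosines of its own
  # context, spread across the interval (a region with 2-3 context sites
  # encodes no recoverable methylation difference for any caller)
  sites <- cytosine_sites(genome$seqs)
  sites_by <- split(sites$pos - 1L, paste(sites$chrom, sites$context))
  informative <- function(ch, ctx, s, e) {
    p <- sites_by[[paste(ch, ctx)]]
    p <- p[p >= s & p < e]
    w <- e - s
    length(p) >= 8L && min(p) <= s + 0.15 * w && max(p) >= e - 1 - 0.15 * w
  }

  planted <- list()
  occupied <- data.frame(chrom = character(), start = numeric(), end = numeric())
  place_dmr <- function(type, context) {
    width <- round(min_size[[context]] * config$dmr_length_multiplier)
    effect <- min_diff[[context]] * config$dmr_effect_multiplier
    for (try in 1:2000) {
      if (type == "constitutive" && nrow(windows)) {
        w <- windows[sample(nrow(windows), 1L), ]
        if (w$end - w$start <= width + 2L) next
        s <- sample(seq(w$start, w$end - width), 1L)
        ch <- w$chrom; host <- w$gene_id
      } else {
        ch <- sample(chroms, 1L)
        s <- sample(seq(0L, config$chrom_length_bp - width), 1L)
        host <- NA_character_
      }
      e <- s + width
      if (!informative(ch, context, s, e)) next
      occ <- occupied[occupied$chrom == ch, , drop = FALSE]
      if (nrow(occ) && any(s < occ$end + 1000 & e + 1000 > occ$start)) next
      occupied <<- rbind(occupied, data.frame(chrom = ch, start = s, end = e))
      # low/high level pair respecting the context's typical band (CG high
      # mode 0.60-0.95, CHG up to ~0.8, CHH near zero)
      lo <- switch(context,
                   CG = stats::runif(1, 0.05, 0.35),
                   CHG = stats::runif(1, 0.02, 0.35),
                   CHH = stats::runif(1, 0.01, 0.05))
      return(data.frame(
        chrom = ch, start = s, end = e, context = context,
        direction = sample(c("hyper", "hypo"), 1L),
        effect = effect, level_lo = lo, level_hi = lo + effect,
        type = type, host_gene = host, stringsAsFactors = FALSE))
    }
    stop("could not place planted DMR (genome too crowded)")
  }

  const_ctx <- sample(CONTEXTS, config$n_constitutive_dmrs, replace = TRUE,
                      prob = config$constitutive_context_mix[CONTEXTS])
  ind_ctx <- sample(CONTEXTS, config$n_induced_dmrs, replace = TRUE,
                    prob = config$induced_context_mix[CONTEXTS])
  for (ctx in const_ctx) planted <- c(planted, list(place_dmr("constitutive", ctx)))
  for (ctx in ind_ctx) planted <- c(planted, list(place_dmr("induced", ctx)))
  dmrs <- if (length(planted)) do.call(rbind, planted) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               context = character(), direction = character(), effect = numeric(),
               level_lo = numeric(), level_hi = numeric(), type = character(),
               host_gene = character(), stringsAsFactors = FALSE)
  if (nrow(dmrs)) dmrs$dmr_id <- paste0("planted_", seq_len(nrow(dmrs)))

  n_deg <- round(config$deg_fraction * nrow(genome$genes))
  deg_genes <- if (n_deg > 0) sample(genome$genes$gene_id, n_deg) else character()
  status <- rep("ns", nrow(genome$genes))
  names(status) <- genome$genes$gene_id
  if (n_deg > 0) {
    status[deg_genes] <- rep_len(c("up", "down"), n_deg)
  }
  degs <- data.frame(gene_id = genome$genes$gene_id,
                     status = unname(status[genome$genes$gene_id]),
                     stringsAsFactors = FALSE)
  structure(list(segments = segments, segment_bp = seg_bp, dmrs = dmrs,
                 degs = degs), class = "sim_truth")
}

# True methylation level of each cytosine site for one (cultivar, timepoint):
# the segment baseline, overridden inside planted DMRs.
true_levels <- function(sites, truth, config, cultivar, timepoint) {
  lev <- numeric(nrow(sites))
  seg_idx <- (sites$pos - 1L) %/% truth$segment_bp + 1L
  for (ch in unique(sites$chrom)) {
    in_ch <- sites$chrom == ch
    for (ctx in CONTEXTS) {
      sel <- in_ch & sites$context == ctx
      lev[sel] <- truth$segments[[ch]][[ctx]][seg_idx[sel]]
    }
  }
  d <- truth$dmrs
  if (nrow(d)) for (i in seq_len(nrow(d))) {
    sel <- sites$chrom == d$chrom[i] & sites$context == d$context[i] &
      (sites$pos - 1L) >= d$start[i] & (sites$pos - 1L) < d$end[i]
    if (!any(sel)) next
    if (d$type[i] == "constitutive") {
      # comparison cultivar is hyper/hypo relative to reference, both time points
      is_cmp <- cultivar == config$cultivar_cmp
      hi_for_cmp <- d$direction[i] == "hyper"
      lev[sel] <- if (is_cmp == hi_for_cmp) d$level_hi[i] else d$level_lo[i]
    } else {
      # induced: both cultivars share the pre-stress level; only the induced
      # cultivar shifts after heat
      pre <- if (d$direction[i] == "hyper") d$level_lo[i] else d$level_hi[i]
      post <- if (d$direction[i] == "hyper") d$level_hi[i] else d$level_lo[i]
      lev[sel] <- if (cultivar == config$induced_cultivar && timepoint == "after")
        post else pre
    }
  }
  pmin(pmax(lev, 0), 1)
}

#' Simulate per-sample cytosine reports
#'
#' Observed counts per cytosine are Binomial(depth, level) with depth ~
#' Poisson(`read_depth_mean`), independent across samples.  Symmetric CG
#' strand pairs are two independent records sharing the same true level.
#' Constitutive planted DMRs differ between cultivars at both time points;
#' induced DMRs only after heat in the designated cultivar.
#'
#' @param config a [sim_config()].
#' @param truth output of [plant_truth()].
#' @param genome output of [generate_genome()].
#' @param cultivars,timepoints which samples to simulate (subsets of the
#'   two cultivars and of `c("before", "after")`); a given sample's counts
#'   are identical whichever subset it is generated in.
#' @return a nested list `methylomes[[cultivar]][[timepoint]]` of
#'   `n_replicates` cytosine record `data.frame`s.
#' @export
simulate_methylome <- function(config, truth, genome,
                               cultivars = c(config$cultivar_cmp, config$cultivar_ref),
                               timepoints = c("before", "after")) {
  sites <- cytosine_sites(genome$seqs)
  all_cultivars <- c(config$cultivar_cmp, config$cultivar_ref)
  out <- list()
  for (cv in cultivars) {
    ci <- match(cv, all_cultivars)
    if (is.na(ci)) stop("unknown cultivar: ", cv)
    out[[cv]] <- list()
    for (tp in timepoints) {
      ti <- match(tp, c("before", "after"))
      lev <- true_levels(sites, truth, config, cv, tp)
      reps <- vector("list", config$n_replicates)
      for (r in seq_len(config$n_replicates)) {
        set.seed(sim_seed(config, 100L + ci * 20L + ti * 5L + r))
        depth <- stats::rpois(nrow(sites), config$read_depth_mean)
        meth <- stats::rbinom(nrow(sites), depth, lev)
        reps[[r]] <- data.frame(
          chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
          meth = meth, unmeth = depth - meth, context = sites$context,
          tri = sites$tri, stringsAsFactors = FALSE)
      }
      out[[cv]][[tp]] <- reps
    }
  }
  out
}

#' Simulate tetraploid variants with a planted methylation-dosage coupling
#'
#' Scatters background SNPs genome-wide (outside planted DMRs) with random
#' tetraploid dosages, QUAL and depth fields drawn so the standard filters
#' remove a known fraction, and plants 1 + Pois(1) filter-passing SNPs
#' inside every constitutive planted DMR.  With probability
#' `dosage_coupling_prob` a constitutive DMR realises the negative
#' coupling: the cultivar *hypo*methylated in that region receives the
#' strictly larger dosage sum (every planted SNP favours it); otherwise
#' the other cultivar does.  Roughly half of all SNPs are deamination-type
#' transitions.
#'
#' @param config a [sim_config()].
#' @param truth output of [plant_truth()]; returned augmented.
#' @param genome output of [generate_genome()].
#' @return a list with `snps` (a SNP `data.frame` in the
#'   [read_vcf_tetraploid()] layout) and `truth` (with per-DMR
#'   `coupling_realised` and expected relation added to `truth$dmrs`).
#' @export
simulate_variants <- function(config, truth, genome) {
  set.seed(sim_seed(config, 3L))
  chroms <- names(genome$seqs)
  cmp <- config$cultivar_cmp
  ref <- config$cultivar_ref
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  rows <- list()

  alt_for <- function(refb, transition) {
    if (transition) return(unname(transitions[refb]))
    sample(setdiff(c("A", "C", "G", "T"), c(refb, transitions[refb])), 1L)
  }

  # background SNPs, outside planted DMRs
  d <- truth$dmrs
  for (ch in chroms) {
    n_bg <- round(config$chrom_length_bp * config$snp_per_bp)
    if (n_bg == 0) next
    pos0 <- sort(sample.int(config$chrom_length_bp - 2L, n_bg))
    if (nrow(d)) {
      dc <- d[d$chrom == ch, , drop = FALSE]
      if (nrow(dc)) {
        inside <- vapply(pos0, function(p) any(p >= dc$start & p < dc$end), logical(1))
        pos0 <- pos0[!inside]
      }
    }
    for (p in pos0) {
      refb <- substr(genome$seqs[[ch]], p + 1L, p + 1L)
      altb <- alt_for(refb, stats::runif(1) < 0.5)
      qual <- if (stats::runif(1) < 0.1) stats::runif(1, 5, 29.9) else stats::runif(1, 30, 200)
      dp <- vapply(1:2, function(k) {
        if (stats::runif(1) < 0.1) sample(c(4:9, 51:70), 1L) else sample(10:50, 1L)
      }, integer(1))
      dd <- sample(0:4, 2L, replace = TRUE, prob = c(0.30, 0.25, 0.20, 0.15, 0.10))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = p + 1L, ref = refb, alt = altb, qual = round(qual, 1),
        depth_cmp = dp[1], dosage_cmp = dd[1],
        depth_ref = dp[2], dosage_ref = dd[2],
        planted_dmr = NA_character_, stringsAsFactors = FALSE)
    }
  }

  # planted, filter-passing SNPs inside constitutive DMRs
  if (nrow(d)) {
    d$coupling_realised <- NA
    d$expected_relation <- NA_character_
    for (i in which(d$type == "constitutive")) {
      realised <- stats::runif(1) < config$dosage_coupling_prob
      d$coupling_realised[i] <- realised
      # coupling: hypo-in-cmp regions favour cmp dosage; hyper favour ref
      favour_cmp <- (d$direction[i] == "hypo") == realised
      d$expected_relation[i] <- if (favour_cmp) "cmp_gt_ref" else "cmp_lt_ref"
      n_snp <- 1L + stats::rpois(1, 1)
      width <- d$end[i] - d$start[i]
      offs <- sample.int(width, min(n_snp, width))
      for (o in offs) {
        p <- d$start[i] + o - 1L
        refb <- substr(genome$seqs[[d$chrom[i]]], p + 1L, p + 1L)
        altb <- alt_for(refb, stats::runif(1) < 0.5)
        hi <- sample(2:4, 1L)
        lo <- sample(0:(hi - 1L), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = d$chrom[i], pos = p + 1L, ref = refb, alt = altb,
          qual = round(stats::runif(1, 30, 200), 1),
          depth_cmp = sample(10:50, 1L), dosage_cmp = if (favour_cmp) hi else lo,
          depth_ref = sample(10:50, 1L), dosage_ref = if (favour_cmp) lo else hi,
          planted_dmr = d$dmr_id[i], stringsAsFactors = FALSE)
      }
    }
    truth$dmrs <- d
  }

  snps <- do.call(rbind, rows)
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  names(snps)[names(snps) == "depth_cmp"] <- paste0("depth_", cmp)
  names(snps)[names(snps) == "dosage_cmp"] <- paste0("dosage_", cmp)
  names(snps)[names(snps) == "depth_ref"] <- paste0("depth_", ref)
  names(snps)[names(snps) == "dosage_ref"] <- paste0("dosage_", ref)
  attr(snps, "samples") <- c(cmp, ref)
  list(snps = snps, truth = truth)
}

#' Simulate a differential-expression results table
#'
#' Planted DEGs receive `|log2fc|` in `log2fc_range` and FDR well below
#' 0.05 by construction; non-DEGs straddle the thresholds, including exact
#' boundary rows (log2FC exactly 1 with small FDR; large fold change with
#' FDR exactly 0.05) that exercise the strictness of the DEG definition.
#'
#' @param config a [sim_config()].
#' @param truth output of [plant_truth()].
#' @return a `data.frame` with `gene_id`, `log2fc`, `fdr`.
#' @export
simulate_de_table <- function(config, truth) {
  set.seed(sim_seed(config, 4L))
  degs <- truth$degs
  n <- nrow(degs)
  log2fc <- numeric(n)
  fdr <- numeric(n)
  is_up <- degs$status == "up"
  is_down <- degs$status == "down"
  is_ns <- degs$status == "ns"
  mag <- stats::runif(n, config$log2fc_range[1], config$log2fc_range[2])
  log2fc[is_up] <- mag[is_up]
  log2fc[is_down] <- -mag[is_down]
  fdr[!is_ns] <- stats::runif(sum(!is_ns), 1e-8, 0.049)
  ns_idx <- which(is_ns)
  for (k in seq_along(ns_idx)) {
    i <- ns_idx[k]
    if (k == 1) { log2fc[i] <- 1.0; fdr[i] <- 0.001 }         # boundary: fold change exactly at threshold
    else if (k == 2) { log2fc[i] <- 3.0; fdr[i] <- 0.05 }     # boundary: FDR exactly at threshold
    else if (k == 3) { log2fc[i] <- -1.0; fdr[i] <- 0.001 }
    else if (stats::runif(1) < 0.5) { log2fc[i] <- stats::runif(1, -1, 1); fdr[i] <- stats::runif(1) }
    else { log2fc[i] <- stats::runif(1, -4, 4); fdr[i] <- stats::runif(1, 0.05, 1) }
  }
  data.frame(gene_id = degs$gene_id, log2fc = log2fc, fdr = fdr,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator stage — genome, truth planting, methylomes for two
#' cultivars at two time points, tetraploid variants, DE table — and
#' optionally writes all of it to disk in the formats the readers consume
#' (CX reports, GFF3, VCF, TSV, truth JSON).
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; created if needed.
#' @param cultivars,timepoints passed to [simulate_methylome()] to
#'   restrict which methylome samples are generated.
#' @return a list: `config`, `genome`, `truth`, `methylomes`, `snps`,
#'   `de_table` (and `paths` if `dir` was given).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL,
                             cultivars = c(config$cultivar_cmp, config$cultivar_ref),
                             timepoints = c("before", "after")) {
  genome <- generate_genome(config)
  truth <- plant_truth(config, genome)
  vr <- simulate_variants(config, truth, genome)
  truth <- vr$truth
  methylomes <- simulate_methylome(config, truth, genome, cultivars, timepoints)
  de_table <- simulate_de_table(config, truth)
  out <- list(config = config, genome = genome, truth = truth,
              methylomes = methylomes, snps = vr$snps, de_table = de_table)
  if (!is.null(dir)) out$paths <- write_dataset(out, dir)
  out
}

write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (cv in names(dataset$methylomes)) {
    for (tp in names(dataset$methylomes[[cv]])) {
      reps <- dataset$methylomes[[cv]][[tp]]
      for (r in seq_along(reps)) {
        p <- file.path(dir, sprintf("%s_%s_rep%d.CX_report.txt", cv, tp, r))
        write_cx_report(reps[[r]], p)
        paths$cx <- c(paths$cx, p)
      }
    }
  }
  paths$genes <- file.path(dir, "genes.gff3")
  write_gff3(dataset$genome$genes, paths$genes, type = "gene")
  paths$repeats <- file.path(dir, "repeats.gff3")
  rr <- dataset$genome$repeats
  names(rr)[1] <- "gene_id"  # writer only needs an id column
  write_gff3(rr, paths$repeats, type = "repeat_region")
  paths$vcf <- file.path(dir, "variants.vcf")
  write_vcf_tetraploid(dataset$snps, paths$vcf,
                       contig_lengths = nchar(dataset$genome$seqs))
  paths$de <- file.path(dir, "de_table.tsv")
  data.table::fwrite(dataset$de_table, paths$de, sep = "\t", quote = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(dmrs = dataset$truth$dmrs, degs = dataset$truth$degs),
                       paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
  paths
}

write_gff3 <- function(features, path, type) {
  lines <- "##gff-version 3"
  if (nrow(features)) {
    strand <- if ("strand" %in% names(features)) features$strand else "."
    strand[is.na(strand) | strand == "*"] <- "."
    lines <- c(lines, sprintf(
      "%s\tdmrdose\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
      features$chrom, type, features$start + 1L, features$end, strand,
      features[[1]]))
  }
  writeLines(lines, path)
  invisible(path)
}

# Minimal VCF v4.2 writer for the synthetic tetraploid genotypes.
write_vcf_tetraploid <- function(snps, path, contig_lengths = NULL) {
  samples <- snp_samples(snps)
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contig_lengths)) sprintf("##contig=<ID=%s,length=%d>",
                                          names(contig_lengths), contig_lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_string <- function(d) {
    vapply(d, function(x) {
      if (is.na(x)) "./././."
      else paste(c(rep("0", 4 - x), rep("1", x)), collapse = "/")
    }, character(1))
  }
  sample_cols <- vapply(samples, function(s) {
    dp <- snps[[paste0("depth_", s)]]
    paste0(gt_string(snps[[paste0("dosage_", s)]]), ":",
           ifelse(is.na(dp), ".", as.character(dp)))
  }, character(nrow(snps)))
  if (is.null(dim(sample_cols))) sample_cols <- matrix(sample_cols, nrow = nrow(snps))
  body <- paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt,
                format(snps$qual, trim = TRUE), "PASS", ".", "GT:DP",
                apply(sample_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Sensitivity of called DMRs against planted truth
#'
#' A planted DMR counts as recovered when some called DMR of the same
#' context and direction overlaps it reciprocally by at least
#' `min_reciprocal` (overlap / planted length and overlap / called length
#' both at or above the threshold).
#'
#' @param called a DMR `data.frame` from [call_dmrs()].
#' @param planted planted DMRs (`truth$dmrs`, optionally pre-filtered to
#'   one type).
#' @param min_reciprocal reciprocal-overlap fraction (default 0.5).
#' @return a list: `sensitivity`, `n_recovered`, `n_planted`, and the
#'   per-planted-DMR logical `recovered`.
#' @export
dmr_recovery <- function(called, planted, min_reciprocal = 0.5) {
  n <- nrow(planted)
  recovered <- logical(n)
  for (i in seq_len(n)) {
    cand <- called[called$chrom == planted$chrom[i] &
                     called$context == planted$context[i] &
                     called$direction == planted$direction[i], , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(cand$end, planted$end[i]) - pmax(cand$start, planted$start[i])
    ok <- ov > 0 &
      ov / (planted$end[i] - planted$start[i]) >= min_reciprocal &
      ov / (cand$end - cand$start) >= min_reciprocal
    recovered[i] <- any(ok)
  }
  list(sensitivity = if (n) mean(recovered) else NA_real_,
       n_recovered = sum(recovered), n_planted = n, recovered = recovered)
}
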