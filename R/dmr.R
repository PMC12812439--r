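#' Context-specific DMR calling parameters
#'
#' The per-context thresholds used throughout DMR calling.  Defaults follow
#' the published analysis settings: FDR < 0.05, minimum mean coverage per
#' cytosine 8, minimum DMR sizes of 50, 50 and 25 bp and minimum
#' methylation proportion differences of 40, 30 and 10% for CG, CHG and
#' CHH respectively, with same-direction DMRs closer than 200 bp merged.
#' The kernel `bandwidth_bp` is the standard deviation of the Gaussian
#' smoothing kernel (weights truncated at 3 sigma); the 10 bp default
#' keeps a DMR at the minimum reportable sizes (25-50 bp) from being
#' smoothed below its proportion-difference threshold, while still pooling
#' several neighbouring cytosines per estimate.  `min_cytosines` guards
#' against single-cytosine "regions".
#'
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_size_bp,min_prop_diff,min_coverage,fdr_threshold,bandwidth_bp,min_cytosines,merge_gap_bp
#'   overrides for the per-context defaults.
#' @return a list of class `dmr_params`.
#' @export
dmr_params <- function(context = c("CG", "CHG", "CHH"),
                       min_size_bp = NULL, min_prop_diff = NULL,
                       min_coverage = 8, fdr_threshold = 0.05,
                       bandwidth_bp = 10, min_cytosines = 4,
                       merge_gap_bp = 200) {
  context <- match.arg(context)
  defaults_size <- c(CG = 50, CHG = 50, CHH = 25)
  defaults_diff <- c(CG = 0.40, CHG = 0.30, CHH = 0.10)
  p <- list(
    context = context,
    min_size_bp = if (is.null(min_size_bp)) unname(defaults_size[context]) else min_size_bp,
    min_prop_diff = if (is.null(min_prop_diff)) unname(defaults_diff[context]) else min_prop_diff,
    min_coverage = min_coverage,
    fdr_threshold = fdr_threshold,
    bandwidth_bp = bandwidth_bp,
    min_cytosines = min_cytosines,
    merge_gap_bp = merge_gap_bp
  )
  stopifnot(p$min_size_bp > 0, p$min_prop_diff > 0,
            p$fdr_threshold > 0, p$fdr_threshold < 1,
            p$bandwidth_bp > 0, p$merge_gap_bp >= 0)
  class(p) <- "dmr_params"
  p
}

#' Pool replicate cytosine tracks by count summation
#'
#' Sums methylated and unmethylated read counts across replicates at each
#' (chromosome, position, strand).  Region-level significance testing is
#' done on pooled counts; no per-replicate dispersion model is fitted.
#' Replicates must agree on the context annotation of every shared
#' position.
#'
#' @param tracks a list of cytosine record `data.frame`s (one per
#'   replicate), or a single `data.frame` (returned after validation).
#' @return a pooled cytosine record `data.frame`, sorted by chromosome and
#'   position.
#' @export
pool_replicates <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  lapply(tracks, validate_cytosine_records)
  dt <- data.table::rbindlist(lapply(tracks, data.table::as.data.table))
  if (nrow(dt) == 0) {
    return(cytosine_records(character(), integer(), character(), integer(),
                            integer(), character(), character()))
  }
  keys <- unique(dt[, .(chrom, pos, strand, context)])
  dup <- duplicated(keys, by = c("chrom", "pos", "strand"))
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("conflicting context annotations at %s:%d(%s)",
                 keys$chrom[i], keys$pos[i], keys$strand[i]))
  }
  pooled <- dt[, .(meth = sum(as.numeric(meth)), unmeth = sum(as.numeric(unmeth)),
                   context = context[1L], tri = tri[1L]),
               by = .(chrom, pos, strand)]
  data.table::setorder(pooled, chrom, pos)
  as.data.frame(pooled[, .(chrom, pos, strand, meth, unmeth, context, tri)])
}

#' Kernel-smoothed methylation proportions
#'
#' At each cytosine position `x`, the smoothed proportion is the
#' kernel-weighted sum of methylated counts over the kernel-weighted sum of
#' total counts across neighbouring cytosines,
#' `sum_i K((x - x_i)/h) meth_i / sum_i K((x - x_i)/h) total_i`,
#' with a Gaussian kernel of standard deviation `bandwidth_bp`, truncated
#' at 3 sigma.  This is the noise-filter smoothing step of the DMR caller:
#' read counts, not per-site proportions, are smoothed, so deep sites weigh
#' more.  `NA` where the weighted total is zero.
#'
#' @param positions strictly increasing numeric positions (bp).
#' @param meth,total per-position methylated and total read counts.
#' @param bandwidth_bp Gaussian kernel standard deviation in bp.
#' @return numeric vector of smoothed proportions, same length as
#'   `positions`.
#' @export
smooth_proportions <- function(positions, meth, total, bandwidth_bp = 10) {
  if (bandwidth_bp <= 0) stop("bandwidth_bp must be positive")
  if (length(positions) == 0) return(numeric(0))
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (any(total < 0) || any(meth < 0)) stop("counts must be non-negative")
  cpp_kernel_smooth(as.numeric(positions), as.numeric(meth),
                    as.numeric(total), bandwidth_bp)
}

#' Candidate differentially methylated regions from smoothed tracks
#'
#' Finds maximal runs of consecutive cytosines where the smoothed
#' proportion difference (comparison minus reference) is `>=`
#' `min_prop_diff` (hyper candidates) or `<= -min_prop_diff` (hypo
#' candidates); ties at the threshold are included.  Positions where
#' either track is `NA` break runs.  Each run's interval spans its first
#' to last cytosine, half-open on the 0-based scale of `positions`.
#'
#' @param positions strictly increasing 0-based cytosine positions.
#' @param smoothed_ref,smoothed_cmp smoothed proportions on `positions`.
#' @param min_prop_diff proportion-difference threshold.
#' @return a `data.frame` with `start`, `end` (half-open), `first_idx`,
#'   `last_idx` (indices into `positions`) and `direction` (`hyper`/`hypo`).
#' @export
candidate_regions <- function(positions, smoothed_ref, smoothed_cmp,
                              min_prop_diff) {
  stopifnot(length(smoothed_ref) == length(positions),
            length(smoothed_cmp) == length(positions))
  if (length(positions) == 0) return(empty_candidates())
  d <- smoothed_cmp - smoothed_ref
  state <- integer(length(d))
  state[!is.na(d) & d >= min_prop_diff] <- 1L
  state[!is.na(d) & d <= -min_prop_diff] <- -1L
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) return(empty_candidates())
  data.frame(
    start = positions[starts[keep]],
    end = positions[ends[keep]] + 1L,
    first_idx = starts[keep],
    last_idx = ends[keep],
    direction = ifelse(r$values[keep] > 0L, "hyper", "hypo"),
    stringsAsFactors = FALSE
  )
}

empty_candidates <- function() {
  data.frame(start = integer(), end = integer(), first_idx = integer(),
             last_idx = integer(), direction = character(),
             stringsAsFactors = FALSE)
}

#' Fisher's exact test on a region's pooled methylation counts
#'
#' Two-sided Fisher's exact test on the 2x2 table of pooled methylated /
#' unmethylated read counts of the comparison and reference groups within
#' one region.  An all-zero table has p = 1 by convention.
#'
#' @param meth_cmp,unmeth_cmp,meth_ref,unmeth_ref pooled read counts.
#' @return a p-value.
#' @export
test_region <- function(meth_cmp, unmeth_cmp, meth_ref, unmeth_ref) {
  tab <- matrix(c(meth_cmp, unmeth_cmp, meth_ref, unmeth_ref),
                nrow = 2, byrow = TRUE)
  if (sum(tab) == 0) return(1)
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up BH adjustment (via [stats::p.adjust()]) across the
#' candidate regions of one context and one comparison.
#'
#' @param p_values numeric vector of p-values.
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Filter candidate DMRs on significance, size, coverage and effect
#'
#' Retains candidates with `q_value < fdr_threshold`, interval span `>=
#' min_size_bp`, mean reads per cytosine (pooled over both groups, i.e.
#' total reads / (n_cytosines * 2)) `>= min_coverage`, absolute pooled
#' proportion difference `>= min_prop_diff` (ties included) and
#' `n_cytosines >= min_cytosines`.
#'
#' @param candidates a DMR `data.frame` carrying `start`, `end`,
#'   `n_cytosines`, pooled count columns `meth_ref`, `unmeth_ref`,
#'   `meth_cmp`, `unmeth_cmp`, `prop_diff` and `q_value`.
#' @param params a [dmr_params()] object.
#' @return the surviving rows, with `direction` assigned from the sign of
#'   `prop_diff`.
#' @export
filter_dmrs <- function(candidates, params) {
  if (nrow(candidates) == 0) return(candidates)
  total_reads <- candidates$meth_ref + candidates$unmeth_ref +
    candidates$meth_cmp + candidates$unmeth_cmp
  mean_cov <- total_reads / (candidates$n_cytosines * 2)
  keep <- candidates$q_value < params$fdr_threshold &
    (candidates$end - candidates$start) >= params$min_size_bp &
    mean_cov >= params$min_coverage &
    abs(candidates$prop_diff) >= params$min_prop_diff &
    candidates$n_cytosines >= params$min_cytosines
  out <- candidates[keep, , drop = FALSE]
  out$direction <- ifelse(out$prop_diff > 0, "hyper", "hypo")
  out$mean_coverage <- mean_cov[keep]
  rownames(out) <- NULL
  out
}

#' Merge nearby same-direction DMRs
#'
#' Merges same-context, same-direction DMRs on one chromosome whose gap
#' (start of the next minus end of the previous) is smaller than
#' `merge_gap_bp`.  Pooled counts and cytosine numbers are summed;
#' p-values are recomputed on the merged pooled table with [test_region()]
#' and q-values re-adjusted across the whole merged set, so the reported
#' statistics stay meaningful for merged intervals.
#'
#' @param dmrs a DMR `data.frame` (sorted or not; it is sorted here).
#' @param merge_gap_bp gap threshold in bp (merge when gap < this).
#' @return the merged DMR `data.frame`.
#' @export
merge_dmrs <- function(dmrs, merge_gap_bp = 200) {
  if (nrow(dmrs) == 0) return(dmrs)
  dt <- data.table::as.data.table(dmrs)
  data.table::setorder(dt, chrom, start)
  # chain: within (chrom, context, direction), a new group starts when the
  # gap to the previous interval's running end is >= merge_gap_bp
  dt[, grp := {
    g <- integer(.N)
    cur <- 1L
    run_end <- end[1L]
    g[1L] <- cur
    if (.N > 1L) for (i in 2L:.N) {
      if (start[i] - run_end >= merge_gap_bp) {
        cur <- cur + 1L
        run_end <- end[i]
      } else {
        run_end <- max(run_end, end[i])
      }
      g[i] <- cur
    }
    g
  }, by = .(chrom, context, direction)]
  merged <- dt[, .(
    start = min(start), end = max(end),
    n_cytosines = sum(n_cytosines),
    meth_ref = sum(meth_ref), unmeth_ref = sum(unmeth_ref),
    meth_cmp = sum(meth_cmp), unmeth_cmp = sum(unmeth_cmp),
    n_merged = .N, p_value = p_value[1L]
  ), by = .(chrom, context, direction, grp)]
  merged[, grp := NULL]
  merged[, prop_diff :=
           meth_cmp / (meth_cmp + unmeth_cmp) - meth_ref / (meth_ref + unmeth_ref)]
  merged[, mean_coverage :=
           (meth_ref + unmeth_ref + meth_cmp + unmeth_cmp) / (n_cytosines * 2)]
  redo <- which(merged$n_merged > 1L)
  for (i in redo) {
    merged$p_value[i] <- test_region(merged$meth_cmp[i], merged$unmeth_cmp[i],
                                     merged$meth_ref[i], merged$unmeth_ref[i])
  }
  merged[, q_value := adjust_fdr(p_value)]
  data.table::setorder(merged, chrom, start)
  as.data.frame(merged)
}

#' Call differentially methylated regions between two groups
#'
#' The full DMR-calling chain for one methylation context: pool replicate
#' counts per group, smooth methylation proportions with a Gaussian
#' kernel, find candidate runs exceeding the context's proportion
#' difference threshold, Fisher-test each candidate's pooled 2x2 count
#' table, Benjamini-Hochberg adjust across all candidates of the
#' comparison, apply the context-specific significance / size / coverage /
#' effect filters, and merge same-direction DMRs separated by less than
#' the merge gap.  Deterministic given its inputs.
#'
#' `direction = "hyper"` means the *comparison* group is more methylated
#' than the reference group inside the DMR (`prop_diff = pooled comparison
#' proportion - pooled reference proportion > 0`).
#'
#' @param group_ref,group_cmp cytosine record `data.frame`s or lists of
#'   per-replicate `data.frame`s for the reference and comparison groups.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param params a [dmr_params()] object; defaults to
#'   `dmr_params(context)`.
#' @return a `data.frame` of DMRs: `chrom`, `start`, `end` (0-based
#'   half-open), `context`, `direction`, `n_cytosines`, `mean_coverage`,
#'   `prop_diff`, pooled counts, `p_value`, `q_value`.
#' @export
call_dmrs <- function(group_ref, group_cmp, context = c("CG", "CHG", "CHH"),
                      params = NULL) {
  context <- match.arg(context)
  if (is.null(params)) params <- dmr_params(context)
  stopifnot(inherits(params, "dmr_params"), params$context == context)
  ref <- pool_replicates(group_ref)
  cmp <- pool_replicates(group_cmp)
  ref <- ref[ref$context == context, , drop = FALSE]
  cmp <- cmp[cmp$context == context, , drop = FALSE]
  if (nrow(ref) == 0 || nrow(cmp) == 0) return(empty_dmrs())

  rdt <- data.table::as.data.table(ref)[, .(chrom, pos, meth_ref = meth, unmeth_ref = unmeth)]
  cdt <- data.table::as.data.table(cmp)[, .(chrom, pos, meth_cmp = meth, unmeth_cmp = unmeth)]
  both <- merge(rdt, cdt, by = c("chrom", "pos"), all = TRUE)
  for (col in c("meth_ref", "unmeth_ref", "meth_cmp", "unmeth_cmp")) {
    data.table::set(both, which(is.na(both[[col]])), col, 0)
  }
  data.table::setorder(both, chrom, pos)

  out <- list()
  for (chr in unique(both$chrom)) {
    cb <- both[chrom == chr]
    pos0 <- cb$pos - 1L                       # internal 0-based
    sm_ref <- smooth_proportions(pos0, cb$meth_ref, cb$meth_ref + cb$unmeth_ref,
                                 params$bandwidth_bp)
    sm_cmp <- smooth_proportions(pos0, cb$meth_cmp, cb$meth_cmp + cb$unmeth_cmp,
                                 params$bandwidth_bp)
    cand <- candidate_regions(pos0, sm_ref, sm_cmp, params$min_prop_diff)
    if (nrow(cand) == 0) next
    stats_list <- lapply(seq_len(nrow(cand)), function(i) {
      idx <- cand$first_idx[i]:cand$last_idx[i]
      c(meth_ref = sum(cb$meth_ref[idx]), unmeth_ref = sum(cb$unmeth_ref[idx]),
        meth_cmp = sum(cb$meth_cmp[idx]), unmeth_cmp = sum(cb$unmeth_cmp[idx]),
        n_cytosines = length(idx))
    })
    st <- do.call(rbind, stats_list)
    cand <- cbind(chrom = chr, cand, as.data.frame(st), stringsAsFactors = FALSE)
    out[[chr]] <- cand
  }
  if (length(out) == 0) return(empty_dmrs())
  cand <- data.table::rbindlist(out)
  cand[, context := context]
  tot_cmp <- cand$meth_cmp + cand$unmeth_cmp
  tot_ref <- cand$meth_ref + cand$unmeth_ref
  cand[, prop_diff := ifelse(tot_cmp > 0, meth_cmp / tot_cmp, 0) -
         ifelse(tot_ref > 0, meth_ref / tot_ref, 0)]
  cand[, p_value := vapply(seq_len(.N), function(i) {
    test_region(meth_cmp[i], unmeth_cmp[i], meth_ref[i], unmeth_ref[i])
  }, numeric(1))]
  cand[, q_value := adjust_fdr(p_value)]
  kept <- filter_dmrs(as.data.frame(cand), params)
  if (nrow(kept) == 0) return(empty_dmrs())
  merged <- merge_dmrs(kept, params$merge_gap_bp)
  cols <- c("chrom", "start", "end", "context", "direction", "n_cytosines",
            "mean_coverage", "prop_diff", "meth_ref", "unmeth_ref",
            "meth_cmp", "unmeth_cmp", "p_value", "q_value")
  merged[, cols]
}

empty_dmrs <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             context = character(), direction = character(),
             n_cytosines = integer(), mean_coverage = numeric(),
             prop_diff = numeric(), meth_ref = numeric(), unmeth_ref = numeric(),
             meth_cmp = numeric(), unmeth_cmp = numeric(),
             p_value = numeric(), q_value = numeric(), stringsAsFactors = FALSE)
}

#' Write DMRs as BED6+ and a statistics TSV
#'
#' BED name is `context:direction`, score is `-log10(q)` capped at 1000,
#' strand is `.`.
#'
#' @param dmrs a DMR `data.frame` from [call_dmrs()].
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    score <- ifelse(dmrs$q_value > 0, pmin(-log10(dmrs$q_value), 1000), 1000)
    bed <- data.frame(dmrs$chrom, dmrs$start, dmrs$end,
                      paste0(dmrs$context, ":", dmrs$direction),
                      round(score, 3), ".")
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
  if (!is.null(tsv_path)) {
    data.table::fwrite(dmrs, tsv_path, sep = "\t", quote = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
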