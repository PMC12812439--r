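#' Weighted methylation level of a set of cytosines
#'
#' The coverage-weighted level of Schultz et al.: the sum of methylated
#' read counts divided by the total read count over all cytosines,
#' `sum(meth) / sum(meth + unmeth)`.  This is *not* a mean of per-site
#' proportions — low-coverage sites contribute proportionally less.
#' Returns `NA` when there are no reads at all (undefined, not an error).
#'
#' @param records a cytosine record `data.frame` (only `meth` and `unmeth`
#'   are used; the caller is responsible for restricting to one context).
#' @return a single value in `[0, 1]`, or `NA_real_`.
#' @export
weighted_methylation_level <- function(records) {
  total <- sum(as.numeric(records$meth)) + sum(as.numeric(records$unmeth))
  if (total == 0) return(NA_real_)
  sum(as.numeric(records$meth)) / total
}

#' Weighted methylation levels in fixed-width genome bins
#'
#' Tiles each chromosome into half-open bins `[k*bin_size, (k+1)*bin_size)`
#' (0-based) and computes the weighted methylation level per bin.  A
#' cytosine at 1-based position `p` falls in the bin containing `p - 1`.
#' Bins with no covered cytosine are reported with `wml = NA`.  Tiling runs
#' from 0 to the last cytosine of each chromosome (the genome length is not
#' known from the records alone).
#'
#' @param records a cytosine record `data.frame`.
#' @param bin_size bin width in bp (default 200, the genome-wide
#'   distribution scale; use [chromosome_density()] for 500 kb tracks).
#' @param context optional context (`"CG"`, `"CHG"`, `"CHH"`) to restrict
#'   to; `NULL` pools all contexts present.
#' @return a `data.frame` with `chrom`, `start`, `end` (0-based half-open),
#'   `context`, `wml`, `n_cytosines`, `total_reads`.
#' @export
bin_methylation <- function(records, bin_size = 200, context = NULL) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  validate_cytosine_records(records)
  if (!is.null(context)) {
    records <- records[records$context == context, , drop = FALSE]
  }
  ctx_label <- if (is.null(context)) "all" else context
  if (nrow(records) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      context = character(), wml = numeric(),
                      n_cytosines = integer(), total_reads = numeric()))
  }
  dt <- data.table::as.data.table(records)
  dt[, bin := (pos - 1L) %/% as.integer(bin_size)]
  agg <- dt[, .(
    n_cytosines = .N,
    meth = sum(as.numeric(meth)),
    total_reads = sum(as.numeric(meth)) + sum(as.numeric(unmeth))
  ), by = .(chrom, bin)]
  # full tiling 0 .. last occupied bin per chromosome
  tiles <- agg[, .(bin = 0:max(bin)), by = chrom]
  out <- agg[tiles, on = c("chrom", "bin")]
  out[is.na(n_cytosines), `:=`(n_cytosines = 0L, meth = 0, total_reads = 0)]
  out[, wml := ifelse(total_reads > 0, meth / total_reads, NA_real_)]
  data.table::setorder(out, chrom, bin)
  data.frame(
    chrom = out$chrom,
    start = out$bin * as.integer(bin_size),
    end = (out$bin + 1L) * as.integer(bin_size),
    context = ctx_label,
    wml = out$wml,
    n_cytosines = out$n_cytosines,
    total_reads = out$total_reads,
    stringsAsFactors = FALSE
  )
}

#' Chromosome-scale methylation density
#'
#' [bin_methylation()] with a large window (500 kb by default), the scale
#' used for chromosome-level methylation density tracks.
#'
#' @inheritParams bin_methylation
#' @param window window width in bp.
#' @return as [bin_methylation()].
#' @export
chromosome_density <- function(records, window = 500000, context = NULL) {
  bin_methylation(records, bin_size = window, context = context)
}

#' Metagene methylation profile around genes or repeats
#'
#' Pools cytosine read counts across features into a fixed-length profile:
#' `n_flank_bins` equal-width bins over the `flank_bp` upstream flank, the
#' feature body rescaled to `n_body_bins` proportional bins (a cytosine at
#' relative body position `r` in `[0, 1)` goes to bin
#' `floor(r * n_body_bins)`), and `n_flank_bins` over the downstream flank.
#' Minus-strand features are reversed so bin 0 is always the 5' end;
#' unstranded features are treated as plus-strand.  Counts are pooled
#' across features *before* the weighted level is computed (weighted, not
#' mean-of-means), so bins covered in no feature are `NA`.
#'
#' @param records a cytosine record `data.frame`.
#' @param features a `data.frame` of genes or repeats as returned by
#'   [read_annotations()] (`chrom`, `start`, `end`, `strand`).
#' @param flank_bp flank width in bp (default 2000: 2 kb upstream of the
#'   TSS and 2 kb downstream of the TES).
#' @param n_flank_bins,n_body_bins number of bins per segment.
#' @param context optional context restriction.
#' @return an object of class `metagene_profile`: a list with `upstream`,
#'   `body`, `downstream` (numeric vectors of weighted levels), the bin
#'   configuration and the pooled counts.
#' @export
metagene_profile <- function(records, features, flank_bp = 2000,
                             n_flank_bins = 100, n_body_bins = 100,
                             context = NULL) {
  if (nrow(features) == 0) stop("no features supplied")
  validate_cytosine_records(records)
  if (!is.null(context)) records <- records[records$context == context, , drop = FALSE]

  n_total <- 2L * n_flank_bins + n_body_bins
  meth_acc <- numeric(n_total)
  total_acc <- numeric(n_total)

  dt <- data.table::as.data.table(records)
  dt[, pos0 := pos - 1L]
  data.table::setkey(dt, chrom, pos0)

  for (i in seq_len(nrow(features))) {
    f_chrom <- features$chrom[i]
    f_start <- features$start[i]
    f_end <- features$end[i]
    f_strand <- if ("strand" %in% names(features)) features$strand[i] else "+"
    if (is.na(f_strand) || !f_strand %in% c("+", "-")) f_strand <- "+"
    win_lo <- f_start - flank_bp
    win_hi <- f_end + flank_bp
    sel <- dt[chrom == f_chrom & pos0 >= win_lo & pos0 < win_hi]
    if (nrow(sel) == 0) next
    p <- sel$pos0
    # segment-relative positions in [0,1) then global bin index on the
    # plus-strand layout; flipped afterwards for minus-strand features
    bin <- integer(length(p))
    up <- p < f_start
    dn <- p >= f_end
    body <- !up & !dn
    bin[up] <- pmin(floor((p[up] - win_lo) / flank_bp * n_flank_bins), n_flank_bins - 1L)
    bin[body] <- n_flank_bins +
      pmin(floor((p[body] - f_start) / (f_end - f_start) * n_body_bins), n_body_bins - 1L)
    bin[dn] <- n_flank_bins + n_body_bins +
      pmin(floor((p[dn] - f_end) / flank_bp * n_flank_bins), n_flank_bins - 1L)
    if (f_strand == "-") bin <- n_total - 1L - bin
    meth_acc <- meth_acc + tabulate_weighted(bin + 1L, as.numeric(sel$meth), n_total)
    total_acc <- total_acc +
      tabulate_weighted(bin + 1L, as.numeric(sel$meth) + as.numeric(sel$unmeth), n_total)
  }

  wml <- ifelse(total_acc > 0, meth_acc / total_acc, NA_real_)
  structure(list(
    context = if (is.null(context)) "all" else context,
    upstream = wml[seq_len(n_flank_bins)],
    body = wml[n_flank_bins + seq_len(n_body_bins)],
    downstream = wml[n_flank_bins + n_body_bins + seq_len(n_flank_bins)],
    flank_bp = flank_bp,
    n_flank_bins = n_flank_bins,
    n_body_bins = n_body_bins,
    meth = meth_acc,
    total = total_acc
  ), class = "metagene_profile")
}

tabulate_weighted <- function(idx, w, nbins) {
  vapply(split(w, factor(idx, levels = seq_len(nbins))),
         sum, numeric(1), USE.NAMES = FALSE)
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "metagene_profile (%s): %d+%d+%d bins, flank %d bp; mean wml up/body/down = %.3f/%.3f/%.3f\n",
    x$context, x$n_flank_bins, x$n_body_bins, x$n_flank_bins, x$flank_bp,
    mean(x$upstream, na.rm = TRUE), mean(x$body, na.rm = TRUE),
    mean(x$downstream, na.rm = TRUE)))
  invisible(x)
}

#' Distribution of per-bin weighted methylation levels
#'
#' Histogram of the defined `wml` values of a binned methylation track
#' (for the genome-wide 200 bp window distributions).  Undefined
#' (uncovered) bins are excluded from the histogram and reported as a
#' separate count.
#'
#' @param bins output of [bin_methylation()].
#' @param breaks histogram break points covering `[0, 1]`.
#' @return a list with `breaks`, `counts` and `n_undefined`.
#' @export
methylation_distribution <- function(bins, breaks = seq(0, 1, by = 0.05)) {
  wml <- bins$wml
  defined <- wml[!is.na(wml)]
  counts <- if (length(defined)) {
    hist(defined, breaks = breaks, plot = FALSE, include.lowest = TRUE,
         right = FALSE)$counts
  } else {
    integer(length(breaks) - 1L)
  }
  list(breaks = breaks, counts = counts, n_undefined = sum(is.na(wml)))
}
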