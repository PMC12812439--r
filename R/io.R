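#' @useDynLib dmrdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct a table of per-cytosine methylation records
#'
#' The package-wide container for per-cytosine counts is a plain
#' `data.frame` with columns `chrom`, `pos` (1-based, as stored on disk),
#' `strand` (`+`/`-`), `meth`, `unmeth` (non-negative read counts),
#' `context` (`CG`, `CHG` or `CHH`) and `tri` (trinucleotide).  This
#' constructor validates and normalises the column types.
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions.
#' @param strand `"+"` or `"-"`.
#' @param meth,unmeth non-negative integer read counts supporting
#'   methylation / non-methylation.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param tri trinucleotide strings (5' to 3' on the cytosine's strand).
#' @return a `data.frame` of cytosine records.
#' @export
cytosine_records <- function(chrom, pos, strand, meth, unmeth, context,
                             tri = context) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), meth = as.integer(meth),
    unmeth = as.integer(unmeth), context = as.character(context),
    tri = as.character(tri), stringsAsFactors = FALSE
  )
  validate_cytosine_records(df)
  df
}

validate_cytosine_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(
    c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri"),
    names(df)
  )
  if (length(missing_cols)) {
    stop("cytosine records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$meth < 0, na.rm = TRUE) || any(df$unmeth < 0, na.rm = TRUE)) {
    stop("negative read counts in cytosine records")
  }
  bad_ctx <- !df$context %in% CONTEXTS
  if (any(bad_ctx)) {
    stop("invalid methylation context: ", paste(unique(df$context[bad_ctx]), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

#' Read a Bismark genome-wide cytosine report (CX file)
#'
#' Parses the seven-column tab-separated CX dialect written by
#' `bismark_methylation_extractor --cytosine_report --CX`: chromosome,
#' 1-based position, strand, count methylated, count unmethylated, context
#' and trinucleotide.  Rows whose context is not `CG`/`CHG`/`CHH` (e.g.
#' `CN`, `Unknown`) are dropped; row order is otherwise preserved.  All
#' cytosines are returned, including zero-coverage ones — coverage filters
#' belong downstream, not in the parser.
#'
#' @param path path to a CX report.
#' @return a `data.frame` of cytosine records (see [cytosine_records()]).
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(cytosine_records(character(), integer(), character(), integer(),
                            integer(), character(), character()))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)[1L]
    stop(sprintf("malformed CX report %s: line %d has %d column(s), expected 7",
                 path, bad, nf[bad]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 7L, byrow = TRUE)
  meth <- suppressWarnings(as.integer(m[, 4L]))
  unmeth <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(meth) || anyNA(unmeth)) {
    stop("non-integer read count in CX report ", path)
  }
  if (any(meth < 0) || any(unmeth < 0)) {
    stop("negative read count in CX report ", path)
  }
  keep <- m[, 6L] %in% CONTEXTS
  df <- data.frame(
    chrom = m[keep, 1L], pos = as.integer(m[keep, 2L]), strand = m[keep, 3L],
    meth = meth[keep], unmeth = unmeth[keep], context = m[keep, 6L],
    tri = m[keep, 7L], stringsAsFactors = FALSE
  )
  validate_cytosine_records(df)
  df
}

#' Write cytosine records as a Bismark CX report
#'
#' Inverse of [read_cx_report()]: emits the seven-column tab-separated CX
#' dialect, one row per record, so that a write/read round trip is exact.
#'
#' @param records a cytosine record `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(records, path) {
  validate_cytosine_records(records)
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  out <- records[, c("chrom", "pos", "strand", "meth", "unmeth", "context", "tri")]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene or repeat annotations from GFF3 or BED
#'
#' Imports features via \pkg{rtracklayer} and converts them to the internal
#' 0-based half-open coordinate convention (GFF3 is 1-based inclusive on
#' disk; BED already 0-based half-open).  Conversion happens only here, at
#' the I/O boundary.  For `kind = "gene"` only rows of GFF3 type
#' `gene`/`mRNA` are kept (BED rows are taken as-is); feature identifiers
#' come from the GFF3 `ID` attribute or BED name column, falling back to
#' `feature_<i>`.
#'
#' @param path a `.gff`/`.gff3` or `.bed` file.
#' @param kind `"gene"` or `"repeat"`.
#' @return a `data.frame` with columns `gene_id` (or `repeat_id`), `chrom`,
#'   `start` (0-based), `end` (exclusive) and `strand` (`+`, `-` or `*`).
#' @export
read_annotations <- function(path, kind = c("gene", "repeat")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (kind == "gene" && "type" %in% names(S4Vectors::mcols(gr))) {
      keep <- as.character(gr$type) %in% c("gene", "mRNA")
      if (any(keep)) gr <- gr[keep]
    }
    ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else NA_character_
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if ("name" %in% names(S4Vectors::mcols(gr))) as.character(gr$name) else NA_character_
  } else {
    stop("unknown annotation format: .", ext, " (expected GFF3 or BED)")
  }
  n <- length(gr)
  ids <- if (length(ids) != n || all(is.na(ids))) paste0("feature_", seq_len(n)) else ids
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  if (anyDuplicated(ids)) stop("duplicate feature identifiers in ", path)
  df <- data.frame(
    id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  names(df)[1] <- if (kind == "gene") "gene_id" else "repeat_id"
  df
}

#' Read a VCF with tetraploid genotypes
#'
#' Reads a VCF (via \pkg{vcfR}) whose `GT` fields are tetraploid (four
#' allele indices, e.g. `0/0/1/1`), and derives the alternative-allele
#' dosage per sample as the count of non-reference allele indices (0-4).
#' Records with a missing genotype (`./././.`) get dosage `NA` — they are
#' flagged, not dropped, so downstream filters can count them.
#'
#' @param path VCF file (v4.x, plain text or bgzipped).
#' @param sample_names optional character vector restricting/ordering the
#'   samples to read; defaults to all samples in the file.
#' @return a `data.frame` with one row per variant: `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `qual`, plus `depth_<sample>` and
#'   `dosage_<sample>` columns.  The sample names are stored in
#'   `attr(, "samples")`.
#' @export
read_vcf_tetraploid <- function(path, sample_names = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_all <- vcfR::extract.gt(vcf, element = "GT")
  dp_all <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  samples <- colnames(gt_all)
  if (!is.null(sample_names)) {
    missing <- setdiff(sample_names, samples)
    if (length(missing)) stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
    samples <- sample_names
  }
  df <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  for (s in samples) {
    gt <- gt_all[, s]
    df[[paste0("depth_", s)]] <- as.integer(dp_all[, s])
    df[[paste0("dosage_", s)]] <- tetraploid_dosage(gt, df$chrom, df$pos)
  }
  attr(df, "samples") <- samples
  df
}

# Dosage from an unphased/phased tetraploid GT string: the count of
# non-zero (non-reference) allele indices.  Missing GT -> NA.
tetraploid_dosage <- function(gt, chrom, pos) {
  alleles <- strsplit(gt, "[/|]")
  n_alleles <- lengths(alleles)
  missing <- is.na(gt) | vapply(alleles, function(a) all(a == "."), logical(1))
  bad <- !missing & n_alleles != 4L
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("non-tetraploid genotype '%s' at %s:%d (%d allele(s))",
                 gt[i], chrom[i], pos[i], n_alleles[i]))
  }
  dosage <- vapply(alleles, function(a) sum(a != "0" & a != "."), integer(1))
  dosage[missing] <- NA_integer_
  dosage
}

#' Read a differential-expression results table
#'
#' Reads a headered TSV/CSV with columns `gene_id`, `log2fc` and `fdr`
#' (extra columns are kept) and recomputes the `status` column (`up`,
#' `down`, `ns`) with [classify_deg()] — the stored table never carries
#' authority over the thresholds.
#'
#' @param path a delimited text file.
#' @param fc_threshold,fdr_threshold passed to [classify_deg()].
#' @return a `data.frame` with at least `gene_id`, `log2fc`, `fdr`, `status`.
#' @export
read_de_table <- function(path, fc_threshold = 1, fdr_threshold = 0.05) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as.data.frame(data.table::fread(path))
  missing_cols <- setdiff(c("gene_id", "log2fc", "fdr"), names(df))
  if (length(missing_cols)) {
    stop("DE table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$fdr < 0 | df$fdr > 1, na.rm = TRUE)) stop("fdr outside [0,1] in ", path)
  df$status <- classify_deg(df$log2fc, df$fdr, fc_threshold, fdr_threshold)
  df
}
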