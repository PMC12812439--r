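# Shared fixture builders.  Everything is generated in code; no binary or
# stored fixtures.

# random valid cytosine records (not position-sorted, duplicates possible)
random_records <- function(n, seed = 1, chroms = c("chr1", "chr2")) {
  set.seed(seed)
  cytosine_records(
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(100000, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    meth = rpois(n, 5),
    unmeth = rpois(n, 5),
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    tri = sample(c("CGA", "CAG", "CTT", "CCG"), n, replace = TRUE)
  )
}

# a uniform cytosine track on one chromosome: one cytosine every `step` bp
uniform_track <- function(from, to, step = 10, meth = 1, unmeth = 1,
                          context = "CG", chrom = "chr1", strand = "+") {
  pos <- seq(from, to, by = step)
  cytosine_records(chrom, pos, strand, rep(meth, length(pos)),
                   rep(unmeth, length(pos)), context, context)
}

# a small complete synthetic dataset, built once and reused read-only
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 60000,
                        n_genes = 10, n_repeats = 5,
                        n_constitutive_dmrs = 3, n_induced_dmrs = 2,
                        rng_seed = 404)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

# independent step-up Benjamini-Hochberg (oracle for adjust_fdr): walk the
# sorted p-values from largest to smallest carrying the running minimum of
# p_(i) * m / i
bh_oracle <- function(p) {
  m <- length(p)
  sorted <- sort(p, index.return = TRUE)
  qs <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, sorted$x[i] * m / i)
    qs[i] <- prev
  }
  out <- numeric(m)
  out[sorted$ix] <- qs
  out
}

# two-sided Fisher p by full hypergeometric enumeration (oracle for
# test_region); same "<= observed * (1 + eps)" tie rule as fisher.test
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b; row2 <- c + d; col1 <- a + c
  if (row1 + row2 == 0) return(1)
  k <- max(0, col1 - row2):min(row1, col1)
  probs <- dhyper(k, row1, row2, col1)
  p_obs <- dhyper(a, row1, row2, col1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct double-loop evaluation of the truncated-Gaussian smoother
smooth_oracle <- function(positions, meth, total, bandwidth, truncate_sd = 3) {
  n <- length(positions)
  out <- numeric(n)
  for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      d <- positions[i] - positions[j]
      if (abs(d) > truncate_sd * bandwidth) next
      w <- exp(-d^2 / (2 * bandwidth^2))
      num <- num + w * meth[i]
      den <- den + w * total[i]
    }
    out[j] <- if (den > 0) num / den else NA_real_
  }
  out
}
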