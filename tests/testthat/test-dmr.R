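test_that("replicate pooling sums counts per position and strand", {
  one <- cytosine_records("chr1", c(10L, 20L), "+", c(1L, 2L), c(1L, 0L),
                          "CG", "CGA")
  expect_equal(pool_replicates(one)[, c("pos", "meth", "unmeth")],
               one[order(one$pos), c("pos", "meth", "unmeth")])
  two <- cytosine_records("chr1", 10L, "+", 2L, 0L, "CG", "CGA")
  pooled <- pool_replicates(list(one[1, ], two))
  expect_equal(pooled$meth, 3)
  expect_equal(pooled$unmeth, 1)
  # three random replicates against a brute-force sum
  reps <- lapply(1:3, function(s) {
    r <- random_records(200, seed = s)
    r$context <- "CHG"  # same context everywhere so positions cannot conflict
    r$tri <- "CAG"
    r
  })
  pooled <- pool_replicates(reps)
  all_rec <- do.call(rbind, reps)
  for (k in sample(nrow(pooled), 20)) {
    sel <- all_rec$chrom == pooled$chrom[k] & all_rec$pos == pooled$pos[k] &
      all_rec$strand == pooled$strand[k]
    expect_equal(pooled$meth[k], sum(all_rec$meth[sel]))
    expect_equal(pooled$unmeth[k], sum(all_rec$unmeth[sel]))
  }
})

test_that("conflicting context annotations at one position are an error", {
  a <- cytosine_records("chr1", 10L, "+", 1L, 1L, "CG", "CGA")
  b <- cytosine_records("chr1", 10L, "+", 1L, 1L, "CHH", "CTT")
  expect_error(pool_replicates(list(a, b)), "conflicting context")
})

test_that("kernel smoothing reproduces closed-form cases", {
  # single cytosine: kernel weight cancels
  expect_equal(smooth_proportions(100, 4, 8, 10), 0.5)
  # two flanking cytosines equidistant from an (uncovered) midpoint get
  # equal weights: p(mid) = (4+8)/(8+8)
  s <- smooth_proportions(c(10, 20, 30), c(4, 0, 8), c(8, 0, 8), 10)
  expect_equal(s[2], 12 / 16)
  expect_error(smooth_proportions(c(10, 20), c(1, 1), c(2, 2), 0), "bandwidth")
  expect_error(smooth_proportions(c(20, 10), c(1, 1), c(2, 2), 5),
               "strictly increasing")
})

test_that("kernel smoothing matches the double-loop oracle on random instances", {
  for (s in 1:5) {
    set.seed(s)
    pos <- sort(sample.int(2000, 30))
    meth <- rpois(30, 4)
    total <- meth + rpois(30, 4)
    total[sample(30, 3)] <- 0
    meth[total == 0] <- 0
    got <- smooth_proportions(pos, meth, total, bandwidth_bp = 25)
    expect_equal(got, smooth_oracle(pos, meth, total, 25), tolerance = 1e-10)
  }
})

test_that("candidate regions are maximal runs at or beyond the threshold", {
  pos <- seq(0, 90, by = 10)
  zero <- rep(0.3, 10)
  expect_equal(nrow(candidate_regions(pos, zero, zero, 0.4)), 0L)
  # five consecutive cytosines at +0.5 -> one hyper candidate spanning all
  ref <- rep(0.2, 10)
  cmp <- ref; cmp[3:7] <- 0.7
  cand <- candidate_regions(pos, ref, cmp, 0.4)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$direction, "hyper")
  expect_equal(cand$start, pos[3])
  expect_equal(cand$end, pos[7] + 1)
  # ties at the threshold are included (0.25/0.75 are exact in binary)
  ref2 <- rep(0.25, 10)
  cmp2 <- ref2; cmp2[5] <- 0.75
  expect_equal(nrow(candidate_regions(pos, ref2, cmp2, 0.5)), 1L)
})

test_that("candidate regions match an exhaustive run-scanner on random tracks", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 80
    pos <- sort(sample.int(5000, n))
    ref <- runif(n)
    cmp <- runif(n)
    cmp[sample(n, 5)] <- NA
    thr <- 0.3
    got <- candidate_regions(pos, ref, cmp, thr)
    # oracle: walk every position, track run state
    d <- cmp - ref
    lab <- ifelse(is.na(d), 0L, ifelse(d >= thr, 1L, ifelse(d <= -thr, -1L, 0L)))
    regions <- list()
    i <- 1
    while (i <= n) {
      if (lab[i] != 0L) {
        j <- i
        while (j < n && lab[j + 1] == lab[i]) j <- j + 1
        regions[[length(regions) + 1]] <- data.frame(
          start = pos[i], end = pos[j] + 1,
          direction = if (lab[i] > 0) "hyper" else "hypo")
        i <- j + 1
      } else i <- i + 1
    }
    oracle <- do.call(rbind, regions)
    expect_equal(got[, c("start", "end", "direction")], oracle)
  }
})

test_that("region testing is two-sided Fisher on the pooled 2x2 table", {
  expect_equal(test_region(10, 0, 0, 10), 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(test_region(5, 5, 5, 5), 1)
  expect_equal(test_region(0, 0, 0, 0), 1)  # all-zero table by convention
})

test_that("Fisher p-values match full hypergeometric enumeration on random tables", {
  set.seed(42)
  for (k in 1:100) {
    tab <- rpois(4, sample(1:10, 1))
    tab <- pmin(tab, 40)
    got <- test_region(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
})

test_that("FDR adjustment is step-up Benjamini-Hochberg", {
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(8)
  for (k in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("DMR filters enforce size, coverage, effect and significance", {
  base <- data.frame(
    chrom = "chr1", start = 100, end = 160, n_cytosines = 6,
    meth_ref = 20, unmeth_ref = 80, meth_cmp = 80, unmeth_cmp = 20,
    prop_diff = 0.6, p_value = 1e-8, q_value = 1e-7,
    stringsAsFactors = FALSE)
  p <- dmr_params("CG")
  expect_equal(nrow(filter_dmrs(base, p)), 1L)
  short <- transform(base, end = 130)          # 30 bp < 50 bp CG minimum
  expect_equal(nrow(filter_dmrs(short, p)), 0L)
  lowcov <- base
  lowcov[, c("meth_ref", "unmeth_ref", "meth_cmp", "unmeth_cmp")] <-
    c(10, 37, 37, 10.8)                        # mean coverage 94.8/12 = 7.9 < 8
  expect_equal(nrow(filter_dmrs(lowcov, p)), 0L)
  weak <- transform(base, prop_diff = 0.39)
  expect_equal(nrow(filter_dmrs(weak, p)), 0L)
  at_thr <- transform(base, prop_diff = 0.40)  # inclusive bound
  expect_equal(nrow(filter_dmrs(at_thr, p)), 1L)
  insig <- transform(base, q_value = 0.05)     # strict q < 0.05
  expect_equal(nrow(filter_dmrs(insig, p)), 0L)
})

test_that("random candidates filter identically to an independent predicate", {
  set.seed(77)
  n <- 200
  cand <- data.frame(
    chrom = "chr1", start = s <- sample.int(10000, n),
    end = s + sample(10:200, n, replace = TRUE),
    n_cytosines = sample(1:20, n, replace = TRUE),
    meth_ref = rpois(n, 40), unmeth_ref = rpois(n, 40),
    meth_cmp = rpois(n, 40), unmeth_cmp = rpois(n, 40),
    prop_diff = runif(n, -0.8, 0.8),
    p_value = runif(n), q_value = runif(n), stringsAsFactors = FALSE)
  p <- dmr_params("CHG")
  got <- filter_dmrs(cand, p)
  keep <- logical(n)
  for (i in 1:n) {
    cov <- (cand$meth_ref[i] + cand$unmeth_ref[i] + cand$meth_cmp[i] +
              cand$unmeth_cmp[i]) / (2 * cand$n_cytosines[i])
    keep[i] <- cand$q_value[i] < 0.05 &&
      (cand$end[i] - cand$start[i]) >= 50 && cov >= 8 &&
      abs(cand$prop_diff[i]) >= 0.30 && cand$n_cytosines[i] >= 4
  }
  expect_equal(got$start, cand$start[keep])
  expect_equal(got$direction, ifelse(cand$prop_diff[keep] > 0, "hyper", "hypo"))
})

test_that("DMRs merge below the gap threshold, never across directions", {
  mk <- function(start, end, direction, context = "CG") data.frame(
    chrom = "chr1", start = start, end = end, context = context,
    direction = direction, n_cytosines = 5, meth_ref = 10, unmeth_ref = 40,
    meth_cmp = 40, unmeth_cmp = 10,
    prop_diff = if (direction == "hyper") 0.6 else -0.6,
    p_value = 1e-6, q_value = 1e-5, mean_coverage = 10,
    stringsAsFactors = FALSE)
  # 199 bp gap: merge
  m <- merge_dmrs(rbind(mk(0, 100, "hyper"), mk(299, 400, "hyper")), 200)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0)
  expect_equal(m$end, 400)
  expect_equal(m$n_cytosines, 10)
  # 200 bp gap: no merge
  m2 <- merge_dmrs(rbind(mk(0, 100, "hyper"), mk(300, 400, "hyper")), 200)
  expect_equal(nrow(m2), 2L)
  # opposite directions never merge, at any gap
  m3 <- merge_dmrs(rbind(mk(0, 100, "hyper"), mk(110, 200, "hypo")), 200)
  expect_equal(nrow(m3), 2L)
  # merged statistics are recomputed from the pooled table
  expect_equal(m$p_value, test_region(80, 20, 20, 80), tolerance = 1e-12)
})

test_that("merging equals exhaustive pairwise merge-until-fixpoint on random sets", {
  for (s in 1:5) {
    set.seed(300 + s)
    n <- 30
    starts <- sort(sample.int(5000, n))
    d <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = starts, end = starts + sample(20:120, n, replace = TRUE),
      context = sample(c("CG", "CHH"), n, replace = TRUE),
      direction = sample(c("hyper", "hypo"), n, replace = TRUE),
      n_cytosines = sample(4:10, n, replace = TRUE),
      meth_ref = rpois(n, 30), unmeth_ref = rpois(n, 30),
      meth_cmp = rpois(n, 30), unmeth_cmp = rpois(n, 30),
      prop_diff = runif(n, -1, 1), p_value = runif(n, 0, 0.01),
      q_value = runif(n, 0, 0.01), mean_coverage = 10, stringsAsFactors = FALSE)
    got <- merge_dmrs(d, 200)
    # oracle: repeatedly merge any mergeable pair until no change
    work <- split(d, seq_len(n))
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (i in seq_along(work)) {
        if (changed) break
        for (j in seq_along(work)) {
          if (i == j) next
          a <- work[[i]]; b <- work[[j]]
          if (a$chrom == b$chrom && a$context == b$context &&
              a$direction == b$direction &&
              max(a$start, b$start) - min(a$end, b$end) < 200) {
            a$start <- min(a$start, b$start); a$end <- max(a$end, b$end)
            a$n_cytosines <- a$n_cytosines + b$n_cytosines
            for (col in c("meth_ref", "unmeth_ref", "meth_cmp", "unmeth_cmp"))
              a[[col]] <- a[[col]] + b[[col]]
            work[[i]] <- a
            work[[j]] <- NULL
            changed <- TRUE
            break
          }
        }
      }
    }
    oracle <- do.call(rbind, work)
    oracle <- oracle[order(oracle$chrom, oracle$start), ]
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
    expect_equal(got$n_cytosines, oracle$n_cytosines)
    expect_equal(got$meth_cmp, oracle$meth_cmp)
  }
})

test_that("identical groups yield no DMRs; a planted block yields exactly one", {
  set.seed(21)
  pos <- sort(sample(1:10000, 800))
  track <- cytosine_records("chr1", pos, "+", rbinom(800, 30, 0.3),
                            30 - rbinom(800, 30, 0.3), "CG", "CGA")
  expect_equal(nrow(call_dmrs(track, track, "CG")), 0L)

  # a 60 bp block at proportion difference 0.6, depth 30
  set.seed(22)
  pos <- seq(5, 9995, by = 10)
  n <- length(pos)
  block <- pos >= 5000 & pos < 5060
  lev_ref <- ifelse(block, 0.15, 0.3)
  lev_cmp <- ifelse(block, 0.75, 0.3)
  mk <- function(lev) {
    depth <- rpois(n, 30)
    m <- rbinom(n, depth, lev)
    cytosine_records("chr1", pos, "+", m, depth - m, "CG", "CGA")
  }
  ref <- replicate(3, mk(lev_ref), simplify = FALSE)
  cmp <- replicate(3, mk(lev_cmp), simplify = FALSE)
  dmrs <- call_dmrs(ref, cmp, "CG")
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$direction, "hyper")
  expect_lt(dmrs$start, 5060)
  expect_gt(dmrs$end, 5000)
})

test_that("swapping group roles flips direction and preserves intervals", {
  ds <- small_dataset()
  for (ctx in c("CG", "CHH")) {
    a <- call_dmrs(ds$methylomes$CA$before, ds$methylomes$AA$before, ctx)
    b <- call_dmrs(ds$methylomes$AA$before, ds$methylomes$CA$before, ctx)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      expect_equal(a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])
      expect_true(all(a$direction != b$direction))
      expect_equal(a$prop_diff, -b$prop_diff)
      expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    }
  }
})

test_that("a CHH-scale difference passes only the CHH thresholds", {
  # 0.15 proportion difference over a 60 bp block: above the CHH minimum
  # difference (0.10) but far below the CG one (0.40)
  set.seed(33)
  pos <- seq(2, 3000, by = 4)
  n <- length(pos)
  block <- pos >= 1000 & pos < 1060
  mk <- function(lev_in, ctx) {
    lev <- ifelse(block, lev_in, 0.03)
    depth <- rpois(n, 30)
    m <- rbinom(n, depth, lev)
    cytosine_records("chr1", pos, "+", m, depth - m, ctx, ctx)
  }
  ref_chh <- replicate(3, mk(0.03, "CHH"), simplify = FALSE)
  cmp_chh <- replicate(3, mk(0.18, "CHH"), simplify = FALSE)
  expect_gt(nrow(call_dmrs(ref_chh, cmp_chh, "CHH")), 0L)
  ref_cg <- lapply(ref_chh, transform, context = "CG")
  cmp_cg <- lapply(cmp_chh, transform, context = "CG")
  expect_equal(nrow(call_dmrs(ref_cg, cmp_cg, "CG")), 0L)
})
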