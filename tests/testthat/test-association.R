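test_that("DEG classification uses strict thresholds on both axes", {
  expect_equal(classify_deg(1.5, 0.01), "up")
  expect_equal(classify_deg(-1.2, 0.049), "down")
  expect_equal(classify_deg(1.0, 0.01), "ns")    # fold change exactly at threshold
  expect_equal(classify_deg(-1.2, 0.05), "ns")   # FDR exactly at threshold
  expect_equal(classify_deg(0.5, 0.001), "ns")
  expect_equal(classify_deg(-3.0, 0.2), "ns")
  expect_equal(classify_deg(c(2, -2, 0), c(0.01, 0.01, 0.01)),
               c("up", "down", "ns"))
  expect_error(classify_deg(1, 1.5), "fdr")
})

test_that("gene windows follow transcription direction and clip at zero", {
  gp <- data.frame(gene_id = "g", chrom = "chr1", start = 5000, end = 6000,
                   strand = "+", stringsAsFactors = FALSE)
  w <- gene_windows(gp)
  expect_equal(w$start[w$region == "upstream"], 3000)
  expect_equal(w$end[w$region == "upstream"], 5000)
  expect_equal(w$start[w$region == "downstream"], 6000)
  expect_equal(w$end[w$region == "downstream"], 8000)
  gm <- transform(gp, strand = "-")
  wm <- gene_windows(gm)
  expect_equal(wm$start[wm$region == "upstream"], 6000)
  expect_equal(wm$end[wm$region == "upstream"], 8000)
  expect_equal(wm$start[wm$region == "downstream"], 3000)
  g0 <- data.frame(gene_id = "g", chrom = "chr1", start = 500, end = 1500,
                   strand = "+", stringsAsFactors = FALSE)
  w0 <- gene_windows(g0)
  expect_equal(w0$start[w0$region == "upstream"], 0)
  expect_equal(w0$end[w0$region == "upstream"], 500)
})

test_that("DMR-gene links cover every overlapping window, including dual membership", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000, end = 7000,
                      strand = "+", stringsAsFactors = FALSE)
  inside <- data.frame(chrom = "chr1", start = 5500, end = 5600,
                       context = "CG", direction = "hyper",
                       stringsAsFactors = FALSE)
  lk <- link_dmrs_to_genes(inside, genes)
  expect_equal(lk$region, "gene_body")
  straddle <- transform(inside, start = 4950, end = 5050)
  lk2 <- link_dmrs_to_genes(straddle, genes)
  expect_setequal(lk2$region, c("upstream", "gene_body"))
  far <- transform(inside, start = 20000, end = 20100)
  expect_equal(nrow(link_dmrs_to_genes(far, genes)), 0L)
})

test_that("links match a quadratic all-pairs overlap scan on random fixtures", {
  for (s in 1:3) {
    set.seed(500 + s)
    ng <- 20; nd <- 40
    genes <- data.frame(
      gene_id = paste0("g", 1:ng), chrom = sample(c("chr1", "chr2"), ng, TRUE),
      start = gs <- sample.int(50000, ng), end = gs + sample(500:3000, ng, TRUE),
      strand = sample(c("+", "-"), ng, TRUE), stringsAsFactors = FALSE)
    dmrs <- data.frame(
      dmr_id = paste0("d", 1:nd), chrom = sample(c("chr1", "chr2"), nd, TRUE),
      start = ds <- sample.int(55000, nd), end = ds + sample(25:300, nd, TRUE),
      context = sample(c("CG", "CHG", "CHH"), nd, TRUE),
      direction = sample(c("hyper", "hypo"), nd, TRUE), stringsAsFactors = FALSE)
    got <- link_dmrs_to_genes(dmrs, genes)
    win <- gene_windows(genes)
    expected <- 0L
    for (i in seq_len(nd)) for (j in seq_len(nrow(win))) {
      if (dmrs$chrom[i] == win$chrom[j] &&
          dmrs$start[i] < win$end[j] && dmrs$end[i] > win$start[j]) {
        expected <- expected + 1L
        expect_true(any(got$dmr_id == dmrs$dmr_id[i] &
                          got$gene_id == win$gene_id[j] &
                          got$region == win$region[j]))
      }
    }
    expect_equal(nrow(got), expected)
  }
})

test_that("DMR-DEG counts fill the 36-cell table and reconcile with link totals", {
  links <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3"),
    dmr_id = c("d1", "d2", "d1", "d3"),
    region = c("upstream", "gene_body", "gene_body", "downstream"),
    context = c("CG", "CG", "CHG", "CHH"),
    direction = c("hyper", "hypo", "hyper", "hypo"), stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = c("g1", "g2", "g3"),
                     status = c("up", "down", "ns"), stringsAsFactors = FALSE)
  tab <- dmr_deg_counts(links, degs)
  expect_equal(nrow(tab), 36L)
  expect_equal(sum(tab$count), 3L)   # g3 is ns -> excluded
  expect_equal(tab$count[tab$context == "CG" & tab$region == "upstream" &
                           tab$direction == "hyper" & tab$regulation == "up"], 1L)
  expect_equal(sum(dmr_deg_counts(links, transform(degs, status = "ns"))$count), 0L)
})

test_that("multi-DMR classes deduplicate DMRs and partition DMR-DEG genes", {
  links <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gD", "gD"),
    dmr_id = c("d1", "d2", "d3", "d3", "d4", "d5", "d6"),
    region = c("upstream", "gene_body", "upstream", "gene_body",
               "gene_body", "upstream", "downstream"),
    context = "CG",
    direction = c("hyper", "hyper", "hypo", "hypo", "hyper", "hyper", "hypo"),
    stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                     status = c("up", "down", "up", "down"),
                     stringsAsFactors = FALSE)
  mc <- multi_dmr_classes(links, degs)
  expect_equal(mc$klass[mc$gene_id == "gA"], "unidirectional_multi")
  expect_equal(mc$n_dmrs[mc$gene_id == "gB"], 1L)  # d3 in two windows is one DMR
  expect_equal(mc$klass[mc$gene_id == "gB"], "single")
  expect_equal(mc$klass[mc$gene_id == "gC"], "single")
  expect_equal(mc$klass[mc$gene_id == "gD"], "bidirectional_multi")
  # partition identity
  expect_equal(sum(mc$klass == "single") + sum(mc$klass == "unidirectional_multi") +
                 sum(mc$klass == "bidirectional_multi"), nrow(mc))
})

test_that("flipping every gene strand swaps upstream/downstream counts only", {
  set.seed(606)
  ng <- 15; nd <- 30
  genes <- data.frame(
    gene_id = paste0("g", 1:ng), chrom = "chr1",
    start = gs <- sample.int(40000, ng), end = gs + sample(500:2500, ng, TRUE),
    strand = sample(c("+", "-"), ng, TRUE), stringsAsFactors = FALSE)
  dmrs <- data.frame(
    dmr_id = paste0("d", 1:nd), chrom = "chr1",
    start = ds <- sample.int(42000, nd), end = ds + sample(30:200, nd, TRUE),
    context = sample(c("CG", "CHG"), nd, TRUE),
    direction = sample(c("hyper", "hypo"), nd, TRUE), stringsAsFactors = FALSE)
  degs <- data.frame(gene_id = genes$gene_id,
                     status = sample(c("up", "down"), ng, TRUE),
                     stringsAsFactors = FALSE)
  flipped <- transform(genes, strand = ifelse(strand == "+", "-", "+"))
  t1 <- dmr_deg_counts(link_dmrs_to_genes(dmrs, genes), degs)
  t2 <- dmr_deg_counts(link_dmrs_to_genes(dmrs, flipped), degs)
  body1 <- t1[t1$region == "gene_body", ]
  body2 <- t2[t2$region == "gene_body", ]
  expect_equal(body1$count, body2$count)
  up1 <- t1[t1$region == "upstream", ]
  dn2 <- t2[t2$region == "downstream", ]
  expect_equal(up1$count, dn2$count[match(
    paste(up1$context, up1$direction, up1$regulation),
    paste(dn2$context, dn2$direction, dn2$regulation))])
})
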