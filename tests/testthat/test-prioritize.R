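# gene prioritization: LD-aware gene test, positional mapping, the
# ten-feature ledger, hypergeometric enrichment

test_that("the gene-level test reduces to the single-SNP p-value", {
  z <- 2.3
  gt <- gene_level_test(z)
  expect_equal(gt$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # perfect LD: any number of identical SNPs behaves as one
  for (k in c(3, 8)) {
    gtk <- gene_level_test(rep(z, k), matrix(1, k, k))
    expect_equal(gtk$p, 2 * pnorm(-abs(z)), tolerance = 1e-6)
  }
  expect_error(gene_level_test(numeric(0)), "1 SNP")
})

test_that("the gene-level test is calibrated for independent null SNPs", {
  set.seed(61)
  ps <- replicate(500, gene_level_test(rnorm(6))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2.576 * sqrt(0.05 * 0.95 / 500))
  # mean statistic ~ chi2_k / k
  stats <- replicate(500, gene_level_test(rnorm(6))$stat)
  expect_equal(mean(stats), 1, tolerance = 0.1)
})

test_that("positional mapping finds nearest, intronic and flanking genes", {
  ga <- gene_annotation(c("inside", "left", "right"),
                        tss = c(95000, 50000, 200000),
                        length = c(20000, 5000, 5000))
  mk_loci <- function(lead_pos) {
    meta <- data.frame(variant_id = "lead", chr = "1", pos = lead_pos,
                       p_meta = 1e-9)
    loci <- data.frame(locus_id = 1, chr = "1", start = lead_pos,
                       end = lead_pos, lead_variant = "lead",
                       lead_p = 1e-9, n_independent = 1, n_members = 1,
                       members = "lead",
                       independent_significant = "lead")
    list(loci = loci, meta = meta)
  }
  # lead inside a gene body: nearest and intronic
  x <- mk_loci(100000)
  pm <- map_positional_genes(x$loci, x$meta, ga)
  row <- pm[pm$gene_id == "inside", ]
  expect_true(row$nearest_gene && row$intronic_lead && row$within_window)
  expect_false(any(pm$flank))
  # intergenic lead at 60000: left gene ends 54999 (-5 kb), right gene
  # starts 95000 (+35 kb): left is within 10 kb, both are flanks
  y <- mk_loci(60000)
  pm2 <- map_positional_genes(y$loci, y$meta, ga)
  expect_true(pm2$within_window[pm2$gene_id == "left"])
  expect_true(all(c("left", "inside") %in% pm2$gene_id[pm2$flank]))
  expect_true(pm2$nearest_gene[pm2$gene_id == "left"])
  expect_false(any(pm2$intronic_lead))
  # supplied exon intervals make an exonic lead non-intronic
  exons <- data.frame(gene_id = "inside", start = 99000, end = 101000)
  pm3 <- map_positional_genes(x$loci, x$meta, ga, exons = exons)
  expect_false(pm3$intronic_lead[pm3$gene_id == "inside"])
})

test_that("the evidence ledger counts features and applies the cut", {
  genes <- c("gA", "gB", "gC")
  positional <- data.frame(gene_id = "gA", locus_id = 1, nearest_gene = TRUE,
                           intronic_lead = TRUE, within_window = TRUE,
                           flank = FALSE)
  gene_test <- data.frame(gene_id = c("gA", "gB"), p = c(1e-6, 0.5),
                          significant = c(TRUE, FALSE))
  ev <- build_evidence_matrix(genes, positional = positional,
                              gene_test = gene_test,
                              valve_eqtl = "gA",
                              twas = data.frame(gene_id = "gB", zscore = -3,
                                                significant = TRUE),
                              coloc = data.frame(gene_id = "gB", pp4 = 0.8),
                              mr = data.frame(gene_id = "gB", ivw = -0.4,
                                              ivw_p = 0.01, wm_p = 0.01,
                                              q_p = 0.5))
  # gA: nearest + intronic + gene test + valve eQTL = 4 -> prioritized
  a <- ev[ev$gene_id == "gA", ]
  expect_equal(a$feature_count, 4)
  expect_true(a$prioritized)
  # gB: twas + coloc + mr = 3 -> not prioritized; negative direction
  b <- ev[ev$gene_id == "gB", ]
  expect_equal(b$feature_count, 3)
  expect_false(b$prioritized)
  expect_equal(b$direction, -1)
  # gC: absent everywhere -> zero features
  expect_equal(ev$feature_count[ev$gene_id == "gC"], 0)
  # recomputation is bit-identical (no hidden state)
  ev2 <- build_evidence_matrix(genes, positional = positional,
                               gene_test = gene_test, valve_eqtl = "gA",
                               twas = data.frame(gene_id = "gB", zscore = -3,
                                                 significant = TRUE),
                               coloc = data.frame(gene_id = "gB", pp4 = 0.8),
                               mr = data.frame(gene_id = "gB", ivw = -0.4,
                                               ivw_p = 0.01, wm_p = 0.01,
                                               q_p = 0.5))
  expect_identical(ev, ev2)
  # MR feature needs all three of its sub-rules
  ev3 <- build_evidence_matrix("gB",
                               mr = data.frame(gene_id = "gB", ivw = 0.4,
                                               ivw_p = 0.01, wm_p = 0.01,
                                               q_p = 0.005))
  expect_false(ev3$mr_significant)
  # coloc feature is strict at 0.75
  ev4 <- build_evidence_matrix("gB",
                               coloc = data.frame(gene_id = "gB", pp4 = 0.75))
  expect_false(ev4$coloc_pp4)
})

test_that("GMT gene sets round-trip through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tanother\tg4"), path)
  sets <- read_gmt(path)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"), setB = "g4"))
  bg <- paste0("g", 1:10)
  enr <- hypergeometric_enrichment(c("g1", "g2"), sets, bg,
                                   min_overlap = 1, p_max = 1)
  expect_equal(enr$overlap[enr$term == "setA"], 2)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  bg <- paste0("g", 1:12)
  set <- bg[1:5]
  query <- bg[c(1, 2, 3, 9)]
  res <- hypergeometric_enrichment(query, list(term1 = set), bg,
                                   min_overlap = 2, p_max = 0.2)
  # brute force over all C(12, 4) query draws
  draws <- combn(12, 4)
  brute <- mean(apply(draws, 2, function(d) sum(d <= 5) >= 3))
  expect_equal(res$p, brute, tolerance = 1e-12)
  expect_true(res$reported)
  # overlap below the minimum is never reported, however small the p
  res4 <- hypergeometric_enrichment(paste0("g", 1:4),
                                    list(t = paste0("g", 1:4)),
                                    paste0("g", 1:1000))
  expect_lt(res4$p, 1e-9)
  expect_false(res4$reported)
  # full-overlap query of size 10 in a background of 1000
  res10 <- hypergeometric_enrichment(paste0("g", 1:10),
                                     list(t = paste0("g", 1:10)),
                                     paste0("g", 1:1000))
  expect_equal(res10$p, 1 / choose(1000, 10), tolerance = 1e-9)
  expect_true(res10$reported)
  # disjoint query: upper tail at zero overlap is one
  resd <- hypergeometric_enrichment(paste0("g", 900:905),
                                    list(t = paste0("g", 1:5)),
                                    paste0("g", 1:1000))
  expect_equal(resd$p, 1)
  expect_error(hypergeometric_enrichment("not_there", list(t = bg), bg),
               "subset")
})
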