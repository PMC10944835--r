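# cis-eQTL mapping: nominal pass, permutation pass, enrichment tests,
# tissue specificity, subgroup heterogeneity

make_eqtl_data <- function(n = 200, m = 6, seed = 1, slope = 0,
                           causal = 1, n_cov = 2) {
  set.seed(seed)
  dosage <- matrix(rbinom(n * m, 2, 0.3), n, m,
                   dimnames = list(NULL, paste0("v", 1:m)))
  covs <- matrix(rnorm(n * n_cov), n, dimnames = list(NULL,
                                                      paste0("c", 1:n_cov)))
  e <- slope * dosage[, causal] + 0.5 * covs[, 1] + rnorm(n)
  vinfo <- data.frame(variant_id = paste0("v", 1:m), chr = "1",
                      pos = 1e5 + 1e4 * (1:m), stringsAsFactors = FALSE)
  list(dosage = dosage, covs = covs, e = e, vinfo = vinfo)
}

test_that("nominal slopes equal the full multiple-regression fit", {
  d <- make_eqtl_data(n = 80, seed = 3, slope = 0.4)
  expr <- matrix(d$e, 1, dimnames = list("g1", NULL))
  ga <- gene_annotation("g1", tss = 1.2e5, length = 100)
  nom <- map_cis_nominal(d$dosage, d$vinfo, expr, d$covs, ga)
  for (j in 1:3) {
    fit <- summary(lm(d$e ~ d$dosage[, j] + d$covs))$coefficients
    row <- nom[nom$variant_id == paste0("v", j), ]
    expect_equal(row$slope, fit[2, 1], tolerance = 1e-10)
    expect_equal(row$se, fit[2, 2], tolerance = 1e-10)
    expect_equal(row$p, fit[2, 4], tolerance = 1e-10)
  }
})

test_that("the cis window is inclusive at 1 Mb and respects strand", {
  dosage <- matrix(rbinom(300 * 3, 2, 0.3), 300,
                   dimnames = list(NULL, c("in_win", "edge", "out")))
  tss <- 2e6
  vinfo <- data.frame(variant_id = colnames(dosage), chr = "1",
                      pos = c(tss - 5e5, tss + 1e6, tss + 1e6 + 1))
  expr <- matrix(rnorm(300), 1, dimnames = list("g1", NULL))
  ga <- gene_annotation("g1", tss = tss, length = 100)
  nom <- map_cis_nominal(dosage, vinfo, expr, NULL, ga)
  expect_setequal(nom$variant_id, c("in_win", "edge"))
  expect_equal(nom$distance[nom$variant_id == "edge"], 1e6)
  # minus strand: distance sign flips
  gam <- gene_annotation("g1", tss = tss, strand = "-", length = 100)
  nomm <- map_cis_nominal(dosage, vinfo, expr, NULL, gam)
  expect_equal(nomm$distance[nomm$variant_id == "edge"], -1e6)
  # low-MAF variants are excluded
  dosage2 <- cbind(dosage, rare = rbinom(300, 2, 0.005))
  vinfo2 <- rbind(vinfo, data.frame(variant_id = "rare", chr = "1",
                                    pos = tss))
  nom2 <- map_cis_nominal(dosage2, vinfo2, expr, NULL, ga, maf_min = 0.01)
  expect_false("rare" %in% nom2$variant_id)
})

test_that("a simulated slope of 0.5 per dose is recovered", {
  d <- make_eqtl_data(n = 400, seed = 5, slope = 0.5, causal = 2)
  expr <- matrix(d$e, 1, dimnames = list("g1", NULL))
  ga <- gene_annotation("g1", tss = 1.2e5, length = 100)
  nom <- map_cis_nominal(d$dosage, d$vinfo, expr, d$covs, ga)
  expect_lt(abs(nom$slope[nom$variant_id == "v2"] - 0.5), 0.15)
})

test_that("permuted labels give uniform nominal p-values", {
  set.seed(11)
  n <- 150
  dosage <- matrix(rbinom(n * 400, 2, 0.3), n,
                   dimnames = list(NULL, paste0("v", 1:400)))
  vinfo <- data.frame(variant_id = colnames(dosage), chr = "1",
                      pos = 1e5 + 100 * (1:400))
  expr <- matrix(rnorm(n), 1, dimnames = list("g1", NULL))
  nom <- map_cis_nominal(dosage, vinfo, expr, NULL,
                         gene_annotation("g1", tss = 1.2e5, length = 100))
  frac <- mean(nom$p < 0.05)
  expect_lt(abs(frac - 0.05), 2.576 * sqrt(0.05 * 0.95 / 400))
})

test_that("permutation pass follows the rank formula and beta smoothing", {
  d <- make_eqtl_data(n = 300, seed = 13, slope = 1)
  pp <- permutation_pass(d$dosage, d$e, d$covs, B = 100, seed = 2)
  # observed best p beats every permutation minimum
  expect_true(all(pp$perm_min > pp$best_p))
  expect_equal(pp$empirical_p_direct, 1 / 101)
  expect_identical(pp$best_variant, "v1")
  # rank formula recomputed from the returned permutation minima
  dn <- make_eqtl_data(n = 200, seed = 14, slope = 0)
  ppn <- permutation_pass(dn$dosage, dn$e, dn$covs, B = 100, seed = 3)
  expect_equal(ppn$empirical_p_direct,
               (sum(ppn$perm_min <= ppn$best_p) + 1) / 101)
  # smoothed and direct empirical p agree on a calibrated gene
  expect_lt(abs(ppn$empirical_p - ppn$empirical_p_direct), 2 / 100)
  expect_error(permutation_pass(d$dosage, d$e, d$covs, B = 50), "B must")
})

test_that("per-gene FDR thresholds separate signal from null genes", {
  perms <- list()
  d <- make_eqtl_data(n = 200, seed = 21, slope = 0.6)
  perms[["signal"]] <- permutation_pass(d$dosage, d$e, d$covs, B = 200,
                                        seed = 4)
  for (i in 1:6) {
    dn <- make_eqtl_data(n = 200, seed = 21 + i, slope = 0)
    perms[[paste0("null", i)]] <- permutation_pass(dn$dosage, dn$e, dn$covs,
                                                   B = 200, seed = 4 + i)
  }
  tab <- eqtl_fdr_thresholds(perms, fdr = 0.05)
  expect_true(tab$significant[tab$gene_id == "signal"])
  thr <- tab$threshold[tab$gene_id == "signal"]
  expect_true(is.finite(thr))
  expect_lt(perms[["signal"]]$best_p, thr)
  # empirical p is monotone in the observed best nominal p by construction
  expect_true(all(diff(tab$empirical_p[order(tab$empirical_p)]) >= 0))
})

test_that("lead-SNP enrichment reproduces the reference chi-squared", {
  enr <- lead_snp_enrichment(48, 915, 4671347, 182925823)
  expect_lt(abs(enr$chisq_p - 4.25e-7) / 4.25e-7, 0.005)
  expect_equal(enr$prop_lead, 48 / 915)
  # identical proportions: no effect
  e0 <- lead_snp_enrichment(50, 1000, 500, 10000)
  expect_gt(e0$chisq_p, 0.9)
  # toy table against a hand-computed continuity-corrected chi-squared
  e1 <- lead_snp_enrichment(8, 10, 2, 10)
  tab <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  expec <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((abs(tab - expec) - 0.5)^2 / expec)
  expect_equal(e1$chisq_stat, stat, tolerance = 1e-12)
  expect_equal(e1$chisq_p, pchisq(stat, 1, lower.tail = FALSE))
  # rank-sum arm
  set.seed(31)
  ew <- lead_snp_enrichment(8, 10, 2, 10, p_lead = runif(50, 0, 0.1),
                            p_all = runif(50))
  expect_lt(ew$wilcox_p, 0.01)
  expect_error(lead_snp_enrichment(0, 10, 0, 10), "zero-margin")
  expect_error(lead_snp_enrichment(0, 0, 1, 10), "non-empty")
})

test_that("tissue-specific pairs are those significant in exactly one tissue", {
  sig <- matrix(c(TRUE, FALSE, FALSE,
                  TRUE, TRUE, FALSE,
                  FALSE, FALSE, FALSE), 3, byrow = TRUE,
                dimnames = list(c("pair1", "pair2", "pair3"),
                                c("aortic_valve", "lung", "aorta")))
  ts <- classify_tissue_specific(sig)
  expect_equal(nrow(ts), 1)
  expect_identical(ts$pair, "pair1")
  expect_identical(ts$tissue, "aortic_valve")
  expect_error(classify_tissue_specific(sig[, 1, drop = FALSE]), "2 tissues")
})

test_that("subgroup heterogeneity is a two-sample z-test", {
  expect_equal(subgroup_heterogeneity(0.4, 0.1, 0.4, 0.2)$z, 0)
  expect_equal(subgroup_heterogeneity(0.4, 0.1, 0.4, 0.2)$p, 1)
  h <- subgroup_heterogeneity(0.5, 0.1, -0.5, 0.1)
  expect_equal(h$z, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_lt(h$p, 1e-10)
  expect_error(subgroup_heterogeneity(1, 0, 1, 0.1), "standard errors")
  # calibrated under equal true slopes
  set.seed(41)
  ps <- replicate(400, {
    b1 <- rnorm(1, 0.3, 0.1); b2 <- rnorm(1, 0.3, 0.15)
    subgroup_heterogeneity(b1, 0.1, b2, 0.15)$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 2.576 * sqrt(0.05 * 0.95 / 400))
})
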