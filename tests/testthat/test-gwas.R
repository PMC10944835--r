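# per-cohort logistic association, QC rules, IVW meta-analysis,
# genomic inflation, clumping/loci, credible sets

test_that("logistic scan is symmetric, consistent and flags bad fits", {
  # phenotype exactly balanced within each genotype class -> beta = 0
  g <- matrix(rep(c(0, 0, 1, 1, 2, 2), 50), ncol = 1)
  y <- rep(c(0, 1), 150)
  gw <- run_cohort_gwas(g, y)
  expect_lt(abs(gw$beta), 1e-8)
  # simulated log-OR 0.4 at MAF 0.3, n = 20000 -> estimate within 0.1
  set.seed(71)
  n <- 20000
  gg <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  yy <- rbinom(n, 1, plogis(-1 + 0.4 * gg[, 1]))
  gw2 <- run_cohort_gwas(gg, yy)
  expect_lt(abs(gw2$beta - 0.4), 0.1)
  # monomorphic variant flagged, not fatal
  gm <- cbind(mono = rep(1, 100), ok = rbinom(100, 2, 0.4))
  gw3 <- run_cohort_gwas(gm, rbinom(100, 1, 0.5))
  expect_identical(gw3$flag[1], "monomorphic")
  expect_true(is.na(gw3$beta[1]))
  expect_identical(gw3$flag[2], "")
  # perfect separation flagged
  gs <- matrix(c(rep(0, 50), rep(2, 50)), ncol = 1)
  ys <- c(rep(0, 50), rep(1, 50))
  gw4 <- run_cohort_gwas(gs, ys)
  expect_true(nzchar(gw4$flag))
  expect_error(run_cohort_gwas(gg, yy * 2), "binary")
})

test_that("QC exclusions are strict inequalities on the quoted bounds", {
  # v4/v5 sit at the MAF boundary with enough cases to clear the MAC rule
  recs <- toy_assoc(beta = rep(0.1, 10), se = rep(0.05, 10),
                    eaf = c(0.3, 0.3, 0.3, 0.001, 0.0009, 0.3, 0.3, 0.3,
                            0.3, 0.3),
                    info = c(1, 0.29, 0.3, 1, 1, 1, 1, 1, 1, 1),
                    n_cases = c(1000, 1000, 1000, 5000, 5000, 1000, 1000,
                                1000, 1000, 1000))
  # make record 6 fail the corrected minor-allele-count rule:
  # 2 * 1000 * maf * info < 5
  recs$eaf[6] <- 0.002; recs$info[6] <- 0.9
  out <- qc_filter(recs)
  expect_setequal(out$excluded$variant_id, c("v2", "v5", "v6"))
  expect_identical(out$excluded$rule[out$excluded$variant_id == "v2"],
                   "low_info")
  expect_identical(out$excluded$rule[out$excluded$variant_id == "v5"],
                   "low_maf")
  expect_identical(out$excluded$rule[out$excluded$variant_id == "v6"],
                   "low_mac_cases")
  expect_equal(nrow(out$kept), 7)
  # boundary values are retained: info = 0.3, maf = 0.001 exactly
  expect_true(all(c("v3", "v4") %in% out$kept$variant_id))
  # MAC rule skipped when info unavailable
  recs$info[6] <- NA
  expect_true("v6" %in% qc_filter(recs)$kept$variant_id)
})

test_that("IVW meta-analysis matches the closed form and is invariant", {
  t1 <- toy_assoc(0.1, 0.1)
  t2 <- toy_assoc(0.3, 0.1)
  m <- meta_analyze(list(t1, t2))
  expect_equal(m$beta_meta, 0.2, tolerance = 1e-12)
  expect_equal(m$se_meta, 0.1 / sqrt(2), tolerance = 1e-12)
  # single cohort: identity, Q = 0
  m1 <- meta_analyze(list(t1))
  expect_equal(m1$beta_meta, 0.1)
  expect_equal(m1$se_meta, 0.1)
  expect_equal(m1$q_stat, 0)
  # identical betas: Q = 0, I2 = 0, p_het = 1
  mh <- meta_analyze(list(t1, t1, t1))
  expect_equal(mh$q_stat, 0, tolerance = 1e-20)
  expect_equal(mh$i2, 0)
  expect_equal(mh$p_het, 1)
  # cohort order invariance
  ma <- meta_analyze(list(t1, t2)); mb <- meta_analyze(list(t2, t1))
  expect_equal(ma$beta_meta, mb$beta_meta)
  expect_equal(ma$q_stat, mb$q_stat)
  # relabeling effect/other alleles flips the sign consistently
  t2f <- t2
  t2f$effect_allele <- "G"; t2f$other_allele <- "A"
  t2f$beta <- -t2f$beta; t2f$eaf <- 1 - t2f$eaf
  mf <- meta_analyze(list(t1, t2f))
  expect_equal(mf$beta_meta, m$beta_meta, tolerance = 1e-12)
  expect_equal(mf$eaf, m$eaf, tolerance = 1e-12)
  # adding a cohort never increases se_meta
  expect_lte(m$se_meta, m1$se_meta)
  # irreconcilable allele pairs are dropped
  t2x <- t2; t2x$effect_allele <- "T"; t2x$other_allele <- "C"
  mx <- meta_analyze(list(t1, t2x))
  expect_equal(mx$n_cohorts, 1)
})

test_that("genomic inflation is 1 under the null and scale-equivariant", {
  p <- (seq_len(10000) - 0.5) / 10000
  expect_equal(genomic_inflation(p), 1, tolerance = 0.01)
  chi2 <- qchisq(p, 1, lower.tail = FALSE)
  p_infl <- pchisq(2 * chi2, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_infl), 2, tolerance = 0.02)
  expect_error(genomic_inflation(runif(50)), "100")
})

test_that("clumping applies the r2 and distance rules exactly", {
  mk_meta <- function(pos, p, ids = paste0("v", seq_along(pos))) {
    data.frame(variant_id = ids, chr = "1", pos = pos,
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta_meta = 1, se_meta = 1, p_meta = p,
               stringsAsFactors = FALSE)
  }
  # three leads at 1.0, 1.4, 2.1 Mb, pairwise r2 < 0.1: first two merge
  meta3 <- mk_meta(c(1e6, 1.4e6, 2.1e6), c(1e-9, 1e-10, 1e-12))
  r2_0 <- diag(3); dimnames(r2_0) <- list(meta3$variant_id, meta3$variant_id)
  loci <- clump_and_define_loci(meta3, r2_0)
  expect_equal(nrow(loci), 2)
  expect_setequal(loci$lead_variant, c("v2", "v3"))
  # merge window 100 kb: all three separate
  expect_equal(nrow(clump_and_define_loci(meta3, r2_0, merge_kb = 100)), 3)
  # perfect proxies 10 kb apart: one locus led by the smaller p
  meta2 <- mk_meta(c(1e6, 1.01e6), c(1e-9, 1e-11))
  r2_1 <- matrix(1, 2, 2)
  dimnames(r2_1) <- list(meta2$variant_id, meta2$variant_id)
  l2 <- clump_and_define_loci(meta2, r2_1)
  expect_equal(nrow(l2), 1)
  expect_identical(l2$lead_variant, "v2")
  expect_equal(l2$n_members, 2)
  # missing LD: treated independent with a warning
  expect_warning(clump_and_define_loci(meta2, r2_0[1:1, 1:1, drop = FALSE]),
                 "independent")
  # deterministic tie-break on equal p: position, then id
  meta_t <- mk_meta(c(1e6, 1.01e6), c(1e-9, 1e-9))
  lt <- clump_and_define_loci(meta_t, r2_1)
  expect_identical(lt$lead_variant, "v1")
})

test_that("credible sets follow the single-causal posterior", {
  d <- data.frame(variant_id = paste0("v", 1:11),
                  beta = c(1, rep(0, 10)), se = 0.1,
                  stringsAsFactors = FALSE)
  cs <- fine_map_credible_set(d)
  expect_identical(cs$set, "v1")
  expect_gt(cs$variants$posterior[1], 0.99)
  expect_equal(sum(cs$variants$posterior), 1, tolerance = 1e-12)
  # identical z: uniform posterior, set size ceiling(0.95 k)
  k <- 20
  dk <- data.frame(variant_id = paste0("v", 1:k), beta = 0.5, se = 0.1)
  csk <- fine_map_credible_set(dk)
  expect_equal(csk$variants$posterior, rep(1 / k, k), tolerance = 1e-12)
  expect_true(csk$uninformative)
  expect_equal(sum(fine_map_credible_set(dk, coverage = 0.95)$variants$cumulative
                   >= 0.95), k - ceiling(0.95 * k) + 1)
  # coverage is monotone in set size
  expect_true(all(diff(cs$variants$cumulative) >= 0))
  expect_error(fine_map_credible_set(data.frame(beta = NA, se = NA)), "finite")
})

test_that("the 95% credible set captures a simulated causal variant", {
  hit <- vapply(1:50, function(r) {
    set.seed(500 + r)
    z <- rnorm(10)
    z[4] <- z[4] + 7
    d <- data.frame(variant_id = paste0("v", 1:10), beta = z * 0.05,
                    se = 0.05)
    "v4" %in% fine_map_credible_set(d)$set
  }, NA)
  expect_gte(mean(hit), 0.9)
})
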