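# shared fixture builders for the test suite; everything is generated in
# code under fixed seeds

# minimal variant table for a hand-built dosage matrix
toy_variants <- function(m, chr = "1", pos = NULL, ea = "A", oa = "G") {
  pos <- pos %||% (1e5 + 5e3 * (seq_len(m) - 1))
  data.frame(variant_id = paste0("v", seq_len(m)), chr = chr, pos = pos,
             effect_allele = rep_len(ea, m), other_allele = rep_len(oa, m),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a per-cohort association table with given effects, for meta-analysis tests
toy_assoc <- function(beta, se, variant_id = paste0("v", seq_along(beta)),
                      ea = "A", oa = "G", eaf = 0.3, p = NULL,
                      info = 1, n_cases = 1000, n_controls = 1000) {
  m <- length(beta)
  data.frame(variant_id = variant_id, chr = "1",
             pos = 1e5 + 5e3 * (seq_len(m) - 1),
             effect_allele = rep_len(ea, m), other_allele = rep_len(oa, m),
             eaf = rep_len(eaf, m), beta = beta, se = se,
             p = p %||% 2 * pnorm(-abs(beta / se)),
             info = rep_len(info, m), n_cases = n_cases,
             n_controls = n_controls, flag = "", stringsAsFactors = FALSE)
}

# independent re-derivation of the TMM factor of each column against a fixed
# reference column, following the trimmed, precision-weighted definition
tmm_oracle <- function(counts, ref_col, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  raw <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; refc <- counts[, ref_col]
    lr <- log2((obs / lib[i]) / (refc / lib[ref_col]))
    ae <- 0.5 * (log2(obs / lib[i]) + log2(refc / lib[ref_col]))
    v <- (lib[i] - obs) / (lib[i] * obs) + (lib[ref_col] - refc) /
      (lib[ref_col] * refc)
    fin <- is.finite(lr) & is.finite(ae) & ae > -1e10
    lr <- lr[fin]; ae <- ae[fin]; v <- v[fin]
    n <- length(lr)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(lr) >= loL & rank(lr) <= hiL &
      rank(ae) >= loS & rank(ae) <= hiS
    f <- sum(lr[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f) || abs(f) < 1e-6) f <- 0
    2^f
  }, 0)
  raw / exp(mean(log(raw)))
}

# direct (non log-sum-exp) evaluation of the five colocalization hypothesis
# sums on a small instance
coloc_direct <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  a1 <- exp(l1); a2 <- exp(l2)
  h <- c(PP0 = 1, PP1 = p1 * sum(a1), PP2 = p2 * sum(a2),
         PP3 = p1 * p2 * (sum(a1) * sum(a2) - sum(a1 * a2)),
         PP4 = p12 * sum(a1 * a2))
  h / sum(h)
}
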