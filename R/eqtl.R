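# cis-eQTL mapping: nominal pass, permutation pass with beta-approximated
# empirical p-values and per-gene FDR thresholds, lead-SNP enrichment tests,
# tissue-specific classification and subgroup heterogeneity.

# residualize columns of y on [1 | covariates] via a shared QR decomposition
.residualize <- function(y, covariates = NULL) {
  x <- cbind(rep(1, NROW(y)), covariates)
  qr.resid(qr(x), y)
}

#' Nominal cis-eQTL pass
#'
#' Tests every variant within `window` bp of a gene's transcription start
#' site (inclusive, strand-signed distance) against the gene's
#' inverse-normal expression with covariate adjustment: expression and
#' dosage are both residualized on the covariates and the simple-regression
#' slope of the residuals is reported with its t-test p-value, which equals
#' the full-model coefficient by the Frisch-Waugh theorem (degrees of
#' freedom account for the projected-out covariates).
#'
#' @param dosage sample x variant matrix.
#' @param variant_info data frame (variant_id, chr, pos) for the dosage
#'   columns; optional `info` column of imputation qualities.
#' @param expr gene x sample inverse-normal expression matrix.
#' @param covariates sample x covariate matrix (no intercept), or NULL.
#' @param gene_annot [gene_annotation()] table covering the rows of `expr`.
#' @param window cis window half-width in bp (inclusive).
#' @param maf_min minimum minor allele frequency.
#' @param info_min minimum imputation quality (applied when available).
#' @return data frame of pair-level associations: gene_id, variant_id,
#'   distance (signed bp from TSS respecting strand), slope, se, p. Genes
#'   with no testable cis variant are absent (listed in attribute
#'   `genes_without_cis`).
#' @export
map_cis_nominal <- function(dosage, variant_info, expr, covariates = NULL,
                            gene_annot, window = 1e6, maf_min = 0.01,
                            info_min = 0.3) {
  samples_ok <- ncol(expr) == nrow(dosage)
  stop_if(!samples_ok, "expression samples must match dosage rows")
  maf <- pmin(colMeans(dosage) / 2, 1 - colMeans(dosage) / 2)
  keep <- maf >= maf_min
  if (!is.null(variant_info$info)) keep <- keep & variant_info$info >= info_min
  n <- nrow(dosage)
  q <- 1 + if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - q - 1
  g_res <- .residualize(dosage[, keep, drop = FALSE], covariates)
  e_res <- .residualize(t(expr), covariates)
  vi <- variant_info[keep, , drop = FALSE]
  gss <- colSums(g_res^2)
  out <- vector("list", nrow(expr))
  empty <- character(0)
  for (i in seq_len(nrow(expr))) {
    gid <- rownames(expr)[i]
    ga <- gene_annot[gene_annot$gene_id == gid, , drop = FALSE]
    if (nrow(ga) == 0) { empty <- c(empty, gid); next }
    cis <- which(vi$chr == ga$chr & abs(vi$pos - ga$tss) <= window & gss > 0)
    if (length(cis) == 0) { empty <- c(empty, gid); next }
    e <- e_res[, i]
    ge <- crossprod(g_res[, cis, drop = FALSE], e)[, 1]
    slope <- ge / gss[cis]
    rss <- sum(e^2) - slope * ge
    se <- sqrt(pmax(rss, 0) / df / gss[cis])
    tt <- slope / se
    sign_d <- if (ga$strand == "-") -1 else 1
    out[[i]] <- data.frame(gene_id = gid, variant_id = vi$variant_id[cis],
                           distance = sign_d * (vi$pos[cis] - ga$tss),
                           slope = slope, se = se,
                           p = 2 * pt(-abs(tt), df),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene_id = character(0))
  attr(res, "genes_without_cis") <- empty
  res
}

# maximum-likelihood beta fit to permutation minima, moment-matched start;
# returns NULL when the fit degenerates
.fit_beta <- function(x) {
  x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
  m <- mean(x); v <- var(x)
  if (v <= 0) return(NULL)
  c0 <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * c0, (1 - m) * c0), 1e-3))
  nll <- function(lp) -sum(dbeta(x, exp(lp[1]), exp(lp[2]), log = TRUE))
  fit <- tryCatch(optim(start, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value)) return(NULL)
  ab <- exp(fit$par)
  if (any(!is.finite(ab)) || any(ab <= 0)) return(NULL)
  list(a = ab[1], b = ab[2])
}

#' Permutation pass for one gene
#'
#' Permutes the gene's (residualized) expression across samples `B` times
#' with covariates fixed, records the best nominal p-value of each
#' permutation among the gene's cis variants, and summarizes the observed
#' best p as (i) the direct empirical p `(r + 1) / (B + 1)` and (ii) a
#' smoothed empirical p from a maximum-likelihood beta fit to the
#' permutation minima (falling back to the direct value when the fit
#' degenerates).
#'
#' @param dosage sample x cis-variant matrix for the gene.
#' @param e gene expression vector (inverse-normal).
#' @param covariates sample x covariate matrix or NULL.
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @return list of class `gene_permutation`: gene-level `best_p`,
#'   `best_variant`, `empirical_p` (beta-smoothed), `empirical_p_direct`,
#'   beta shape parameters `a`, `b` (NA on fallback), `B`, and the
#'   permutation minima.
#' @export
permutation_pass <- function(dosage, e, covariates = NULL, B = 1000,
                             seed = 1) {
  stop_if(B < 100, "B must be >= 100")
  n <- length(e)
  q <- 1 + if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - q - 1
  g_res <- .residualize(dosage, covariates)
  e_res <- .residualize(e, covariates)
  ok <- colSums(g_res^2) > 0
  stop_if(!any(ok), "no polymorphic cis variant")
  gn <- sweep(g_res[, ok, drop = FALSE], 2,
              sqrt(colSums(g_res[, ok, drop = FALSE]^2)), `/`)
  en <- sum(e_res^2)
  # |r| -> two-sided p through the monotone t transform
  p_from_r2 <- function(r2) {
    r2 <- pmin(r2, 1 - 1e-15)
    2 * pt(-sqrt(df * r2 / (1 - r2)), df)
  }
  r_obs <- crossprod(gn, e_res)[, 1] / sqrt(en)
  p_obs_all <- p_from_r2(r_obs^2)
  best <- which.min(p_obs_all)
  best_p <- p_obs_all[best]
  set.seed(seed)
  perm_min <- numeric(B)
  for (b in seq_len(B)) {
    ep <- e_res[sample.int(n)]
    r2 <- (crossprod(gn, ep)[, 1])^2 / en
    perm_min[b] <- p_from_r2(max(r2))
  }
  direct <- (sum(perm_min <= best_p) + 1) / (B + 1)
  fit <- .fit_beta(perm_min)
  smoothed <- if (is.null(fit)) direct else pbeta(best_p, fit$a, fit$b)
  structure(list(best_p = best_p,
                 best_variant = colnames(dosage)[which(ok)[best]],
                 empirical_p = smoothed, empirical_p_direct = direct,
                 a = fit$a %||% NA_real_, b = fit$b %||% NA_real_,
                 B = B, perm_min = perm_min),
            class = "gene_permutation")
}

#' Per-gene nominal significance thresholds at a target FDR
#'
#' Applies Benjamini-Hochberg across genes to the beta-smoothed empirical
#' p-values, locates the empirical p-value cutoff separating passing from
#' failing genes (midpoint between the largest passing and smallest failing
#' value), and inverts each passing gene's fitted beta CDF at that cutoff to
#' obtain its gene-specific nominal p-value threshold.
#'
#' @param perm_results list of [permutation_pass()] results, named by gene.
#' @param fdr target false discovery rate.
#' @return data frame: gene_id, empirical_p, qvalue, significant, threshold
#'   (nominal p threshold; NA for non-significant genes or fallback fits).
#' @export
eqtl_fdr_thresholds <- function(perm_results, fdr = 0.05) {
  emp <- vapply(perm_results, `[[`, 0, "empirical_p")
  qv <- p.adjust(emp, "BH")
  sig <- qv <= fdr
  if (any(sig)) {
    pass_max <- max(emp[sig])
    cutoff <- if (any(!sig)) (pass_max + min(emp[!sig])) / 2 else pass_max
  } else cutoff <- NA_real_
  thr <- rep(NA_real_, length(emp))
  for (i in which(sig)) {
    a <- perm_results[[i]]$a; b <- perm_results[[i]]$b
    thr[i] <- if (is.finite(a) && is.finite(b)) qbeta(cutoff, a, b) else NA_real_
  }
  data.frame(gene_id = names(perm_results), empirical_p = emp, qvalue = qv,
             significant = sig, threshold = thr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Enrichment of significant eQTL among lead-SNP pairs
#'
#' Compares the proportion of significant SNP-gene pairs among lead-SNP
#' pairs with the proportion among all tested pairs using a
#' continuity-corrected Pearson chi-squared test on the 2x2 table, and
#' optionally compares the two nominal p-value distributions with a
#' Wilcoxon rank-sum test (normal approximation with tie correction).
#'
#' @param n_sig_lead,n_lead significant and total pair counts for lead SNPs.
#' @param n_sig_all,n_all counts for all tested pairs.
#' @param p_lead,p_all optional nominal p-value vectors for the rank test.
#' @return list: `chisq_stat`, `chisq_p`, `prop_lead`, `prop_all`,
#'   `wilcox_p` (NA unless both p-value vectors are given).
#' @export
lead_snp_enrichment <- function(n_sig_lead, n_lead, n_sig_all, n_all,
                                p_lead = NULL, p_all = NULL) {
  stop_if(n_lead <= 0 || n_all <= 0, "both groups must be non-empty")
  tab <- matrix(c(n_sig_lead, n_lead - n_sig_lead,
                  n_sig_all, n_all - n_sig_all), nrow = 2, byrow = TRUE)
  stop_if(any(tab < 0), "counts must be non-negative")
  stop_if(any(rowSums(tab) == 0) || any(colSums(tab) == 0),
          "zero-margin contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  wp <- NA_real_
  if (!is.null(p_lead) && !is.null(p_all))
    wp <- suppressWarnings(wilcox.test(p_lead, p_all)$p.value)
  list(chisq_stat = unname(ct$statistic), chisq_p = ct$p.value,
       prop_lead = n_sig_lead / n_lead, prop_all = n_sig_all / n_all,
       wilcox_p = wp)
}

#' Classify tissue-specific eQTL pairs
#'
#' A SNP-gene pair is tissue-specific when it is significant in exactly one
#' of the tested tissues.
#'
#' @param sig pair x tissue logical matrix (rownames identify the pairs).
#' @return data frame: pair, tissue — one row per tissue-specific pair;
#'   pairs significant in zero or several tissues are absent.
#' @export
classify_tissue_specific <- function(sig) {
  stop_if(ncol(sig) < 2, "need >= 2 tissues")
  k <- rowSums(sig)
  idx <- which(k == 1)
  data.frame(pair = rownames(sig)[idx],
             tissue = colnames(sig)[apply(sig[idx, , drop = FALSE], 1, which)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Heterogeneity of an eQTL effect between two subgroups
#'
#' Two-sample z-test for a difference in slopes, e.g. between tricuspid and
#' bicuspid valves.
#'
#' @param slope1,se1,slope2,se2 subgroup estimates and standard errors.
#' @return list with `z` and two-sided `p`.
#' @export
subgroup_heterogeneity <- function(slope1, se1, slope2, se2) {
  stop_if(any(c(se1, se2) <= 0), "standard errors must be > 0")
  z <- (slope1 - slope2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
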