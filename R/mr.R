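# Two-sample Mendelian randomization of tissue expression (exposure) on
# disease (outcome): instrument selection, IVW / Egger / weighted-median
# estimators, heterogeneity, and the gene-level decision rule.

#' Select MR instruments for one gene
#'
#' Starting from harmonized exposure (cis-eQTL) and outcome (GWAS) summary
#' statistics, keeps variants with exposure p-value below `p_max` and
#' per-instrument strength `F = (bx / bx_se)^2` above `f_min`, clumps them
#' greedily by ascending exposure p at `r2 < r2_max`, and requires at least
#' `min_n` surviving instruments.
#'
#' @param exposure data frame: variant_id, beta, se, p (effect of dose on
#'   inverse-normal expression).
#' @param outcome data frame: variant_id, beta, se (log-OR per dose,
#'   aligned to the same effect allele); optional effect_allele /
#'   other_allele columns trigger harmonization (swaps flip the outcome
#'   sign, irreconcilable or ambiguous palindromic pairs are dropped).
#' @param r2 squared-correlation LD matrix for the candidate variants.
#' @param p_max,r2_max,min_n,f_min selection parameters.
#' @return data frame of instruments (variant_id, bx, bx_se, by, by_se, F),
#'   or an empty data frame with attribute `reason` when fewer than `min_n`
#'   survive.
#' @export
select_instruments <- function(exposure, outcome, r2, p_max = 1e-4,
                               r2_max = 0.1, min_n = 3, f_min = 15) {
  if (!is.null(exposure$effect_allele) && !is.null(outcome$effect_allele)) {
    h <- .harmonize(exposure, outcome)
    ok <- !is.na(h$beta)
    if (any(!ok)) warning("dropping ", sum(!ok),
                          " variant(s) with unresolvable alleles")
    outcome <- h
  } else {
    outcome <- outcome[match(exposure$variant_id, outcome$variant_id), ,
                       drop = FALSE]
  }
  cand <- data.frame(variant_id = exposure$variant_id,
                     bx = exposure$beta, bx_se = exposure$se,
                     px = exposure$p, by = outcome$beta, by_se = outcome$se,
                     stringsAsFactors = FALSE)
  cand$F <- (cand$bx / cand$bx_se)^2
  cand <- cand[complete.cases(cand) & cand$px < p_max & cand$F > f_min, ,
               drop = FALSE]
  cand <- cand[order(cand$px, cand$variant_id), , drop = FALSE]
  keep <- character(0)
  for (v in cand$variant_id) {
    ld <- vapply(keep, function(u)
      if (v %in% rownames(r2) && u %in% colnames(r2)) r2[v, u] else 0, 0)
    if (all(ld < r2_max)) keep <- c(keep, v)
  }
  out <- cand[cand$variant_id %in% keep,
              c("variant_id", "bx", "bx_se", "by", "by_se", "F"),
              drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < min_n) {
    res <- out[0, , drop = FALSE]
    attr(res, "reason") <- sprintf("only %d instrument(s) after selection (need %d)",
                                   nrow(out), min_n)
    return(res)
  }
  out
}

# weighted median of ratio estimates; weights need not be normalized
.weighted_median <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(ratio[1])
  k <- max(which(s < 0.5))
  if (k == length(ratio)) return(ratio[k])
  ratio[k] + (ratio[k + 1] - ratio[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Mendelian randomization estimates for one gene
#'
#' Computes three estimators of the causal effect of expression on disease
#' from instrument-level summary statistics: fixed-effect inverse-variance
#' weighted regression through the origin; Egger regression (weighted least
#' squares of outcome on exposure effects with an intercept testing
#' directional pleiotropy, instruments oriented to positive exposure
#' effects); and the weighted median of the per-instrument ratio estimates
#' with a seeded parametric-bootstrap standard error. Heterogeneity is
#' Cochran's Q about the IVW slope with a chi-squared (k-1) p-value.
#'
#' The default IVW standard error is first-order fixed-effect, treating the
#' exposure effects as known. When the exposure is estimated in a modest
#' sample its measurement error overdisperses the ratio estimates beyond
#' the outcome standard errors; `model = "random"` applies the
#' multiplicative random-effects correction, inflating the IVW standard
#' error by `sqrt(Q / (k - 1))` when that exceeds 1, and
#' `model = "second"` uses second-order weights
#' `1 / (by_se^2 + theta^2 bx_se^2)` (iterated) that model the exposure
#' measurement error directly. The weighted-median bootstrap already
#' propagates both noise sources.
#'
#' @param instruments data frame from [select_instruments()] (variant_id,
#'   bx, bx_se, by, by_se).
#' @param n_boot bootstrap draws for the weighted-median standard error.
#' @param seed integer seed for the bootstrap.
#' @param model IVW error model: "fixed" (first-order fixed-effect,
#'   default), "random" (multiplicative random-effects) or "second"
#'   (second-order weights).
#' @return object of class `mr_result` with ivw / egger / wm estimates,
#'   standard errors and p-values, the Egger intercept test, Q and its p,
#'   and `n_instruments`.
#' @export
mr_estimates <- function(instruments, n_boot = 1000, seed = 1,
                         model = c("fixed", "random", "second")) {
  model <- match.arg(model)
  k <- nrow(instruments)
  stop_if(k < 3, "need >= 3 instruments")
  bx <- instruments$bx; bx_se <- instruments$bx_se
  by <- instruments$by; by_se <- instruments$by_se
  w <- 1 / by_se^2
  ivw <- sum(bx * by * w) / sum(bx^2 * w)
  ivw_se <- 1 / sqrt(sum(bx^2 * w))
  ivw_p <- 2 * pnorm(-abs(ivw / ivw_se))
  q <- sum(w * (by - ivw * bx)^2)
  q_p <- pchisq(q, k - 1, lower.tail = FALSE)
  if (model == "random") {
    infl <- max(1, sqrt(q / (k - 1)))
    ivw_se <- ivw_se * infl
    ivw_p <- 2 * pnorm(-abs(ivw / ivw_se))
  } else if (model == "second") {
    bx_se <- instruments$bx_se
    th <- ivw
    for (it in 1:3) {
      w2 <- 1 / (by_se^2 + th^2 * bx_se^2)
      th <- sum(w2 * bx * by) / sum(w2 * bx^2)
    }
    ivw <- th
    ivw_se <- 1 / sqrt(sum(w2 * bx^2))
    ivw_p <- 2 * pnorm(-abs(ivw / ivw_se))
  }
  # Egger with instruments oriented so all exposure effects are positive
  sgn <- ifelse(bx < 0, -1, 1)
  eg <- lm(I(sgn * by) ~ I(sgn * bx), weights = w)
  egs <- summary(eg)$coefficients
  # weighted median of ratio estimates, inverse-variance weights on ratios
  nz <- bx != 0
  if (any(!nz)) warning("excluding ", sum(!nz),
                        " instrument(s) with zero exposure effect from the weighted median")
  ratio <- by[nz] / bx[nz]
  wm_w <- bx[nz]^2 / by_se[nz]^2
  wm <- .weighted_median(ratio, wm_w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    bxs <- rnorm(sum(nz), bx[nz], bx_se[nz])
    bys <- rnorm(sum(nz), by[nz], by_se[nz])
    ok <- bxs != 0
    .weighted_median(bys[ok] / bxs[ok], bxs[ok]^2 / by_se[nz][ok]^2)
  }, 0)
  wm_se <- sd(boot)
  structure(list(n_instruments = k,
                 ivw = ivw, ivw_se = ivw_se, ivw_p = ivw_p,
                 egger = unname(egs[2, 1]), egger_se = unname(egs[2, 2]),
                 egger_p = unname(egs[2, 4]),
                 egger_intercept = unname(egs[1, 1]),
                 egger_intercept_se = unname(egs[1, 2]),
                 egger_intercept_p = unname(egs[1, 4]),
                 wm = wm, wm_se = wm_se,
                 wm_p = 2 * pnorm(-abs(wm / wm_se)),
                 q = q, q_p = q_p, model = model),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR with %d instruments\n", x$n_instruments))
  cat(sprintf("  IVW:             %8.4f (se %.4f, p %.3g)\n", x$ivw, x$ivw_se, x$ivw_p))
  cat(sprintf("  Egger slope:     %8.4f (se %.4f, p %.3g)\n", x$egger, x$egger_se, x$egger_p))
  cat(sprintf("  Egger intercept: %8.4f (p %.3g)\n", x$egger_intercept, x$egger_intercept_p))
  cat(sprintf("  Weighted median: %8.4f (se %.4f, p %.3g)\n", x$wm, x$wm_se, x$wm_p))
  cat(sprintf("  Cochran Q: %.3f (p %.3g)\n", x$q, x$q_p))
  invisible(x)
}

#' Gene-level MR decision rule
#'
#' Drops genes whose instrument heterogeneity p-value is below `q_alpha`,
#' Benjamini-Hochberg adjusts the IVW and weighted-median p-values
#' separately across the remaining genes, and calls a gene a causal
#' candidate when both adjusted tests pass at `fdr` and the Egger intercept
#' shows no pleiotropy (p > 0.05).
#'
#' @param results data frame with one row per gene: gene_id, ivw_p, wm_p,
#'   egger_intercept_p, q_p (e.g. rows assembled from [mr_estimates()]).
#' @param q_alpha heterogeneity exclusion threshold.
#' @param fdr target false discovery rate.
#' @param intercept_alpha pleiotropy threshold on the Egger intercept p.
#' @return the table restricted to genes passing the heterogeneity filter,
#'   with `ivw_q`, `wm_q` and `candidate` columns appended; removed genes in
#'   attribute `removed_heterogeneity`.
#' @export
gene_screen <- function(results, q_alpha = 0.01, fdr = 0.05,
                        intercept_alpha = 0.05) {
  het <- !is.na(results$q_p) & results$q_p < q_alpha
  kept <- results[!het, , drop = FALSE]
  kept$ivw_q <- p.adjust(kept$ivw_p, "BH")
  kept$wm_q <- p.adjust(kept$wm_p, "BH")
  kept$candidate <- kept$ivw_q <= fdr & kept$wm_q <= fdr &
    kept$egger_intercept_p > intercept_alpha
  attr(kept, "removed_heterogeneity") <- results$gene_id[het]
  kept
}
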