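# Expression matrix processing: TPM, expression filters, TMM normalization,
# inverse-normal transform, expression covariates, tissue specificity scores
# and the high-expression flag.

#' Transcripts per million
#'
#' Length-normalized abundance: per-gene read rate `count / length`, scaled
#' per sample so columns sum to 1e6. Samples with zero library size are
#' returned as NA columns with a warning.
#'
#' @param counts gene x sample count matrix.
#' @param lengths gene lengths in bp (named or in row order).
#' @return TPM matrix with the same dimensions.
#' @export
compute_tpm <- function(counts, lengths) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  stop_if(any(lengths <= 0), "gene lengths must be > 0")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " sample(s) with zero library size flagged as NA")
    tot[tot == 0] <- NA_real_
  }
  sweep(rate, 2, tot, `/`) * 1e6
}

#' Expression filter for eQTL analysis
#'
#' A gene is kept when its TPM exceeds `min_tpm` (strictly) in at least
#' `min_frac` of samples and its read count is at least `min_reads` in at
#' least `min_frac` of samples.
#'
#' @param counts gene x sample count matrix.
#' @param tpm matching TPM matrix.
#' @param min_tpm,min_reads,min_frac filter parameters.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, tpm, min_tpm = 0.1, min_reads = 6,
                             min_frac = 0.2) {
  frac_tpm <- rowMeans(tpm > min_tpm, na.rm = TRUE)
  frac_reads <- rowMeans(counts >= min_reads)
  rownames(counts)[frac_tpm >= min_frac & frac_reads >= min_frac]
}

#' TMM between-sample normalization
#'
#' Trimmed mean of M-values scale factors (trimming 30% of M-values and 5%
#' of A-values, precision-weighted), with the reference sample chosen as the
#' column whose upper quartile is closest to the mean upper quartile, and
#' factors rescaled so their log-mean is zero. Computed with the canonical
#' implementation in edgeR. Samples with all-zero counts are rejected.
#'
#' @param counts gene x sample count matrix.
#' @param reference_sample optional reference column (index or name).
#' @return list: `factors` (per-sample TMM factors), `effective_lib`
#'   (library size times factor), `log_cpm` (log2 counts per million using
#'   effective library sizes, prior count 0.5), `reference`.
#' @export
tmm_normalize <- function(counts, reference_sample = NULL) {
  stop_if(ncol(counts) < 2, "need >= 2 samples")
  lib <- colSums(counts)
  stop_if(any(lib == 0), "sample(s) with all-zero counts: ",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  ref <- if (is.character(reference_sample))
    match(reference_sample, colnames(counts)) else reference_sample
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  eff <- lib * f
  log_cpm <- log2(sweep(counts + 0.5, 2, (eff + 1) / 1e6, `/`))
  list(factors = setNames(f, colnames(counts)), effective_lib = eff,
       log_cpm = log_cpm, reference = ref)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles `qnorm((rank - 0.5) / n)` with ties
#' receiving the average rank. Output depends on the input only through its
#' ranks.
#'
#' @param x numeric vector (>= 3 values).
#' @return transformed vector; constant input returns all-NA with a warning.
#' @export
inverse_normal <- function(x) {
  stop_if(length(x) < 3, "need >= 3 values")
  if (length(unique(x[!is.na(x)])) <= 1) {
    warning("constant input; returning NA (gene should be excluded)")
    return(rep(NA_real_, length(x)))
  }
  r <- rank(x, ties.method = "average", na.last = "keep")
  qnorm((r - 0.5) / sum(!is.na(x)))
}

#' Apply the inverse normal transform gene-wise
#'
#' @param mat gene x sample matrix.
#' @return matrix of the same shape; constant genes are dropped with a
#'   message.
#' @export
inverse_normal_matrix <- function(mat) {
  const <- apply(mat, 1, function(v) length(unique(v)) <= 1)
  if (any(const))
    message("dropping ", sum(const), " constant gene(s) before transform")
  t(apply(mat[!const, , drop = FALSE], 1, inverse_normal))
}

#' Top expression components for covariate adjustment
#'
#' Orthonormal sample-loading vectors of the centered expression matrix
#' (left singular vectors of the sample x gene matrix), ordered by variance
#' explained. These act as data-driven covariates capturing broad expression
#' structure (batch, cell composition), analogous to factor-analysis
#' residual methods used in large eQTL studies.
#'
#' @param mat gene x sample normalized expression matrix.
#' @param k number of components; must satisfy `k < min(genes, samples)`.
#' @return sample x k matrix with orthonormal columns; attribute
#'   `variance_explained` gives the per-component fraction.
#' @export
expression_covariates <- function(mat, k) {
  stop_if(k >= min(dim(mat)), "k must be < min(n_genes, n_samples)")
  x <- scale(t(mat), center = TRUE, scale = FALSE)
  sv <- svd(x, nu = k, nv = 0)
  u <- sv$u
  dimnames(u) <- list(colnames(mat), paste0("EC", seq_len(k)))
  attr(u, "variance_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  u
}

#' Per-gene median log2 TPM
#'
#' The default offset of 1 (log2(TPM+1)) keeps medians non-negative, the
#' convention assumed by the specificity scores; `offset = 0` gives raw
#' log2 TPM, in which case negative medians are clamped downstream.
#'
#' @param tpm gene x sample TPM matrix.
#' @param offset pseudocount added before the log.
#' @return named vector of per-gene medians.
#' @export
median_log2_tpm <- function(tpm, offset = 1) {
  apply(log2(tpm + offset), 1, median, na.rm = TRUE)
}

#' Expression specificity scores across tissues
#'
#' For each gene, a tissue's score is its median log2 TPM divided by the sum
#' of the medians over all tissues, giving a share in \[0, 1\] that sums to
#' one per gene. Negative medians (possible when raw log2 TPM rather than
#' log2(TPM+1) is supplied) are clamped to zero before the division, since
#' the ratio is undefined for negative values. Genes whose medians are all
#' zero get NA scores and are flagged.
#'
#' @param med tissue x gene matrix of median log2 TPM.
#' @param valve_tissue row name of the target tissue.
#' @param threshold specificity flag threshold (strictly above).
#' @return list: `ess` (tissue x gene score matrix), `valve_ess` (named
#'   vector for the target tissue), `valve_specific` (logical,
#'   `valve_ess > threshold`), `undefined` (gene ids with all-zero medians).
#' @export
specificity_scores <- function(med, valve_tissue = "aortic_valve",
                               threshold = 0.1) {
  stop_if(!all(is.finite(med)), "medians must be finite")
  stop_if(!valve_tissue %in% rownames(med),
          "tissue not found: ", valve_tissue)
  m <- pmax(med, 0)
  tot <- colSums(m)
  undefined <- colnames(m)[tot == 0]
  tot[tot == 0] <- NA_real_
  ess <- sweep(m, 2, tot, `/`)
  valve <- ess[valve_tissue, ]
  list(ess = ess, valve_ess = valve,
       valve_specific = !is.na(valve) & valve > threshold,
       undefined = undefined)
}

#' High-expression flag
#'
#' Flags genes whose median expression lies strictly above the empirical
#' 90th percentile of all genes' medians.
#'
#' @param medians named vector of per-gene median log2 TPM in the target
#'   tissue.
#' @param probs percentile defining "high" (default 0.9).
#' @return named logical vector.
#' @export
flag_high_expression <- function(medians, probs = 0.9) {
  stop_if(length(medians) < 10, "need >= 10 genes")
  medians > quantile(medians, probs, na.rm = TRUE)
}
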