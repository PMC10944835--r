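# TWAS: per-gene elastic-net expression prediction with nested
# cross-validation, the model qualification rule, and the summary-statistic
# association test.

#' Train an elastic-net expression prediction model
#'
#' Nested cross-validation: outer folds provide honest out-of-sample
#' predictions; within each outer training set an inner cross-validation
#' selects the elastic-net penalty (mixing parameter fixed at 0.5). The
#' per-fold Pearson correlations between predicted and observed expression
#' are averaged; the one-sided p-value for the average correlation uses the
#' t transform at n - 2 degrees of freedom. A model qualifies when the
#' average correlation exceeds 0.1 (strictly), its p-value is below 0.05 and
#' the final refit keeps at least one variant. Final weights are refit on
#' all samples with the penalty chosen by inner cross-validation on the full
#' data.
#'
#' @param dosage sample x cis-variant matrix (>= 2 variants, >= 50 samples).
#' @param e inverse-normal expression vector.
#' @param n_folds,n_inner outer and inner fold counts.
#' @param alpha elastic-net mixing parameter.
#' @param seed integer seed controlling fold assignment.
#' @param two_sided use a two-sided correlation test instead of the default
#'   one-sided (positive) test.
#' @return object of class `expression_model`: `weights` (named, nonzero
#'   only), `sigma_l` (training SDs of the weighted variants), `sigma_g`
#'   (SD of the predicted expression), `cv_r` (average fold correlation),
#'   `cv_p`, `qualified`, `n`, `fold_r`.
#' @export
train_expression_model <- function(dosage, e, n_folds = 5, n_inner = 5,
                                   alpha = 0.5, seed = 1, two_sided = FALSE) {
  stop_if(ncol(dosage) < 2, "need >= 2 cis variants")
  stop_if(nrow(dosage) < 50, "need >= 50 samples")
  n <- nrow(dosage)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  fold_r <- rep(NA_real_, n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    cvfit <- tryCatch(glmnet::cv.glmnet(dosage[tr, , drop = FALSE], e[tr],
                                        alpha = alpha, nfolds = n_inner),
                      error = function(err) NULL)
    if (is.null(cvfit)) next
    pred <- predict(cvfit, dosage[!tr, , drop = FALSE], s = "lambda.min")[, 1]
    fold_r[k] <- if (sd(pred) > 0) cor(pred, e[!tr]) else 0
  }
  cv_r <- mean(fold_r, na.rm = TRUE)
  tt <- cv_r * sqrt((n - 2) / max(1 - cv_r^2, 1e-12))
  cv_p <- if (two_sided) 2 * pt(-abs(tt), n - 2) else pt(tt, n - 2,
                                                         lower.tail = FALSE)
  final <- tryCatch(glmnet::cv.glmnet(dosage, e, alpha = alpha,
                                      nfolds = n_inner),
                    error = function(err) NULL)
  w <- numeric(0)
  if (!is.null(final)) {
    cf <- as.matrix(coef(final, s = "lambda.min"))[-1, 1]
    w <- cf[cf != 0]
  }
  sigma_l <- apply(dosage[, names(w), drop = FALSE], 2, sd)
  sigma_g <- if (length(w) > 0)
    sd(as.vector(dosage[, names(w), drop = FALSE] %*% w)) else 0
  qualified <- model_qualifies(cv_r, cv_p, length(w), sigma_g)
  structure(list(weights = w, sigma_l = sigma_l, sigma_g = sigma_g,
                 cv_r = cv_r, cv_p = cv_p, qualified = qualified, n = n,
                 fold_r = fold_r),
            class = "expression_model")
}

#' Expression-model qualification rule
#'
#' A prediction model qualifies when the cross-validated average Pearson
#' correlation is strictly greater than 0.1, its p-value is below 0.05, and
#' the refit keeps at least one variant with positive predicted-expression
#' variance.
#'
#' @param cv_r average cross-validated correlation.
#' @param cv_p its p-value.
#' @param n_nonzero number of nonzero weights in the final refit.
#' @param sigma_g predicted-expression standard deviation.
#' @export
model_qualifies <- function(cv_r, cv_p, n_nonzero = 1, sigma_g = 1) {
  is.finite(cv_r) && cv_r > 0.1 && is.finite(cv_p) && cv_p < 0.05 &&
    n_nonzero > 0 && sigma_g > 0
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf("expression model: %d variant(s), cv r = %.3f (p = %.3g), %s\n",
              length(x$weights), x$cv_r, x$cv_p,
              if (x$qualified) "qualified" else "not qualified"))
  invisible(x)
}

#' Summary-statistic TWAS association
#'
#' Combines a gene's expression-model weights with GWAS z-scores:
#' `Z_g = sum_l w_l (sigma_l / sigma_g) z_l` where
#' `sigma_g^2 = w' Sigma w` and `Sigma` is the covariance of the weighted
#' variants in the LD reference (`diag(sigma_l) R diag(sigma_l)`). Variants
#' with no z-score are dropped with a warning; `sigma_g` is recomputed on
#' the used set.
#'
#' @param model a qualified [train_expression_model()] result.
#' @param z named vector of GWAS z-scores (effect-allele aligned with the
#'   model's training dosages).
#' @param ld correlation matrix of the model variants (LD reference).
#' @return data frame row: zscore, p, n_variants_used; NULL (with a
#'   warning) when `sigma_g` is not positive.
#' @export
spredixcan <- function(model, z, ld) {
  stop_if(!isTRUE(model$qualified), "model is not qualified")
  w <- model$weights
  have <- names(w) %in% names(z) & is.finite(z[names(w)])
  if (!all(have)) {
    warning("dropping ", sum(!have), " weighted variant(s) with no z-score")
    w <- w[have]
  }
  if (length(w) == 0) { warning("no usable variant"); return(NULL) }
  sl <- model$sigma_l[names(w)]
  r <- ld[names(w), names(w), drop = FALSE]
  sigma2 <- as.numeric(t(w * sl) %*% r %*% (w * sl))
  if (sigma2 <= 0) { warning("non-positive predicted-expression variance"); return(NULL) }
  zg <- sum(w * sl * z[names(w)]) / sqrt(sigma2)
  data.frame(zscore = zg, p = 2 * pnorm(-abs(zg)),
             n_variants_used = length(w))
}

#' Benjamini-Hochberg flagging of TWAS associations
#'
#' @param assoc data frame with a `p` column (one row per tested gene).
#' @param fdr target false discovery rate.
#' @return the table with `qvalue` and `significant` columns appended.
#' @export
twas_fdr <- function(assoc, fdr = 0.05) {
  assoc$qvalue <- p.adjust(assoc$p, "BH")
  assoc$significant <- !is.na(assoc$qvalue) & assoc$qvalue <= fdr
  assoc
}
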