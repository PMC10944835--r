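# Per-cohort logistic GWAS, QC filtering, inverse-variance weighted
# fixed-effect meta-analysis, genomic inflation, LD clumping / locus
# definition, and single-causal-variant credible sets.

#' Per-cohort logistic association scan
#'
#' Fits a maximum-likelihood logistic regression of case status on each
#' variant's dosage with covariate adjustment and reports the Wald test on
#' the log-odds scale. Monomorphic variants and fits showing signs of
#' separation are returned with a `flag` and unusable (NA) statistics.
#'
#' @param dosage sample x variant dosage matrix.
#' @param phenotype 0/1 vector.
#' @param covariates numeric covariate matrix (no intercept column), or NULL.
#' @param variants optional variant table (variant_id, chr, pos,
#'   effect_allele, other_allele); defaults to minimal ids from column names.
#' @param info imputation quality per variant (default 1 for simulated
#'   genotypes).
#' @return data frame of per-variant associations: variant_id, chr, pos,
#'   effect_allele, other_allele, eaf, beta, se, p, info, n_cases,
#'   n_controls, flag.
#' @export
run_cohort_gwas <- function(dosage, phenotype, covariates = NULL,
                            variants = NULL, info = 1) {
  stop_if(!all(phenotype %in% c(0, 1)), "phenotype must be binary 0/1")
  n <- length(phenotype)
  stop_if(nrow(dosage) != n, "dosage rows must match phenotype length")
  if (is.null(variants)) {
    variants <- data.frame(variant_id = colnames(dosage) %||%
                             paste0("v", seq_len(ncol(dosage))),
                           chr = NA_character_, pos = NA_real_,
                           effect_allele = "A", other_allele = "G",
                           stringsAsFactors = FALSE)
  }
  base <- cbind(`(Intercept)` = rep(1, n), covariates)
  stop_if(qr(base)$rank < ncol(base), "covariate matrix is rank deficient")
  m <- ncol(dosage)
  beta <- se <- p <- rep(NA_real_, m)
  flag <- rep("", m)
  eaf <- colMeans(dosage) / 2
  n_cases <- sum(phenotype); n_controls <- n - n_cases
  for (j in seq_len(m)) {
    g <- dosage[, j]
    if (var(g) == 0) { flag[j] <- "monomorphic"; next }
    x <- cbind(base, dose = g)
    fit <- tryCatch(suppressWarnings(
      glm.fit(x, phenotype, family = binomial())), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { flag[j] <- "nonconverged"; next }
    k <- ncol(x)
    # Wald SE from the unscaled covariance of the IRLS fit
    xtwx <- crossprod(sqrt(fit$weights) * x)
    cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
    if (is.null(cov)) { flag[j] <- "singular"; next }
    b <- fit$coefficients[k]; s <- sqrt(cov[k, k])
    if (!is.finite(s) || s > 10 || abs(b) > 10) { flag[j] <- "separation"; next }
    beta[j] <- b; se[j] <- s
    p[j] <- 2 * pnorm(-abs(b / s))
  }
  data.frame(variant_id = variants$variant_id, chr = variants$chr,
             pos = variants$pos, effect_allele = variants$effect_allele,
             other_allele = variants$other_allele, eaf = eaf, beta = beta,
             se = se, p = p, info = rep_len(info, m),
             n_cases = n_cases, n_controls = n_controls, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname run_cohort_gwas
#' @param cohort a `sim_cohort` object.
#' @export
run_cohort_gwas_sim <- function(cohort) {
  run_cohort_gwas(cohort$dosage, cohort$phenotype, cohort$covariates,
                  variants = cohort$variants)
}

#' Quality-control filter for per-cohort summary statistics
#'
#' Excludes records with imputation quality below `info_min`, minor allele
#' frequency below `maf_min`, or minor allele count in cases corrected for
#' imputation quality (`2 * n_cases * MAF * INFO`) below `mac_min`. All
#' bounds are strict (`<`), so a record exactly at a bound is retained. Rules
#' needing unavailable fields (NA) are skipped for that record. Records
#' carrying a non-empty `flag` are also excluded.
#'
#' @param records data frame as returned by [run_cohort_gwas()].
#' @param info_min,maf_min,mac_min exclusion thresholds.
#' @return list with `kept` (surviving records) and `excluded` (records with
#'   an added `rule` column naming the first violated rule).
#' @export
qc_filter <- function(records, info_min = 0.3, maf_min = 0.001, mac_min = 5) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  mac_cases <- 2 * records$n_cases * maf * records$info
  rule <- rep(NA_character_, nrow(records))
  bad_flag <- !is.na(records$flag) & nzchar(records$flag)
  rule[bad_flag] <- paste0("flag:", records$flag[bad_flag])
  hit <- function(cond) !is.na(cond) & cond & is.na(rule)
  rule[hit(records$info < info_min)] <- "low_info"
  rule[hit(maf < maf_min)] <- "low_maf"
  rule[hit(mac_cases < mac_min)] <- "low_mac_cases"
  excluded <- records[!is.na(rule), , drop = FALSE]
  if (nrow(excluded) > 0) excluded$rule <- rule[!is.na(rule)]
  list(kept = records[is.na(rule), , drop = FALSE], excluded = excluded)
}

# harmonize a cohort table onto reference alleles keyed by (variant_id);
# swapped allele pairs flip the effect sign and the allele frequency;
# returns NULL rows for irreconcilable pairs
.harmonize <- function(ref, tab, drop_palindromic = TRUE) {
  i <- match(ref$variant_id, tab$variant_id)
  out <- tab[i, , drop = FALSE]
  same <- !is.na(i) & out$effect_allele == ref$effect_allele &
    out$other_allele == ref$other_allele
  swap <- !is.na(i) & out$effect_allele == ref$other_allele &
    out$other_allele == ref$effect_allele
  out$beta[swap] <- -out$beta[swap]
  out$eaf[swap] <- 1 - out$eaf[swap]
  out$effect_allele[swap] <- ref$effect_allele[swap]
  out$other_allele[swap] <- ref$other_allele[swap]
  bad <- !is.na(i) & !(same | swap)
  if (drop_palindromic) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    pal <- !is.na(i) & comp[out$effect_allele] == out$other_allele
    ambig <- pal & pmin(out$eaf, 1 - out$eaf) > 0.4
    bad <- bad | ambig
  }
  out[bad | is.na(i), ] <- NA
  attr(out, "n_irreconcilable") <- sum(bad, na.rm = TRUE)
  out
}

#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Combines per-cohort log-odds ratios with weights `1/se^2` after
#' harmonizing alleles against the first cohort carrying each variant
#' (swapped effect/other alleles flip the sign and allele frequency;
#' irreconcilable pairs and strand-ambiguous A/T, G/C variants with MAF >
#' 0.4 are dropped with a log entry). Heterogeneity is summarized by
#' Cochran's Q with a chi-squared (k-1) p-value and `I2 = max(0,
#' (Q-(k-1))/Q) * 100`.
#'
#' @param cohort_tables list of per-cohort association tables (columns as in
#'   [run_cohort_gwas()]).
#' @return data frame of meta records: variant_id, chr, pos, effect_allele,
#'   other_allele, eaf (weighted), beta_meta, se_meta, p_meta, q_stat,
#'   p_het, i2, n_cohorts, direction.
#' @export
meta_analyze <- function(cohort_tables) {
  stopifnot(length(cohort_tables) >= 1)
  usable <- lapply(cohort_tables, function(t)
    t[!is.na(t$beta) & !is.na(t$se) & t$se > 0, , drop = FALSE])
  ids <- unique(unlist(lapply(usable, `[[`, "variant_id")))
  first <- usable[[which.max(vapply(usable, nrow, 0L))]]
  ref <- do.call(rbind, usable)
  ref <- ref[!duplicated(ref$variant_id), , drop = FALSE]
  ref <- ref[match(ids, ref$variant_id), , drop = FALSE]
  k <- length(usable)
  B <- S <- matrix(NA_real_, length(ids), k)
  EAF <- matrix(NA_real_, length(ids), k)
  dropped <- 0L
  for (j in seq_len(k)) {
    h <- .harmonize(ref, usable[[j]])
    dropped <- dropped + attr(h, "n_irreconcilable")
    B[, j] <- h$beta; S[, j] <- h$se; EAF[, j] <- h$eaf
  }
  w <- 1 / S^2
  sw <- rowSums(w, na.rm = TRUE)
  beta_meta <- rowSums(w * B, na.rm = TRUE) / sw
  se_meta <- 1 / sqrt(sw)
  q <- rowSums(w * (B - beta_meta)^2, na.rm = TRUE)
  ncoh <- rowSums(!is.na(B))
  p_het <- ifelse(ncoh > 1, pchisq(q, ncoh - 1, lower.tail = FALSE), 1)
  i2 <- ifelse(q > 0, pmax(0, (q - (ncoh - 1)) / q) * 100, 0)
  dir <- apply(B, 1, function(b)
    paste(ifelse(is.na(b), "?", ifelse(b >= 0, "+", "-")), collapse = ""))
  out <- data.frame(variant_id = ids, chr = ref$chr, pos = ref$pos,
                    effect_allele = ref$effect_allele,
                    other_allele = ref$other_allele,
                    eaf = rowSums(EAF * w, na.rm = TRUE) / sw,
                    beta_meta = beta_meta, se_meta = se_meta,
                    p_meta = 2 * pnorm(-abs(beta_meta / se_meta)),
                    q_stat = q, p_het = p_het, i2 = i2,
                    n_cohorts = ncoh, direction = dir,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_irreconcilable") <- dropped
  out[out$n_cohorts > 0, , drop = FALSE]
}

#' Genomic inflation factor
#'
#' Lambda is the median association chi-square (one degree of freedom,
#' recovered from the two-sided p-values) divided by the null median
#' 0.4549364.
#'
#' @param p vector of p-values (at least 100 for a stable median).
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  stop_if(length(p) < 100, "need >= 100 p-values for a stable median")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

# deterministic ordering: ascending p, then position, then id
.order_assoc <- function(p, pos, id) order(p, pos, id, method = "radix")

#' LD clumping and locus definition
#'
#' Greedy clumping of genome-wide significant meta-analysis records by
#' ascending p-value: variants with `r2 >= r2_independent` to a better
#' variant collapse onto it (independent significant set), independent
#' significant variants with `r2 >= r2_lead` to a better one collapse onto
#' that lead, and leads on the same chromosome within `merge_kb` kilobases
#' are merged into one locus keeping the smallest-p lead. Variants missing
#' from the LD matrix are treated as independent with a warning.
#'
#' @param meta meta-analysis table (needs variant_id, chr, pos, p_meta).
#' @param r2 squared-correlation LD matrix (dimnames = variant ids), computed
#'   on dosages.
#' @param p_threshold genome-wide significance threshold.
#' @param r2_independent,r2_lead,merge_kb clumping parameters.
#' @return data frame of loci: locus_id, chr, start, end, lead_variant,
#'   lead_p, n_independent, n_members, members (comma-separated ids),
#'   independent_significant (comma-separated lead + independent ids).
#' @export
clump_and_define_loci <- function(meta, r2, p_threshold = 5e-8,
                                  r2_independent = 0.6, r2_lead = 0.1,
                                  merge_kb = 500) {
  sig <- meta[!is.na(meta$p_meta) & meta$p_meta < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(data.frame())
  sig <- sig[.order_assoc(sig$p_meta, sig$pos, sig$variant_id), , drop = FALSE]
  have_ld <- sig$variant_id %in% rownames(r2)
  if (!all(have_ld))
    warning("no LD available for ", sum(!have_ld),
            " variant(s); treated as independent")
  ld_of <- function(a, b) {
    if (!a %in% rownames(r2) || !b %in% colnames(r2)) return(0)
    r2[a, b]
  }
  # pass 1: independent significant variants at r2 >= r2_independent
  indep <- character(0); member_of <- setNames(character(nrow(sig)), sig$variant_id)
  for (v in sig$variant_id) {
    hit <- indep[vapply(indep, function(u) ld_of(v, u) >= r2_independent, NA)]
    if (length(hit) == 0 && !v %in% indep) indep <- c(indep, v)
    member_of[v] <- if (length(hit) > 0) hit[1] else v
  }
  # pass 2: leads at r2 >= r2_lead among the independent significant set
  leads <- character(0); lead_of <- setNames(character(length(indep)), indep)
  for (v in indep) {
    hit <- leads[vapply(leads, function(u) ld_of(v, u) >= r2_lead, NA)]
    if (length(hit) == 0) leads <- c(leads, v)
    lead_of[v] <- if (length(hit) > 0) hit[1] else v
  }
  # pass 3: merge leads within merge_kb on the same chromosome
  li <- sig[match(leads, sig$variant_id), , drop = FALSE]
  li <- li[order(li$chr, li$pos), , drop = FALSE]
  locus_of_lead <- setNames(integer(nrow(li)), li$variant_id)
  locus <- 0L
  for (i in seq_len(nrow(li))) {
    if (i == 1 || li$chr[i] != li$chr[i - 1] ||
        li$pos[i] - li$pos[i - 1] > merge_kb * 1000) locus <- locus + 1L
    locus_of_lead[li$variant_id[i]] <- locus
  }
  # assign every significant variant to a locus through its clump chain
  sig$locus <- locus_of_lead[lead_of[member_of[sig$variant_id]]]
  out <- do.call(rbind, lapply(split(sig, sig$locus), function(d) {
    lead <- d$variant_id[.order_assoc(d$p_meta, d$pos, d$variant_id)[1]]
    ind <- intersect(indep, d$variant_id)
    data.frame(locus_id = d$locus[1], chr = d$chr[1],
               start = min(d$pos), end = max(d$pos),
               lead_variant = lead, lead_p = min(d$p_meta),
               n_independent = length(ind), n_members = nrow(d),
               members = paste(d$variant_id, collapse = ","),
               independent_significant = paste(ind, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$locus_id), , drop = FALSE]
}

#' Single-causal-variant 95% credible set
#'
#' Computes per-variant Wakefield log approximate Bayes factors
#' ([wakefield_labf()]) for the locus, converts them to posterior
#' probabilities under a flat prior over which single variant is causal, and
#' returns the smallest set of top-posterior variants whose cumulative
#' posterior reaches the coverage level.
#'
#' @param locus_records data frame with variant_id, beta (or beta_meta), se
#'   (or se_meta) for one locus.
#' @param prior_sd prior standard deviation of the causal log-odds ratio.
#' @param coverage credible-set coverage level.
#' @return list of class `credible_set`: `variants` (data frame ordered by
#'   posterior: variant_id, posterior, cumulative, in_set), `set` (ids in the
#'   credible set), `coverage`, `uninformative` flag.
#' @export
fine_map_credible_set <- function(locus_records, prior_sd = 0.2,
                                  coverage = 0.95) {
  beta <- locus_records$beta_meta %||% locus_records$beta
  se <- locus_records$se_meta %||% locus_records$se
  ok <- is.finite(beta) & is.finite(se) & se > 0
  stop_if(!any(ok), "no variant with finite beta/se in locus")
  d <- locus_records[ok, , drop = FALSE]
  labf <- wakefield_labf(beta[ok], se[ok], prior_sd)
  post <- exp(labf - logsumexp(labf))
  o <- order(-post, d$pos %||% seq_along(post), d$variant_id)
  post <- post[o]
  cum <- cumsum(post)
  size <- which(cum >= coverage)[1]
  uninformative <- length(unique(round(labf, 12))) == 1
  if (is.na(size) || uninformative) size <- length(post)
  vars <- data.frame(variant_id = d$variant_id[o], posterior = post,
                     cumulative = cum,
                     in_set = seq_along(post) <= size,
                     stringsAsFactors = FALSE)
  structure(list(variants = vars, set = vars$variant_id[vars$in_set],
                 coverage = coverage, uninformative = uninformative),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%d%% credible set: %d variant(s)%s\n",
              round(100 * x$coverage), length(x$set),
              if (x$uninformative) " [uninformative: flat ABFs]" else ""))
  print(utils::head(x$variants, 10), row.names = FALSE)
  invisible(x)
}
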