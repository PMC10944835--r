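# Synthetic-data generators: LD-structured genotypes, case-control cohorts,
# negative-binomial expression with cis-eQTL effects, and tissue panels.
# Every generator is a pure function of (parameters, seed).

#' LD specification for the genotype simulator
#'
#' Describes a panel of biallelic variants organized in blocks with
#' autoregressive latent-Gaussian haplotype correlation. Within a block,
#' adjacent variants have latent correlation `rho`; blocks are independent.
#'
#' @param n_variants number of variants.
#' @param maf_low,maf_high bounds for the per-variant minor allele frequency,
#'   drawn uniformly.
#' @param rho adjacent-variant latent haplotype correlation, in \[0, 1).
#' @param block_size number of variants per LD block.
#' @param positions 1-based base-pair coordinates, strictly increasing;
#'   default every 5 kb starting at 1e5.
#' @param chr chromosome label.
#' @param seed integer seed fixing the MAFs and allele labels.
#' @return an object of class `ld_spec`.
#' @export
ld_spec <- function(n_variants, maf_low = 0.05, maf_high = 0.5, rho = 0.8,
                    block_size = 10, positions = NULL, chr = "1", seed = 1) {
  stop_if(n_variants < 1, "n_variants must be >= 1")
  stop_if(maf_low > maf_high, "maf_low must be <= maf_high")
  stop_if(maf_low < 0 || maf_high > 1, "MAF bounds must lie in [0, 1]")
  stop_if(rho < 0 || rho >= 1, "rho must lie in [0, 1)")
  stop_if(block_size < 1, "block_size must be >= 1")
  if (is.null(positions)) positions <- 1e5 + 5e3 * (seq_len(n_variants) - 1)
  stop_if(length(positions) != n_variants, "positions length must equal n_variants")
  stop_if(any(diff(positions) <= 0), "positions must be strictly increasing")
  structure(list(n_variants = as.integer(n_variants), maf_low = maf_low,
                 maf_high = maf_high, rho = rho,
                 block_size = as.integer(block_size),
                 positions = as.numeric(positions), chr = as.character(chr),
                 seed = as.integer(seed)),
            class = "ld_spec")
}

# non-strand-ambiguous allele pairs used for simulated variants
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                        ncol = 2, byrow = TRUE)

#' Simulate LD-structured genotype dosages
#'
#' Haplotypes are drawn from a blockwise AR(1) latent-Gaussian threshold
#' model: each haplotype's latent vector follows an AR(1) process with
#' parameter `rho` within blocks (independent across blocks), and carries the
#' alternative allele where the latent value falls below the normal quantile
#' of the variant's allele frequency. Dosage is the sum of two independent
#' haplotypes, so values lie in \{0, 1, 2\}.
#'
#' @param spec an [ld_spec()].
#' @param n_samples number of diploid samples (>= 2).
#' @param seed optional seed overriding `spec$seed` for the haplotype draw.
#' @return list of class `sim_genotypes` with elements `dosage` (sample x
#'   variant matrix), `variants` (data frame: variant_id, chr, pos,
#'   effect_allele, other_allele, maf), `r2` (realized pairwise squared
#'   Pearson correlation of dosages), and `spec`.
#' @export
simulate_genotypes <- function(spec, n_samples, seed = NULL) {
  stopifnot(inherits(spec, "ld_spec"))
  stop_if(n_samples < 2, "n_samples must be >= 2")
  m <- spec$n_variants
  set.seed(spec$seed)
  maf <- runif(m, spec$maf_low, spec$maf_high)
  ap <- .allele_pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
  set.seed(seed %||% spec$seed)
  nh <- 2L * n_samples
  z <- matrix(rnorm(nh * m), nh, m)
  if (spec$rho > 0 && m > 1) {
    s <- sqrt(1 - spec$rho^2)
    new_block <- (seq_len(m) - 1) %% spec$block_size == 0
    for (j in 2:m) {
      if (!new_block[j]) z[, j] <- spec$rho * z[, j - 1] + s * z[, j]
    }
  }
  thr <- qnorm(maf)
  hap <- sweep(z, 2, thr, `<`) + 0
  dosage <- hap[seq_len(n_samples), , drop = FALSE] +
    hap[n_samples + seq_len(n_samples), , drop = FALSE]
  ids <- sprintf("snp_%s_%d", spec$chr, as.integer(spec$positions))
  dimnames(dosage) <- list(sprintf("sample_%04d", seq_len(n_samples)), ids)
  variants <- data.frame(variant_id = ids, chr = spec$chr,
                         pos = spec$positions,
                         effect_allele = ap[, 1], other_allele = ap[, 2],
                         maf = maf, stringsAsFactors = FALSE)
  r2 <- suppressWarnings(cor(dosage))^2
  r2[!is.finite(r2)] <- 0
  structure(list(dosage = dosage, variants = variants, r2 = r2, spec = spec),
            class = "sim_genotypes")
}

#' Ground-truth generating parameters for a simulation scenario
#'
#' Encodes the causal structure: direct variant effects on disease liability
#' (log-odds per effect-allele dose), cis-eQTL effects expressed as per-gene
#' proportions of expression variance explained, and per-gene effects of
#' expression on liability (the mediated path probed by MR).
#'
#' @param causal_variants data frame with columns `variant_id`, `beta`
#'   (log-OR per dose), or NULL.
#' @param eqtl_effects data frame with columns `gene_id`, `variant_id`,
#'   `pve` (per-variant proportion of expression variance), or NULL.
#' @param mediation data frame with columns `gene_id`, `theta` (effect of a
#'   1-SD change in expression on liability, log-odds scale), or NULL.
#' @param prevalence population disease probability in (0, 1).
#' @return object of class `sim_truth`.
#' @export
sim_truth <- function(causal_variants = NULL, eqtl_effects = NULL,
                      mediation = NULL, prevalence = 0.5) {
  stop_if(prevalence <= 0 || prevalence >= 1, "prevalence must lie in (0, 1)")
  if (!is.null(eqtl_effects)) {
    stop_if(any(eqtl_effects$pve < 0 | eqtl_effects$pve >= 1),
            "eQTL per-variant PVE must lie in [0, 1)")
    tot <- tapply(eqtl_effects$pve, eqtl_effects$gene_id, sum)
    stop_if(any(tot >= 1), "total cis PVE per gene must be < 1")
  }
  structure(list(causal_variants = causal_variants,
                 eqtl_effects = eqtl_effects, mediation = mediation,
                 prevalence = prevalence),
            class = "sim_truth")
}

.truth_check_ids <- function(truth, variant_ids) {
  ids <- c(truth$causal_variants$variant_id, truth$eqtl_effects$variant_id)
  missing <- setdiff(ids, variant_ids)
  stop_if(length(missing) > 0,
          "truth references variants absent from the genotype panel: ",
          paste(missing, collapse = ", "))
}

# latent genetic component of expression for mediated genes, given dosages;
# returns sample x gene matrix of genetic values plus realized per-dose betas
.expression_genetic <- function(dosage, truth) {
  eff <- truth$eqtl_effects
  genes <- unique(eff$gene_id)
  gmat <- matrix(0, nrow(dosage), length(genes),
                 dimnames = list(rownames(dosage), genes))
  beta <- numeric(nrow(eff))
  for (i in seq_len(nrow(eff))) {
    g <- dosage[, eff$variant_id[i]]
    v <- var(g)
    b <- if (v > 0) sqrt(eff$pve[i] / v) else 0
    beta[i] <- b
    gmat[, eff$gene_id[i]] <- gmat[, eff$gene_id[i]] + b * (g - mean(g))
  }
  list(genetic = gmat, beta = beta)
}

#' Simulate case-control cohorts under a liability model
#'
#' Liability is the sum of direct genetic effects, expression-mediated
#' effects, mild age and sex effects and latent noise. With the default
#' standard-logistic noise, thresholding the liability is exactly a logistic
#' regression model, so the per-dose effects in the truth object are
#' log-odds ratios on the scale the GWAS estimates. Case status is drawn so
#' that the expected case fraction matches `truth$prevalence` (emulating
#' ascertained case-control sampling when prevalence is 0.5).
#'
#' @param genotypes a `sim_genotypes` object (cohort 1 uses it directly; for
#'   `n_cohorts > 1` fresh genotype panels are drawn from its spec).
#' @param truth a [sim_truth()].
#' @param n_cohorts number of cohorts.
#' @param n_samples per-cohort sample sizes (recycled).
#' @param seed integer seed.
#' @param noise latent noise law: "logistic" (default) or "normal".
#' @param n_pcs number of genotype principal components returned as covariates.
#' @return list of cohorts; each has `dosage`, `variants`, `phenotype` (0/1),
#'   `covariates` (age, sex, PCs), and `truth`.
#' @export
simulate_case_control <- function(genotypes, truth, n_cohorts = 1,
                                  n_samples = 2000, seed = 1,
                                  noise = c("logistic", "normal"),
                                  n_pcs = 2) {
  stopifnot(inherits(genotypes, "sim_genotypes"), inherits(truth, "sim_truth"))
  noise <- match.arg(noise)
  .truth_check_ids(truth, genotypes$variants$variant_id)
  n_samples <- rep_len(n_samples, n_cohorts)
  cohorts <- vector("list", n_cohorts)
  for (k in seq_len(n_cohorts)) {
    geno <- if (k == 1 && n_samples[k] == nrow(genotypes$dosage)) genotypes
            else simulate_genotypes(genotypes$spec, n_samples[k],
                                    seed = child_seed(seed, 100 + k))
    set.seed(child_seed(seed, k))
    n <- nrow(geno$dosage)
    eta <- numeric(n)
    cv <- truth$causal_variants
    if (!is.null(cv) && nrow(cv) > 0) {
      eta <- eta + as.vector(geno$dosage[, cv$variant_id, drop = FALSE] %*% cv$beta)
    }
    if (!is.null(truth$mediation) && !is.null(truth$eqtl_effects)) {
      eg <- .expression_genetic(geno$dosage, truth)
      for (i in seq_len(nrow(truth$mediation))) {
        gid <- truth$mediation$gene_id[i]
        pve <- sum(truth$eqtl_effects$pve[truth$eqtl_effects$gene_id == gid])
        # expression = genetic value + environmental residual, total variance 1
        expr <- eg$genetic[, gid] + rnorm(n, 0, sqrt(max(1 - pve, 0)))
        eta <- eta + truth$mediation$theta[i] * expr
      }
    }
    age <- rnorm(n, 65, 10)
    sex <- rbinom(n, 1, 0.5)
    eta <- eta + 0.01 * (age - 65) + 0.1 * sex
    # intercept chosen so the expected case fraction equals the prevalence
    if (noise == "logistic") {
      f <- function(a) mean(plogis(a + eta)) - truth$prevalence
      a0 <- uniroot(f, c(-30, 30))$root
      y <- rbinom(n, 1, plogis(a0 + eta))
    } else {
      thr <- quantile(eta, 1 - truth$prevalence) # empirical threshold
      y <- as.integer(eta + rnorm(n) > thr)
    }
    pcs <- NULL
    if (n_pcs > 0) {
      x <- scale(geno$dosage, center = TRUE, scale = FALSE)
      sv <- svd(x, nu = n_pcs, nv = 0)
      pcs <- sv$u[, seq_len(n_pcs), drop = FALSE]
      colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    }
    covariates <- cbind(age = age, sex = sex, pcs)
    rownames(covariates) <- rownames(geno$dosage)
    cohorts[[k]] <- structure(list(dosage = geno$dosage,
                                   variants = geno$variants,
                                   phenotype = y, covariates = covariates,
                                   truth = truth),
                              class = "sim_cohort")
  }
  cohorts
}

#' Gene annotation table for simulated genes
#'
#' @param gene_id gene identifiers.
#' @param chr chromosome labels (recycled).
#' @param tss transcription start sites (1-based).
#' @param strand "+" or "-" (recycled).
#' @param length transcript length in bp used for TPM (recycled).
#' @return data frame with columns gene_id, chr, start, end, strand, tss,
#'   length. Gene bodies span `tss` to `tss + length - 1` on the + strand and
#'   `tss - length + 1` to `tss` on the - strand.
#' @export
gene_annotation <- function(gene_id, chr = "1", tss, strand = "+",
                            length = 2000) {
  n <- length(gene_id)
  chr <- rep_len(chr, n); strand <- rep_len(strand, n)
  len <- rep_len(length, n)
  start <- ifelse(strand == "+", tss, tss - len + 1)
  end <- ifelse(strand == "+", tss + len - 1, tss)
  data.frame(gene_id = gene_id, chr = chr, start = start, end = end,
             strand = strand, tss = tss, length = len,
             stringsAsFactors = FALSE)
}

#' Simulate RNA-seq counts with cis-eQTL effects
#'
#' Latent log-expression per gene is the (standardized) genetic value from
#' the truth's cis-eQTL effects plus environmental noise with total latent
#' variance 1; counts are drawn negative-binomial around
#' `baseline * size_factor * exp(latent)` with a common gene-level
#' dispersion.
#'
#' @param genotypes `sim_genotypes` for the expression cohort samples.
#' @param truth [sim_truth()]; genes with no eQTL entry get pure-noise
#'   latent expression.
#' @param gene_annot [gene_annotation()] for all simulated genes.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be >= 0, 0 means Poisson.
#' @param library_size_range range of per-sample library-size factors drawn
#'   uniformly, expressed relative to the mean baseline.
#' @param baseline_log_mean,baseline_log_sd log-normal baseline mean counts.
#' @param seed integer seed.
#' @return object of class `sim_expression`: `counts` (gene x sample),
#'   `lengths`, `library_sizes`, `dispersion`, `dosage`, `gene_annot`,
#'   `latent` (gene x sample latent log-expression), `truth` (with realized
#'   per-dose betas attached as `realized_beta`).
#' @export
simulate_expression <- function(genotypes, truth, gene_annot,
                                nb_dispersion = 0.1,
                                library_size_range = c(0.8, 1.2),
                                baseline_log_mean = log(500),
                                baseline_log_sd = 1, seed = 1) {
  stopifnot(inherits(genotypes, "sim_genotypes"), inherits(truth, "sim_truth"))
  stop_if(nb_dispersion < 0, "nb_dispersion must be >= 0")
  .truth_check_ids(truth, genotypes$variants$variant_id)
  # every eQTL variant must lie within the cis window of its gene
  if (!is.null(truth$eqtl_effects)) {
    eff <- truth$eqtl_effects
    pos <- genotypes$variants$pos[match(eff$variant_id,
                                        genotypes$variants$variant_id)]
    tss <- gene_annot$tss[match(eff$gene_id, gene_annot$gene_id)]
    stop_if(any(abs(pos - tss) > 1e6),
            "eQTL variants must lie within 1 Mb of their gene's TSS")
  }
  set.seed(seed)
  n <- nrow(genotypes$dosage)
  genes <- gene_annot$gene_id
  latent <- matrix(rnorm(length(genes) * n), length(genes), n,
                   dimnames = list(genes, rownames(genotypes$dosage)))
  realized <- NULL
  if (!is.null(truth$eqtl_effects)) {
    eg <- .expression_genetic(genotypes$dosage, truth)
    realized <- cbind(truth$eqtl_effects, realized_beta = eg$beta)
    for (g in colnames(eg$genetic)) {
      pve <- sum(truth$eqtl_effects$pve[truth$eqtl_effects$gene_id == g])
      latent[g, ] <- eg$genetic[, g] + rnorm(n, 0, sqrt(max(1 - pve, 0)))
    }
  }
  base <- exp(rnorm(length(genes), baseline_log_mean, baseline_log_sd))
  libf <- runif(n, library_size_range[1], library_size_range[2])
  mu <- (base %o% libf) * exp(latent)
  counts <- matrix(0L, length(genes), n, dimnames = dimnames(latent))
  if (nb_dispersion > 0) {
    counts[] <- rnbinom(length(mu), size = 1 / nb_dispersion, mu = mu)
  } else {
    counts[] <- rpois(length(mu), mu)
  }
  truth$realized_beta <- realized
  structure(list(counts = counts, lengths = setNames(gene_annot$length, genes),
                 library_sizes = colSums(counts), dispersion = nb_dispersion,
                 dosage = genotypes$dosage, gene_annot = gene_annot,
                 latent = latent, truth = truth),
            class = "sim_expression")
}

#' Simulate a multi-tissue median-expression panel
#'
#' Produces a tissue x gene table of median log2 TPM. Genes named in
#' `specificity_pattern` receive the stated share of their summed median
#' expression in the designated tissue; all other genes are expressed
#' uniformly across tissues.
#'
#' @param n_tissues number of tissues (>= 2); tissue 1 is named
#'   "aortic_valve", the rest "tissue_02"...
#' @param gene_id gene identifiers.
#' @param specificity_pattern optional data frame with columns `gene_id`,
#'   `tissue`, `share` (target expression specificity score in (0, 1)).
#' @param base median log2 TPM given to non-designated tissue/gene cells.
#' @param noise_sd optional Gaussian jitter (default 0, exact shares).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return matrix (tissue x gene) of median log2 TPM.
#' @export
simulate_tissue_panel <- function(n_tissues = 44, gene_id,
                                  specificity_pattern = NULL, base = 2,
                                  noise_sd = 0, seed = 1) {
  stop_if(n_tissues < 2, "n_tissues must be >= 2")
  tissues <- c("aortic_valve", sprintf("tissue_%02d", seq_len(n_tissues - 1) + 1))
  med <- matrix(base, n_tissues, length(gene_id),
                dimnames = list(tissues, gene_id))
  if (!is.null(specificity_pattern)) {
    for (i in seq_len(nrow(specificity_pattern))) {
      g <- specificity_pattern$gene_id[i]
      tis <- specificity_pattern$tissue[i]
      s <- specificity_pattern$share[i]
      stop_if(s <= 0 || s >= 1, "share must lie in (0, 1)")
      stop_if(!tis %in% tissues, "unknown tissue: ", tis)
      # value v with all others at `base` such that v / (v + (T-1) base) = s
      med[tis, g] <- s * (n_tissues - 1) * base / (1 - s)
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    med <- pmax(med + rnorm(length(med), 0, noise_sd), 0)
  }
  med
}
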