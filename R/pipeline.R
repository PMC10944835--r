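# Configuration and orchestration of the full synthetic-to-prioritization
# run: simulation, GWAS meta-analysis, loci, fine-mapping, expression
# processing, cis-eQTL, TWAS, colocalization, MR and the evidence ledger.

#' Pipeline configuration with documented defaults
#'
#' Returns the default configuration as a named list; any supplied argument
#' overrides a default, unknown names are rejected. Analysis thresholds
#' default to the conventional values used throughout the package
#' (genome-wide significance 5e-8; clumping r2 0.6 / 0.1 with 500 kb locus
#' merging; expression filter TPM > 0.1 and >= 6 reads in >= 20% of
#' samples; cis window +/- 1 Mb; eQTL MAF >= 0.01; FDR 5%; PP4 > 0.75; MR
#' instrument p < 1e-4, r2 < 0.1, >= 3 instruments, F > 15, heterogeneity
#' exclusion p < 0.01; ESS > 0.1; >= 4 evidence features). Scenario
#' parameters define the simulated study: an expression-mediated causal
#' gene (total cis PVE 0.3 over `n_causal_cis` variants, expression-on-
#' liability effect `theta` 0.3), an eQTL cohort of 400, and 20,000
#' case-control GWAS samples split over 2 cohorts.
#'
#' @param ... overrides for any configuration entry.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    # simulation scenario
    n_gwas = 20000, n_cohorts = 2, n_eqtl = 400, prevalence = 0.5,
    cis_pve = 0.3, n_causal_cis = 4, theta = 0.3, nb_dispersion = 0.1,
    n_background_genes = 100, n_tissues = 44, valve_share = 0.2,
    n_variants = 40, block_size = 5, rho = 0.8,
    # analysis thresholds
    p_threshold = 5e-8, r2_independent = 0.6, r2_lead = 0.1, merge_kb = 500,
    finemap_prior_sd = 0.2, finemap_coverage = 0.95,
    min_tpm = 0.1, min_reads = 6, min_frac = 0.2,
    cis_window = 1e6, maf_min = 0.01, n_expr_covariates = 5,
    n_permutations = 200, fdr = 0.05,
    twas_folds = 5, twas_inner_folds = 5, twas_alpha = 0.5,
    coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5, pp4_threshold = 0.75,
    mr_p_exposure = 1e-4, mr_clump_r2 = 0.1, mr_min_instruments = 3,
    mr_f_min = 15, mr_q_alpha = 0.01,
    ess_threshold = 0.1, gene_window = 1e4, min_features = 4)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  stop_if(length(unknown) > 0, "unknown configuration key(s): ",
          paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; absent keys take their defaults.
#'
#' @param path YAML file with configuration entries.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Simulate the expression-mediated disease scenario
#'
#' Builds the study design the pipeline defaults to: one focal region whose
#' causal gene carries `n_causal_cis` cis-eQTL variants in separate LD
#' blocks (equal per-variant PVE summing to `cis_pve`), with gene
#' expression affecting disease liability by `theta` per expression SD; two
#' flanking genes in the cis window with pure-noise expression; background
#' genes on another chromosome providing the expression percentile
#' distribution; a tissue panel in which the causal gene is valve-specific.
#'
#' @param config a [pipeline_config()].
#' @param seed overrides `config$seed`.
#' @return list: `spec`, `truth`, `gene_annot`, `cohorts` (GWAS),
#'   `expression` (eQTL cohort `sim_expression`), `tissue_panel`,
#'   `focal_genes` (causal + flanks), `causal_gene`.
#' @export
mediation_scenario <- function(config = pipeline_config(), seed = NULL) {
  seed <- seed %||% config$seed
  m <- config$n_variants
  spec <- ld_spec(m, rho = config$rho, block_size = config$block_size,
                  seed = child_seed(seed, 1))
  # one causal variant in the middle of every other LD block
  nblock <- ceiling(m / config$block_size)
  blocks <- unique(round(seq(1, nblock, length.out = config$n_causal_cis)))
  causal_idx <- pmin((blocks - 1) * config$block_size +
                       ceiling(config$block_size / 2), m)
  panel <- simulate_genotypes(spec, 2, seed = child_seed(seed, 2))
  causal_ids <- panel$variants$variant_id[causal_idx]
  pos <- spec$positions
  gene_annot <- rbind(
    gene_annotation("g_causal", chr = spec$chr,
                    tss = pos[min(causal_idx)] - 1000,
                    length = pos[max(causal_idx)] - pos[min(causal_idx)] + 2000),
    gene_annotation("g_left", chr = spec$chr, tss = max(pos[1] - 2e5, 1),
                    length = 20000, strand = "-"),
    gene_annotation("g_right", chr = spec$chr, tss = pos[m] + 2e5,
                    length = 20000),
    gene_annotation(sprintf("bg_%02d", seq_len(config$n_background_genes)),
                    chr = "background",
                    tss = 1e5 + 5e4 * seq_len(config$n_background_genes),
                    length = 2000))
  truth <- sim_truth(
    eqtl_effects = data.frame(gene_id = "g_causal", variant_id = causal_ids,
                              pve = config$cis_pve / config$n_causal_cis,
                              stringsAsFactors = FALSE),
    mediation = data.frame(gene_id = "g_causal", theta = config$theta,
                           stringsAsFactors = FALSE),
    prevalence = config$prevalence)
  geno_panel <- simulate_genotypes(spec, max(config$n_eqtl, 2000),
                                   seed = child_seed(seed, 3))
  cohorts <- simulate_case_control(
    geno_panel, truth, n_cohorts = config$n_cohorts,
    n_samples = rep(ceiling(config$n_gwas / config$n_cohorts),
                    config$n_cohorts),
    seed = child_seed(seed, 4))
  geno_eqtl <- simulate_genotypes(spec, config$n_eqtl,
                                  seed = child_seed(seed, 5))
  expression <- simulate_expression(geno_eqtl, truth, gene_annot,
                                    nb_dispersion = config$nb_dispersion,
                                    seed = child_seed(seed, 6))
  panel_med <- simulate_tissue_panel(
    config$n_tissues, gene_annot$gene_id,
    specificity_pattern = data.frame(gene_id = "g_causal",
                                     tissue = "aortic_valve",
                                     share = config$valve_share,
                                     stringsAsFactors = FALSE))
  list(spec = spec, truth = truth, gene_annot = gene_annot,
       cohorts = cohorts, expression = expression, tissue_panel = panel_med,
       focal_genes = c("g_causal", "g_left", "g_right"),
       causal_gene = "g_causal")
}

#' One lean MR replicate of the mediation scenario
#'
#' Runs only the stages needed to estimate the expression-on-disease effect
#' in a fresh draw of the mediation scenario: the eQTL cohort is simulated
#' and processed (TPM, filters, TMM, inverse-normal transform, expression
#' covariates, nominal cis pass for the causal gene), a single GWAS cohort
#' of `config$n_gwas` samples is analyzed and meta-formatted, instruments
#' are selected and the MR estimators computed. Used for replicate-based
#' coverage evaluation.
#'
#' @param config a [pipeline_config()].
#' @param seed integer seed for this replicate.
#' @param model IVW error model passed to [mr_estimates()].
#' @return list: `n_instruments`, `est` ([mr_estimates()] result or NULL
#'   when fewer than `config$mr_min_instruments` instruments survive).
#' @export
run_mediation_mr <- function(config = pipeline_config(), seed = 1,
                             model = "fixed") {
  cfg <- config; cfg$n_cohorts <- 1
  sc <- mediation_scenario(cfg, seed = seed)
  ex <- sc$expression
  tpm <- compute_tpm(ex$counts, ex$lengths)
  kept <- filter_expressed(ex$counts, tpm, cfg$min_tpm, cfg$min_reads,
                           cfg$min_frac)
  tmm <- tmm_normalize(ex$counts[kept, , drop = FALSE])
  einv <- inverse_normal_matrix(tmm$log_cpm)
  ecov <- expression_covariates(einv, min(cfg$n_expr_covariates,
                                          nrow(einv) - 1))
  nom <- map_cis_nominal(ex$dosage, sc$cohorts[[1]]$variants,
                         einv[sc$causal_gene, , drop = FALSE], ecov,
                         sc$gene_annot, window = cfg$cis_window,
                         maf_min = cfg$maf_min)
  gw <- run_cohort_gwas_sim(sc$cohorts[[1]])
  meta <- meta_analyze(list(qc_filter(gw)$kept))
  mi <- match(nom$variant_id, meta$variant_id)
  expo <- data.frame(variant_id = nom$variant_id, beta = nom$slope,
                     se = nom$se, p = nom$p, stringsAsFactors = FALSE)
  outc <- data.frame(variant_id = nom$variant_id, beta = meta$beta_meta[mi],
                     se = meta$se_meta[mi], stringsAsFactors = FALSE)
  ld2 <- suppressWarnings(cor(ex$dosage))^2; ld2[!is.finite(ld2)] <- 0
  inst <- select_instruments(expo, outc, ld2, cfg$mr_p_exposure,
                             cfg$mr_clump_r2, cfg$mr_min_instruments,
                             cfg$mr_f_min)
  est <- if (nrow(inst) >= cfg$mr_min_instruments)
    mr_estimates(inst, seed = child_seed(seed, 50), model = model) else NULL
  list(n_instruments = nrow(inst), instruments = inst, est = est)
}

#' Run the full synthetic-to-prioritization pipeline
#'
#' Executes every stage in dependency order on a simulated scenario:
#' per-cohort GWAS, QC, meta-analysis, genomic inflation, clumping and
#' locus definition, credible sets, expression processing (TPM, filters,
#' TMM, inverse-normal transform, expression covariates), specificity
#' scores and high-expression flags, cis-eQTL nominal and permutation
#' passes with per-gene FDR thresholds, TWAS, colocalization, MR with the
#' gene-level screen, the LD-aware gene test, and the ten-feature evidence
#' matrix. When `outdir` is given, stage tables are written as TSV along
#' with a YAML run manifest; otherwise everything is returned in memory.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param seed overrides `config$seed`.
#' @param scenario optional pre-built [mediation_scenario()] result.
#' @return list of class `pipeline_result` with one element per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         seed = NULL, scenario = NULL) {
  seed <- seed %||% config$seed
  sc <- scenario %||% mediation_scenario(config, seed = seed)

  ## GWAS per cohort, QC, meta
  gwas_tabs <- lapply(sc$cohorts, run_cohort_gwas_sim)
  qc <- lapply(gwas_tabs, qc_filter)
  meta <- meta_analyze(lapply(qc, `[[`, "kept"))
  lambda <- if (sum(!is.na(meta$p_meta)) >= 100)
    genomic_inflation(meta$p_meta) else NA_real_

  ## LD reference from the expression cohort dosages
  dosage <- sc$expression$dosage
  ld_r <- suppressWarnings(cor(dosage)); ld_r[!is.finite(ld_r)] <- 0
  ld_r2 <- ld_r^2

  ## loci and credible sets
  loci <- clump_and_define_loci(meta, ld_r2, config$p_threshold,
                                config$r2_independent, config$r2_lead,
                                config$merge_kb)
  credible <- list()
  if (nrow(loci) > 0) {
    for (i in seq_len(nrow(loci))) {
      members <- strsplit(loci$members[i], ",")[[1]]
      credible[[as.character(loci$locus_id[i])]] <-
        fine_map_credible_set(meta[meta$variant_id %in% members, ,
                                   drop = FALSE],
                              prior_sd = config$finemap_prior_sd,
                              coverage = config$finemap_coverage)
    }
  }

  ## expression processing
  counts <- sc$expression$counts
  tpm <- compute_tpm(counts, sc$expression$lengths)
  kept_genes <- filter_expressed(counts, tpm, config$min_tpm,
                                 config$min_reads, config$min_frac)
  tmm <- tmm_normalize(counts[kept_genes, , drop = FALSE])
  expr_inv <- inverse_normal_matrix(tmm$log_cpm)
  k_cov <- min(config$n_expr_covariates, nrow(expr_inv) - 1,
               ncol(expr_inv) - 1)
  # expression components only: the simulated population is unstratified and
  # ancestry PCs computed from a focal cis panel (rather than genome-wide
  # variants) would absorb cis-genetic signal
  covariates <- expression_covariates(expr_inv, k_cov)

  ## tissue specificity and high expression
  ess <- specificity_scores(sc$tissue_panel, threshold = config$ess_threshold)
  high_expr <- flag_high_expression(sc$tissue_panel["aortic_valve", ])

  ## cis-eQTL: nominal + permutation + thresholds
  vinfo <- sc$cohorts[[1]]$variants
  nominal <- map_cis_nominal(dosage, vinfo, expr_inv, covariates,
                             sc$gene_annot, window = config$cis_window,
                             maf_min = config$maf_min)
  cis_genes <- unique(nominal$gene_id)
  perms <- list()
  for (g in cis_genes) {
    vids <- nominal$variant_id[nominal$gene_id == g]
    perms[[g]] <- permutation_pass(dosage[, vids, drop = FALSE],
                                   expr_inv[g, ], covariates,
                                   B = config$n_permutations,
                                   seed = child_seed(seed, 20))
  }
  perm_tab <- eqtl_fdr_thresholds(perms, config$fdr)
  sig_pairs <- do.call(rbind, lapply(cis_genes, function(g) {
    thr <- perm_tab$threshold[perm_tab$gene_id == g]
    d <- nominal[nominal$gene_id == g, , drop = FALSE]
    if (!is.finite(thr)) return(d[0, , drop = FALSE])
    d[d$p < thr, , drop = FALSE]
  }))

  ## TWAS
  twas_models <- list(); twas_rows <- list()
  zmeta <- setNames(meta$beta_meta / meta$se_meta, meta$variant_id)
  for (g in cis_genes) {
    vids <- nominal$variant_id[nominal$gene_id == g]
    if (length(vids) < 2) next
    mdl <- train_expression_model(dosage[, vids, drop = FALSE], expr_inv[g, ],
                                  n_folds = config$twas_folds,
                                  n_inner = config$twas_inner_folds,
                                  alpha = config$twas_alpha,
                                  seed = child_seed(seed, 30))
    twas_models[[g]] <- mdl
    if (!mdl$qualified) next
    a <- spredixcan(mdl, zmeta, ld_r)
    if (!is.null(a)) twas_rows[[g]] <- cbind(gene_id = g, a)
  }
  twas <- if (length(twas_rows) > 0)
    twas_fdr(do.call(rbind, twas_rows), config$fdr) else
    data.frame(gene_id = character(0), zscore = numeric(0), p = numeric(0),
               significant = logical(0))

  ## colocalization per cis gene
  coloc_rows <- list()
  for (g in cis_genes) {
    d <- nominal[nominal$gene_id == g, , drop = FALSE]
    mi <- match(d$variant_id, meta$variant_id)
    ok <- !is.na(mi)
    if (sum(ok) == 0) next
    t_gwas <- abf_track(d$variant_id[ok], meta$beta_meta[mi[ok]],
                        meta$se_meta[mi[ok]], type = "cc")
    t_eqtl <- abf_track(d$variant_id[ok], d$slope[ok], d$se[ok],
                        type = "quant")
    cr <- coloc_abf(t_gwas, t_eqtl, config$coloc_p1, config$coloc_p2,
                    config$coloc_p12)
    coloc_rows[[g]] <- data.frame(gene_id = g, pp0 = cr$pp["PP0"],
                                  pp1 = cr$pp["PP1"], pp2 = cr$pp["PP2"],
                                  pp3 = cr$pp["PP3"], pp4 = cr$pp["PP4"],
                                  colocalized = cr$colocalized,
                                  row.names = NULL)
  }
  coloc <- if (length(coloc_rows) > 0) do.call(rbind, coloc_rows) else
    data.frame(gene_id = character(0), pp4 = numeric(0))

  ## Mendelian randomization per cis gene
  mr_rows <- list()
  for (g in cis_genes) {
    d <- nominal[nominal$gene_id == g, , drop = FALSE]
    expo <- data.frame(variant_id = d$variant_id, beta = d$slope, se = d$se,
                       p = d$p, stringsAsFactors = FALSE)
    outc <- data.frame(variant_id = meta$variant_id, beta = meta$beta_meta,
                       se = meta$se_meta, stringsAsFactors = FALSE)
    outc <- outc[match(expo$variant_id, outc$variant_id), , drop = FALSE]
    inst <- select_instruments(expo, outc, ld_r2, config$mr_p_exposure,
                               config$mr_clump_r2, config$mr_min_instruments,
                               config$mr_f_min)
    if (nrow(inst) == 0) next
    est <- mr_estimates(inst, seed = child_seed(seed, 40))
    mr_rows[[g]] <- data.frame(gene_id = g, n_instruments = est$n_instruments,
                               ivw = est$ivw, ivw_se = est$ivw_se,
                               ivw_p = est$ivw_p, wm = est$wm,
                               wm_p = est$wm_p,
                               egger_intercept_p = est$egger_intercept_p,
                               q_p = est$q_p, stringsAsFactors = FALSE)
  }
  mr <- if (length(mr_rows) > 0) do.call(rbind, mr_rows) else NULL
  mr_screen <- if (!is.null(mr)) gene_screen(mr, config$mr_q_alpha,
                                             config$fdr) else NULL

  ## gene-level association test around each gene
  gt_rows <- list()
  for (g in sc$gene_annot$gene_id) {
    ga <- sc$gene_annot[sc$gene_annot$gene_id == g, ]
    win <- meta$chr == ga$chr & meta$pos >= ga$start - config$gene_window &
      meta$pos <= ga$end + config$gene_window
    if (!any(win, na.rm = TRUE)) next
    vids <- meta$variant_id[which(win)]
    gt <- gene_level_test(zmeta[vids], ld_r[vids, vids, drop = FALSE])
    gt_rows[[g]] <- data.frame(gene_id = g, p = gt$p, n_snps = gt$n_snps,
                               stringsAsFactors = FALSE)
  }
  gene_test <- NULL
  if (length(gt_rows) > 0) {
    gene_test <- do.call(rbind, gt_rows)
    gene_test$significant <- p.adjust(gene_test$p, "BH") <= config$fdr
  }

  ## evidence ledger
  positional <- if (nrow(loci) > 0)
    map_positional_genes(loci, meta, sc$gene_annot, config$gene_window) else
    NULL
  lead_ids <- if (nrow(loci) > 0) loci$lead_variant else character(0)
  valve_eqtl_genes <- unique(sig_pairs$gene_id[sig_pairs$variant_id %in%
                                                 lead_ids])
  evidence <- build_evidence_matrix(
    genes = sc$gene_annot$gene_id, positional = positional,
    gene_test = gene_test,
    high_expression = high_expr, valve_specific = ess$valve_specific,
    valve_eqtl = valve_eqtl_genes, twas = twas, coloc = coloc, mr = mr,
    min_features = config$min_features)

  res <- structure(list(config = config, seed = seed, scenario = sc,
                        gwas = gwas_tabs, qc = qc, meta = meta,
                        lambda = lambda, loci = loci, credible = credible,
                        tpm = tpm, kept_genes = kept_genes, tmm = tmm,
                        expr_inv = expr_inv, covariates = covariates,
                        ess = ess, high_expr = high_expr, nominal = nominal,
                        permutations = perm_tab, sig_pairs = sig_pairs,
                        twas_models = twas_models, twas = twas,
                        coloc = coloc, mr = mr, mr_screen = mr_screen,
                        gene_test = gene_test, evidence = evidence),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' Write pipeline stage tables and a run manifest
#'
#' @param res a `pipeline_result`.
#' @param outdir output directory (created if absent).
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv(res$meta, p("meta.tsv"))
  if (nrow(res$loci) > 0) write_tsv(res$loci, p("loci.tsv"))
  if (length(res$credible) > 0) {
    cs <- do.call(rbind, lapply(names(res$credible), function(l)
      cbind(locus_id = l, res$credible[[l]]$variants)))
    write_tsv(cs, p("credible_sets.tsv"))
  }
  write_tsv(res$nominal, p("eqtl_nominal.tsv"))
  write_tsv(res$permutations, p("eqtl_permutations.tsv"))
  if (nrow(res$sig_pairs) > 0) write_tsv(res$sig_pairs, p("eqtl_significant.tsv"))
  if (nrow(res$twas) > 0) write_tsv(res$twas, p("twas.tsv"))
  if (nrow(res$coloc) > 0) write_tsv(res$coloc, p("coloc.tsv"))
  if (!is.null(res$mr)) write_tsv(res$mr, p("mr.tsv"))
  write_tsv(res$evidence, p("evidence_matrix.tsv"))
  manifest <- list(
    package = "valvomics",
    version = as.character(utils::packageVersion("valvomics")),
    seed = res$seed, lambda = res$lambda,
    n_loci = nrow(res$loci),
    n_twas_significant = sum(res$twas$significant),
    config = unclass(res$config),
    tables = list(
      meta = unname(tools::md5sum(p("meta.tsv"))),
      evidence = unname(tools::md5sum(p("evidence_matrix.tsv")))))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  meta-analysis variants: ", nrow(x$meta),
      "; lambda = ", round(x$lambda, 3), "\n", sep = "")
  cat("  genome-wide loci: ", nrow(x$loci), "\n", sep = "")
  cat("  genes with cis eQTL tested: ", nrow(x$permutations), "\n", sep = "")
  cat("  TWAS significant: ", sum(x$twas$significant), "\n", sep = "")
  cat("  prioritized genes (>= ", x$config$min_features, " features): ",
      paste(x$evidence$gene_id[x$evidence$prioritized], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
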