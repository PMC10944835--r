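# Gene prioritization: LD-aware gene-level association test, positional
# gene mapping, the ten-feature evidence ledger, and hypergeometric pathway
# enrichment.

#' LD-aware gene-level association test
#'
#' Summarizes the SNP z-scores in a gene's window (TSS +/- 10 kb by
#' convention) as the mean squared z. Under the null the statistic is a
#' weighted mean of correlated one-degree chi-squares whose weights are the
#' eigenvalues of the SNP correlation (LD) matrix; the p-value comes from
#' Satterthwaite moment matching to a scaled chi-square. With a single SNP
#' the test reduces exactly to that SNP's p-value, and under perfect LD it
#' behaves as a single SNP regardless of how many are included.
#'
#' @param z SNP z-scores in the gene window.
#' @param ld SNP correlation matrix (signed r, not r2); eigenvalues are
#'   clipped at 1e-8 for stability.
#' @return list: `stat` (mean chi-square), `p`, `n_snps`, effective scale
#'   `a` and degrees of freedom `nu`.
#' @export
gene_level_test <- function(z, ld = NULL) {
  k <- length(z)
  stop_if(k < 1, "need >= 1 SNP in the window")
  if (is.null(ld)) ld <- diag(k)
  stat <- mean(z^2)
  lam <- pmax(eigen(ld, symmetric = TRUE, only.values = TRUE)$values, 1e-8)
  mu <- sum(lam) / k
  v <- 2 * sum(lam^2) / k^2
  a <- v / (2 * mu)
  nu <- 2 * mu^2 / v
  list(stat = stat, p = pchisq(stat / a, nu, lower.tail = FALSE),
       n_snps = k, a = a, nu = nu)
}

# distance of a point to a gene body; 0 when inside
.gene_dist <- function(pos, start, end) pmax(start - pos, pos - end, 0)

#' Map positional candidate genes around GWAS loci
#'
#' For each locus: protein-coding genes within `window` bp of any
#' genome-wide significant member SNP; the nearest gene to the lead variant;
#' and, when the lead is intergenic (inside no gene body), the closest gene
#' on each side as flanking candidates. The lead is called intronic for a
#' gene when it falls inside the gene body (and outside any supplied exon
#' intervals).
#'
#' @param loci locus table from [clump_and_define_loci()].
#' @param meta meta table giving member positions (variant_id, chr, pos).
#' @param gene_annot [gene_annotation()] table.
#' @param window positional window in bp.
#' @param exons optional data frame (gene_id, start, end) of exon intervals;
#'   absent exons mean whole-body containment counts as intronic.
#' @return data frame: gene_id, locus_id, nearest_gene, intronic_lead,
#'   within_window, flank — one row per (gene, locus) candidate pairing.
#' @export
map_positional_genes <- function(loci, meta, gene_annot, window = 1e4,
                                 exons = NULL) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    lead_id <- loci$lead_variant[i]
    members <- strsplit(loci$members[i], ",")[[1]]
    mpos <- meta$pos[match(members, meta$variant_id)]
    lead_pos <- meta$pos[match(lead_id, meta$variant_id)]
    ga <- gene_annot[gene_annot$chr == loci$chr[i], , drop = FALSE]
    if (nrow(ga) == 0) next
    within <- vapply(seq_len(nrow(ga)), function(j)
      any(.gene_dist(mpos, ga$start[j], ga$end[j]) <= window), NA)
    dlead <- .gene_dist(lead_pos, ga$start, ga$end)
    nearest <- rep(FALSE, nrow(ga))
    nearest[which.min(dlead)] <- TRUE
    inside <- dlead == 0
    intronic <- inside
    if (!is.null(exons)) {
      for (j in which(inside)) {
        ex <- exons[exons$gene_id == ga$gene_id[j], , drop = FALSE]
        if (nrow(ex) > 0 && any(lead_pos >= ex$start & lead_pos <= ex$end))
          intronic[j] <- FALSE
      }
    }
    flank <- rep(FALSE, nrow(ga))
    if (!any(inside)) { # intergenic lead: nearest gene on each side
      left <- which(ga$end < lead_pos); right <- which(ga$start > lead_pos)
      if (length(left) > 0) flank[left[which.max(ga$end[left])]] <- TRUE
      if (length(right) > 0) flank[right[which.min(ga$start[right])]] <- TRUE
    }
    sel <- within | nearest | flank
    if (!any(sel)) next
    rows[[length(rows) + 1]] <-
      data.frame(gene_id = ga$gene_id[sel], locus_id = loci$locus_id[i],
                 nearest_gene = nearest[sel], intronic_lead = intronic[sel],
                 within_window = within[sel], flank = flank[sel],
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(data.frame(gene_id = character(0)))
  do.call(rbind, rows)
}

#' Genes with a missense or nonsense proxy for a lead SNP
#'
#' A gene satisfies the coding-proxy criterion when some missense or
#' nonsense variant annotated to it is in LD `r2 >= r2_min` with a lead
#' GWAS SNP.
#'
#' @param lead_variants lead SNP ids.
#' @param coding data frame (variant_id, gene_id) of missense/nonsense
#'   variants.
#' @param r2 squared-correlation LD matrix covering both sets.
#' @param r2_min LD threshold (inclusive).
#' @return character vector of gene ids.
#' @export
missense_ld_genes <- function(lead_variants, coding, r2, r2_min = 0.8) {
  hit <- vapply(seq_len(nrow(coding)), function(i) {
    v <- coding$variant_id[i]
    if (!v %in% rownames(r2)) return(FALSE)
    any(vapply(intersect(lead_variants, colnames(r2)),
               function(u) r2[v, u] >= r2_min, NA))
  }, NA)
  unique(coding$gene_id[hit])
}

#' Assemble the ten-feature gene evidence ledger
#'
#' Combines the upstream module outputs into one boolean feature per
#' criterion per gene: (1) nearest gene to a lead SNP, (2) lead SNP
#' intronic for the gene, (3) lead SNP in LD (r2 >= 0.8) with a missense or
#' nonsense variant of the gene, (4) significant gene-level association
#' test, (5) high expression in the valve (90th-percentile flag),
#' (6) valve-specific expression (ESS > 0.1), (7) lead SNP is a significant
#' valve eQTL for the gene, (8) significant TWAS association, (9)
#' colocalization PP4 > 0.75, (10) MR support (IVW p < 0.05, weighted
#' median p < 0.05 and heterogeneity p > 0.01). Missing upstream tables set
#' their features to FALSE. A gene is prioritized when at least
#' `min_features` features hold.
#'
#' @param genes gene ids to score.
#' @param positional output of [map_positional_genes()] (features 1-2).
#' @param missense_ld gene ids with a missense/nonsense proxy (feature 3).
#' @param gene_test data frame gene_id, p, significant (feature 4).
#' @param high_expression named logical (feature 5).
#' @param valve_specific named logical (feature 6).
#' @param valve_eqtl gene ids with a significant lead-SNP eQTL (feature 7).
#' @param twas data frame gene_id, zscore, significant (feature 8).
#' @param coloc data frame gene_id, pp4 (feature 9).
#' @param mr data frame gene_id, ivw, ivw_p, wm_p, q_p (feature 10).
#' @param min_features prioritization cut (>= 4 features).
#' @return data frame with the ten logical feature columns, `direction`
#'   (sign of the TWAS z or MR estimate where available), `feature_count`
#'   and `prioritized`.
#' @export
build_evidence_matrix <- function(genes, positional = NULL,
                                  missense_ld = NULL, gene_test = NULL,
                                  high_expression = NULL,
                                  valve_specific = NULL, valve_eqtl = NULL,
                                  twas = NULL, coloc = NULL, mr = NULL,
                                  min_features = 4) {
  f <- function(x) { x[is.na(x)] <- FALSE; x }
  lk <- function(tab, col, default = NA_real_) {
    if (is.null(tab)) return(rep(default, length(genes)))
    tab[[col]][match(genes, tab$gene_id)]
  }
  flag <- function(named) {
    if (is.null(named)) return(rep(FALSE, length(genes)))
    f(named[genes])
  }
  nearest <- intronic <- rep(FALSE, length(genes))
  if (!is.null(positional) && nrow(positional) > 0) {
    nearest <- genes %in% positional$gene_id[positional$nearest_gene]
    intronic <- genes %in% positional$gene_id[positional$intronic_lead]
  }
  ev <- data.frame(
    gene_id = genes,
    nearest_gene = nearest,
    intronic_lead = intronic,
    missense_ld = genes %in% (missense_ld %||% character(0)),
    gene_test_significant = f(lk(gene_test, "significant", FALSE) > 0),
    high_expression = flag(high_expression),
    valve_specific = flag(valve_specific),
    valve_eqtl = genes %in% (valve_eqtl %||% character(0)),
    twas_significant = f(lk(twas, "significant", FALSE) > 0),
    coloc_pp4 = f(lk(coloc, "pp4") > 0.75),
    mr_significant = f(lk(mr, "ivw_p") < 0.05 & lk(mr, "wm_p") < 0.05 &
                         lk(mr, "q_p") > 0.01),
    stringsAsFactors = FALSE)
  dir_mr <- sign(lk(mr, "ivw"))
  dir_twas <- sign(lk(twas, "zscore"))
  ev$direction <- ifelse(!is.na(dir_mr), dir_mr, dir_twas)
  feature_cols <- setdiff(names(ev), c("gene_id", "direction"))
  ev$feature_count <- rowSums(ev[feature_cols])
  ev$prioritized <- ev$feature_count >= min_features
  ev
}

#' Read gene sets from a GMT file
#'
#' Tab-separated, one set per line: name, description, member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, "", 1))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set against a common background; a term is reported when
#' the overlap reaches `min_overlap` and the p-value is below `p_max`.
#'
#' @param query character vector of genes (must lie in the background).
#' @param gene_sets named list of character vectors.
#' @param background character vector of background genes (the universe).
#' @param min_overlap,p_max reporting thresholds.
#' @return data frame: term, set_size, overlap, p, reported.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, background,
                                      min_overlap = 5, p_max = 0.001) {
  stop_if(!all(query %in% background), "query must be a subset of the background")
  stop_if(any(!vapply(gene_sets, length, 0L)), "gene sets must be non-empty")
  N <- length(unique(background))
  n <- length(unique(query))
  res <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], background)
    stop_if(length(gene_sets[[term]]) > N, "gene set larger than background: ", term)
    m <- length(set)
    k <- length(intersect(query, set))
    p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(term = term, set_size = m, overlap = k, p = p,
               reported = k >= min_overlap & p < p_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}
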