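# Plain-text writers for simulated data: VCF (GT:DS), dosage/phenotype/counts
# TSV, BED gene annotations, and the truth file.

#' Write simulated genotypes to a VCF with GT:DS fields
#'
#' Dosages are rounded to the nearest genotype for GT and written exactly in
#' the DS field. Uncompressed VCF 4.2, one ALT allele per record.
#'
#' @param genotypes a `sim_genotypes` object.
#' @param path output path.
#' @export
write_dosage_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(v$chr)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    ds <- d[, j]
    cells <- paste0(gt[pmin(pmax(round(ds), 0), 2) + 1], ":", format(ds))
    writeLines(paste(c(v$chr[j], format(as.integer(v$pos[j])), v$variant_id[j],
                       v$other_allele[j], v$effect_allele[j], ".", "PASS", ".",
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write sample x variant dosages to TSV
#' @param genotypes a `sim_genotypes` object.
#' @param path output path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE)
  write_tsv(df, path)
}

#' Write phenotype and covariates for one cohort to TSV
#' @param cohort a `sim_cohort` object.
#' @param path output path.
#' @export
write_phenotypes_tsv <- function(cohort, path) {
  df <- data.frame(sample_id = rownames(cohort$covariates),
                   phenotype = cohort$phenotype, cohort$covariates,
                   check.names = FALSE)
  write_tsv(df, path)
}

#' Write a counts matrix with a gene-length column to TSV
#' @param expression a `sim_expression` object (or list with `counts`,
#'   `lengths`).
#' @param path output path.
#' @export
write_counts_tsv <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression$counts),
                   length = expression$lengths[rownames(expression$counts)],
                   expression$counts, check.names = FALSE)
  write_tsv(df, path)
}

#' Write gene annotations to BED
#'
#' BED6, 0-based half-open. The thickStart-like 4th-6th columns carry the
#' gene id, a 0 score and the strand; the TSS is the interval start for +
#' strand genes and `end - 1` for - strand genes.
#'
#' @param gene_annot a [gene_annotation()] table.
#' @param path output path.
#' @export
write_bed <- function(gene_annot, path) {
  bed <- data.frame(chrom = gene_annot$chr,
                    chromStart = as.integer(gene_annot$start - 1),
                    chromEnd = as.integer(gene_annot$end),
                    name = gene_annot$gene_id, score = 0L,
                    strand = gene_annot$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 gene annotation written by [write_bed()]
#' @param path BED file path.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand")
  start <- bed$chromStart + 1
  end <- bed$chromEnd
  data.frame(gene_id = bed$name, chr = bed$chrom, start = start, end = end,
             strand = bed$strand, tss = ifelse(bed$strand == "+", start, end),
             length = end - start + 1, stringsAsFactors = FALSE)
}

#' Write the generating truth to a structured text (YAML) file
#' @param truth a [sim_truth()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  as_list <- function(x) if (is.data.frame(x)) lapply(x, I) else x
  yaml::write_yaml(lapply(unclass(truth), as_list), path)
  invisible(path)
}
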