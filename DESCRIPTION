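Package: valvomics
Title: Integrative Genomics for Candidate Causal Gene Nomination in Calcific Aortic Valve Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-data-testable implementation of an
    integrative genomics pipeline for nominating causal genes for calcific
    aortic valve stenosis (CAVS): multi-cohort logistic GWAS and
    inverse-variance weighted fixed-effect meta-analysis with Cochran's Q
    heterogeneity, LD clumping and locus definition, single-causal-variant
    approximate-Bayes-factor credible sets, aortic-valve RNA-seq processing
    (TPM, expression filters, TMM, inverse-normal transform, expression
    principal components), tissue expression-specificity scoring, cis-eQTL
    mapping with a beta-approximated permutation pass and per-gene FDR
    thresholds, elastic-net TWAS with a summary-statistic association test,
    Bayesian colocalization from Wakefield approximate Bayes factors,
    two-sample Mendelian randomization (IVW, Egger, weighted median), an
    LD-aware gene-level association test, hypergeometric pathway enrichment,
    and a ten-feature per-gene evidence ledger. A seeded synthetic-data
    module generates LD-structured genotypes, liability-driven case-control
    phenotypes, negative-binomial expression counts with cis-eQTL effects and
    expression-mediated disease scenarios with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    glmnet,
    edgeR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
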