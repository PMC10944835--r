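---
title: "Methods: integrative nomination of causal genes for calcific aortic valve stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative nomination of causal genes for calcific aortic valve stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Calcific aortic valve stenosis (CAVS) has a substantial polygenic
component, but genome-wide association signals only mark regions. To move
from loci to genes one must ask whether risk variants regulate the
expression of particular genes *in the aortic valve*, whether genetically
predicted expression associates with disease, whether the association and
regulatory signals share a causal variant, and whether the relationship
behaves like a causal dose-response. `valvomics` implements that whole
chain and — because individual-level cardiovascular cohorts are access
restricted — ships a generative model of the study so that every stage can
be validated against known truth.

## Models and estimators

### Association and meta-analysis

Per-cohort association is maximum-likelihood logistic regression of case
status on expected allele dosage with age, sex and genotype principal
components as covariates; the Wald test on the log-odds scale is reported.
Cohorts are combined by fixed-effect inverse-variance weighting,
$\hat\beta = \sum_i w_i\beta_i / \sum_i w_i$ with $w_i = 1/se_i^2$ and
$se = (\sum_i w_i)^{-1/2}$, after allele harmonization (a swapped
effect/other pair flips the sign and the allele frequency; A/T and G/C
variants with MAF > 0.4 are dropped as strand-ambiguous, the standard
practice when the generating platform is unknown). Heterogeneity is
Cochran's $Q = \sum_i w_i(\beta_i-\hat\beta)^2$ with a $\chi^2_{k-1}$
p-value and $I^2 = \max(0,\,(Q-(k-1))/Q)\times 100$; a single-cohort
record has $Q \equiv 0$ and its heterogeneity p is reported as 1 (the
0-degree chi-square is degenerate). QC exclusions are strict
inequalities: imputation quality < 0.3, MAF < 0.001, or
quality-corrected minor allele count in cases
$2\,n_\text{cases}\cdot\text{MAF}\cdot\text{INFO} < 5$ — a record exactly
at a bound survives.

Loci are defined greedily by ascending p-value among genome-wide
significant variants (p < 5e-8): members collapse onto a better variant
at $r^2 \ge 0.6$, independent significant variants collapse onto leads at
$r^2 \ge 0.1$, and leads within 500 kb merge into one locus. $r^2$ is the
squared Pearson correlation of dosages. Ties break by p-value, then
position, then identifier, making the output deterministic.

### Fine-mapping

Credible sets assume a single causal variant per locus. Each variant gets
a Wakefield log approximate Bayes factor
$\log\text{ABF} = \tfrac12[\log(1-r) + z^2 r]$, $r = W/(V+W)$ with
$V = se^2$ and prior effect variance $W = 0.2^2$ on the log-odds scale
(a standard weakly-informative choice for binary traits). Posteriors are
ABFs normalized over the locus; the 95% credible set is the smallest
top-posterior prefix reaching 0.95. When every ABF is equal the set is
flagged uninformative and returned whole.

### Expression processing

TPM divides each gene's read count by its length and rescales each sample
to $10^6$. The expression filter keeps genes with TPM strictly above 0.1
in at least 20% of samples *and* at least 6 reads in at least 20% of
samples. Between-sample normalization is TMM — the trimmed (30% of
M-values, 5% of A-values), precision-weighted mean of log-ratios against
the reference sample whose upper quartile is closest to the mean upper
quartile — delegated to the canonical implementation in edgeR and
re-derived independently in the test suite. Each gene is then mapped to
exact normal scores, $\Phi^{-1}((\text{rank}-0.5)/n)$ with average ranks
for ties; this makes every downstream eQTL slope an effect in SD units
and depends on the data only through ranks. Expression covariates are the
top left singular vectors of the centered sample-by-gene matrix — a
principal-component stand-in for the factor-analysis residual methods
used at full scale; the component count is configurable (the scaled
default is 5, see below).

For tissue specificity, a gene's expression specificity score in a tissue
is its median log2 TPM divided by the summed medians over all tissues.
The input convention is log2(TPM+1); if raw log2 TPM is supplied,
negative medians are clamped to zero before the division since the ratio
is undefined for negative mass. Scores sum to one per gene; the valve
flag is strict, ESS > 0.1. High expression is a median strictly above
the empirical 90th percentile of all genes' medians.

### cis-eQTL

The nominal pass tests every variant with MAF ≥ 0.01 within 1 Mb
(inclusive) of the TSS, with distance signed by strand. Expression and
dosage are residualized on the covariates and the simple slope of the
residuals is reported; by the Frisch–Waugh theorem this equals the
multiple-regression coefficient, and the t-test uses
$n - (\text{covariates}+1) - 1$ degrees of freedom so p-values are exact,
not merely asymptotic. The permutation pass permutes the residualized
expression $B$ times (default 1000 at full scale, 200 in the scaled
pipeline), records the best nominal p per permutation, and smooths the
empirical p-value $(r+1)/(B+1)$ with a maximum-likelihood Beta$(a,b)$ fit
to the permutation minima (moment-matched start, Nelder–Mead; a
degenerate fit falls back to the direct estimate). Benjamini–Hochberg
across genes on the smoothed empirical p-values at 5% FDR gives the
passing set; the per-gene nominal threshold inverts each passing gene's
beta CDF at the midpoint between the largest passing and the smallest
failing empirical p-value.

The lead-SNP enrichment compares the proportion of significant SNP-gene
pairs among lead-SNP pairs with the proportion among all tested pairs by
a Pearson chi-squared test *with* continuity correction (required to
reproduce the reference value on the published counts), plus a Wilcoxon
rank-sum comparison of the p-value distributions.

### TWAS

Per-gene elastic-net models (mixing 0.5, the PredictDB convention) are
trained on cis dosages under nested cross-validation: five outer folds
give honest predictions; the penalty is chosen by five-fold inner
cross-validation entirely within each training split, so the outer
correlation has no optimism leak. The model qualifies when the average
out-of-fold Pearson correlation exceeds 0.1 strictly and its one-sided
t-test p-value (the directional test is the natural reading of a
prediction-quality rule; a two-sided switch exists) is below 0.05, and
the final refit keeps at least one variant. The association statistic is
$Z_g = \sum_l w_l (\sigma_l/\sigma_g) z_l$ with
$\sigma_g^2 = w^\top\Sigma w$ taken from the training genotype panel,
which doubles as the LD reference. $Z_g$ is invariant to rescaling the
weights. Genes are flagged at 5% FDR by Benjamini–Hochberg.

### Colocalization

For each gene, GWAS and eQTL tracks of Wakefield ABFs (prior sd 0.2 for
the binary trait, 0.15 for expression — tool conventions) are combined
into the five-hypothesis posterior under one causal variant per trait,
with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. All sums are
log-sum-exp; the test suite checks agreement with direct summation to
1e-10. The shared-signal call is strict, PP4 > 0.75.

### Mendelian randomization

Instruments for a gene are cis variants with exposure p < 1e-4 and
per-instrument strength $F = (b_x/se_{b_x})^2 > 15$, clumped at
$r^2 < 0.1$ by ascending exposure p; genes with fewer than three
surviving instruments are skipped. Estimators: fixed-effect IVW
(equivalently, weighted regression of outcome on exposure effects through
the origin), Egger regression with instruments oriented to positive
exposure effects (its intercept tests directional pleiotropy), and the
weighted median of ratio estimates with a seeded 1000-draw parametric
bootstrap standard error. Cochran's Q about the IVW slope screens
heterogeneity. The gene decision rule drops genes with Q p < 0.01,
adjusts IVW and weighted-median p-values separately by
Benjamini–Hochberg at 5% (the separate-family choice is configurable; the
source procedure does not specify pooling), and calls a candidate when
both pass and the Egger intercept p exceeds 0.05.

The IVW standard error deserves a note. The first-order fixed-effect
form treats exposure effects as known; that is accurate when instruments
are very strong. In the bundled scenario the exposure cohort has 400
samples, so $se_{b_x}/b_x \approx 0.2$ and the exposure noise — scaled by
the causal effect — rivals the outcome standard errors, overdispersing
the ratio estimates and shrinking the nominal CI below its true
coverage. `mr_estimates()` therefore exposes two documented
alternatives: a multiplicative random-effects inflation by
$\sqrt{Q/(k-1)}$, and second-order weights
$w_i = 1/(se_{b_y,i}^2 + \hat\theta^2 se_{b_x,i}^2)$ iterated to
convergence, which model the exposure noise directly and restore nominal
coverage without relying on a heterogeneity estimate that has only
$k-1$ degrees of freedom. The fixed-effect form remains the default; the
coverage evaluation in the acceptance script uses the second-order form
because its assumptions are the ones that actually hold there.

### Gene-level test and the evidence ledger

The gene-level association stand-in is the mean squared z over SNPs in
the gene window (gene body ± 10 kb). Under the null this is a weighted
mean of correlated 1-df chi-squares with weights equal to the LD-matrix
eigenvalues (clipped at 1e-8); Satterthwaite moment matching to a scaled
chi-square gives the p-value. The test reduces exactly to the single-SNP
p-value for one SNP and behaves as one SNP under perfect LD — it is
validated for calibration, not for numeric equality with any external
gene-based tool.

The evidence ledger scores ten binary features per gene — nearest gene to
a lead SNP; lead SNP inside the gene (intronic; with exon intervals
supplied, exonic hits are excluded, otherwise body containment counts);
missense/nonsense proxy at $r^2 \ge 0.8$; significant gene-level test;
high valve expression; valve specificity; lead-SNP valve eQTL; TWAS;
coloc; MR (IVW p < 0.05, weighted-median p < 0.05 and heterogeneity
p > 0.01) — plus a direction from the MR (or TWAS) sign. Four or more
features prioritize a gene. Pathway enrichment is the upper-tail
hypergeometric test, reported at ≥ 5 overlapping genes and p < 0.001.

## The synthetic study and its design choices

Genotypes come from a blockwise AR(1) latent-Gaussian threshold model:
each haplotype has a latent normal vector with within-block
autocorrelation `rho`, thresholded at each variant's allele-frequency
quantile; dosage is the sum of two haplotypes. This controls realized
$r^2$ smoothly with one parameter and is deliberately simpler than a
coalescent: there is no recombination map, no allele-frequency spectrum,
no population structure. MAFs are uniform on a configurable range.

Disease liability is the sum of direct variant effects,
expression-mediated effects, mild age and sex effects, and latent noise.
The default noise is standard *logistic* rather than normal: with
logistic noise, thresholding is exactly a logistic regression whose
coefficients are log-odds ratios per dose, so the effects declared in
the truth object live on precisely the scale the GWAS estimates and MR
ratios target, and recovery tests are unbiased by construction rather
than up to a liability-to-logit factor (the two latent laws are otherwise
interchangeable here; a normal switch exists). The intercept is solved
so the expected case fraction matches the configured prevalence — set to
0.5 in the default scenario, emulating ascertained surgical case-control
sampling rather than population prevalence.

Expression counts are negative-binomial around
$\text{baseline}_g \times \text{sizefactor}_s \times e^{\eta_{gs}}$,
where the latent $\eta$ has unit variance split between the cis-genetic
part (the configured per-variant proportions of variance) and
environmental noise; dispersion defaults to 0.1, typical of bulk
RNA-seq. The count layer adds roughly
$\phi + 1/\mu$ of log-scale noise, so observed cis heritability is
attenuated by a few percent relative to the latent target — a real
feature of count data that the recovery tolerances must absorb.

The default **mediation scenario** is the package's study condition: one
causal gene whose four causal cis variants sit in separate LD blocks with
equal per-variant variance summing to cis-PVE 0.3; expression raises
liability by 0.3 per SD; 400 expression samples; 20,000 GWAS samples in
two balanced case-control cohorts; two flanking null-expression genes in
the cis window; 100 background genes on another chromosome that provide
the expression percentile and covariate-estimation mass; and a 44-tissue
panel in which the causal gene holds a 20% valve share. Four variants is
the smallest number that leaves a margin over the ≥ 3-instrument MR rule
while keeping each instrument strong (expected exposure F ≈ 30) and the
lead GWAS variant genome-wide significant (expected z ≈ 5.8). The
choice is a compromise with a known cost, discussed under limitations.

Two scaled-design details matter and are deliberate. First, the number
of inferred expression covariates must stay small relative to the number
of genes: components estimated from a ~100-gene panel partially align
with any single gene's variation, so the scaled default is 5 components
per ~100 genes (the full-scale convention of 60 factors is against
~20,000 genes). Second, the eQTL covariates omit genotype principal
components: ancestry PCs are genome-wide objects, and PCs computed from a
40-variant focal panel would absorb cis-block dosage variance while the
simulated population contains no stratification for them to correct.
GWAS cohorts keep their genotype-SVD PCs as covariates.

Problem sizes in the test suite and acceptance script (500-variant null
scans, 20,000-variant inflation panels, 500-gene permutation nulls, 20
end-to-end replicates, 200 MR-coverage replicates) were chosen so the
Monte-Carlo error of each checked quantity is small against its
acceptance band on a single CPU.

## What passing tests do and do not show

The generators produce additive, well-imputed, autosomal biallelic
variation with clean binary phenotypes and a single tissue; they contain
no genotyping error, no relatedness or stratification, no
context-dependent eQTL, no trans effects, and LD without recombination
hotspots. Green tests therefore demonstrate that the estimators and
decision rules are implemented correctly and are calibrated under their
own assumptions — not that those assumptions hold in any real cohort.
Conversely, one documented red zone is informative about real analysis:
when a gene's expression is driven by several comparably strong cis
variants (which the ≥ 3-instrument MR rule demands), the
single-causal-variant colocalization posterior can place substantial mass
on the distinct-variants hypothesis whenever the two traits' strongest
signals rank differently — so PP4 > 0.75 is *not* achieved in a
reliable fraction of scenario replicates, and the same behavior (many
TWAS genes failing colocalization) is expected, and observed, in
practice. The evidence ledger is designed so that prioritization does not
hinge on any single feature.

## Numerical choices

* Beta fit of permutation minima: values clipped to
  [1e-12, 1-1e-12]; method-of-moments start; Nelder–Mead on log-shape
  parameters; fallback to the direct empirical p on degeneracy.
* All hypothesis sums in colocalization use log-sum-exp; the H3 term uses
  a guarded log-difference.
* Logistic fits use `glm.fit` with the Wald covariance from the final
  IRLS weights; non-convergence, |β| > 10 or se > 10 flag the record
  (separation) instead of failing the scan.
* Tie-breaking everywhere is (p, position, identifier) with radix
  ordering, making clumping and credible sets reproducible across
  platforms.
* Degenerate inputs are first-class: monomorphic variants, constant
  genes, all-zero samples, empty LD rows, flat ABF tracks and zero
  exposure effects are flagged or excluded with explicit messages, never
  silently dropped.
* Child seeds are derived linearly from the user seed modulo $2^{31}-1$;
  every stochastic stage takes an explicit seed.

## Known limitations

* The LD model has no recombination map; realized $r^2$ decays
  geometrically within blocks and is zero across blocks, which makes
  clump boundaries cleaner than in real data. Dosage correlation between
  variants with very different allele frequencies is further attenuated by
  the thresholding, as in real data.
* Every cohort observes every variant — there is no per-platform
  missingness structure; partially observed variants are exercised only
  through the meta-analysis handling of absent records.
* The permutation pass uses a fixed permutation count with beta
  smoothing, not adaptive stopping; very small empirical p-values are
  extrapolations through the fitted beta.
* The gene-level test is a calibrated stand-in, not a reimplementation of
  any specific gene-based association tool.
* Single-tissue, bulk expression only; specificity scoring takes the
  multi-tissue medians as given.
* The coloc/MR tension described above is inherent to combining a
  single-causal colocalization with a multi-instrument MR on the same
  gene; multi-causal colocalization is out of scope.
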