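---
title: "Models and methods behind proteoQTL"
author: "proteoQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proteoQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

proteoQTL maps genetic determinants of molecular abundance in cohorts of
cell lines with matched genotypes, RNA-seq and isobaric-label (TMT)
proteomics. It covers the chain from raw peptide intensity matrices to
quantitative trait loci (QTL) at four molecular layers — gene-level RNA,
transcript-level RNA, protein groups and peptides — plus cross-layer
replication, mechanistic classification of protein QTLs, trans effects
through protein complexes, variance-component decomposition and
X-chromosome-inactivation (XCI) analysis. Because cohort-scale human data
of this kind is managed-access, the package ships a fully synthetic cohort
generator with a ground-truth table, and every statistical guarantee the
package makes is demonstrated on that generator.

# The synthetic cohort

`cohortConfig()` / `simulateCohort()` emulate a population-scale induced
pluripotent stem cell cohort: by default 202 lines derived from 151
unrelated donors, a subset of donors contributing two lines each. Repeat
lines share their donor's genotype column exactly, which is what makes a
kinship random effect necessary downstream.

**Genotypes.** Variants are organised in LD blocks. Each block draws one
allele frequency uniformly from `mafRange`; within a block, each haplotype
allele is copied from its neighbour with probability `ldDecay` (default
0.98) and redrawn otherwise, so the genotype correlation between variants
decays geometrically with distance. This gives every causal variant
realistic proxies, which the LD-proxy machinery (r² > 0.8) needs.

**Abundances.** All layers are generated on the natural-log scale and
exponentiated for the "raw" outputs. Transcript log abundance carries a
per-gene donor random effect (`donorSd`, default 0.4) and i.i.d. noise
(`noiseSdRna`, default 1). The gene-level RNA value is the
abundance-weighted mean of its transcripts' log values — that weighting is
what lets opposite-signed isoform effects cancel exactly at the gene
level. Protein log signal couples to the coding transcript's baseline
deviation (`rnaProteinCoupling`, default 0.7), adds complex co-expression
where applicable, and protein noise (`noiseSdProtein`, default 1).
Peptides share their protein's signal plus small peptide noise; protein
group intensities are then *recomputed* as the sum of raw peptide
intensities, the same aggregation rule the analysis applies, so the
generator and the pipeline cannot drift apart.

**Planted cis effects.** Four mechanistic classes, planted as
`beta * z` where `z` is the standardized dosage of the causal variant:

* `shared` — the same beta on gene RNA, the coding transcript, protein
  and peptides;
* `rna_only` — beta on all RNA features, zero on protein;
* `isoform_opposite` — `+beta` on the coding transcript and
  `-beta * w+/w-` on a second transcript, so the expected gene-level
  effect is exactly zero while the protein, driven by the coding isoform,
  carries the full effect;
* `protein_altering` — beta on protein and peptides only, with the causal
  variant placed inside the gene body and annotated as a missense variant
  (protein-altering variants are coding by nature, and the downstream
  proxy-annotation rule only looks inside the gene body).

Effect sizes are drawn from `effectSizeRange` (default 0.5–1.0 standard
deviations of log abundance per genotype SD). `betaForVariance()` converts
a target fraction of explained variance into this scale using the
generator's base variance, which the power studies use.

**Trans effects.** Each complex has a limiting subunit with a cis effect;
partner subunits receive `transPropagation` (default 0.8) times that
effect at the protein level, emulating stoichiometric propagation through
complex assembly. Within-complex pairs are also emitted as the synthetic
protein-protein-interaction reference.

**TMT structure.** `applyTmtStructure()` adds, on the log scale, (i) a
shared per-batch sample-loading shift applied to every feature
(`batchLoadingSd`, default `batchSd`) — the coherent component that makes
batch structure visible to principal components — (ii) independent
per-feature per-batch shifts (`batchSd`, default 0.3) and (iii)
per-feature per-channel shifts (`channelSd`, default 0.1). Values are
masked missing independently at `missingRate` (default 0.05), never
silencing the reference line entirely. The designated reference line is
additionally re-measured in every batch (one reserved channel), yielding
the replicate profile used for the reference-line coefficient of error.

**XCI.** Each female line draws an erosion level uniformly from
`xciErosionRange` (0 = one X fully silenced, 0.5 = fully biallelic).
Heterozygous chrX SNP counts are binomial with minor-allele expectation
equal to the erosion; male lines contribute no heterozygous chrX counts.
chrX genes shift by `slope * erosion` across all layers.

What the generator does **not** emulate: real mass spectra and
identification errors, read-level RNA-seq, population demography beyond
unrelated donors, non-random missingness, and trans regulation beyond
complex stoichiometry. Tests passing on this generator therefore certify
the statistical machinery, not robustness to those real-data features.

# Quality control and normalization

The proteomics path (`processProteomics()`) applies, in order: (1) drop
lines whose detected-peptide count falls below 75% of the median count
across lines; (2) drop peptides overlapping common (MAF > 0.01)
non-synonymous variants at any mapped location, and peptides without a
genomic position — such peptides are undetectable on the alternate allele
and create synthetic associations; (3) keep features detected in at least
30 lines, and protein groups with at least one recurrent peptide; (4)
aggregate protein groups as the sum of detected peptide intensities
(missing only if all peptides are missing); (5) scale each feature/batch
by the ratio of its global median to its within-batch median; (6)
quantile-normalize each line to the reference line (the line with the
most detected features, ties broken lexicographically): the i-th ranked
detected value is replaced by the i-th ranked reference value, ties
resolved by stable feature order, and lines with fewer detected features
than the reference take reference values at linearly interpolated
quantiles. Missing values are never imputed anywhere; downstream
statistics use pairwise-complete data. RNA enters as TPM, filtered to
population mean TPM > 1 and transformed to log2(TPM + 1) (log base 2 for
interpretability; the pseudocount keeps zeros finite).

`ratioCompressionDiagnostic()` quantifies TMT ratio compression from
variant-overlapping peptides: heterozygous lines should show half the
hom-reference intensity, so a median het/hom ratio of 0.5 means no
compression and values above it measure background co-isolation (a 50%
background mixture yields 0.75).

# Hidden factors

`fitHiddenFactors()` estimates latent confounders with
expectation-maximisation for probabilistic PCA carrying an
automatic-relevance (ARD) precision per loading column: surplus factors
shrink to zero rather than fitting noise. The fit is SVD-initialised and
deterministic, runs on the most highly expressed 10,000 features (or all,
if fewer), and regresses known covariates out first. Factors are
zero-mean, unit-variance and ordered by explained variance. It is a
behavioural, not numerical, equivalent of Bayesian factor-residual tools
used for expression QTL covariate correction — factors only ever enter
the association model as fixed covariates, so only confounder capture
matters. `selectFactorCount()` scans k upward and keeps the largest k for
which all pairwise factor correlations stay below 0.7 in absolute value,
stopping at the first violation. No known covariates are supplied by
default.

# Association model

The core model is `y = C a + g b + u + e`, with `u ~ N(0, s2g K)` for the
kinship `K = Z'Z / M` over column-standardized dosages (population
scaling; monomorphic variants excluded) and `e ~ N(0, s2e I)`. Minor
allele frequencies are computed across unique donors, so repeat lines do
not pseudo-replicate alleles; the effect allele is the alternate allele,
with beta per alternate-allele dosage on the standardized phenotype.

Numerically, the kinship eigendecomposition rotates the model to
independent errors with variances proportional to `S + delta`,
`delta = s2e / s2g`; `delta` is estimated once per feature by 1-D maximum
likelihood under the null (no genotype) and reused for every cis variant
— the standard fast-mixed-model approximation, which costs nothing in
power for the small per-variant effects mapped here. Cis windows span
±250 kb of the gene boundaries (1-based inclusive; strand ignored) with
MAF > 5%. The lead variant is the smallest nominal p, ties broken by
larger |beta| and then smaller position.

Two calibration-driven choices deserve explanation:

* **t reference.** The per-variant p-value uses the exact t distribution
  with `n - q - 1` degrees of freedom rather than a normal reference.
  With ~200 lines the two differ little per test, but the permutation
  machinery fits a Beta law to *minima* of these p-values, and minima
  amplify tail behaviour: with a normal reference the permutation p-values
  are not uniform and the downstream adjustment inherits a measurable
  left-tail inflation.
* **Anchored Beta adjustment.** For each feature, the
  covariate-and-kinship-whitened residual vector is permuted (100
  permutations by default) and re-projected onto the covariate
  complement; the minimum p over cis variants is recorded per
  permutation, and a Beta(a, b) law is fitted to the minima by maximum
  likelihood from a moment-matching start. The adjusted p is the fitted
  Beta CDF *anchored at the permutation order statistics*: within the
  range of the minima the Beta CDF interpolates the empirical permutation
  distribution, so adjusted p-values are exactly calibrated at the
  permutation ranks; below the smallest minimum the Beta left tail
  extrapolates, retaining resolution finer than 1/(n_perm + 1). The
  anchoring matters because the law of a minimum over LD-correlated
  variants is close to, but not exactly, Beta: the raw plug-in CDF
  over-rejects at small p by roughly half again as much as nominal, and
  no number of permutations repairs a family misfit. If the Beta fit
  degenerates, the empirical permutation p is used and flagged.

Gene-level significance applies Bonferroni across a gene's features
(min over features of `min(1, p_adj * n_features)`) and then
Benjamini-Hochberg across genes within a layer, significant at FDR < 10%.
Trans scans test every (lead cis variant, protein) pair with the same
model, exclude pairs where the trans protein's gene is the cis gene or
lies in the variant's cis window, and apply BH across all remaining
tests. Trans associations whose quantifying peptides locally align to the
cis protein with fewer than two mismatches (match +1, mismatch 0, every
gap position −1; mismatches = peptide length minus aligned identities,
so unaligned residues count against the peptide — the conservative
reading) are discarded as potential peptide-assignment artifacts; the
discard triggers on *any* offending peptide, again the conservative
alternative.

# Variance components

`fitVarianceComponents()` maximizes the multivariate-normal likelihood of
`y = mu + sum_k u_k + e` over non-negative variances with the mean
profiled out by GLS, for categorical covariance matrices
(`M_k[i, j] = 1` iff lines i and j share the label) built for donor, sex,
age (5-year bins anchored at 0 — the anchor is a choice we expose),
culture medium, TMT batch and TMT channel. Optimization runs on the
log-variance scale (the zero boundary becomes open) with Nelder-Mead and
5 random restarts, convergence tolerance 1e-8 on the log-likelihood.
Maximum likelihood with a single profiled mean matches the stated model;
the difference from REML is O(1/n) for fractions and the fit agrees with
an independent ML mixed-model fit to optimizer tolerance on balanced
designs. Phenotypes are standardized per gene (in
`decomposeVarianceMatrix()`, not in the core fitter, which stays
scale-equivariant) so fractions are comparable across genes. Donor
components are estimated on the paired-donor line subset, where they are
identifiable. RNA-adjusted protein decompositions regress protein on RNA
per gene (ordinary least squares) and decompose the residuals.

# XCI analysis

Per heterozygous chrX SNP with at least 20 reads, the allele-specific
fraction is min(ref, alt)/total — invariant to allele labelling and
bounded by [0, 0.5]; the line's XCI score is the mean over its SNPs, with
lines lacking qualifying SNPs flagged. Genes tracking XCI are found by
Pearson correlation (Spearman available; the estimator choice is ours)
between abundance and score across female lines, BH-adjusted per layer at
FDR 10%, with the direction reported. Enrichment of strong (>20%) sex
variance fractions among chrX-encoded genes uses Fisher's exact test with
the sample odds ratio (0.5 continuity correction only when a cell is
zero, flagged) and the minimum-likelihood two-sided p.

# Replication and the predictor

A QTL replicates in another layer iff the lead variant reaches nominal
p < 0.01 there with the same effect direction; for transcript and peptide
layers any feature of the gene may carry the replication. The identical
operation serves both directions (protein to RNA and RNA to protein).
Mechanism classes for significant pQTLs follow ordered rules: gene-RNA
replication → gene expression effect; else any transcript nominally
significant → transcript-isoform-specific; else any gene-body LD proxy
(r² > 0.8) in the inframe category → protein-altering variant; else
unexplained. The replication predictor is a random forest (100 trees)
over eight gene-level features (eQTL effect size, reference-line
coefficient of error across batches, protein CV, protein abundance, SNP
MAF, RNA abundance, peptide count, missing-measurement count — missing
counted as lines where the protein is unobserved), evaluated over 50
random 80/20 splits with mean feature importances and mean average
precision.

# Validation sizes and determinism

The packaged validation suite runs, among others: oracle equivalence of
the mixed model against closed-form OLS/GLS (50 lines, 20 phenotypes);
Beta-versus-10,000-permutation agreement on 20 genes; 20 all-null
cohorts of 200 lines x 300 genes x 3,000 variants for FDR control and
p-value uniformity; 100 planted genes per point of the effect grid
{5%, 10%, 20%} for recovery power; 90 planted genes for mechanism
accuracy; 500 simulated genes on 51 donor pairs for variance-component
recovery; 10 cohorts for trans propagation; and 20 XCI replicates at 110
female lines x 50 SNPs x 100 reads. These sizes were chosen so each
property is measured with Monte-Carlo error well inside its acceptance
margin while a full run stays comfortable on a laptop. All stochastic
stages take explicit seeds, and identical configuration plus seed
reproduces every output byte for byte.

# Known limitations

Single-signal cis mapping only (no conditional analysis or
colocalization); variant-effect and SIFT annotations are consumed as
tables, never computed; the factor model does not reproduce any specific
published software numerically; permutation of whitened residuals assumes
the estimated null covariance decorrelates lines adequately — under
strong, badly mis-estimated relatedness the exchangeability is only
approximate; and the generator's idealisations listed above bound what
green tests can certify about real cohorts.
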