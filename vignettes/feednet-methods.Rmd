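---
title: "Methods: co-association networks and genomic prediction for feed efficiency"
author: "feednet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-association networks and genomic prediction for feed efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `feednet`,
the assumptions behind them, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate. Nothing here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

# Phenotype derivation

Residual feed intake is defined as the residual of an ordinary
least-squares regression of average daily feed intake on batch intercepts,
a single (unnested) age-at-midpoint covariate, and metabolic weight
(body weight^0.75, kg), average daily gain and backfat, each nested within
batch. The nesting follows the literal reading of the model statement:
batch-nested partial regressions for the three production covariates, one
global age slope. Consequences that the tests assert: the RFI column has
mean zero to 1e-10, is orthogonal to every design column, and is
uncorrelated with growth and backfat within batch. FCR is the plain ratio
ADFI/ADG; a non-positive ADG raises an error rather than propagating NaN
into downstream scans.

Each batch must contain at least as many animals as nested coefficients;
otherwise the design is rank deficient and `deriveTraits()` says so rather
than silently dropping columns.

# Genotype quality control

Filters run in a fixed order — missingness, minor allele frequency,
Hardy–Weinberg, unmapped/X — with strict inequalities on the failing side:
MAF < 0.05 fails, MAF = 0.05 survives; missingness > 0.10 fails; HWE
p < 0.001 fails. HWE uses the conventional 1-df chi-square on genotype
counts; a conditional exact test is available via `hwe_test = "exact"`.
Ties at the thresholds are resolved by the strict inequalities because the
protocol wording ("lower than 5%") implies them; this is recorded as an
interpretation, not a fact. Missing genotypes surviving QC are imputed to
the per-SNP mean dosage, which preserves allele frequencies for
relationship-matrix construction.

# Mixed-model association scans

The animal model is y = Xb + u + s·a + e with u ~ N(0, K σ²u). The null
model (no SNP) is fitted by REML after rotating by the eigenvectors of K,
which reduces the problem to a one-dimensional optimization in
γ = σ²u/σ²e on a log10 grid over [−6, 6]; hitting the boundary is flagged,
and a K numerically proportional to the identity raises a
non-identifiability warning (σ²u and σ²e cannot be split). The scan is
two-step: the covariance structure is frozen at the null fit and each
SNP's allele-substitution effect is the GLS estimate under it, with the
residual scale re-estimated per marker, so with σ²u = 0 the scan is
exactly per-SNP OLS (asserted to 1e-8 against a normal-equations oracle).
Wald p-values use the normal reference, p = 2(1 − Φ(|z|)). The candidate
SNP stays in the relationship matrix — no leave-one-chromosome-out — which
slightly deflates planted-QTL signal; the power test documents the
magnitude rather than hiding it.

Two GRM estimators are provided: per-SNP standardization
( (x−2p)(x−2p)'/2p(1−p), averaged over SNPs) and overall scaling
(cross-product of centered dosages over Σ2p(1−p)). Their off-diagonals
correlate above 0.99 on MAF-uniform data, but the choice matters for
*estimands*: when marker effects are drawn independently of allele
frequency — as in this package's generator — the overall-scaled GRM is the
correctly specified genetic covariance, and parameter-recovery experiments
use it (see "Calibration choices" below).

The eGWAS model replaces the age covariate with a laboratory fixed effect
(two levels, matching the split microarray processing) and controls
multiplicity within gene across SNPs: Benjamini–Hochberg q-values (the
"q ≤ 0.05" genome-wide rule) plus a Bonferroni column. Genome ×
transcriptome joint correction is deliberately not applied, since
per-gene q-values are what the output tables report. An eSNP is cis when
it lies within 1 Mb of the gene on the same chromosome; the gene anchor is
the start coordinate by default (`gene_pos = "midpoint"` is the
alternative), a choice exposed because the convention is not dictated by
anything upstream.

# The association weight matrix and PCIT

A SNP enters the AWM when it is nominally associated (p < 0.05) with the
key trait (RFI) **or** with at least three of the other eight traits,
**and** maps within 10 kb of an annotated gene. Rows carry signed
z = effect/SE for all nine traits, including non-significant ones. Trait
relationships are read off the columns (Pearson correlations,
complete-linkage clustering on 1 − r, serialized as Newick); complete
linkage is an assumption recorded as such — it is the default of the
clustering routine the protocol names.

PCIT decides edge significance trio-locally. For nodes x, y, z with
pairwise correlations r, the first-order partials are
r_xy.z = (r_xy − r_xz r_yz)/√((1−r²_xz)(1−r²_yz)) and the trio tolerance
is ε = (r_xy.z/r_xy + r_xz.y/r_xz + r_yz.x/r_yz)/3. Edge x–y is flagged in
the trio when |r_xy| ≤ |ε r_xz| and |r_xy| ≤ |ε r_yz|. Aggregation over
trios is a config switch: under `"any"` (default, matching the
"discarded if" phrasing of the algorithm's description) a single flagging
trio removes the edge; under `"all"` every valid trio must flag it. Both
modes are checked edge-for-edge against a naive triple-loop reference on
random node sets. Numerical guards: trios with any |r| < 1e-12 in a
tolerance denominator contribute nothing, and partial-correlation
denominators are clamped at 1e-12 when |r| = 1 (duplicated rows).
Because AWM profiles have only nine points, the correlations themselves
are never significance-tested — PCIT replaces that test — and the function
warns to that effect whenever profiles are shorter than 30 points.

Edge weights are the raw correlations (not partials): downstream
degree/hub logic counts connections only.

# The lossless regulator search

Every trio and quartet of TF nodes is scored exhaustively — "lossless"
implies exactness, and C(68,4) ≈ 814k combinations is tractable with
precomputed neighborhood rows — by coverage (distinct nodes adjacent to at
least one member) and redundancy (summed pairwise neighborhood
intersections). Ranking is coverage descending, redundancy ascending, then
lexicographic member ids; whether the original approach penalizes
redundancy explicitly is not restated anywhere authoritative, so the
tie-break is documented as this package's convention. Coverage excludes
the seed TFs themselves by default ("number of target genes"); the
self-inclusive count is a flag, and both modes are tested. A guard refuses
enumerations beyond 10^7 combinations with advice to pre-filter TFs by
degree.

# Transcriptome analyses

**Preprocessing.** Control probes are dropped, probes detected in fewer
than 25% of samples are dropped (the complement of "below detection in 75%
of animals"), unmapped probes are dropped, and surviving probes of one
gene are averaged per sample.

**Differential expression.** Per-gene least squares on group + batch +
laboratory, then empirical-Bayes variance moderation with an
intensity-dependent prior: the prior log-variance is a lowess fit of the
bias-corrected log residual variance on mean intensity, and the prior
degrees of freedom d₀ solve trigamma(d₀/2) = var(log deviates) −
trigamma(d/2) via a Newton inverse. The moderated t uses the posterior
variance (d₀s₀² + d s²)/(d₀ + d) on d₀ + d degrees of freedom. Setting
d₀ = 0 recovers the ordinary t exactly (asserted to 1e-10); the full
statistic tracks `limma::eBayes(trend = TRUE)` closely (correlation
> 0.999 in the cross-check), with small differences from limma's more
elaborate prior-df estimator. The fold-change convention: the group
difference Δ is estimated on the log2 scale (adjusted for batch and
laboratory), the reported FC is sign(Δ)·2^|Δ| on the linear scale, and the
|FC| > 1.5 threshold applies on the linear scale — the only reading under
which a published top-gene FC of 4.94 at plausible log2 differences is
coherent; log-scale thresholding remains available (`fc_scale = "log2"`).
Positive FC means higher expression in the low-feed-efficiency group.

**Sparse PLS-DA.** Per component, the X-loading from the SVD of X'Y is
refined by the alternating NIPALS scheme with soft-thresholding that keeps
exactly `keepX` genes; both blocks are deflated by regression on the
score. `keepX = p` is exactly dense PLS-DA (asserted to 1e-6, and the
dense and sparse fits match `mixOmics` loadings and selections in the
cross-check). keepX per component is tuned by repeated stratified 5-fold
cross-validation minimizing the balanced error rate under the
maximum-distance rule; the repetition count defaults to a desk-scale 10
(the study-scale analogue is 500 and is a single argument away).
Components are oriented so the first variate is higher in the
high-efficiency class, so genes up-regulated in inefficient animals carry
negative first-component loadings — the sign contract the integration step
and its tests rely on.

**Regularized CCA.** Directions come from the eigen-decomposition of
(S_XX + λ₁I)⁻¹ S_XY (S_YY + λ₂I)⁻¹ S_YX on standardized data; reported
canonical correlations are the square roots of the regularized
eigenvalues, which equal the empirical variate correlations and the
multiple correlation √R² when λ = 0 (asserted to 1e-8) and match
`mixOmics::rcc` to 1e-6. In shrinkage mode λ is the analytic
shrinkage intensity of each side's correlation matrix (sum of estimated
sampling variances of the off-diagonal correlations over their sum of
squares, clipped to [0,1]). Components are oriented so the dominant trait
loads negatively — the "efficient direction up" convention that makes
rCCA gene loadings sign-consistent with the sPLS-DA loadings. Candidate
genes are selected where the maximum absolute per-gene trait correlation
exceeds median + 2·SD of that distribution; the population over which the
statistic is computed is ambiguous in the source protocol, so both options
are implemented — genes weighted on CC1 (above-median |loading|, default)
or all genes.

**Integration.** Genes reported by at least two of DE/sPLS-DA/rCCA are
candidates; concordance is the correlation between sPLS-DA component-1
loadings and rCCA CC1 loadings over genes common to both selections, and
is NA (not a fabricated number) when fewer than three genes are common.

# Variance components and prediction

The Gibbs sampler targets the single-trait animal model with flat priors
on location effects and flat (scaled inverse chi-square, ν = −2) priors on
both variances. The relationship matrix is eigen-decomposed once; in the
rotated basis the breeding-value conditional is diagonal, so a 20,000
iteration chain at n = 350 costs seconds. Dimensions with numerically zero
eigenvalues (rank-deficient GRMs from small SNP panels) carry no genetic
variance and are fixed at zero — the proper degenerate normal, not a
ridge. Chains are summarized by posterior mean ± SD of σ²u, σ²e and
h² = σ²u/(σ²u+σ²e); a split-chain potential-scale-reduction heuristic on
h² above 1.1 triggers a warning that is carried in the output. The
desk-scale default is 20,000/2,000/10 (iterations/burn-in/thinning); the
study-scale 100,000/10,000/10 is a configuration choice.

GBLUP solves the training-records mixed model by GLS under
V = Rσ²u + Iσ²e and propagates breeding values through R; a validation
animal unrelated to training is predicted by fixed effects alone, and the
implementation is verified against a direct Henderson
mixed-model-equation solve to 1e-8. Cross-validation uses 20 random
~88/12 splits with full-data variance components — exactly the published
scheme, optimistic bias and all; splits missing a batch level in training
are resampled (up to 100 attempts, logged). Prediction accuracy is the
Pearson correlation of observed and predicted records in validation.

Because every synthetic animal with a phenotype is genotyped, single-step
blending reduces to GBLUP; the full H-matrix machinery is out of scope.

# The synthetic-data generator

The generator emulates the study design downstream stages assume: 350
offspring of 5 sires (half-sib families; each offspring has a distinct
founder dam), four fattening batches, age at the trial midpoint uniform on
121–148 days, ~thousands of SNPs on autosomes with founder MAF uniform on
(0.05, 0.5], LD induced by copying parental haplotypes in blocks of 10
SNPs (a cheap surrogate for recombination, not a coalescent), genes placed
along chromosomes with 8% flagged TF, and nine analysis traits built from
eight simulated primaries (ADFI, ADG, body weight, BF, CW, KO, LEAN, IMF)
with Table-1-scale means and SDs. Pleiotropy is effect-sharing with
correlation 1 inside two trait groups (production: ADFI/ADG/BW/CW; fat:
BF/IMF), the simplest structure that makes the trait dendrogram cluster
feed-efficiency traits together. Heritabilities default to 0.3–0.5 by
trait (within the published 0.14–0.53 range for RFI-type traits); each
trait's genetic value mixes QTL (70%) and a polygenic background (30%) by
default. Expression adds baseline N(7, 1.5) log2 intensities, batch
(SD 0.3) and laboratory (+0.5 log2 in lab 2) shifts, cis-eQTL within 1 Mb
of the gene (1.0 log2/allele), trans-eQTL on other chromosomes
(0.8 log2/allele), a 1.0 log2 DE offset in LFE animals for 50 genes
(80% up-regulated, echoing the direction imbalance such contrasts show),
Gaussian noise (SD 0.5), and intensity-dependent detection calls. RFI and
FCR are never simulated — they are derived downstream, so the derivation
code is exercised by every end-to-end test.

What the generator does **not** emulate: genotyping error, realistic
recombination maps and MAF spectra, dominance/epistasis, selection,
non-Gaussian expression noise, probe-level artifacts (RMA/MAS5 live
upstream of this package's inputs), or population-scale LD decay.
Passing tests therefore demonstrate algorithmic correctness and
statistical calibration under the stated structure, not robustness to
everything real data can do.

# Calibration choices (and why they are not tuning)

Two experiment-design decisions deserve explicit justification:

* **Heritability recovery uses a polygenic architecture.** The estimand of
  a GRM-based variance component equals the simulated h² only when the
  genetic covariance actually is proportional to the GRM. With a
  100-large-QTL architecture both REML and the Gibbs sampler sit visibly
  above the simulated value — a misspecification effect, reproduced by two
  independent estimation routes, not a sampler bug. The recovery
  experiments therefore simulate the matched (fully polygenic) model; the
  QTL architectures are exercised by the power and prediction tests where
  misspecification is part of the question.
* **Prediction-ordering experiments predict RFI.** RFI is
  fixed-effect-free by construction; predicting a batch-laden raw trait
  adds the same fixed-effect variance to every method's accuracy and
  compresses the differences between relationship matrices. The study's
  own target trait is RFI, so the synthetic check uses it too.

Problem sizes throughout (hundreds of SNPs and genes in unit tests; 350
animals, 1,200–5,000 SNPs, 20 seeds/replicates in the acceptance checks;
3,000 SNPs and 1,000 genes in the acceptance script) are the package's
chosen desk scale: large enough for the statistical properties under test,
small enough to iterate on.

# Known limitations

* The two-step scan fixes the variance ratio at the null fit; per-SNP
  exact REML is not implemented (the standard approximation's deflation is
  documented in the power tests instead).
* The PCIT loop is O(n³) in AWM rows in pure R; at the hundreds-of-nodes
  scale used here that is seconds, but a 10⁴-node network would want a
  compiled kernel.
* eGWAS multiplicity is per gene; a genome × transcriptome FDR is a
  deliberate non-goal.
* The Gibbs convergence heuristic is a single split-chain diagnostic, not
  a replacement for running longer chains when estimates matter.
* PLINK ingestion covers the text pair (.ped/.map); binary .bed and VCF
  are out of scope for this version.
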