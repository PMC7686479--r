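---
title: "From genotypes to symptoms: transcriptome-imputed polygenic scores, behavioral PLS, and sex-moderated mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genotypes to symptoms: transcriptome-imputed polygenic scores, behavioral PLS, and sex-moderated mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model chain

`tprspls` implements a four-stage statistical chain that links common
genetic variation to depressive symptoms through brain function, together
with a synthetic-data generator that plants every structure the chain is
designed to detect.

1. **Transcriptome-based polygenic score (T-PRS).** For each gene $g$ with
   a pre-trained cis-eQTL weight model, predicted cortical expression of
   subject $s$ is the linear combination
   $\hat e_{sg} = \sum_{v} d_{sv} w_{vg}$ of allele dosages $d_{sv}$ and
   weights $w_{vg}$ (PrediXcan-style imputation). The score is
   $\mathrm{TPRS}_s = \sum_g \delta_g\, z_g(\hat e_{sg})$, where
   $\delta_g \in \{-1, +1\}$ (optionally scaled by a continuous effect
   weight) is the gene's direction of association with depression in
   postmortem corticolimbic tissue, and $z_g$ standardises each gene
   across the sample. Higher scores mean a more depression-like
   transcriptome.
2. **Conventional polygenic score (PGC-PRS).** GWAS summary statistics
   are allele-harmonised against the panel, greedily LD-clumped (index
   SNPs by ascending p, absorbing same-chromosome variants within 250 kb
   at $r^2 \ge 0.1$), and averaged as $\beta \times$ dosage over index
   variants passing each of nine p-value thresholds.
3. **Behavioral PLS.** For each of six cells (two sex groups $\times$
   three task conditions) and each voxel, the Pearson correlation between
   score and activation forms a $6 \times V$ matrix $R$. Its SVD
   $R = U S V^\top$ yields latent variables; LV $k$ explains
   $100\, s_k^2 / \sum_j s_j^2$ percent of crossblock covariance.
   Significance comes from permutation of the score-to-subject assignment
   within group; voxel reliability from bootstrap ratios (salience over
   bootstrap SE, thresholded at 2.5); spatial structure from connected
   components of suprathreshold voxels larger than 20 voxels.
   Brainscores project each subject's condition-wise activation onto the
   LV voxel salience.
4. **Symptom paths.** Brainscore–anhedonia association (Pearson $r$, $R^2$,
   t-based p), covariate-adjusted standardized regression, and
   sex-stratified mediation: $a$ from the mediator-on-score OLS, $b$ from
   the outcome-on-mediator OLS adjusting for the score, indirect effect
   $ab$, with stratified bootstrap percentile intervals and a
   difference-in-$ab$ moderation index. Nine parallel PGC-PRS analyses are
   gated by Bonferroni at $0.05/9 \approx 0.0056$.

## What the generator emulates

The generator reproduces the statistical skeleton of a young-adult
imaging-genetics cohort (478 subjects; 253 women, 225 men; three
face-matching task conditions), not its biology:

- **Genotypes.** Blockwise exchangeable LD via a latent Gaussian copula
  thresholded at the allele-frequency quantile, two haplotype draws per
  variant. This controls within-block dosage correlation with one knob
  (`within_block_r`) — exactly what clumping tests need — and makes no
  attempt at coalescent realism, recombination maps, or genotyping error.
  INFO scores are drawn uniformly on (0.5, 1], so the INFO > 0.8 filter
  has real work to do.
- **eQTL weights.** Each gene gets `snps_per_gene` variants with normal
  weights; the implied expression is recorded as ground truth, making
  imputation exact by construction.
- **Brain activation.** Signal voxels form one contiguous grid block
  (at least 21 voxels whenever any signal is requested, so the >20-voxel
  cluster rule is exercised) with a flat unit-norm salience. In each
  (group, condition) cell the planted entry of `planted_effects` is the
  *target per-voxel score–activation correlation*: the generator scales
  the standardized score by $\rho/\sqrt{1-\rho^2}\cdot\sigma$ before
  adding noise with SD $\sigma$, so the realized per-voxel correlation is
  $\rho$. (Planting the raw coefficient instead would make the realized
  correlation an opaque function of the noise level; the noiseless limit,
  correlation $\pm 1$, and the null case are unaffected.) Defaults plant
  the study's qualitative pattern: $-0.3$ for women viewing neutral faces,
  $+0.2$ for men viewing emotional faces and shapes.
- **Symptoms.** Anhedonia is `mediation_b` times the *standardized*
  brainscore plus Gaussian noise — standardizing makes the planted path a
  scale-free coefficient rather than an artifact of voxel count. The other
  three MASQ subscales share a configurable correlation with anhedonia
  (default 0.4), the stress scales half of it. Scales stay continuous; no
  Likert discretisation. A companion generator (`simulate_brainscore`)
  plants the score-to-mediator path $a$ directly for mediation studies.

Passing tests on these data show that the estimators recover planted
linear, low-rank and indirect-path structure at realistic sample sizes.
They do not show robustness to spatial autocorrelation, hemodynamic
confounds, LD between causal and scored variants, population
stratification of the phenotype, or non-Gaussian symptom distributions —
none of which the generator produces.

## Numerical and design choices

- **Determinism.** Every generator derives a fixed sub-seed from the
  config seed (`derive_seed(master, stage)` with
  $\mathrm{seed}_i = (131\,m + 7i) \bmod (2^{31}-1)$), and restores the
  caller's RNG state afterwards. Identical config and seed give
  bit-identical output; the pipeline manifest records artifact checksums.
- **QC boundaries** are strict: MAF must exceed 0.01 and INFO must exceed
  0.80; a variant at either boundary is removed. A/T and C/G variants are
  strand-ambiguous and dropped; duplicate chrom:pos:allele-set entries
  keep their first occurrence.
- **PIHAT** uses method-of-moments IBD from pairwise IBS with
  plug-in allele frequencies, clamped to [0, 1] (clamping counts are
  reported). Small-sample corrections are deliberately omitted: only the
  thresholding behaviour (exclude above 0.2, dropping the
  higher-missingness member, ties to the lexicographically later id)
  matters downstream. At a few hundred effective markers the estimates
  are noisy, which the QC driver reports honestly; panels of several
  thousand independent variants bring the null mean within ±0.02 of zero.
- **MDS** is classical Torgerson scaling of $1 -$ IBS proportion.
  With no planted population structure the leading component explains
  only a few percent of variance; the >40% seen in real cohorts requires
  real stratification, which the generator does not emulate. Reference
  clustering is nearest-centroid in MDS space with a quantile-based
  outlier radius — the published analyses name no explicit rule, so this
  stand-in is a package decision, flagged as such.
- **Clumping ties** on p break by smaller position, then lexicographic id.
  PRS averages over used variants by default (comparable across
  thresholds); `score_mode = "sum"` gives the plain weighted sum. An empty
  threshold yields an all-zero score with a warning rather than an error.
- **Permutation scheme.** Published descriptions of condition resampling
  are ambiguous when conditions enter as rows of a correlation matrix
  rather than exchangeable per-subject labels; the implemented null —
  shuffling score-to-subject assignment within group — is the exchangeable
  null of no score–brain association and is the variant calibrated here
  (type-I error within [0.01, 0.09] at $\alpha = 0.05$ on pure noise).
  P-values use the add-one convention, so the smallest attainable p is
  $1/(n_{perm}+1)$.
- **Bootstrap alignment.** SVD axes and signs are arbitrary per resample;
  each bootstrap solution is aligned to the original by orthogonal
  Procrustes on the behavior saliences, with the rotation applied to the
  voxel saliences. Behavior-side intervals are percentiles of
  $R_{boot} v_1$ (the resampled correlation rows projected on the fixed
  original voxel pattern), which keeps them interpretable as cell-wise
  association strengths and asymmetric by construction. Zero bootstrap SD
  (noiseless data) maps to an infinite bootstrap ratio of the salience's
  sign. Degenerate resamples (a group collapsing below 3 distinct
  subjects) are redrawn with an attempt cap.
- **Clusters** default to 6-connectivity (faces only); 18 and 26 are
  available. Both size and BSR thresholds are strict inequalities.
- **Recovery expectations.** With a planted per-voxel correlation $\rho$
  over $k$ of $V$ voxels and $n$ subjects in the signal-bearing group, the
  expected cosine between the LV1 voxel salience and the truth is
  approximately $\sqrt{s^2/(s^2 + V/n)}$ with
  $s^2 = k\rho^2/(1-\rho^2)$: about 0.81 at $\rho = 0.3$, 10% signal,
  $n = 200$ in the group. Recovery checks therefore size the *group*, not
  the pooled sample — the correlations that feed the SVD are within-group
  quantities, and halving the group size drops the expected cosine to
  about 0.69 regardless of voxel count.
- **Mediation.** Variables are z-scored within stratum by default so paths
  are standardized coefficients; `standardize = FALSE` keeps the raw scale
  (used when checking coverage of a raw-scale planted $ab$). Percentile
  intervals, not bias-corrected: no correction is named in the analyses
  this mirrors, and the percentile interval is the simplest member of the
  family. Aliased columns in the outcome model (e.g. a mediator identical
  to the score) contribute zero, keeping degenerate chains estimable;
  `adjusted_regression()`, by contrast, errors on rank deficiency and
  names the collinear columns. Mediation-through-an-estimated-LV couples
  the mediator tightly to the score (the aggregate of many signal voxels
  correlates with the score far more strongly than any single voxel),
  inflating collinearity in the outcome model; mediation studies that
  need a specific planted $a$ should use `simulate_brainscore()`.
- **Missing dosages** are mean-imputed per variant before scoring, LD and
  MDS, keeping the linear operations total; missingness still drives the
  relatedness exclusion rule.

## Problem sizes

Simulation-based checks in the test suite use 200 pure-noise datasets
(120 subjects, 6 cells, 500 voxels, 200 permutations) for permutation
calibration; one planted dataset (200 subjects per sex group, 500 voxels,
10% signal, 500 bootstraps) for salience-ratio calibration and recovery;
100 replicates at $n = 500$ (500 bootstraps) for mediation coverage; and
50 replicates at 250 per stratum for sex-specific pathway recovery. These
sizes put each Monte-Carlo estimate's sampling error well inside the
accepted band while keeping the full suite around a minute of compute.

## Known limitations

- PIHAT omits PLINK's exact small-sample corrections; estimates at low
  marker counts are biased toward extremes and are clamped.
- The permutation unit (subjects within group) is one of two defensible
  readings of condition resampling; the alternative is not calibrated
  here.
- The nearest-centroid ancestry rule is a stand-in for an unspecified
  published procedure.
- Imputed INFO scores are consumed, never computed; X-chromosome
  handling, genome-build liftover and eQTL model training are out of
  scope.
- The generator's voxel noise is i.i.d. Gaussian; cluster sizes on real,
  spatially smooth data behave differently.
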