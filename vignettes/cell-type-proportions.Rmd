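---
title: "Estimating cortical cell-type proportions and their Alzheimer's disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cortical cell-type proportions and their Alzheimer's disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bulk brain RNA-seq mixes transcripts from every cell in a tissue block, so a
gene's bulk expression confounds per-cell expression change with change in
the abundance of the cells that express it. `cortexCTP` addresses the second
quantity at the *subclass* level of the neocortical cell taxonomy — 19
subclasses spanning five GABAergic interneuron groups (LAMP5, PAX6, SST,
VIP, PVALB), seven glutamatergic projection-neuron groups (IT, L4 IT,
L5 6 IT Car3, L5 6 NP, L5 ET, L6 CT, L6b), and seven non-neuronal groups —
and asks which subclasses differ in relative abundance between Alzheimer's
disease (AD) cases and controls, and how those abundances relate to
neuropathology and longitudinal cognition.

Two complementary estimators are implemented:

* **rCTPs** (relative cell-type proportions) from bulk tissue: for each
  subclass, the first principal component of its marker genes' expression
  across samples. These are latent relative scores, not counts; only
  between-sample contrasts are interpretable.
* **snCTPs** (single-nucleus cell-type proportions): the percentage of a
  subject's QC-passing annotated nuclei belonging to each subclass. Direct,
  but available for far fewer subjects.

## The marker-gene-profile model

For subclass $k$ with marker set $G_k$, let $E$ be the normalized
log~2~-expression matrix. Each marker is z-scored across samples and the
score is the first right-singular direction of the samples × markers
matrix:

$$\text{rCTP}_{ik} = u_{i1} d_1, \qquad
  \text{var explained} = d_1^2 / \textstyle\sum_j d_j^2 .$$

Correlation-mode PCA (z-scored markers) rather than covariance PCA is the
declared choice: it makes the score invariant to positive rescaling of any
marker, so no highly expressed gene dominates. The SVD sign ambiguity is
resolved by requiring the loading sum to be positive, so a higher score
always means higher average marker expression. An optional iterative
removal of markers misaligned with PC1 exists in some marker-profile
implementations; it is deliberately off here (no statement supports its
use), and fewer than 3 surviving markers is treated as a failure because a
2-gene PCA is degenerate.

Marker derivation uses the fold enrichment of the in-subclass mean CPM over
the **maximum** other-subclass mean (+1 CPM pseudocount), not the mean of
others: at subclass resolution the realistic failure mode is one confusable
sibling subclass, and the max statistic is robust to exactly that. Defaults
`fold_threshold = 4`, `min_detect = 0.3`, `top_n = 50` yield tens of
markers per subclass on the synthetic reference. Markers claimed by more
than one subclass are assigned to none. Because the exact derivation
criteria used upstream of published marker sets vary, every one of these
thresholds is a visible, configurable argument.

## Bulk preprocessing protocol

The QC protocol runs in a fixed order: (1) drop genes with median expected
count ≤ 15 (strict inequality retained: a gene at exactly the threshold is
removed); (2) embed samples by classical MDS of Euclidean distances on
log~2~ CPM and drop any sample farther than 3 IQRs from the median on any
of the first 5 components — a single pass, no re-detection after removal;
(3) winsorize each gene's log~2~(count + 0.5) values into
median ± 3 IQR, computed **per gene across samples** (per-sample
winsorization would destroy gene identity), and transform back with
$2^x - 0.5$ clamped at zero; (4) TMM normalization (double-trimmed,
precision-weighted mean of log-ratios against an automatically chosen
reference sample; trims 0.3 on M and 0.05 on A); (5) mean-variance
observation weights (lowess of $\sqrt{\text{residual SD}}$ on mean log~2~
expression, inverted as trend$^{-4}$); (6) removal of technical covariates
(batch, RIN, PMI, percent mapped/usable bases) by per-gene weighted least
squares, with categorical covariates in sum-to-zero contrasts so the grand
mean survives.

Numerical choices worth noting: the MDS embedding uses log~2~(CPM + 1) — a
distance on raw counts would conflate library size with composition, and a
pure depth rescaling of a sample is deliberately *not* an outlier under
this embedding; a zero-IQR gene collapses to its median under
winsorization; TMM factors are rescaled to geometric mean one; weights fall
back to units (with a warning) below 10 genes, where the smoother is
meaningless.

## Association models

* **Cross-cohort mega-analysis** (per subclass): linear mixed model
  `rctp_z ~ AD + study + age_z + sex + (1 | subject)` fit by REML, pooling
  subject-level data across studies; the random intercept absorbs repeated
  regional samples from the same individual. Inference is a Wald z test —
  the reported two-sided p carries no degrees-of-freedom approximation, a
  deliberate and logged choice. Betas are standardized by z-scoring the
  outcome and leaving the 0/1 AD indicator unscaled, so a beta of −0.5
  reads "half an SD lower in AD". With no repeated subjects the model
  reduces to OLS (verified against `lm` to 1e-6); a singular random-effect
  fit falls back to OLS with a flag in the model tag.
* **Single-nucleus variant**: plain OLS with PMI added (nothing upstream
  removes it from snCTPs) and a dataset fixed effect; overlap between sn
  datasets is assumed negligible.
* **Phenotype battery**: 19 subclasses × 14 outcomes (11 pathologies,
  cognitive slope, cognition proximal to death, residual cognition) = 266
  OLS tests. Pathology models covary for age at death, sex, PMI; cognitive
  models for sex, education, age at baseline. FDR is controlled across the
  full 266-cell family; the Bonferroni family for the case/control analyses
  is the 19 subclasses. Ordinal measures (Braak, atherosclerosis grade) are
  modeled as continuous, matching standard practice for this battery.
* **Variance partitioning**: nested OLS models compared by likelihood-ratio
  test, with generalization-adjusted R² from the 0.632+ bootstrap (100
  iterations by default): apparent error and out-of-bag bootstrap error are
  blended with weight $w = 0.632/(1 - 0.368R)$, where the relative overfit
  $R$ is clipped to [0, 1] and the no-information error is the mean squared
  error over all response/prediction pairs.
* **Mediation**: mediator and outcome models fit by OLS, ACME = a·b, ADE =
  the outcome-model treatment coefficient, total = ACME + ADE (exact in
  the linear, no-interaction decomposition; an interaction term is
  deliberately not included by default). Uncertainty comes from a
  nonparametric row-resampling bootstrap (1000 draws by default) with
  percentile CIs and two-sided p = 2·min(frac ≤ 0, frac ≥ 0). The four
  standard configurations place SST and IT scores as predictor or mediator
  against global AD pathology (mean of diffuse plaques, neuritic plaques,
  neurofibrillary tangles), with cognition at the last visit as outcome and
  APOE ε4 dose among the covariates.

## Phenotype derivation

Consensus AD labels combine Braak stage, CERAD category, and cognition
(clinical diagnosis code, or CDR where that is the instrument): case
requires Braak ≥ 4, CERAD moderate/frequent, and impairment; control
requires Braak ≤ 3, CERAD none/sparse, and intact cognition; everything
else — including any subject with a required field missing — is "other",
with the reason logged. The cut-points are config-encoded because published
harmonizations state the ingredients rather than exact thresholds; a
neuropathology-only variant serves cohorts without antemortem cognition.

The global cognitive composite z-scores each of 17 tests against the whole
population's *baseline* means/SDs, averages within five domains (a domain
needs ≥ 50% of its tests observed), then averages the domain composites —
rather than averaging all 17 tests directly; the alternative is a config
switch. Per-subject slopes come from a mixed model with correlated random
intercepts and slopes (empirical-Bayes shrinkage, since visits are few and
noisy), not per-subject OLS. Residual cognition is the OLS residual of
last-visit cognition on the 11 pathologies plus age at death, sex, and
education — orthogonal to every regressor by construction.

## What the synthetic generator emulates — and what it does not

The generator exists so that every stage is testable against known ground
truth without any controlled-access download. It emulates: a labeled
high-depth reference in which each subclass owns a disjoint block of 20
designated markers; three bulk studies over six neocortical regions with
400 subjects, one study (MSBB-like) re-sampling the same 100 subjects in
four regions; negative-binomial counts whose expectation is the
proportion-weighted mixture of subclass signatures, with log-normal batch
effects and log-linear technical-covariate effects matching the removal
model downstream; nucleus-level cohorts drawn multinomially from the same
per-subject true proportions; and phenotypes causally linked to the latent
proportions (SST negatively loaded on every amyloid/tau measure; SST and IT
protective for the cognitive slope; IT carrying no pathology loading, so it
acts purely through cognition — the resilience configuration).

Proportions follow a logistic-normal model (Gaussian on logits with SD 0.4,
softmax-normalized) rather than a Dirichlet: AD shifts are additive on the
logit scale in units of the logit SD, so an effect of −0.5 plants a
half-SD latent deficit directly, the scale on which standardized betas are
read out. Default shifts are SST −0.5 and IT −0.45, the magnitudes of the
strongest reported bulk associations; "other"-diagnosis subjects receive
half the shift. Mean proportions follow a realistic neocortical
composition (IT ~25%, oligodendrocytes ~15%, astrocytes ~12%, SST ~4%,
vascular types ≤ 1%).

Designated markers are enriched 50-fold over background by default — the
near-exclusive regime of genuine subclass-defining genes, whose bulk signal
is dominated by their own subclass. This matters: at much weaker
enrichment, a 0.5%-abundance subclass contributes ~1% of marker-expression
variation while NB noise across 20 markers contributes ~5%, and no
deconvolution method could recover it; the generator's default is chosen so
that the designed signal stands in the realistic relation to noise.
Dispersion defaults to 0.05 with a 2 × 10⁶ mean library over 2000 genes.

The generator deliberately omits: non-compositional biological covariation
between subjects (gene-regulatory programs shared across cell types),
cross-subclass marker overlap (a stress-test flag, not the default),
gene-length/GC biases, read-level error, and the missingness patterns of
real cohorts. Passing tests therefore demonstrate correctness of the
estimators under the generative assumptions the analysis itself makes —
not performance on real tissue, where marker quality and unmodeled
covariation dominate.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the default desk scale (2000
genes, 19 subclasses, 20 markers each, 400 subjects, ~700 bulk samples),
which completes in seconds. Replicate-based calibration checks use reduced
per-replicate sizes chosen for tight Monte-Carlo error at reasonable
runtime: the mega-analysis type-I simulation runs 500 replicates of a
150-subject two-study design; mediation CI coverage runs 500 replicates at
n = 80 with 400 bootstrap draws. The single-nucleus concordance check uses
120 subjects at 1000–3000 nuclei each; the default pipeline configuration
samples 60 sn subjects at 500–2000 nuclei, mirroring the scale of real
case/control sn datasets, and accordingly shows noisier effect-vector
concordance.

## Known limitations

rCTPs are relative latent scores: monotone in abundance under the model,
but not proportions, and a rise in one score can reflect a fall in
everything else. The mediation decomposition is associational — with
cross-sectional data the "bidirectional" configurations cannot be
distinguished causally, only described. The consensus-diagnosis thresholds
and the marker-derivation criteria are declared defaults, not canonical
values. The Wald z inference in the mega-analysis is mildly anticonservative
at small subject counts; at the hundreds-of-subjects scale the package
targets, the type-I simulations show nominal calibration.
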