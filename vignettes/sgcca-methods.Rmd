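---
title: "Supervised sparse generalized CCA for multi-omics classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised sparse generalized CCA for multi-omics classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgccaDA)
```

## The model

`sgcca()` fits a supervised, sparse variant of generalized canonical
correlation analysis over Q omics blocks measured on the same samples.
The outcome enters as an extra block: the n × K indicator matrix of class
membership, column-centered. Component h maximizes the design-weighted
sum of score covariances

$$\max_{a_h^{(1)},\dots,a_h^{(Q+1)}}\ \sum_{q \ne j} c_{qj}\,
\mathrm{cov}\!\left(X_h^{(q)} a_h^{(q)},\, X_h^{(j)} a_h^{(j)}\right),
\qquad \lVert a_h^{(q)}\rVert_2 = 1,$$

with a cardinality bound `keepX` on each data block's loading vector and
the outcome block unpenalized. Covariances use the n − 1 denominator.
The model assumes blocks are sample-aligned, numeric and free of missing
values, and that the class signal is carried by a low-dimensional latent
structure shared across blocks — which is why K − 1 components
(`choose_ncomp()`) are the default: K centered class means span a
(K − 1)-dimensional space.

### Solver

Each component is fit by block-coordinate ascent. The objective is linear
in any single block's loading with gradient
$z^{(q)} = X^{(q)\top} \sum_{j \ne q} c_{qj} t^{(j)}$, so each update
reduces to a constrained linear maximization:

* **Data blocks** — soft-thresholding to cardinality: with τ the
  (k+1)-th largest |z|, the update is
  $a \propto \mathrm{sign}(z)\max(|z| - \tau, 0)$, ℓ2-normalized. This is
  the exact maximizer of $a^\top z - \tau \lVert a\rVert_1$ over the unit
  ball, and keeps exactly k features when no ties sit at τ (ties are
  resolved toward the lowest feature index, for determinism).
* **Outcome block** — the unpenalized maximizer $z / \lVert z\rVert_2$.

Two numerical choices deserve explanation because the design here was
genuinely open:

* **Monotone-ascent safeguard.** Soft-thresholding with a
  cardinality-driven τ is *not* the exact maximizer of the unpenalized
  linear subproblem (that would be hard-thresholding), and on
  noise-dominated inputs the raw update can lower the objective. Each
  data-block update is therefore accepted only if it does not decrease
  $a^\top z$; otherwise the previous feasible loading is kept. The first
  sweep always accepts, because the dense SVD warm start is not feasible
  under the cardinality constraint. With the safeguard the objective
  trace is non-decreasing by construction (the package asserts this on
  100 random instances), while on signal-dominant problems the safeguard
  never triggers and the fit is plain soft-thresholding.
* **Initialization.** Each block's loading starts at its first right
  singular vector. The outcome block's start is then refined once from
  the data-block scores before iterating: the dummy block's own singular
  vector is arbitrary with respect to the class contrast that the data
  support, and starting from it can lock a sparse update onto noise
  features. The refinement step costs one matrix-vector product and
  makes the solver recover the exhaustively-enumerated optimum on small
  signal-dominant instances (the test suite checks ≥ 99% of the best
  support's objective for p = 12, k = 3).

Convergence is declared when every block's loading moves by less than
`tol` (default 1e-6) in the max norm, up to a sign flip; `max_iter`
defaults to 100 and non-convergence is a warning, not an error. The
returned solution is put in a canonical form by a single *global* sign
flip that makes the largest-magnitude outcome loading positive. A
per-block sign convention was rejected: flipping one block alone negates
its cross-covariances with every other block and can lower the very
objective the solver just maximized.

After each component, every data block is deflated by its own scores
(X ← X − t b with b the regression coefficients of X on t), and the
outcome block likewise. The b vectors are stored so that
`sgcca_transform()` replays the exact same sequence on new samples,
which makes train-time scores and test-time projections consistent by
construction.

## Preprocessing

`nzv_filter()` removes features with zero variance or with few distinct
values (fraction of distinct values below 0.10 of n) combined with a
dominant mode (most-common to second-most-common frequency ratio above
19, i.e. 95/5). `stratified_split()` rounds per-class training counts
half away from zero and corrects any off-by-one on the largest class.
Blocks are standardized to zero mean and unit variance (n − 1
denominator) inside `sgcca()` by default, and the training statistics are
stored and re-applied to test data — standardization before a
covariance-based fit is conventional for the CCA family, and the default
is configurable (`scale = FALSE`) for users who want covariance on the
original scale.

## Design matrix, components, tuning

The block-connectivity weights come from a preliminary pairwise analysis:
for each pair of data blocks, a one-component PLS (rank-1 SVD of
X₁ᵀX₂) gives score vectors whose Pearson correlation r is floored to one
decimal, $c_{qj} = \lfloor 10\,|r| \rfloor / 10$. Flooring (rather than
rounding) reproduces both reference mappings 0.8796 → 0.8 and
0.6027 → 0.6. The input correlation matrix is symmetrized before
flooring so the rule is idempotent. Outcome links are always 1.

`tune_keepX()` tunes the per-block feature counts by repeated stratified
cross-validation (5 × 5 by default) on the *overall* misclassification
error of the full prediction path (centroid + weighted vote). Components
are tuned sequentially — component 1 with later components absent, then
frozen. Within a component the blocks are scanned coordinate-wise over
the candidate grid (the other blocks held at their current value) rather
than factorially: the factorial grid grows as |grid|^Q and adds little
on the instances we examined, and the coordinate scheme keeps the
evaluation count linear in Q. Each block's winner is then refined by
step halving around it until the step reaches 1 or the winner stops
moving. Ties always break toward the sparser model. Every evaluated
(component, block, value, error) point is returned in the tuning
surface.

## Classification

Per block, a test sample is scored on the H components and assigned the
class of the nearest centroid (Euclidean distance in score space;
distance ties go to the first class in level order). Block votes are
fused by a weighted vote in which block q's weight is

$$w_q = \frac{1}{H}\sum_{h=1}^{H}\ \max_k\ \bigl|\,\mathrm{cor}(t_h^{(q)},
\tilde Y_{\cdot k})\bigr|,$$

the mean over components of the strongest absolute correlation between
the block's training scores and a centered dummy column. The
score-outcome-correlation idea admits several aggregations (mean vs max
over classes, weighting components); this package takes max over classes
and mean over components, and records the formula in its metrics output
so downstream consumers know which reading was used. Vote ties go to the
class supported by the highest-weight block (block order breaks exact
weight ties). For ROC analysis the per-class continuous score is the
negative distance to that class's centroid — needed because a centroid
classifier does not natively produce a ranking score — and AUC is
computed as the Mann–Whitney concordance with ties counted ½.

## Consensus feature selection

`consensus_fit()` refits the model on `n_partitions` (default 30)
stratified 70/30 partitions, with partition p seeded `base_seed + p`,
keeping `keepX` fixed at its tuned value (tuning is done once, not per
partition). For every block, component and feature it records the
nonzero loadings; `select_consensus()` keeps a feature iff

* frequency > 15 and median |loading| > 0.05, or
* frequency > 10 and median |loading| > 0.2,

with strict inequalities, the median taken over the partitions where the
feature was actually selected (no zero padding — padding would conflate
"rarely selected" with "weakly loaded"). Records are kept at the
component level, since a feature can be stable on one component and not
another; the final biomarker list is the union. Each selected feature is
then assigned an outcome class per modality: expression features by a
max–min rule over pairwise differential-expression contrasts (a class
qualifies when both of its contrasts are significant with consistent
direction; its score is the smaller |logFC|; fallback to the
smallest-FDR contrast's higher-mean class, flagged low-confidence);
methylation features by the largest mean absolute beta difference to the
other classes; miRNA features (two-class setting) by the higher mean.

## Differential expression

`de_contrast()` runs the count path: genes with CPM ≤ 1 in fewer than
(smallest group size) samples are dropped; TMM normalization factors are
computed (via edgeR, 30%/5% double trimming, factors rescaled to unit
geometric mean); each gene is tested with a negative-binomial GLM with
log link and library-size offsets. The gene-level test is the
quasi-likelihood F form — deviance drop divided by the full model's
residual deviance per degree of freedom, referred to F(1, n − 2) — with
the dispersion a moment estimate (residual-df corrected) shrunk 25/75
toward the trimmed-mean common dispersion. The chi-squared reference for
the raw likelihood ratio was measured anticonservative at n = 10 per
group on null simulations, while the F form is calibrated there; the F
form is also the convention of the reference tooling for this analysis.
P-values are BH-adjusted.

Significant genes (FDR < 0.05) are then split by the sloped cut-line:
with M = max(−log10 FDR) over the contrast and c = −log10 0.05, a gene is
*positively relevant* when −log10 FDR > M + logFC·(c − M) and *negatively
relevant* when −log10 FDR > M + logFC·(log10 0.05 + M). The boundary
passes through c exactly at logFC = ±1 and through M at logFC = 0, so
only genes combining significance with fold change clear it; remaining
DEGs are labeled significant-but-not-relevant. Fold changes are log2
from group CPM with a 0.5 prior count; the lone log10(0.05) terms of the
boundary stay base-10 as defined. If M ≤ c (no gene below the
significance level) the line is degenerate; the case is flagged and no
gene can be relevant. The GSEA-ready rank metric is
−log10(p) × sign(logFC), with p = 0 clamped to the smallest positive
double.

## Correlation and survival

`pearson_matrix()` returns product-moment correlations with two-sided
p-values from t = r√(n−2)/√(1−r²). `dichotomize_expression()` estimates
a Gaussian kernel density (Silverman bandwidth, 512 grid points) and
uses the valley between the two most prominent peaks as the low/high
cutoff when at least two peaks have prominence ≥ 5% of the density
maximum, otherwise the median; values ≤ cutoff are "low". The peak
criterion and prominence fraction are configurable since density
bimodality has no canonical definition. Kaplan–Meier estimation and the
log-rank test delegate to the survival package (the package's tests pin
them to hand-computed product-limit and hypergeometric-moment values).
The simulator's survival times are exponential with rate
exp(lp)/baseline_scale; censoring is uniform on [0, c] with c solved
numerically so the expected censored fraction matches the target, which
keeps `censor_fraction` directly interpretable.

## The simulator: what it does and does not emulate

`generate_study()` draws K class means at the vertices of a regular
simplex in K − 1 latent dimensions, scaled so each latent axis has
class-mean variance `class_separation`², plus unit within-class noise.
Each block assigns its informative features to latent axes round-robin
with loading magnitude `loading_scale` and adds `noise_sd` Gaussian
noise; methylation ("beta") blocks pass the linear predictor through the
inverse logit with half the informative loadings sign-flipped, emulating
the negative expression–methylation correlations seen in tumor data;
count blocks draw negative binomials with log-mean linear in the latent
factors and dispersion 0.1 (a typical bulk RNA-seq magnitude). Defaults
— 50 samples per class, 300 features per block with 20 informative,
separation 3 — give a strongly but not trivially separated three-class
problem sized so the whole consensus analysis runs in seconds.

What passing on this generator shows: the solver finds planted sparse
structure, the classification path converts it into held-out accuracy,
consensus selection is stable, and the error rates of the statistical
tests are calibrated under their assumed models. What it does not show:
robustness to batch effects, missing values, unbalanced and tiny
classes, non-NB count dispersion trends, or annotation-level artifacts
(cross-reactive methylation probes are supported only via a
user-supplied blacklist). Conclusions about real cohorts still require
real data.

One null-behavior subtlety is worth recording: the chance-level check
for the classifier uses permuted labels on a *zero-separation* draw. A
single fixed permutation of strongly structured data inherits a chance
association between the permuted labels and the latent classes that is
shared by training and held-out folds, biasing cross-validated error
below 1 − (largest class prior); averaging over many permutations or
removing the structure eliminates it, and the latter is cheaper.

## Problem sizes and seeds

The test-suite and acceptance sizes were chosen to make the checks
statistically meaningful yet quick: 50 random instances for the SVD
oracle, 20 enumerable instances (p = 12, k = 3) for sparse optimality,
100 instances for monotonicity, the default generator (n = 150, three
300-feature blocks) with 30 partitions for consensus recovery, 5000
genes at n = 10 per group for test calibration, and 1000 replicates for
log-rank type-I error. Every stochastic step takes an explicit integer
seed; repeated partitions use `base_seed + p`, cross-validation repeats
use `seed + repeat − 1`, and `run_pipeline()` expands one master seed
into fixed stage offsets so that stages stay reproducible independently.

## Known limitations

* The solver handles complete data only; impute upstream.
* Deflation is the regression ("predictive") mode throughout; canonical
  deflation variants are out of scope.
* The centroid metric is Euclidean; a Mahalanobis variant would need
  per-class covariance estimates the selected dimensionality rarely
  supports.
* The NB test approximates the reference quasi-likelihood machinery
  (no empirical-Bayes trend); it is validated by calibration properties,
  not numerical parity.
* `component_auc()` reports one-vs-rest AUCs only.
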