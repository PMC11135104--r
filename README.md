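# sgccaDA

Supervised sparse generalized canonical correlation analysis (sGCCA) for
multi-omics classification and biomarker discovery.

Tumor classification increasingly relies on several omics layers measured
on the same patients — for gliomas, typically mRNA expression,
DNA-methylation beta values and miRNA expression, with the diagnostic
classes being astrocytoma, oligodendroglioma and glioblastoma. The
features that matter are few, correlated across layers, and class
specific. `sgccaDA` implements the full analysis path for this setting:
a supervised sparse multiblock model that selects discriminative features
in every layer simultaneously, plus the downstream characterization
(differential expression, correlation structure, survival) of the
selected biomarkers.

## The model

For Q data blocks X⁽¹⁾ … X⁽Q⁾ (samples × features, standardized) and a
column-centered class-indicator block Y, each component h solves

    max  Σ_{q≠j} c_qj · cov(X⁽q⁾ a⁽q⁾, X⁽j⁾ a⁽j⁾)
    s.t. ‖a⁽q⁾‖₂ = 1,  ‖a⁽q⁾‖₀ ≤ keepX_q

where the design matrix C = {c_qj} ∈ [0,1] weights which block pairs are
forced to covary (Y counts as one of the blocks, always fully linked to
the data). Sparsity is imposed by soft-thresholding each loading update
to a fixed feature count `keepX`, and successive components are
orthogonalized by regression deflation. The package adds, around this
core:

* a **data-driven design matrix** — pairwise one-component PLS
  correlations floored to one decimal (`r = 0.8796 → 0.8`);
* **K − 1 components** by default for K classes;
* **cross-validated tuning** of `keepX` (repeated stratified CV,
  coarse-to-fine grids);
* **prediction** by per-block centroid distance in score space, fused
  across blocks by a weighted vote (weights = score–outcome correlation);
* **consensus selection** over 30 repeated 70/30 partitions, retaining
  features by selection frequency and median absolute loading
  (frequency > 15 & median > 0.05, or frequency > 10 & median > 0.2);
* **differential expression** for count data (TMM normalization,
  negative-binomial quasi-likelihood F-test, BH adjustment, and a sloped
  significance/fold-change boundary separating *relevant* from merely
  significant genes);
* **correlation and survival screening** of selected features
  (Pearson matrices, median/density-valley dichotomization, Kaplan–Meier
  curves, log-rank tests);
* a **latent-factor simulator** producing class-structured expression,
  methylation, count and survival data with known ground truth.

## Worked example

```r
library(sgccaDA)

study <- generate_study(sim_config(seed = 42))   # 3 classes, 3 blocks
study
#> Multi-omics dataset: 150 samples, 3 block(s)
#>   mrna       300 features (20 informative)
#>   meth       300 features (20 informative)
#>   mirna      300 features (20 informative)
#> Classes: class1=50, class2=50, class3=50

split <- stratified_split(study$labels, train_frac = 0.7, seed = 42)
train <- lapply(study$blocks, function(b) b[split$train, ])
test  <- lapply(study$blocks, function(b) b[split$test, ])

fit <- sgcca(train, study$labels[split$train], keepX = 20)
fit
#> Supervised sparse generalized CCA
#>   3 block(s), 2 component(s), 3 classes (class1, class2, class3)
#>   mrna         300 features; selected per component: 20, 20
#>   meth         300 features; selected per component: 20, 20
#>   mirna        300 features; selected per component: 20, 20
#>   block weights: mrna=0.885, meth=0.897, mirna=0.883

pred <- predict(fit, test)
performance_metrics(study$labels[split$test], pred$class)$accuracy
#> [1] 1
```

Each block keeps 20 features per component (its sparse loading vector),
and the block weights near 0.9 say that every layer's component scores
track the class outcome strongly, so each layer gets a comparable say in
the weighted vote. Held-out accuracy is 1 on this strongly separated
simulation.

Stability selection over 30 partitions, checked against the simulator's
planted truth:

```r
cons <- consensus_fit(study$blocks, study$labels, keepX = 20, ncomp = 2,
                      n_partitions = 30, base_seed = 42)
cons
#> Consensus fit over 30 partitions: mean test accuracy 1.000
sel <- select_consensus(cons$records)
sapply(names(study$truth), function(q) {
  s <- unique(sel$feature[sel$block == q])
  length(intersect(s, study$truth[[q]])) / length(union(s, study$truth[[q]]))
})
#>  mrna  meth mirna
#>     1     1     1
```

The consensus table keeps exactly the 20 planted informative features in
every block (Jaccard 1 against truth). `run_pipeline()` chains all of the
stages (simulate/load → filter → split → design → tune → fit → evaluate →
consensus → differential expression → survival) behind one configuration
list and writes every artifact plus a manifest to a run directory.

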