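# eplearn

Supervised learning of enhancer–promoter (EP) specificity from genome-wide
CRISPRi perturbation screens integrated with chromatin assays.

Massively parallel CRISPRi screens silence candidate enhancers and call an
EP pair *functional* when the target gene is significantly down-regulated
(adjusted p < 0.1). At genome scale these data are brutally imbalanced
(≈ 2% positives) and confounded with detectability. `eplearn` is for
computational genomicists who want a tested, leakage-free pipeline that

- enumerates candidate pairs within a 5-Mb window and engineers the feature
  families that matter: the activity-by-contact score
  `ABC(e,p) = A_e C_ep / Σ_{e'} A_{e'} C_{e'p}`, focal-versus-neighborhood
  relative contact (`diff.from.max.contact.to.TSS`, contact ranks),
  remaining-contact sums, element-density counts, histone/expression
  signals, and per-TF binary presence at both sides;
- labels every pair by its distance in a promoter-centric chromatin
  interaction network (ChIN) built from significant loops — `e0` (same
  Hi-C bin), `e1`/`e2`/`e3` (1–3 edges through enhancer intermediates
  only), `einf` — and splits direct (`e1minus`) from indirect (`e2plus`)
  contacts;
- splits data without genomic leakage: 5-Mb-gap single-linkage groups,
  chromosome holdout, and a 4 × 4 nested blocked CV with group-preserving,
  positive-stratified greedy packing;
- clusters TF co-binding with non-negative matrix factorization (per side),
  adding `TF_NMF<i>_e` / `TF_NMF<i>_TSS` cluster scores;
- trains per-fold XGBoost classifiers with unit-interval scaling,
  Boruta-style shadow-feature selection scored by tree-SHAP, random-search
  tuning maximizing inner-fold mean average precision, and early stopping —
  everything fitted strictly inside the outer training split;
- attributes predictions with exact tree-SHAP, ranks features by mean
  |SHAP|, and evaluates with average precision, confusion at matched recall
  (0.70), ABC and inverse-distance baselines, gene-conditioned filtering,
  density-stratified error proportions, and weak/strong contact partitions.

A synthetic-genome generator (`simulate_ep_dataset()`) reproduces the
statistical structure of such screens — distance-decaying contact, clustered
element density, block-structured TF co-binding, insensitive promoters,
calibrated 2% prevalence — so the entire pipeline is testable offline.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "eplearn", load_package = "installed")'
```

## Worked example

```r
library(eplearn)

sim <- simulate_ep_dataset(sim_config(seed = 1))   # ~21,000 candidate pairs
fz  <- featurize_ep_dataset(sim, nmf_k = 5)

labeled <- label_positives(sim$ep)                 # adjusted p < 0.1, down only
keep    <- !is.na(sim$ep$adj_p)
feats   <- fz$features[keep]
groups  <- ep_groups(labeled, assign_groups(sim$elements, gap_bp = 5e6))
ho      <- chromosome_holdout(labeled, c("chr5", "chr10", "chr15"))

fit <- run_ep_pipeline(feats[!ho], labeled$label[!ho], groups[!ho],
                       pipeline_config(seed = 1))
fit
#> ep_pipeline_fit: 4 folds, out-of-fold AP per fold: 0.275, 0.302, 0.283, 0.334

hs <- predict_holdout(fit, feats[ho])
average_precision(hs$mean, labeled$label[ho])
#> [1] 0.2701939
average_precision(baseline_scores(labeled[ho], "inverse_distance"),
                  labeled$label[ho])
#> [1] 0.1843944

head(fit$ranking, 5)
#>                 feature mean_abs_shap
#> 1:             distance     0.3106786
#> 2: normalized_H3K27ac_e     0.2617518
#> 3:            abc_score     0.2502987
#> 4:            TF_NMF5_e     0.2458946
#> 5:              contact     0.1830319
```

At ≈ 2% prevalence, a held-out average precision of 0.27 is a ~14× lift
over random and well above the inverse-distance baseline (0.18); the
ranking recovers the planted drivers — distance, enhancer H3K27ac, contact
(directly and through the composite ABC score), and the causal TF cluster
surfacing as its enhancer-side NMF component (`TF_NMF5_e` here).

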