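---
title: "Predicting functional enhancer-promoter pairs: models and methods"
author: "eplearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting functional enhancer-promoter pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eplearn)
library(data.table)
```

## The problem

Massively parallel CRISPRi enhancer screens assay thousands of candidate
enhancer-promoter (EP) pairs: an enhancer is silenced, and the pair is called
*functional* when the target gene shows significant down-regulation (adjusted
p < 0.1; up-regulation is never counted as positive). Genome-wide screens of
this kind are extremely imbalanced — on the order of 2% positives — and the
positives are confounded with detectability: highly expressed genes and
strongly contacted enhancers are easier to call. `eplearn` implements a
supervised pipeline that learns EP specificity from such screens integrated
with chromatin assays (histone marks, Hi-C contact, TF ChIP-seq), and an
interpretation layer that asks *which* genomic features carry the signal.

The package is organized around eight stages: data input, synthetic-genome
simulation, feature engineering, chromatin-interaction-network (ChIN)
labeling, genomically blocked cross-validation, NMF TF co-binding clustering,
gradient-boosted learning with shadow-feature selection and Shapley
attribution, and imbalance-aware evaluation.

## Feature engineering

For every gene, candidate enhancers are enumerated within a 5-Mb window
(center-to-center distance at most `window_bp / 2 = 2.5` Mb; the boundary is
closed). Whether "a 5-Mb window" means a 5-Mb total span or ±5 Mb is
genuinely ambiguous; the package uses the total span and makes it a
configuration knob. The same half-window defines every "neighborhood" below —
there is deliberately a single window parameter.

The feature families, all computed per EP pair:

* **Activity-by-contact (ABC) score.** With enhancer activity $A_e$ (we use
  the normalized H3K27ac signal) and KR-normalized Hi-C contact $C_{ep}$,

  $$\mathrm{ABC}(e,p) = \frac{A_e\,C_{ep}}{\sum_{e' \in \mathcal{C}(p)} A_{e'}\,C_{e'p}},$$

  where $\mathcal{C}(p)$ is the candidate set of promoter $p$. Scores of one
  promoter sum to 1 whenever the denominator is positive; a zero denominator
  yields all-zero scores rather than NaN.
* **Relative contact.** For the focal contact versus its two neighborhoods
  (all enhancers of the focal promoter; all promoters of the focal enhancer):
  the neighborhood maximum, the difference from that maximum
  (`diff.from.max.contact.to.TSS`, `diff.from.max.contact.from.enhancer`;
  zero exactly when the focal contact is the strongest), and the dense rank
  of the focal contact (rank 1 is strongest, ties share the better rank).
* **Remaining contact.** `remaining.TSS.contact.from.enhancer` and
  `remaining.enhancers.contact.to.TSS` sum the contacts from the focal
  element to all *other* partners in its window.
* **Density.** `Enhancer.count.near.TSS` and `TSS.count.near.enhancer` are
  region totals within the half-window; the focal element is counted, so
  both are at least 1 on candidate rows.
* **Signals.** Histone marks at both sides (H3K27ac, H3K4me3, H3K27me3),
  target gene expression, genomic distance, and the focal contact itself.
* **TF presence.** One binary column per TF and side (`<TF>_e`, `<TF>_TSS`);
  a peak marks an enhancer when the half-open intervals overlap (abutting
  intervals do not), and a promoter when it overlaps the TSS ± 500 bp. The
  500-bp promoter flank is a package default; no published value exists.
* **NMF cluster scores.** See below.

Contact is looked up between the Hi-C bins containing the element midpoints;
the bin size defaults to 5 kb (common ABC practice) and is configurable, as
no resolution is prescribed by the data formats themselves. Every
neighborhood feature is validated in the test suite against a naive
all-pairs loop implementation on small instances, and is invariant to row
order by construction.

## ChIN distance classes

Per promoter, a chromatin interaction network is built: nodes are the
promoter and the screen-tested enhancers, edges are Hi-C contacts that
survive a loop-significance filter, weighted by contact. Each EP pair is
then classed by graph distance:

* `e0` — enhancer and promoter share a contact bin (this test precedes the
  graph test);
* `e1`, `e2`, `e3` — shortest path of length 1, 2, 3 from the promoter,
  where **all intermediate nodes must be enhancers** (a promoter never
  mediates);
* `einf` — farther than 3 or unreachable.

`e1minus` (= `e0` ∪ `e1`, direct contact) and `e2plus` (the rest) partition
the data for the direct/indirect analyses. Shortest-path semantics make node
revisits irrelevant. The labeling is tested against exhaustive enumeration
of enhancer-mediated simple paths on hundreds of random graphs.

The primary loop filter consumes an external loop caller's q-values
(`q < 0.05`). A builtin fallback — keep the top fraction of contact within
log-spaced distance bins — exists only so the pipeline can run
self-contained, and is flagged as `builtin` in its output.

## Blocked nested cross-validation

Nearby EP pairs share features and must never straddle a train/test
boundary. Elements are grouped by single-linkage along each chromosome with
a 5-Mb gap rule; a pair inherits its endpoints' groups, and bridging pairs
merge groups (union-find), preserving the separation guarantee. Whole
chromosomes (defaults: 5, 10, 15, 20) are held out as an independent test
set; the remainder is split into a 4 × 4 nested blocked CV. Groups are
packed into folds greedily — positives balanced first, then sizes, with a
seeded shuffle breaking ties; groups without positives are placed purely by
size, since they cannot help stratification. This deterministic packing
replaces a library group-stratified splitter with the same contract: groups
stay intact, positives spread approximately evenly. The suite asserts the
leakage invariant directly: across seeded synthetic genomes, no two pairs in
different outer folds have same-chromosome elements closer than the gap.

## Learning

Per outer fold, strictly inside the training split:

1. **Scaling** to the unit interval by training min/max; constant columns
   map to 0; unseen rows are *not* clipped, so out-of-range test values stay
   visible.
2. **Shadow-feature selection.** Each of `boruta_rounds` rounds appends a
   permuted shadow copy of every feature, trains a preliminary booster, and
   scores features by mean |tree-SHAP|; a feature hits when it beats the best
   shadow. Hits above the upper binomial(n, ½) quantile are confirmed,
   below the lower quantile rejected, the rest tentative and kept by default
   — conservative under 2% prevalence, where weak signal is easily discarded.
   The preliminary boosters use fixed moderate defaults (depth 4, learning
   rate 0.1, 40 rounds) rather than their own search, fit each round on a
   stratified row subsample (every positive plus random negatives, capped at
   8000 rows) with importances read from a further 3000-row sample:
   selection only needs importances that are roughly right, and under
   extreme imbalance the positives carry the signal, so this keeps the
   stage cheap without changing what gets confirmed.
3. **Tuning.** Random search (depth 2–10; learning rate 0.005–0.3
   log-uniform; min child weight, L1/L2 log-uniform; subsamples 0.5–1;
   positive-class weight up to the negative/positive ratio), each candidate
   scored by mean average precision across the inner folds with early
   stopping on each inner validation split; the default parameter set is
   always candidate 1, so the search can never do worse than the default.
4. **Training** with early stopping (patience `early_stop_rounds = 25`) on
   one inner fold, using the same average-precision metric as tuning.
5. **Attribution.** Exact tree-SHAP values on the held-out outer fold; the
   four folds' matrices are combined by concatenation (never by averaging
   models — per-fold models are intentionally kept separate to expose
   performance variance). Features are ranked by mean |SHAP|.

A poisoning test pins the no-leakage property: filling an outer test fold
with sentinel values leaves that fold's fitted bundle bit-identical.

## Evaluation

Average precision (the non-interpolated mean of precision at each positive's
rank, ties resolved by stable order) is the scalar metric throughout — under
extreme imbalance it is far more informative than ROC area. Models are also
compared at a matched operating point: the largest threshold reaching recall
≥ 0.70, where confusion counts, precision, and false-positive rate are
reported (undefined ratios are `NA`, never 0). Baselines are the ABC score
and inverse genomic distance. Further slices: genes with at least one
positive pair (where TF features are expected to stop helping),
density-stratified error proportions, and weak/strong contact partitions at
0.002 (class analysis) or 0.005 (distribution splits) — both thresholds are
configuration presets.

## The synthetic genome generator

No public screen data ships with the package; instead `simulate_ep_dataset()`
emulates the *statistical structure* the pipeline assumes, with defaults
chosen once to mirror the study conditions:

* 16 chromosomes × 15 Mb, 1920 enhancers + 576 TSSs placed by an
  inhomogeneous point process (250-kb tiles with log-normal weights;
  `density_heterogeneity` is the log-sd, 0 = uniform) — yielding ≈ 21,000
  candidate pairs, matching the ≈ 20,000-pair, 2%-prevalence regime of
  genome-wide screens and giving the blocked CV enough groups;
* contact decaying as $(d/5\,\mathrm{kb})^{-1}$ from 0.02 at the 5-kb
  reference, log-normal multiplicative noise (sd 0.5), symmetric, zero
  beyond the window;
* 30 TFs in 5 planted co-binding clusters (presence probability 0.7 within
  an element's active clusters, 0.05 background);
* 15% of promoters flagged *insensitive* — robust to enhancer perturbation —
  with 3× elevated H3K27ac/H3K4me3 at the TSS;
* labels drawn from a planted logit
  $a + 1.0\,\log(1+1000\,C) + 1.0\,A_e + 1.5\,(-\log_{10} d) - 3.0\,\mathrm{insens} + 2.0\,s_{\mathrm{TF}}$,
  with the intercept calibrated by bisection so the mean success probability
  equals the 2% target exactly (no rejection sampling); `-log distance` is
  implemented base-10 so a coefficient is an effect per distance decade;
* adjusted p-values consistent with the labeling rule (positives uniform
  below 0.1 with direction `down`; negatives with direction `down` drawn
  above 0.1, since a sub-threshold down-regulated "negative" would
  contradict the rule); 5% of pairs get missing p, emulating untested pairs.

The insensitivity flag is deliberately *latent*: the learner sees only its
correlated promoter marks, so perfect prediction is impossible — mirroring
the real ceiling. What passing tests show is therefore that the pipeline
recovers planted structure under realistic imbalance, decay, and blocking;
they do not show real-data performance, which depends on screen noise,
batch structure, multi-TSS genes (one gene per TSS here), and inter-assay
biases the generator does not model.

## Numerical and degenerate-input policies

* Duplicate contact rows are summed (with a warning on read) — deterministic
  and order-independent; inter-chromosomal rows are skipped with a warning.
* Zero ABC denominators give zero scores; undefined evaluation ratios give
  `NA`; an empty significant-edge set yields promoter-only ChINs and `einf`.
* NMF minimizes squared Frobenius error by multiplicative updates, 5 seeded
  restarts keeping the best, stopping at relative improvement < 1e-8; the
  scale indeterminacy is resolved by normalizing H rows to unit maximum.
  Error is non-increasing over iterations (asserted to 1e-10).
* Dense ranks break ties toward the better rank; argmax ties are broken by
  element id; all fits are single-threaded with explicit seeds, so every
  result in the package is bit-reproducible within one build.
* Single-class validation splits fall back from `aucpr` to `logloss` for
  early stopping; inner folds without positives are dropped from the tuning
  mean; a selection round that rejects every feature falls back to keeping
  all of them with a warning.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the default generator size
(≈ 21,000 pairs, 10 seeds for the stochastic recovery check), the ChIN
oracle on 500 random graphs of up to 12 nodes, the leakage invariant on 100
small clustered genomes, and the feature oracle on instances of ≤ 50
elements. These sizes are the package's choices for routine validation;
larger genomes only change runtimes, not the properties under test.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_ep_dataset(sim_config(seed = 1))
fz  <- featurize_ep_dataset(sim, nmf_k = 5)

labeled <- label_positives(sim$ep)
keep    <- !is.na(sim$ep$adj_p)
feats   <- fz$features[keep]
groups  <- ep_groups(labeled, assign_groups(sim$elements, gap_bp = 5e6))
ho      <- chromosome_holdout(labeled, c("chr5", "chr10", "chr15"))

fit <- run_ep_pipeline(feats[!ho], labeled$label[!ho], groups[!ho],
                       pipeline_config(seed = 1))
hs  <- predict_holdout(fit, feats[ho])
average_precision(hs$mean, labeled$label[ho])
head(fit$ranking, 8)
```

## Known limitations

* The builtin loop filter is a stand-in, not a loop caller; real analyses
  should supply external loop significance calls.
* One gene per TSS; no multi-TSS genes, no strand awareness anywhere.
* The generator plants a single causal TF cluster and log-linear effects; it
  cannot falsify interactions the model might exploit in real data.
* Per-fold models are reported separately by design; no ensembling or
  refitting on combined folds is provided.
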