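---
title: "Methods: ensemble gene selection, GAN augmentation and boosted classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble gene selection, GAN augmentation and boosted classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microarray cohorts for rare cancers are tiny: the motivating design is a
15-sample ovarian study — 5 benign tumors (OVT), 5 stage-I cancers
(OVC_I), 5 stage-III cancers (OVC_III) — measured on 9,600 cDNA clones.
Two things make such data hard: the gene-to-sample ratio (~640:1) makes
single-model feature selection unstable, and any classifier trained on
10 samples per fold is starved for data. `ovaboost` implements a
pipeline that attacks both: an *ensemble* of feature selectors whose
agreement filters out selector-specific noise, and *class-conditional
generative augmentation* that enlarges training folds without ever
contaminating test folds.

## The selection model

Three gradient-boosted tree learners each run recursive feature
elimination (RFE) from the full gene universe down to 30 genes. The
boosted model is the standard additive ensemble
$\hat y_i = \sum_{j=1}^{m} f_j(x_i)$ fit by gradient boosting with a
regularized cost $\sum_i \mathrm{loss}(y_i, \hat y_i) + \pi(f)$; we
treat it as a pluggable backend (xgboost) and do not reimplement tree
construction. What distinguishes the three learners is the importance
criterion that drives elimination:

| learner kind    | criterion               | meaning |
|-----------------|-------------------------|---------|
| `gbdt`          | weight                  | how often a gene is split on |
| `catboost_like` | prediction value change | mean absolute change in predicted class probabilities when the gene's column is permuted |
| `xgboost_like`  | gain                    | total loss reduction contributed by the gene's splits |

A learner kind is defined by its criterion, not by a vendor
implementation; one backend exposing all three criteria serves all
three kinds.

Each RFE iteration refits the surviving genes and removes the
`ceiling(step_fraction * surviving)` lowest-importance genes (default
`step_fraction = 0.1`, floor of one gene, never dropping below the
target size). The final 30 survivors are ordered by final-model
importance with ties broken by the previous iteration's importance,
then by gene id.

**Elimination tie-breaks are randomized per learner.** Ties in
importance are almost always blocks of genes no tree ever used
(importance exactly 0). A fixed lexicographic rule would make all three
learners retain the *same* zero-importance padding genes, and the
downstream consensus vote would read that shared padding as multi-
learner agreement — we observed planted-gene recovery capped at 7/10
because 3-vote padding outranked genuine 2-vote signal genes. Ties are
therefore broken by a random key derived from the learner seed: still
fully deterministic given the seed, but decorrelated across learners,
so padding genes cannot reach two votes.

**Column subsampling is on by default** (`colsample = 0.3` per tree).
With several redundant discriminative genes, a boosted model fit on all
columns concentrates importance on whichever gene it happens to split
on first and starves the rest, so RFE discards genes that are
individually informative but shadowed by a correlated partner.
Sub-unit column sampling — a standard boosting device — forces trees to
spread splits across the redundant set. The remaining hyperparameters
default to 200 trees, depth 3, learning rate 0.1: small, because the
intended regime is tens of samples.

## Consensus voting

A gene enters the candidate pool only if it appears in at least 2 of
the 3 subsets. Candidates are ranked by vote count, then by mean
normalized rank — position $r$ (1-based) in a subset of size $m$ scores
$(r-1)/(m-1)$, and $0$ when $m = 1$ — then by gene id. Normalized ranks
are used because the three raw importance scales (split counts,
probability changes, gains) are incommensurable; comparing ranks is the
scale-free alternative. The top 10 candidates form the panel. When
fewer than 10 genes reach 2 votes the panel is returned *short* with a
warning; it is never padded with single-vote genes, because "appears in
at least two subsets" is the defining property of the method.

## The augmentation GAN

The augmentation model is a class-conditional GAN with an auxiliary
classifier head. The generator maps a one-hot class vector $c$
concatenated with Gaussian noise $z$ to an expression vector over the
panel; the discriminator maps an expression vector to a source
probability $P(\mathrm{source}=\mathrm{real})$ and a class distribution
$P(c)$. Training maximizes, for the discriminator,

$$ \mathrm{Loss}_x = \mathbb{E}\log P(x{=}\mathrm{real}\mid X_\mathrm{real})
                  + \mathbb{E}\log P(x{=}\mathrm{fake}\mid X_\mathrm{fake}), $$
$$ \mathrm{Loss}_c = \mathbb{E}\log P(c{=}c_\mathrm{true}\mid X_\mathrm{real})
                  + \mathbb{E}\log P(c{=}c_\mathrm{intended}\mid X_\mathrm{fake}). $$

For the generator two objectives are available. The default
(`ac_gan_standard`) ascends
$\mathbb{E}\log P(x{=}\mathrm{real}\mid X_\mathrm{fake}) +
\mathbb{E}\log P(c{=}c_\mathrm{intended}\mid X_\mathrm{fake})$, the
non-saturating auxiliary-classifier form. The literal alternative
(`paper_literal`) *descends* $\mathrm{Loss}_x + \mathrm{Loss}_c$, which
rewards the generator for fakes being *mis*classified by the class head
— at odds with the purpose of conditioning on $c$. Both are
implemented; the default follows the construction that makes the class
head useful, and we take no stance on which a given description "really
meant".

### Numerical and stability choices

The networks are two-hidden-layer perceptrons (32 units, leaky
rectifiers, linear generator output) trained with Adam on features
standardized per gene over the training fold; all gradients are
computed analytically and were verified against central finite
differences to 1e-10. Probabilities are clamped at $10^{-7}$ before
logs. Four devices stabilize the adversarial game at fold sizes of ~10
samples per class, where a vanilla GAN either collapses its variance or
orbits the target in a limit cycle:

* **Instance noise** (`instance_noise = 0.5`): Gaussian noise added to
  both real and fake discriminator inputs, linearly annealed to zero,
  keeps the two input distributions overlapping early in training.
* **Learning-rate decay**: the Adam step size anneals linearly to zero,
  damping the oscillation radius.
* **Generator weight averaging**: samples are drawn from an
  exponential moving average (decay 0.995) of the generator weights,
  i.e. from the center of the residual orbit rather than a random
  point on it.
* **Class-conditional moment matching** (`moment_weight = 20`): the
  generator objective adds a penalty on the squared gap between
  generated and real per-class feature means and variances (on the
  standardized scale). Purely adversarial training matched
  class-conditional means only to within ~1 within-class SD at these
  fold sizes; with the penalty, ~90% of gene-class means land within
  0.5 within-class SD. The penalty touches only the generator, not the
  discriminator's game.

Fake batches mirror the real batch's class composition, so the
generator is never asked for a class absent from the training fold (a
class with fewer than 2 fold samples is an error — augmentation must
not invent unseen classes). Sampling is deterministic given a seed, and
generated vectors are returned on the original expression scale with an
immutable synthetic-origin flag. An optional discriminator-confidence
filter rejects vectors whose class probability for the intended class
falls below a threshold, with bounded retries; together with the
moment diagnostics this concretizes "validating the generated data".

## Leakage-safe evaluation

Evaluation is stratified k-fold cross-validation (default $k = 3$;
folds deal each class round-robin after a seeded shuffle, with a
rotating starting fold so remainders spread evenly). Inside each fold:
the GAN is trained *from scratch on the training fold only* (seed
derived from the run seed and fold index), synthetic samples — 10 per
real training sample of each class by default — are appended to the
training fold, each learner is fitted, and the held-out fold is
predicted by soft voting (mean of class-probability vectors, argmax,
ties to the earliest class in class order). Test folds contain original
samples only; a synthetic id intersecting a test fold is a hard
assertion failure, not a warning, and the report asserts exactly one
prediction per original sample. Pooled accuracy (total correct / n) is
reported rather than the mean of fold accuracies because it stays
well-defined with unequal folds; per-fold numbers are logged anyway.

Gene selection runs once on the full dataset before cross-validation,
following the method's single-pass flow (selection, then augmentation,
then evaluation); nothing in the flow iterates, so the pipeline's
"stopping" rule is simply that each stage runs exactly once. Because
selection sees all samples, the cross-validated accuracy estimates the
performance of the *selected panel*, not of the full selection
procedure — the usual optimism of out-of-fold selection applies and is
deliberate fidelity to the method being implemented.

## Clustering verification

The selected panel is verified unsupervised: k-means (Euclidean, 10
restarts keeping the lowest within-cluster sum of squares) and
agglomerative clustering (Ward/average/complete linkage on Euclidean
distances, tree cut at $K$ = class count) on gene-standardized data.
"Agglomerative" and "hierarchical" clustering are treated as one family
— agglomerative with a dendrogram export (newick) — since nothing
distinguishes them algorithmically here; default linkage is Ward.

Cluster-to-class scoring reports three numbers: **purity** (fraction of
samples in their cluster's majority class, $\sum_k \max_c n_{kc} / n$),
**aligned accuracy** (matched fraction under the best cluster-to-class
bijection when $K = C$, majority mapping otherwise — what a printed
cluster-vs-stage table measures), and the **adjusted Rand index**.
Purity and aligned accuracy differ exactly when two clusters share a
majority class, which is why both are reported. Substage labels (IA,
IC, IIIB, IIIC) are collapsed through an explicit grouping map before
scoring, making the stage-level 100% claim computable and transparent.

## The synthetic-data generator

`simulate_expression()` emulates the study design so every stage is
testable without any external download: by default 9,600 genes, 3
classes of 5 samples. Values are Gaussian log-intensity-like (per-gene
baseline ~ N(7, 1), within-class SD 1). Genes form consecutive
equicorrelated blocks (size 10, correlation 0.3) mimicking co-expressed
modules. A planted set of informative genes (20 by default) is placed
at evenly spaced positions — one per block where possible — and
receives class means evenly spaced by `effect` within-class SDs along
the class order, a stage-progression-like signal that also gives
clustering a 3-group structure. The generator does **not** model
two-channel dye effects, missing spots, heavy tails, or batch
structure; passing tests therefore demonstrate correctness of the
machinery on well-behaved data, not robustness to real microarray
artifacts.

## Problem sizes used in the test suite

The packaged checks run the method at a reduced but structurally
faithful scale, chosen as the smallest sizes at which each property is
meaningfully exercised: selection recovery on 500 genes, 3 classes x 20
samples, 10 planted genes at 3 SD (5 seeds); GAN fidelity on a 10-gene
panel's training folds (3 seeds); chance-level calibration with
permuted labels (20 seeds, 1,200 pooled predictions); the separability
ceiling at 5 SD; and the printed 15-sample cluster-vs-stage table,
which is reproduced exactly.

## Known limitations

* The three learner kinds share one tree-boosting backend; they differ
  by importance criterion and seed, not by vendor-specific tree
  algorithms (ordered boosting, oblivious trees).
* Cross-learner importance aggregation by normalized ranks is a design
  choice; raw importance scales cannot be compared directly and no
  canonical cross-learner definition of "most important" exists.
* The GAN matches first and second class-conditional moments well at
  tiny n; higher-order structure (skew, multimodality within a class)
  is neither targeted nor verified.
* With 5-per-class cohorts, 3-fold stratification leaves 1–2 samples
  per class per fold; accuracy granularity is coarse (1/15) and
  reported fractions should be read alongside the exact counts the
  report carries.
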