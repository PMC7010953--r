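---
title: "Two-stage mRMR + IFS feature selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage mRMR + IFS feature selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmrifs)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, the numerical conventions, and the limitations a user should keep
in mind. The worked numbers shown are computed by the code in this
document; nothing here is asserted that the test suite or the acceptance
script does not itself compute.

## The procedure

The input is a genes × samples expression matrix `X` with continuous
values on a common scale (the motivating setting is L1000 landmark-gene
profiles of cancer cell lines), plus a binary phenotype `t` per sample
(positive class encoded explicitly as 1 — for instance KRAS-mutant — and
typically rare, a few percent of samples).

**Stage 1: mRMR ranking on discretized expression.** Mutual information
needs discrete variables, so each gene is reduced to three states relative
to its own distribution: state 0 below `mean − t·sd`, state 2 above
`mean + t·sd`, state 1 between, with threshold `t = threshold_sigma = 0.5`
by default. Relevance of gene *g* is the plug-in mutual information
`D(g) = I(g, t)` in bits; redundancy of *g* against the already-ranked set
Ω_s of size *m* is the mean `R(g) = (1/m) Σ I(g, g_i)`. Genes are ranked
greedily by the difference criterion: rank 1 is the relevance argmax
(redundancy is zero for an empty Ω_s), and each later rank maximizes
`D(g) − R(g)` over the unranked genes. The top 200 ranks (`top_n`) pass to
stage 2.

**Stage 2: incremental feature selection.** For every prefix size
`k = 1..max_k` (default 200, capped at the ranked-list length) and every
classifier family, the classifier is trained on the *continuous* expression
of the top-k genes and evaluated by leave-one-out cross-validation; the
prefix with the best Matthews correlation coefficient is the selected
panel, and the best peak across families wins. Six families are supported —
SVM, 1/3/5-nearest-neighbour, decision tree, neural network — through the
same packages a working analyst would use (`e1071`, `class`, `rpart`,
`nnet`).

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `threshold_sigma` | 0.5 | half-width, in per-gene SD units, of the middle discretization band. 0.5 is the convention of the classical C/C++ mRMR implementation; smaller values push mass to the extreme states, larger values toward the middle state. Ranking is invariant to positive affine transforms of expression for any fixed value. |
| `top_n` | 200 | stage-1 cut. Large enough that the IFS peak is interior in practice; the IFS stage is what actually fixes the panel size. |
| `max_k` | 200 | largest prefix evaluated in stage 2. |
| kNN `k` | 1, 3, 5 | the three kNN families. Odd k with binary labels cannot produce a vote tie among exactly k neighbours. Euclidean distance on raw values — L1000-style data is on a common scale; `scale_features = TRUE` enables per-feature z-scaling for sensitivity analysis. |
| SVM | RBF, cost 1, gamma 1/p | the `e1071::svm` defaults, including its feature scaling; all exposed as hyperparameters. |
| neural net `size` | 5 | `nnet` has no default hidden-layer size; 5 units is a modest capacity for ≤ 200 inputs. `decay = 0`, `maxit = 100` (the `nnet` default), fit under the spec's fixed seed. |
| `seed` | per `classifier_spec` / config | every stochastic step (neural-net initialization, kNN tie sampling in the naive path, synthetic generation) runs under an explicit seed; identical spec + data + seed gives identical predictions. |

Mutual information uses the plug-in (maximum-likelihood) estimator with
base-2 logs and the `0·log 0 = 0` convention, no small-sample bias
correction — matching the classical implementation. The difference (MID)
form of the criterion is the one implemented; the quotient (MIQ) variant is
not.

## Metrics and degenerate cases

From LOOCV confusion counts: `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
`ACC = (TP+TN)/N`, and
`MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. MCC is the
headline metric because it stays honest under the ~24:1 class imbalance
this method targets: a classifier that calls everything negative scores
`ACC ≈ 0.96` but `MCC = 0`. When any factor of the MCC denominator is zero
(a degenerate predictor), MCC is defined as 0 — real data rarely hits this,
but synthetic null runs do. Reports round to 3 decimals; full precision is
kept internally. For example:

```{r}
metrics(confusion_matrix(TP = 131, FN = 25, FP = 10, TN = 3572))
```

## Numerical choices

* **Greedy tie-break.** The argmax at each mRMR step takes the lowest
  input gene index among candidates whose scores are within 1e-9 bits of
  the step maximum. The tolerance matters: two genes whose joint tables are
  permutations of each other have *exactly* equal criteria in exact
  arithmetic, yet their floating-point scores can differ by a few ulps
  depending on summation order. A strict `which.max` would let those ulps
  decide the ranking.
* **Zero-variance genes** discretize to the all-middle state, get
  relevance 0, and can never occupy rank 1 unless every gene is constant.
* **Missing values are rejected at load**, not imputed: imputation would
  silently move mutual-information estimates.
* **kNN LOOCV caching.** Naive LOOCV refits per fold; for kNN this is
  wasteful, so the default path computes one full distance matrix and, in
  `build_curve`, grows squared distances gene-by-gene across prefixes (an
  O(n²) update per k instead of O(n²·k)). The cached path is
  prediction-identical to naive per-fold `class::knn` on continuous data
  and the suite asserts bit-identity on a 50-sample fixture; the one
  behavioural difference is exact distance ties (probability zero for
  continuous features), where the cached path votes among all tied
  neighbours and resolves a tied *vote* toward the negative class
  deterministically, while `class::knn` samples.
* **LOOCV degeneracy.** A class with exactly one member would produce a
  single-class training fold; this is a hard error naming the fold rather
  than a silently skipped sample.

## The synthetic-data generator

`generate_expression_data()` emulates the statistical structure the
analysis assumes, at any scale: every gene is Gaussian with SD `noise_sd`;
`n_informative` genes shift their mean by `effect_size · noise_sd` in the
positive class; each of `n_redundant_blocks` redundant genes is a parent
informative gene's realized values plus Gaussian noise calibrated against
the parent's empirical spread so the empirical correlation hits
`block_correlation` (within ±0.05 at n ≥ 500 in the test suite); all other
genes are class-independent noise. Default dimensions mirror the motivating
cohort — 978 genes, 156 positive and 3,582 negative samples — because the
imbalance is central to the metric choice; the remaining defaults
(`n_informative = 10`, `effect_size = 1.5`, `n_redundant_blocks = 5`,
`block_correlation = 0.8`, `noise_sd = 1`) describe a modest, realistic
signal: a small panel of moderately shifted genes among noise, with enough
redundancy to exercise the mRMR penalty.

What it does **not** emulate: bead-array technical artifacts, perturbation
structure, heavy-tailed or multimodal expression, gene–gene correlation
beyond the planted blocks, or label noise. Passing tests on this generator
therefore show the pipeline recovers planted structure under its own
model assumptions — they do not certify performance on any particular real
cohort.

Two calibrated behaviours worth knowing, both exercised by the suite at
pilot-verified thresholds:

* *Parameter recovery.* With 120 genes, 60/540 samples and 8 informative
  genes at `effect_size = 2`, the selected peak panel contains ≥ 6 of the
  8 planted genes in ≥ 9 of 10 seeded replicates (kNN families,
  `max_k = 120`).
* *Redundancy demotion.* With a single strong informative gene
  (`effect_size = 2.5`, 1,000 samples) and one `r = 0.95` near-duplicate,
  the duplicate sits directly under its parent in univariate relevance but
  is strictly demoted by mRMR in 20 of 20 seeded replicates. The sample
  size matters: the construction needs the duplicate's systematic
  information loss (state flips induced by the added noise) to dominate
  sampling noise, otherwise the duplicate occasionally *beats* its parent
  empirically and, as the new relevance argmax, cannot be demoted by
  definition.

A small-scale run, as in the README:

```{r, eval = FALSE}
cfg <- synthetic_config(n_genes = 120, n_pos = 60, n_neg = 540,
                        n_informative = 8, effect_size = 2,
                        n_redundant_blocks = 4, block_correlation = 0.9,
                        seed = 42)
d <- generate_expression_data(cfg)
ranked <- mrmr_rank(discretize(d$expression), d$labels, top_n = 120)
curve <- build_curve(ranked, d$expression, d$labels,
                     families = c("1NN", "3NN", "5NN"), max_k = 40)
select_best(curve)
plot_ifs_curve(curve)
```

The suite and the acceptance script run at these desk scales (hundreds of
samples, ~120 genes) rather than the full 978 × 3,738 cohort; the method
itself is scale-free and the full-cohort path is the documented optional
script `inst/scripts/reproduce_gse83744.R`.

## Design choices where the design was open

* **Ranking once, outside the CV loop.** mRMR runs once on the full data
  set; LOOCV cross-validates classifier *training* only. This mirrors the
  two-stage procedure as practiced (rank first, then build the prefix
  classifiers), and it is the major caveat of the whole approach: the
  feature ranking has seen every sample, so IFS-peak MCCs are optimistically
  biased relative to a fully nested CV. Treat the reported peak as a model
  selection signal, not an unbiased generalization estimate.
* **Classifiers see continuous expression.** Discretization exists only to
  make mutual information computable in stage 1; the cited kNN/SVM
  implementations operate on continuous inputs, so the IFS stage feeds them
  raw expression.
* **IFS peak ties go to the smaller k** (parsimony), and across families to
  the smaller panel, then the earlier family in declaration order. Any
  other rule would be equally defensible; this one is deterministic and
  favours compact panels.
* **No class reweighting.** Imbalance is handled by *measuring* with MCC,
  not by resampling or reweighting the classifiers — consistent with the
  procedure this package operationalizes.
* **Orientation and labels.** Genes-as-rows is canonical; the loader's
  `transpose` flag accepts the other orientation. The positive class is
  explicit (1), never inferred from level order or prevalence.

## Known limitations

* The selection-bias caveat above is the big one.
* LOOCV for the non-kNN families is genuinely N-fold refitting: SVM or
  neural-net curves over hundreds of prefixes at thousands of samples are
  expensive; the family subset flag exists for exactly that reason.
* The plug-in MI estimator is biased upward at small n (visible as small
  positive relevance for null genes); ranking, which compares genes at
  equal n, is largely unaffected, but absolute bit values should not be
  over-interpreted.
* With three discretization states the method is insensitive to
  within-band expression differences by construction; a gene whose signal
  lives entirely inside ± 0.5 SD of its mean will be missed by stage 1
  regardless of classifier.
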