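# mrmrifs

Two-stage feature selection for expression biomarker discovery: **mRMR**
gene ranking by mutual information, followed by **incremental feature
selection (IFS)** under leave-one-out cross-validation.

## The problem

Given a gene × sample expression matrix (for example, 978 L1000 landmark
genes over a few thousand cancer cell lines) and a binary phenotype (for
example, KRAS mutation status, with mutants a rare ~4% positive class), the
goal is a *compact* gene panel that predicts the phenotype well. Univariate
filters pick genes that are individually informative but collectively
redundant; wrapper searches over all subsets are intractable. The two-stage
procedure implemented here threads that needle:

**Stage 1 — mRMR ranking.** Expression is discretized gene-by-gene into
three states (below mean − t·σ, within, above mean + t·σ; default t = 0.5)
and relevance is measured by mutual information. With Ω_s the set of m
already-selected genes, the next gene g<sub>j</sub> maximizes

> I(g<sub>j</sub>, t) − (1/m) Σ<sub>g<sub>i</sub>∈Ω<sub>s</sub></sub> I(g<sub>j</sub>, g<sub>i</sub>)

— maximal relevance to the class label t, minimal mean redundancy with what
is already chosen (the MID, difference, form of the criterion). Repeating N
times yields a full ranking S = {g′₁, …, g′_N}; the top 200 go to stage 2.

**Stage 2 — IFS.** For k = 1, 2, …, 200 a classifier is trained on the
top-k gene prefix and scored by leave-one-out cross-validation (LOOCV).
Performance is summarized by sensitivity, specificity, accuracy and — since
the classes are heavily imbalanced — primarily the Matthews correlation
coefficient,

> MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

The peak of the MCC-versus-k curve fixes the panel size; the best peak
across six classifier families (SVM, 1NN, 3NN, 5NN, decision tree, neural
network — via `e1071`, `class`, `rpart`, `nnet`) picks the final panel.

A synthetic-data generator with planted class-informative genes and
correlated (redundant) gene blocks makes every stage testable end to end
without any external download.

## Worked example

Simulate a 120-gene screen (60 positive / 540 negative samples, 8 planted
informative genes at a 2σ mean shift, 4 redundant genes at r = 0.9), rank,
and size the panel:

```r
library(mrmrifs)

cfg <- synthetic_config(n_genes = 120, n_pos = 60, n_neg = 540,
                        n_informative = 8, effect_size = 2,
                        n_redundant_blocks = 4, block_correlation = 0.9,
                        seed = 42)
d <- generate_expression_data(cfg)

ranked <- mrmr_rank(discretize(d$expression), d$labels, top_n = 120)
head(ranked, 5)
#>   rank gene_id relevance redundancy score
#> 1    1   g0044     0.154     0.0000 0.154
#> 2    2   g0098     0.146     0.0203 0.126
#> 3    3   g0105     0.143     0.0258 0.117
#> 4    4   g0028     0.135     0.0300 0.105
#> 5    5   g0024     0.139     0.0376 0.101

curve <- build_curve(ranked, d$expression, d$labels,
                     families = c("1NN", "3NN", "5NN"), max_k = 40)
(best <- select_best(curve))
#> 3NN peak: MCC = 0.991 with 8 genes

sum(d$truth$informative %in% best$gene_ids)
#> [1] 8
```

The ranking columns are the stage-1 quantities: `relevance` is I(g, t) in
bits, `redundancy` the mean MI with the genes ranked above it at its
selection step, `score` their difference. The peak selection reads: the
3-nearest-neighbour classifier attains its best LOOCV MCC, 0.991, with the
top 8 genes — and those 8 are exactly the planted informative genes.
`plot_ifs_curve(curve)` draws the MCC-versus-k curves per family.

Metric arithmetic from a published-style confusion matrix:

```r
metrics(confusion_matrix(TP = 131, FN = 25, FP = 10, TN = 3572))
#> Sn = 0.840  Sp = 0.997  ACC = 0.991  MCC = 0.879
```

An end-to-end run with artifacts (ranked list, IFS curve TSV + figure,
report, manifest with checksums) is one call:
`run_pipeline("config.yaml")` — see `?run_pipeline` for the config schema,
and `inst/scripts/mrmrifs.R` for a command-line wrapper with
`run` / `simulate` / `rank` / `ifs` / `evaluate` verbs.

## Documentation

The methods vignette (`vignettes/two-stage-feature-selection.Rmd`) covers
the model and its assumptions, parameter defaults and their rationale, what
the synthetic generator does and does not emulate, numerical conventions
(tie-breaks, degenerate cases), and known limitations — including the
selection-bias caveat of ranking genes once on the full data set outside
the cross-validation loop.
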