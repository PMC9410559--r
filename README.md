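# pirnarank

Learning-to-rank prediction of piRNA–disease associations.

Piwi-interacting RNAs (piRNAs, 24–31 nt small non-coding RNAs) are
increasingly linked to human disease, but confirmed piRNA–disease
associations are sparse. What a researcher needs from a predictor is a
short, reliable ranked list of candidate diseases for each piRNA of
interest — a retrieval problem, not a pair classification problem.
pirnarank implements that view end to end, for two settings:

* **missing-association**: the query piRNA is known and some of its
  associations are known; rank its remaining candidate diseases;
* **cold start**: the query piRNA is newly detected; only its sequence is
  available.

## The method

Association features for a pair (p, d) combine two similarity spaces —
normalized Smith–Waterman sequence similarity among piRNAs,

  S_P(p_i, p_j) = SW(p_i, p_j) / sqrt(SW(p_i, p_i) · SW(p_j, p_j)),

and Wang-style semantic similarity among diseases over the ontology DAG,

  S_D(m, n) = Σ_{i ∈ T_m ∩ T_n} (S_m(i) + S_n(i)) / (Σ S_m + Σ S_n),

with semantic values decaying by 0.5 per is_a edge. Four component scorers
are trained on the benchmark pairs: neighbourhood collaborative filtering
(guilt-by-association over the most similar piRNAs, leakage-free by
self-exclusion), ridge logistic regression, a random forest, and a
calibrated linear SVM. Their stacked 4-vector Q(p,d) = (V_CF, V_LR, V_RF,
V_SVM) is the feature space of a LambdaMART listwise ranker — gradient
boosted regression trees driven by pairwise lambda gradients weighted by
|ΔNDCG@k|, so the top of each per-query ranking is optimized directly.
Evaluation is grouped and macro-averaged per query piRNA: AUC, AUPR,
NDCG@k, MAP and the truncated ROC-k retrieval score.

A self-contained synthetic benchmark generator (mutation-derived sequence
families, a rooted disease ontology with clustered leaves, and a planted
family → disease-cluster block association structure) makes every stage
testable without downloads.

## A worked example

Cold-start ranking on the default synthetic benchmark (300 piRNAs in 30
sequence families, 20 diseases in 5 ontology clusters):

```r
library(pirnarank)
cfg   <- synthetic_config(seed = 7)
seqs  <- generate_sequences(cfg)
dag   <- generate_ontology(cfg)
assoc <- generate_associations(seqs, dag, cfg)

res <- run_pipeline(pipeline_config(seqs, dag, assoc,
                                    scenario = "pirna-wise", seed = 7))
print(res$report)
#> evaluation_report: 58 queries evaluated, 2 skipped (no positive)
#>     auc    aupr  ndcg@5 ndcg@10     map   roc@1   roc@3   roc@5  roc@10
#>  0.9162  0.7630  0.8007  0.8360  0.7630  0.4776  0.7130  0.7909  0.8734
```

60 piRNAs were held out as "newly detected" and ranked over all 20
diseases from their sequences alone. Macro AUC 0.92 and NDCG@5 0.80 mean
the planted family signal is recovered: for a typical held-out piRNA most
of its true diseases appear in the top 5 of its ranked list. The fitted
ranker and its reliance on each component are inspectable:

```r
print(res$fit$model)
#> LambdaMART ranker: 30 trees (k = 15, shrinkage = 0.1, leaves <= 29)
feature_usage(res$fit$model)
#>  cf  lr  rf svm
#> 319 206 102 213
head(res$predictions[[1]], 3)
#>     pirna  disease    score rank
#> 1 f01_m03 DOID:1.1 1.754601    1
#> 2 f01_m03 DOID:1.4 1.754601    2
#> 3 f01_m03 DOID:1.2 1.548490    3
```

The collaborative-filtering score is the most used split feature — on
this benchmark the local sequence-neighbourhood signal is what carries
the block structure.

Other entry points: `pirank()` (the fitting function behind
`run_pipeline()`), `lambdamart()` (the ranker alone, with `predict()`,
`summary()`, `plot()`, text-format persistence), `cross_validate()`,
`grid_search()` (coordinate-wise hyperparameter search by CV macro AUPR),
and a thin command-line wrapper `inst/scripts/pirnarank` with subcommands
`simulate`, `similarity`, `split`, `components`, `train`, `predict`,
`evaluate`, `cv`, `gridsearch`, `run`.

See `vignettes/ranking-pirna-disease.Rmd` for the full model description,
parameter semantics and design rationale.

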