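---
title: "Ranking candidate diseases for piRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate diseases for piRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Piwi-interacting RNAs (piRNAs) are 24–31 nt small non-coding RNAs with
growing evidence of disease involvement, but experimentally confirmed
piRNA–disease associations are sparse: a few thousand known pairs over
thousands of piRNAs and a few tens of diseases. For a biologist the useful
output is not a yes/no classification of every pair but a short, reliable
ranked list of candidate diseases per piRNA of interest. pirnarank
therefore treats the task as grouped information retrieval — each query
piRNA is a "query", its candidate diseases are the "documents" — and
optimizes the quality of the top of each per-query ranking directly.

Two application scenarios are supported:

* **missing-association** (`"association-wise"`): the query piRNA is known,
  some of its associations are known, and we rank the *remaining* candidate
  diseases;
* **cold start** (`"pirna-wise"`): the query piRNA is newly detected and has
  no known associations at all; only its sequence is available.

## The model

### Association features

Two similarity spaces are combined.

*Sequence similarity.* For piRNAs $p_i, p_j$ the normalized Smith–Waterman
similarity is
$$S_P(p_i,p_j) = \frac{SW(p_i,p_j)}{\sqrt{SW(p_i,p_i)\,SW(p_j,p_j)}},$$
where $SW$ is the exact local-alignment dynamic program with a uniform
match reward, mismatch score and linear gap penalty. With a positive match
reward this quantity lies in $[0,1]$ and equals 1 exactly for identical
sequences. Scoring defaults are match $+2$, mismatch $-1$, gap $-1$ —
deliberately the simplest scheme with positive self-scores; all three are
configurable through `alignment_scoring()`. Gap treatment is linear, not
affine: at 24–31 nt there is little room for multi-symbol gap structure,
and the exact DP stays trivially fast without heuristic seeding.

*Disease similarity.* Diseases live in an ontology DAG connected by
`is_a` edges. Each term $n$ assigns a semantic value to itself and its
ancestors, $S_n(n)=1$ and $S_n(i)=\max\{0.5\,S_n(j) : j \in
\mathrm{children}(i) \text{ on a path to } n\}$, and two terms are compared
by their shared-ancestor mass:
$$S_D(m,n)=\frac{\sum_{i\in T_m\cap T_n}(S_m(i)+S_n(i))}
{\sum_{j\in T_m}S_m(j)+\sum_{j\in T_n}S_n(j)}.$$
The decay factor is fixed at 0.5 (exposed as the `decay` argument). The
maximum in $S_n(i)$ runs only over children of $i$ that lie on a path to
$n$ — the value is undefined for others. Multi-root ontologies are
accepted; terms with disjoint ancestries get similarity 0.

The feature vector of a pair $(p,d)$ is the concatenation
$F(p,d)=\{S_P(p,\cdot), S_D(d,\cdot)\}$ of the piRNA's similarity profile
against the *benchmark* (training-side) piRNAs and the disease's profile
against all candidate diseases. Using benchmark piRNAs as the fixed
reference columns in both scenarios is what makes the cold-start case
well-defined: a newly detected piRNA's features are computable from its
sequence alone.

### Component scorers

Four scorers map a pair to an association score in $[0,1]$:

* **CF** — neighbourhood collaborative filtering on the piRNA side:
  $$V_{CF}(p,d) = \frac{\sum_{p'\in N(p)} S_P(p,p')\,A(p',d)}
  {\sum_{p'\in N(p)} S_P(p,p')},$$
  where $A$ holds the benchmark labels and $N(p)$ is the `cf_k_neighbors`
  (default 20) most similar benchmark piRNAs excluding $p$ itself. The
  self-exclusion guarantees a benchmark pair's own label can never leak
  into its CF score. The neighbourhood bound is essential, not cosmetic:
  normalized local-alignment similarity between two *unrelated* short RNAs
  over a 4-letter alphabet has a substantial baseline (around 0.5), so an
  average weighted over the whole reference set is dominated by hundreds
  of uninformative baseline neighbours and degenerates into a disease
  prevalence estimate. Guilt-by-association is local by nature; 20
  neighbours is about twice a typical sequence-family size and a standard
  user-KNN scale in the recommender literature. `k_neighbors = Inf`
  recovers the global average.
* **LR** — L2-regularized logistic regression (ridge penalty $1/n$).
* **RF** — random forest with 80 trees, at most 10 terminal nodes per tree
  and 20% of features tried per split.
* **SVM** — linear-kernel SVM whose decision values are mapped to
  probabilities by a Platt-style logistic sigmoid fitted on the training
  decision values.

The classifiers are trained on all benchmark pairs with no class
rebalancing. The stacked score vector
$Q(p,d)=(V_{CF},V_{LR},V_{RF},V_{SVM})$, in this fixed order, is all the
ranker ever sees — the raw high-dimensional features are deliberately not
passed through, keeping the ranker a 4-feature model whose split structure
is directly interpretable (`feature_usage()`, `plot()` on the model).

By default the benchmark pairs that train the ranker are scored by
classifiers trained on those same pairs; `score_mode = "out-of-fold"`
replaces them with 5-fold out-of-fold scores for users concerned about
training-score optimism. CF needs no such mode — it is leakage-free by
construction.

### The listwise ranker

`lambdamart()` implements gradient-boosted regression trees driven by
lambda gradients. Ranking quality is measured by NDCG at a truncation
level $k$: with binary gains,
$$DCG@k=\sum_{i=1}^{k}\frac{2^{rel_i}-1}{\log_2(i+1)}, \qquad
NDCG@k = DCG@k / IDCG@k .$$
Each boosting round computes, within every query group and for every
(positive, negative) candidate pair,
$$\rho_{ij} = \frac{1}{1+e^{\sigma(s_i-s_j)}},\qquad
\lambda_{ij} = \sigma\,\rho_{ij}\,|\Delta NDCG@k(i,j)|,$$
where $|\Delta NDCG@k|$ is the change from swapping the two candidates in
the current score-sorted order (stable ties by input position).
$\lambda_{ij}$ accumulates positively on the positive candidate and
negatively on the negative one; second-order weights
$\sigma^2\rho(1-\rho)|\Delta NDCG@k|$ accumulate on both. One
variance-reduction regression tree is fitted per round on the pooled
samples (greedy best-first splitting up to `n_leaves`, Newton leaf values
$\sum\lambda/(\sum w + 10^{-9})$) and added with shrinkage. Query groups
without a positive label have undefined ideal DCG and are excluded from
training, but remain rankable at prediction time. Training is
deterministic: there is no row or feature subsampling (with only four
features there is nothing useful to subsample), and the recorded seed is
reserved for future stochastic options.

Scenario presets for `(n_trees, k, shrinkage, n_leaves)` are
`(120, 14, 0.22, 3)` for the missing-association scenario and
`(30, 15, 0.10, 29)` for cold start — the tuned operating points for the
two settings. The coordinate-wise search that produces such points is
available as `grid_search()`: one parameter is optimized at a time by mean
cross-validated macro AUPR in the order trees → k → shrinkage → leaves,
with the not-yet-optimized three starting from `(10, 0.10, 10)`. Because
component scores do not depend on ranker hyperparameters, each fold's
component stack is computed once and only the ranker is retrained per
evaluated point — numerically identical to full retraining, and the trace
length is the *sum* of grid sizes, not their product.

Models persist as a versioned human-readable text format
(`write_lambdamart()`/`read_lambdamart()`), so ensembles can be inspected,
diffed and ported across languages; a write/read round trip is exact.

## Evaluation

All criteria are computed per query piRNA over that query's evaluation
pairs only, then arithmetic-averaged across queries ("macro"):

* **AUC** — Mann–Whitney statistic with half credit for score ties;
* **AUPR** — non-interpolated average precision over the score-sorted
  pairs;
* **NDCG@k** — as above, for a configurable set of k;
* **MAP** — mean precision at the rank of each positive;
* **ROC-k** — the truncated ROC score standard in ranked retrieval:
  $\frac{1}{kT}\sum_{i=1}^{k}t_i$ with $t_i$ the number of positives
  ranked above the $i$-th negative and $T$ the total positives. Fewer than
  $k$ negatives truncate and renormalize; a list with no negative scores 1.

Queries without a positive cannot be scored by any of these and are
skipped and counted, never zero-filled; AUC additionally requires a
negative. MAP is computed from the discrete ranking and AUPR from the
scores — identical whenever scores are distinct. `evaluate(pooled = TRUE)`
additionally reports AUC/AUPR pooled over all pairs, since macro and
pooled averages answer different questions when query sizes differ.

Ties everywhere keep candidate input order (stable sorts); only AUC uses
the half-credit tie convention.

## The synthetic benchmark

`synthetic_config()` + `generate_benchmark()` produce self-contained
fixtures with the statistical structure the method assumes — sequence
similarity predicts shared diseases:

* **families**: 30 families × 10 members (default); each family has a
  random seed sequence of length 24–31 nt and members are per-position
  substitution mutants at rate 0.08 (~2 substitutions per copy), so
  within-family similarity (~0.9) clearly exceeds the unrelated-pair
  baseline (~0.55). An optional indel rate makes harder fixtures.
* **ontology**: a rooted tree, by default depth 2 with per-level branching
  (5, 4): five cluster subtrees of four leaf diseases each, 20 candidate
  diseases. Leaves in the same subtree are semantically closer than leaves
  across subtrees, mirroring how related diseases share ontology ancestry.
* **associations**: each family is assigned one disease cluster
  round-robin; a pair is positive with probability `p_in = 0.7` inside the
  family's cluster and `p_out = 0.02` outside. Setting `p_in = p_out`
  yields a negative control in which sequence structure carries no
  information about the labels.

Everything is a pure function of `(config, seed)`, byte-for-byte.

What the generator deliberately does **not** emulate: piRNA biology
(genomic clusters, ping-pong signatures), the heavy-tailed degree
distribution of real disease databases, and disease-prevalence
heterogeneity. The last point matters for interpreting component
behaviour: the feature map $F(p,d)$ is additive between the piRNA block
and the disease block, so a *linear* scorer (LR, linear SVM) induces the
same disease ordering for every query and its per-query ranking power on
this symmetric synthetic data is near chance. On real data, where disease
degrees differ by orders of magnitude and disease profiles interact with
the label distribution, linear components carry real signal. Passing the
synthetic recovery tests therefore demonstrates that the pipeline
mechanics recover a planted sequence-family → disease-cluster signal
(driven mainly by CF and the forest), not that every component is
individually strong on real data.

Label noise also caps attainable scores: with `p_in = 0.7`, 30% of
in-block pairs are negatives indistinguishable from positives by any
block-structure model, so even the oracle block indicator reaches only
macro AUC ≈ 0.92 on the default fixture. Observed pipeline values around
0.90 (missing-association) should be read against that ceiling.

## Reference splits and their arithmetic

`split_associations()` draws `floor(f·N)` of the positives and,
independently, of the unknown pairs into the independent set (association
scenario); `split_pirnas()` draws `floor(f·n)` whole piRNAs (cold-start
scenario). The floor convention reproduces the reference benchmark's
published composition exactly: from 5002 positives over 4350 × 21 pairs at
f = 0.2, the independent set receives 1000 positives and 17269 unknowns
(benchmark keeps 4002 / 69079), and the piRNA-wise split yields 3480
known vs 870 newly-detected piRNAs. Unknown pairs are *all* non-positive
pairs — no negative subsampling.

## Numerical choices

* Ridge logistic regression: the configured iteration cap is calibrated
  in solver outer iterations (default 300); the coordinate-descent backend
  counts much cheaper passes, so the effective cap is
  `max(1e5, lr_iteration_cap)` passes to guarantee convergence.
* SVM: optimizer tolerance 0.01; Platt calibration is fitted on training
  decision values rather than by internal cross-validation — same
  calibration family at a fraction of the cost, and fully deterministic.
* Degenerate inputs: a similarity of 0 is returned when no positive-scoring
  local alignment exists; CF returns 0 on an all-zero neighbourhood; NDCG
  returns 0 when the ideal DCG is 0; queries that cannot be scored are
  skipped and counted.
* All randomness (splits, fold assignment, classifier seeds, generator)
  flows from explicit integer seeds; identical configuration + seed gives
  bit-identical outputs, including written files.

## Problem sizes used by the tests and the acceptance script

Unit tests run on a small planted benchmark (8 families × 4 members,
8 diseases). The end-to-end recovery checks use the full default fixture
(300 piRNAs, 20 diseases) across 5 generator seeds per condition in the
test suite, and 3 seeds per condition in `scripts/acceptance.R` — the
package's chosen replicate counts for, respectively, the tighter
statistical claim and the quick reproduction run.

## Known limitations

* The exact DP is quadratic per pair; all-against-all similarity is
  O(n² L²). Fine for thousands of short sequences (it is C++ under the
  hood), but heuristic seeding would be needed far beyond that scale.
* The CF neighbourhood size is a fixed default, not tuned per dataset.
* Ranker hyperparameter presets are operating points for the reference
  benchmark scale; other datasets should re-run `grid_search()`.
* ROC-k has no single universal definition; the one implemented (area up
  to the k-th false positive, normalized) is the ranked-retrieval
  standard, and comparisons with numbers computed under another reading
  should be made with care.
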