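#' Component classifier configuration
#'
#' Hyperparameters for the three classification-based component scorers.
#' Defaults follow the reference protocol: logistic regression capped at 300
#' solver iterations; a random forest of 80 trees, at most 10 leaf nodes per
#' tree and 20% of features tried per split; a linear-kernel SVM with
#' Platt-style probability calibration.
#'
#' @param lr_iteration_cap Iteration cap for the logistic-regression solver.
#'   The ridge backend counts cheap coordinate-descent passes, so caps below
#'   1e5 passes are raised to that floor to guarantee convergence.
#' @param rf_n_trees Number of random-forest trees.
#' @param rf_max_leaf_nodes Maximum terminal nodes per tree.
#' @param rf_feature_fraction Fraction of features tried at each split.
#' @param svm_cost SVM soft-margin cost.
#' @param svm_tolerance SVM optimizer stopping tolerance.
#' @param cf_k_neighbors Collaborative-filtering neighbourhood size (see
#'   [cf_scores()]).
#' @param seed Integer seed controlling every stochastic component.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(lr_iteration_cap = 300L, rf_n_trees = 80L,
                              rf_max_leaf_nodes = 10L,
                              rf_feature_fraction = 0.2,
                              svm_cost = 1, svm_tolerance = 0.01,
                              cf_k_neighbors = 20L, seed = 1L) {
  stopifnot(lr_iteration_cap > 0, rf_n_trees > 0, rf_max_leaf_nodes > 0,
            rf_feature_fraction > 0, rf_feature_fraction <= 1, svm_cost > 0,
            cf_k_neighbors >= 1)
  structure(list(lr_iteration_cap = as.integer(lr_iteration_cap),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_max_leaf_nodes = as.integer(rf_max_leaf_nodes),
                 rf_feature_fraction = rf_feature_fraction,
                 svm_cost = svm_cost, svm_tolerance = svm_tolerance,
                 cf_k_neighbors = cf_k_neighbors,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build per-pair association features
#'
#' The feature vector of a (piRNA, disease) pair is the piRNA's similarity
#' profile against the reference piRNAs concatenated with the disease's
#' semantic-similarity profile against all diseases; the label comes from the
#' association matrix.
#'
#' @param sp_rows Similarity matrix whose rows cover every queried piRNA and
#'   whose columns are the fixed reference piRNAs.
#' @param sd Disease semantic similarity matrix.
#' @param pairs Two-column matrix of (piRNA id, disease id) or of integer
#'   indices into `labels`.
#' @param labels Binary association matrix supplying the pair labels.
#' @return A list with `x` (feature matrix, one row per pair), `label`
#'   (integer 0/1), `pirna`, `disease` (character ids).
#' @export
build_pair_features <- function(sp_rows, sd, pairs, labels) {
  pairs <- resolve_pairs(pairs, labels)
  pi_id <- rownames(labels)[pairs[, 1L]]
  di_id <- colnames(labels)[pairs[, 2L]]
  miss <- setdiff(unique(pi_id), rownames(sp_rows))
  if (length(miss)) stop("no similarity row for piRNA(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  miss_d <- setdiff(unique(di_id), rownames(sd))
  if (length(miss_d)) stop("no similarity row for disease(s): ",
                           paste(utils::head(miss_d, 5L), collapse = ", "))
  x <- cbind(sp_rows[pi_id, , drop = FALSE], sd[di_id, , drop = FALSE])
  rownames(x) <- NULL
  list(x = x, label = labels[pairs], pirna = pi_id, disease = di_id)
}

# Accept either id pairs or index pairs; return an integer index matrix.
resolve_pairs <- function(pairs, labels) {
  pairs <- as.matrix(pairs)
  if (is.character(pairs))
    pairs <- cbind(match(pairs[, 1L], rownames(labels)),
                   match(pairs[, 2L], colnames(labels)))
  if (anyNA(pairs)) stop("pair refers to unknown piRNA or disease id")
  storage.mode(pairs) <- "integer"
  pairs[, 1:2, drop = FALSE]
}

#' Collaborative-filtering association scores
#'
#' Guilt-by-association neighbourhood score on the piRNA side: the score of a
#' pair (p, d) is the similarity-weighted average of the benchmark labels of
#' d across p's nearest benchmark neighbours,
#' `V_CF(p,d) = sum_{p' in N(p)} S_P(p,p') A(p',d) /
#' sum_{p' in N(p)} S_P(p,p')`, and 0 when the denominator vanishes.
#' `N(p)` is the `k_neighbors` most similar benchmark piRNAs other than `p`
#' itself (ties at the cutoff are all kept; `k_neighbors = Inf` uses every
#' neighbour). A bounded neighbourhood keeps the score local: normalized
#' local-alignment similarity between unrelated short RNAs has a substantial
#' baseline, and averaging over the whole reference set would dilute the few
#' informative close neighbours into that baseline. The query's own label
#' never enters its score (self-similarity is excluded), so benchmark pairs
#' are scored without label leakage.
#'
#' @param bench_labels Binary association matrix restricted to benchmark
#'   labels (independent-set positives set to 0), rows = benchmark piRNAs.
#' @param sp_rows Similarity of each queried piRNA (rows) against the
#'   benchmark piRNAs (columns, matching `rownames(bench_labels)`).
#' @param pairs Two-column matrix of (piRNA id, disease id) pairs to score,
#'   ids or indices into `bench_labels`' dimnames... queried piRNAs need not
#'   be benchmark piRNAs (cold start).
#' @param k_neighbors Neighbourhood size (default 20; `Inf` = every
#'   benchmark piRNA).
#' @return Numeric vector of scores in `[0, 1]`, one per pair.
#' @export
cf_scores <- function(bench_labels, sp_rows, pairs, k_neighbors = 20L) {
  stopifnot(identical(colnames(sp_rows), rownames(bench_labels)),
            k_neighbors >= 1)
  w <- sp_rows
  self <- match(rownames(w), colnames(w))
  has_self <- which(!is.na(self))
  w[cbind(has_self, self[has_self])] <- 0
  if (is.finite(k_neighbors) && k_neighbors < ncol(w)) {
    for (i in seq_len(nrow(w))) {
      cut <- sort(w[i, ], decreasing = TRUE)[[k_neighbors]]
      w[i, w[i, ] < cut] <- 0
    }
  }
  num <- w %*% bench_labels
  den <- rowSums(w)
  sc <- num / ifelse(den == 0, 1, den)
  sc[den == 0, ] <- 0
  pi_id <- if (is.character(pairs[, 1L])) pairs[, 1L] else
    rownames(bench_labels)[as.integer(pairs[, 1L])]
  di_id <- if (is.character(pairs[, 2L])) pairs[, 2L] else
    colnames(bench_labels)[as.integer(pairs[, 2L])]
  sc[cbind(match(pi_id, rownames(sc)), match(di_id, colnames(sc)))]
}

#' Train the three classification component scorers
#'
#' Fits (i) an L2-regularized logistic regression, (ii) a random forest with
#' capped leaf count, and (iii) a linear SVM whose decision values are
#' Platt-calibrated with a logistic sigmoid fitted on the training decision
#' values, all on the benchmark pair features. Each scorer maps a feature
#' vector to a class-1 probability.
#'
#' @param features Output of [build_pair_features()] on the benchmark pairs.
#' @param config A [classifier_config()].
#' @return An object of class `component_scorers`: list of three predict
#'   closures (`lr`, `rf`, `svm`), each `function(x) -> probabilities`.
#' @export
train_classifiers <- function(features, config = classifier_config()) {
  y <- features$label
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  x <- features$x
  yf <- factor(y, levels = c(0L, 1L))
  n <- nrow(x)

  lr_fit <- with_seed(config$seed, glmnet::glmnet(
    x, yf, family = "binomial", alpha = 0, lambda = 1 / n,
    standardize = FALSE, maxit = max(1e5, config$lr_iteration_cap)))
  rf_fit <- with_seed(config$seed, randomForest::randomForest(
    x, yf, ntree = config$rf_n_trees, maxnodes = config$rf_max_leaf_nodes,
    mtry = max(1L, floor(config$rf_feature_fraction * ncol(x)))))
  svm_fit <- with_seed(config$seed, e1071::svm(
    x, yf, kernel = "linear", cost = config$svm_cost,
    tolerance = config$svm_tolerance, scale = FALSE))
  dv <- drop(attr(stats::predict(svm_fit, x, decision.values = TRUE),
                  "decision.values"))
  platt <- suppressWarnings(stats::glm.fit(cbind(1, dv), y,
                                           family = stats::binomial()))
  platt_coef <- platt$coefficients

  structure(list(
    lr = function(x) drop(stats::predict(lr_fit, x, type = "response")),
    rf = function(x) stats::predict(rf_fit, x, type = "prob")[, "1"],
    svm = function(x) {
      d <- drop(attr(stats::predict(svm_fit, x, decision.values = TRUE),
                     "decision.values"))
      stats::plogis(platt_coef[[1L]] + platt_coef[[2L]] * d)
    },
    config = config), class = "component_scorers")
}

#' Stack the four component scores
#'
#' Assembles the per-pair score vector in the fixed order (CF, LR, RF, SVM).
#'
#' @param scorers A `component_scorers` object from [train_classifiers()].
#' @param cf Numeric CF score per pair, aligned with `features` (same pairs,
#'   same order).
#' @param features Pair features from [build_pair_features()].
#' @return Numeric matrix, one row per pair, columns
#'   `c("cf", "lr", "rf", "svm")`, with `pirna`/`disease`/`label` attached as
#'   attributes.
#' @export
score_pairs <- function(scorers, cf, features) {
  if (length(cf) != nrow(features$x))
    stop("cf scores and features cover different pair sets")
  q <- cbind(cf = as.numeric(cf),
             lr = scorers$lr(features$x),
             rf = scorers$rf(features$x),
             svm = scorers$svm(features$x))
  rownames(q) <- NULL
  structure(q, pirna = features$pirna, disease = features$disease,
            label = features$label)
}

#' Export component scores as TSV
#'
#' @param q Score matrix from [score_pairs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_component_scores <- function(q, path) {
  utils::write.table(
    data.frame(pirna = attr(q, "pirna"), disease = attr(q, "disease"),
               v_cf = q[, "cf"], v_lr = q[, "lr"], v_rf = q[, "rf"],
               v_svm = q[, "svm"], label = attr(q, "label")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
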