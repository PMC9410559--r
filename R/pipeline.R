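#' Fit the stacked piRNA-disease ranking model
#'
#' End-to-end training on the benchmark side of a split: computes the
#' normalized Smith-Waterman similarity matrix among benchmark piRNAs and
#' the Wang semantic similarity matrix among diseases, builds per-pair
#' association features, trains the four component scorers (collaborative
#' filtering plus LR / RF / SVM), stacks their scores, and fits the
#' LambdaMART ranker on the benchmark query groups. Reference piRNA columns
#' are always the benchmark piRNAs, so newly detected piRNAs can be scored.
#'
#' @param seqs Named character vector of piRNA sequences covering at least
#'   the benchmark piRNAs.
#' @param dag An `ontology_dag` covering all diseases of `assoc`.
#' @param assoc Binary association matrix (piRNAs x diseases).
#' @param split A `benchmark_split` from [split_associations()] or
#'   [split_pirnas()].
#' @param scoring An [alignment_scoring()] scheme.
#' @param components A [classifier_config()].
#' @param ranker A [ranker_config()]; defaults to the preset matching the
#'   split's scenario.
#' @param use_cf Include the collaborative-filtering component (set `FALSE`
#'   for the machine-learning-only ablation; the ranker then stacks only
#'   LR / RF / SVM).
#' @param score_mode How classifier scores for the benchmark pairs (the
#'   ranker's training features) are produced: `"in-sample"` (default)
#'   scores them with the classifiers trained on those same pairs;
#'   `"out-of-fold"` scores each benchmark pair with classifiers trained on
#'   the other folds (`score_folds`-fold, label-stratified), for users
#'   concerned about training-score optimism. Independent pairs are always
#'   scored by the full-benchmark classifiers.
#' @param score_folds Folds for `score_mode = "out-of-fold"`.
#' @return An object of class `pirank` holding the fitted ranker, component
#'   scorers, similarity matrices and benchmark labels.
#' @seealso [predict.pirank()], [run_pipeline()]
#' @export
pirank <- function(seqs, dag, assoc, split,
                   scoring = alignment_scoring(),
                   components = classifier_config(),
                   ranker = NULL, use_cf = TRUE,
                   score_mode = c("in-sample", "out-of-fold"),
                   score_folds = 5L) {
  score_mode <- match.arg(score_mode)
  if (is.null(ranker))
    ranker <- ranker_config(seed = components$seed, scenario = split$scenario)
  prep <- pirank_prepare(seqs, dag, assoc, split, scoring, components, use_cf,
                         score_mode, score_folds)
  model <- lambdamart(prep$q, prep$label, prep$group, ranker)
  structure(c(prep["scorers"],
              list(model = model, train = prep[c("q", "label", "group")],
                   sp_bench = prep$sp_bench, sd = prep$sd,
                   a_bench = prep$a_bench, bench_ids = prep$bench_ids,
                   seqs = seqs, scoring = scoring, split = split,
                   assoc = assoc, use_cf = use_cf,
                   components = components, ranker = ranker)),
            class = "pirank")
}

# Everything up to (and including) the stacked benchmark score matrix; shared
# by pirank() and the cross-validation / grid-search machinery, which retrain
# only the ranker across hyperparameter candidates.
pirank_prepare <- function(seqs, dag, assoc, split, scoring, components,
                           use_cf, score_mode = "in-sample",
                           score_folds = 5L) {
  bench_rows <- sort(unique(split$bench_pairs[, 1L]))
  bench_ids <- rownames(assoc)[bench_rows]
  missing <- setdiff(bench_ids, names(seqs))
  if (length(missing)) stop("no sequence for benchmark piRNA(s): ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  sp_bench <- similarity_matrix(seqs[bench_ids], scoring)
  sd <- disease_similarity_matrix(dag, colnames(assoc))
  # benchmark-visible labels: independent-set positives are unknown here
  a_bench <- matrix(0L, length(bench_ids), ncol(assoc),
                    dimnames = list(bench_ids, colnames(assoc)))
  bp <- split$bench_pairs
  a_bench[cbind(match(rownames(assoc)[bp[, 1L]], bench_ids), bp[, 2L])] <-
    assoc[bp]
  feats <- build_pair_features(sp_bench, sd, bp, assoc)
  scorers <- train_classifiers(feats, components)
  cf <- cf_scores(a_bench, sp_bench, cbind(feats$pirna, feats$disease),
                  k_neighbors = components$cf_k_neighbors)
  q <- score_pairs(scorers, cf, feats)
  if (score_mode == "out-of-fold") {
    fold <- with_seed(components$seed, {
      f <- integer(length(feats$label))
      for (cls in c(0L, 1L)) {
        idx <- which(feats$label == cls)
        f[idx] <- sample(rep_len(seq_len(score_folds), length(idx)))
      }
      f
    })
    for (fd in seq_len(score_folds)) {
      held <- fold == fd
      sub <- list(x = feats$x[!held, , drop = FALSE],
                  label = feats$label[!held])
      sc_fd <- train_classifiers(sub, components)
      q[held, "lr"] <- sc_fd$lr(feats$x[held, , drop = FALSE])
      q[held, "rf"] <- sc_fd$rf(feats$x[held, , drop = FALSE])
      q[held, "svm"] <- sc_fd$svm(feats$x[held, , drop = FALSE])
    }
  }
  if (!use_cf) q <- q[, c("lr", "rf", "svm"), drop = FALSE]
  list(q = q, label = feats$label, group = feats$pirna,
       sp_bench = sp_bench, sd = sd, a_bench = a_bench,
       bench_ids = bench_ids, scorers = scorers)
}

# Stacked component scores for an arbitrary pair set against the fitted
# reference; queries outside the benchmark are aligned against it.
pirank_score_pairs <- function(object, pairs, newseqs = NULL) {
  pairs <- resolve_pairs(pairs, object$assoc)
  q_ids <- rownames(object$assoc)[sort(unique(pairs[, 1L]))]
  pool <- c(object$seqs, newseqs[setdiff(names(newseqs), names(object$seqs))])
  known <- intersect(q_ids, object$bench_ids)
  novel <- setdiff(q_ids, object$bench_ids)
  sp_rows <- object$sp_bench[known, , drop = FALSE]
  if (length(novel)) {
    miss <- setdiff(novel, names(pool))
    if (length(miss)) stop("no sequence for query piRNA(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    sp_rows <- rbind(sp_rows,
                     cross_similarity(pool[novel], pool[object$bench_ids],
                                      object$scoring))
  }
  feats <- build_pair_features(sp_rows, object$sd, pairs, object$assoc)
  cf <- cf_scores(object$a_bench, sp_rows, cbind(feats$pirna, feats$disease),
                  k_neighbors = object$components$cf_k_neighbors)
  q <- score_pairs(object$scorers, cf, feats)
  if (!object$use_cf) q <- q[, c("lr", "rf", "svm"), drop = FALSE]
  structure(q, pirna = feats$pirna, disease = feats$disease,
            label = feats$label)
}

#' Stacked component scores from a fitted model
#'
#' Computes the (CF, LR, RF, SVM) score vector for arbitrary (piRNA,
#' disease) pairs using a fitted [pirank()] model — the exact features the
#' ranker consumes. Useful for exporting intermediate scores
#' ([write_component_scores()]) or for retraining rankers on score subsets.
#'
#' @param object A fitted `pirank` model.
#' @param pairs Two-column matrix of (piRNA, disease) ids or indices;
#'   defaults to the split's independent pairs.
#' @param newseqs Optional named sequences for piRNAs unseen at fit time.
#' @return Numeric score matrix with `pirna`, `disease` and `label`
#'   attributes (as [score_pairs()]).
#' @export
component_scores <- function(object, pairs = NULL, newseqs = NULL) {
  stopifnot(inherits(object, "pirank"))
  if (is.null(pairs)) pairs <- object$split$ind_pairs
  pirank_score_pairs(object, pairs, newseqs)
}

#' Rank candidate diseases for query piRNAs
#'
#' Scores the requested (piRNA, disease) pairs with the four component
#' scorers and the fitted LambdaMART model, and returns one ranked candidate
#' list per query piRNA. By default the independent pairs of the fitted
#' split are ranked. Query piRNAs absent from the benchmark (newly detected)
#' are aligned against the benchmark reference set, so cold-start queries
#' need only a sequence.
#'
#' @param object A fitted [pirank()] model.
#' @param pairs Two-column matrix of (piRNA, disease) ids or indices;
#'   defaults to the split's independent pairs.
#' @param newseqs Optional named character vector with sequences for query
#'   piRNAs not covered at fit time.
#' @param ... Unused.
#' @return Named list of per-query ranked data frames (columns `pirna`,
#'   `disease`, `score`, `rank`).
#' @export
predict.pirank <- function(object, pairs = NULL, newseqs = NULL, ...) {
  if (is.null(pairs)) pairs <- object$split$ind_pairs
  q <- pirank_score_pairs(object, pairs, newseqs)
  stats::predict(object$model, q, group = attr(q, "pirna"),
                 candidates = attr(q, "disease"))
}

#' @export
print.pirank <- function(x, ...) {
  cat("pirank model (", x$split$scenario, " scenario)\n", sep = "")
  cat("  benchmark piRNAs: ", length(x$bench_ids),
      ", diseases: ", ncol(x$assoc), "\n", sep = "")
  cat("  components: ", if (x$use_cf) "CF + LR + RF + SVM" else
    "LR + RF + SVM (no CF)", "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @export
summary.pirank <- function(object, ...) {
  print(object)
  cat("component usage in the ranker:\n")
  print(feature_usage(object$model))
  invisible(object)
}

#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end workflow. Inputs may be
#' given as file paths (FASTA / ontology / association TSV) or as already
#' constructed objects.
#'
#' @param fasta,ontology,associations Input paths or objects (named sequence
#'   vector, `ontology_dag`, association matrix).
#' @param ontology_dialect `"edge-tsv"` or `"obo"`.
#' @param scenario `"association-wise"` or `"pirna-wise"`.
#' @param ind_fraction Independent-set fraction for the split.
#' @param scoring,components,ranker Stage configurations (`NULL` ranker =
#'   scenario preset).
#' @param k_list,roc_k_list Metric truncation levels.
#' @param use_cf Include the collaborative-filtering component.
#' @param diseases Candidate disease set. `NULL` keeps the columns of an
#'   in-memory association matrix, or defaults to the ontology's leaf terms
#'   when the associations are read from a file.
#' @param seed Master seed (controls split and all stochastic stages).
#' @param out_dir Optional output directory for predictions, report, model
#'   and manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, ontology, associations,
                            ontology_dialect = "edge-tsv",
                            scenario = c("association-wise", "pirna-wise"),
                            ind_fraction = 0.2,
                            scoring = alignment_scoring(),
                            components = NULL, ranker = NULL,
                            k_list = c(5L, 10L),
                            roc_k_list = c(1L, 3L, 5L, 10L),
                            use_cf = TRUE, diseases = NULL, seed = 1L,
                            out_dir = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(components)) components <- classifier_config(seed = seed)
  structure(list(fasta = fasta, ontology = ontology,
                 associations = associations, diseases = diseases,
                 ontology_dialect = ontology_dialect, scenario = scenario,
                 ind_fraction = ind_fraction, scoring = scoring,
                 components = components, ranker = ranker,
                 k_list = k_list, roc_k_list = roc_k_list,
                 use_cf = use_cf, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the end-to-end ranking pipeline
#'
#' Load -> split -> similarities -> pair features -> component training and
#' stacking -> LambdaMART training on benchmark query groups -> ranking of
#' the independent pairs -> grouped evaluation. With `out_dir` set, the
#' predictions TSV, per-query report TSV, model file and a manifest echoing
#' the seed are written there.
#'
#' @param config A [pipeline_config()].
#' @return List with `fit` (the `pirank` object), `predictions` (ranked
#'   lists) and `report` (an `evaluation_report`).
#' @export
run_pipeline <- function(config) {
  seqs <- if (is.character(config$fasta) && length(config$fasta) == 1L &&
              file.exists(config$fasta)) read_fasta(config$fasta)
          else config$fasta
  dag <- if (inherits(config$ontology, "ontology_dag")) config$ontology
         else read_ontology(config$ontology, config$ontology_dialect)
  assoc <- if (is.matrix(config$associations)) config$associations
           else read_associations(config$associations, seqs, dag,
                                  diseases = config$diseases %||%
                                    ontology_leaves(dag))
  split <- if (config$scenario == "association-wise")
    split_associations(assoc, config$ind_fraction, config$seed)
  else split_pirnas(assoc, config$ind_fraction, config$seed)
  fit <- pirank(seqs, dag, assoc, split, scoring = config$scoring,
                components = config$components, ranker = config$ranker,
                use_cf = config$use_cf)
  predictions <- stats::predict(fit)
  report <- evaluate(predictions, assoc, k_list = config$k_list,
                     roc_k_list = config$roc_k_list)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_predictions(file.path(config$out_dir, "predictions.tsv"),
                      predictions)
    write_report(report, file.path(config$out_dir, "report.tsv"))
    write_lambdamart(fit$model, file.path(config$out_dir, "model.txt"))
    writeLines(c(paste0("scenario=", config$scenario),
                 paste0("ind_fraction=", config$ind_fraction),
                 paste0("use_cf=", config$use_cf),
                 paste0("seed=", config$seed)),
               file.path(config$out_dir, "manifest.txt"))
  }
  list(fit = fit, predictions = predictions, report = report)
}

# Fold assignments: association-wise stratifies by label so every fold keeps
# both classes; pirna-wise partitions the piRNAs.
cv_folds <- function(assoc, scenario, n_folds, seed) {
  with_seed(seed, {
    if (scenario == "association-wise") {
      fold <- integer(length(assoc))
      for (cls in c(1L, 0L)) {
        idx <- which(assoc == cls)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      lapply(seq_len(n_folds), function(f) which(fold == f))
    } else {
      fold <- sample(rep_len(seq_len(n_folds), nrow(assoc)))
      idx <- arrayInd(seq_len(length(assoc)), dim(assoc))
      lapply(seq_len(n_folds), function(f) which(fold[idx[, 1L]] == f))
    }
  })
}

#' Cross-validate the full pipeline
#'
#' k-fold cross-validation on the benchmark data: association-wise folds
#' partition the pairs (stratified by label so each fold sees both classes);
#' pirna-wise folds partition the piRNAs. The full stage stack (similarity,
#' components, ranker) is retrained for every fold.
#'
#' @inheritParams pirank
#' @param scenario `"association-wise"` or `"pirna-wise"`.
#' @param n_folds Number of folds (>= 2).
#' @param seed Seed controlling fold assignment and all stages.
#' @param k_list,roc_k_list Metric truncation levels.
#' @return List of per-fold `evaluation_report`s.
#' @export
cross_validate <- function(seqs, dag, assoc,
                           scenario = c("association-wise", "pirna-wise"),
                           n_folds = 5L, seed = 1L,
                           scoring = alignment_scoring(),
                           components = NULL, ranker = NULL, use_cf = TRUE,
                           k_list = c(5L, 10L),
                           roc_k_list = c(1L, 3L, 5L, 10L)) {
  scenario <- match.arg(scenario)
  stopifnot(n_folds >= 2L)
  if (is.null(components)) components <- classifier_config(seed = seed)
  folds <- cv_folds(assoc, scenario, n_folds, seed)
  lapply(seq_along(folds), function(f) {
    split <- new_split(scenario, assoc,
                       bench = setdiff(seq_len(length(assoc)), folds[[f]]),
                       ind = folds[[f]], seed = seed)
    if (!any(assoc[split$bench_pairs]) || all(assoc[split$bench_pairs] == 1L)) {
      warning("fold ", f, " skipped: single-class benchmark")
      return(NULL)
    }
    fit <- pirank(seqs, dag, assoc, split, scoring = scoring,
                  components = components, ranker = ranker, use_cf = use_cf)
    evaluate(stats::predict(fit), assoc, k_list, roc_k_list)
  })
}

#' Coordinate-wise hyperparameter search for the ranker
#'
#' Optimizes the four ranker hyperparameters one at a time by mean
#' cross-validated macro AUPR, holding the other three fixed, in the order
#' number of trees -> truncation level k -> shrinkage -> number of leaves.
#' The three parameters not yet optimized start from (k, shrinkage, leaves)
#' = (10, 0.10, 10). Component scores do not depend on the ranker
#' configuration, so each fold's component stack is computed once and only
#' the ranker is retrained per evaluated point.
#'
#' @inheritParams cross_validate
#' @param grids Named list of candidate vectors for any of `n_trees`,
#'   `truncation_k`, `shrinkage`, `n_leaves`; parameters without a grid stay
#'   at their current value.
#' @return List with `best` (a [ranker_config()]) and `trace` (data frame of
#'   every evaluated point and its mean AUPR, one row per grid value).
#' @export
grid_search <- function(seqs, dag, assoc,
                        scenario = c("association-wise", "pirna-wise"),
                        grids, n_folds = 5L, seed = 1L,
                        scoring = alignment_scoring(),
                        components = NULL, use_cf = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(is.list(grids), length(grids) > 0,
            all(lengths(grids) > 0),
            all(names(grids) %in% c("n_trees", "truncation_k", "shrinkage",
                                    "n_leaves")))
  if (is.null(components)) components <- classifier_config(seed = seed)
  folds <- cv_folds(assoc, scenario, n_folds, seed)
  prep <- lapply(folds, function(ind) {
    split <- new_split(scenario, assoc,
                       bench = setdiff(seq_len(length(assoc)), ind),
                       ind = ind, seed = seed)
    p <- pirank_prepare(seqs, dag, assoc, split, scoring, components, use_cf)
    fit_stub <- structure(c(p["scorers"],
                            list(sp_bench = p$sp_bench, sd = p$sd,
                                 a_bench = p$a_bench, bench_ids = p$bench_ids,
                                 seqs = seqs, scoring = scoring,
                                 split = split, assoc = assoc,
                                 use_cf = use_cf, components = components)),
                          class = "pirank")
    q_test <- pirank_score_pairs(fit_stub, split$ind_pairs)
    list(train = p, q_test = q_test)
  })
  eval_point <- function(cur) {
    cfg <- ranker_config(n_trees = cur$n_trees,
                         truncation_k = cur$truncation_k,
                         shrinkage = cur$shrinkage, n_leaves = cur$n_leaves,
                         seed = seed, scenario = scenario)
    auprs <- vapply(prep, function(fd) {
      model <- lambdamart(fd$train$q, fd$train$label, fd$train$group, cfg)
      preds <- stats::predict(model, fd$q_test,
                              group = attr(fd$q_test, "pirna"),
                              candidates = attr(fd$q_test, "disease"))
      evaluate(preds, assoc, k_list = 5L, roc_k_list = 1L)$macro[["aupr"]]
    }, numeric(1L))
    mean(auprs)
  }
  cur <- list(n_trees = if (is.null(grids$n_trees)) 100L else
                grids$n_trees[[1L]],
              truncation_k = 10L, shrinkage = 0.10, n_leaves = 10L)
  trace <- NULL
  for (param in intersect(c("n_trees", "truncation_k", "shrinkage",
                            "n_leaves"), names(grids))) {
    vals <- grids[[param]]
    scores <- vapply(vals, function(v) {
      cand <- cur; cand[[param]] <- v
      eval_point(cand)
    }, numeric(1L))
    trace <- rbind(trace, data.frame(
      parameter = param, value = vals,
      n_trees = ifelse(param == "n_trees", vals, cur$n_trees),
      truncation_k = ifelse(param == "truncation_k", vals, cur$truncation_k),
      shrinkage = ifelse(param == "shrinkage", vals, cur$shrinkage),
      n_leaves = ifelse(param == "n_leaves", vals, cur$n_leaves),
      mean_aupr = scores))
    cur[[param]] <- vals[[which.max(scores)]]
  }
  list(best = ranker_config(n_trees = cur$n_trees,
                            truncation_k = cur$truncation_k,
                            shrinkage = cur$shrinkage,
                            n_leaves = cur$n_leaves,
                            seed = seed, scenario = scenario),
       trace = trace)
}
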