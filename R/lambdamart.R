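#' LambdaMART ranker configuration
#'
#' The four main hyperparameters of the listwise ranker: ensemble size,
#' NDCG truncation level `k`, shrinkage (learning rate) and leaves per tree,
#' plus the pairwise-logistic scale `sigma`. The two presets mirror the
#' tuned settings for the two application scenarios: missing-association
#' (120 trees, k = 14, shrinkage 0.22, 3 leaves) and cold-start
#' (30 trees, k = 15, shrinkage 0.10, 29 leaves).
#'
#' @param n_trees Number of boosting rounds (regression trees).
#' @param truncation_k NDCG truncation level optimized by the lambdas.
#' @param shrinkage Learning rate in `(0, 1]`.
#' @param n_leaves Maximum leaves per tree (>= 2).
#' @param sigma Scale of the pairwise logistic, > 0.
#' @param seed Integer seed (training is deterministic; the seed is recorded
#'   and reserved for stochastic options).
#' @param scenario Optional shortcut: `"association-wise"` or `"pirna-wise"`
#'   loads the corresponding preset for any parameter not given explicitly.
#' @return An object of class `ranker_config`.
#' @export
ranker_config <- function(n_trees = NULL, truncation_k = NULL,
                          shrinkage = NULL, n_leaves = NULL, sigma = 1,
                          seed = 1L, scenario = c("association-wise",
                                                  "pirna-wise")) {
  scenario <- match.arg(scenario)
  preset <- if (scenario == "association-wise")
    list(n_trees = 120L, truncation_k = 14L, shrinkage = 0.22, n_leaves = 3L)
  else
    list(n_trees = 30L, truncation_k = 15L, shrinkage = 0.10, n_leaves = 29L)
  cfg <- list(n_trees = if (is.null(n_trees)) preset$n_trees else as.integer(n_trees),
              truncation_k = if (is.null(truncation_k)) preset$truncation_k else as.integer(truncation_k),
              shrinkage = if (is.null(shrinkage)) preset$shrinkage else shrinkage,
              n_leaves = if (is.null(n_leaves)) preset$n_leaves else as.integer(n_leaves),
              sigma = sigma, seed = as.integer(seed), scenario = scenario)
  stopifnot(cfg$n_trees >= 0, cfg$truncation_k >= 1,
            cfg$shrinkage > 0, cfg$shrinkage <= 1,
            cfg$n_leaves >= 2, cfg$sigma > 0)
  structure(cfg, class = "ranker_config")
}

dcg_discount <- function(pos, k) ifelse(pos <= k, 1 / log2(pos + 1), 0)

#' Lambda gradients for one query group
#'
#' For every (positive, negative) candidate pair the pairwise logistic
#' gradient is weighted by the absolute NDCG@k change that swapping the two
#' candidates in the current score-sorted order would cause:
#' `rho = 1 / (1 + exp(sigma (s_i - s_j)))`,
#' `lambda_pair = sigma * rho * |dNDCG@k|`, accumulated positively on the
#' positive candidate and negatively on the negative one. Hessian weights
#' accumulate `sigma^2 rho (1 - rho) |dNDCG@k|` on both. Ties in the score
#' sort keep candidate input order (stable).
#'
#' @param scores Current model scores, one per candidate.
#' @param labels Binary relevance labels, one per candidate.
#' @param k NDCG truncation level.
#' @param sigma Pairwise logistic scale.
#' @return List with numeric vectors `lambda` and `hessian` (both zero when
#'   the group lacks a positive or a negative).
#' @export
compute_lambdas <- function(scores, labels, k, sigma = 1) {
  n <- length(scores)
  lambda <- numeric(n); hessian <- numeric(n)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg))
    return(list(lambda = lambda, hessian = hessian))
  ord <- order(-scores)              # stable: ties keep input order
  rank_pos <- integer(n); rank_pos[ord] <- seq_len(n)
  disc <- dcg_discount(rank_pos, k)
  idcg <- sum(dcg_discount(seq_len(min(length(pos), k)), k))
  # binary gains: swapping i (rel 1) and j (rel 0) changes DCG by
  # disc(rank_j) - disc(rank_i); normalize by IDCG
  dndcg <- abs(outer(disc[pos], disc[neg], "-")) / idcg
  rho <- 1 / (1 + exp(sigma * outer(scores[pos], scores[neg], "-")))
  lp <- sigma * rho * dndcg
  hp <- sigma^2 * rho * (1 - rho) * dndcg
  lambda[pos] <- rowSums(lp)
  lambda[neg] <- -colSums(lp)
  hessian[pos] <- rowSums(hp)
  hessian[neg] <- colSums(hp)
  list(lambda = lambda, hessian = hessian)
}

#' Fit one regression tree on lambda targets
#'
#' Greedy variance-reduction tree: leaves are split best-first on the
#' stacking features until `n_leaves` leaves are reached or no split reduces
#' the squared error of the targets. Each leaf takes the Newton value
#' `sum(targets) / (sum(weights) + 1e-9)`.
#'
#' @param x Feature matrix (one row per sample).
#' @param targets Lambda gradients.
#' @param weights Hessian weights (non-negative).
#' @param n_leaves Maximum number of leaves (>= 1).
#' @return A `pr_tree` object: data frame of nodes (columns `feature`,
#'   `threshold`, `left`, `right`, `value`; `feature == 0` marks a leaf).
#' @export
fit_tree <- function(x, targets, weights, n_leaves) {
  stopifnot(nrow(x) >= 1L, n_leaves >= 1L)
  eps <- 1e-9
  nodes <- list(list(idx = seq_len(nrow(x)), feature = 0L, threshold = NA_real_,
                     left = 0L, right = 0L,
                     value = sum(targets) / (sum(weights) + eps)))
  cand <- list(best_split(x, targets, nodes[[1L]]$idx))  # per-leaf split cache
  repeat {
    leaves <- which(vapply(nodes, function(nd) nd$feature == 0L, logical(1L)))
    if (length(leaves) >= n_leaves) break
    gains <- vapply(leaves, function(i)
      if (is.null(cand[[i]])) -Inf else cand[[i]]$gain, numeric(1L))
    if (all(gains <= 0)) break
    i <- leaves[[which.max(gains)]]
    sp <- cand[[i]]
    go_l <- x[nodes[[i]]$idx, sp$feature] <= sp$threshold
    for (side in c("l", "r")) {
      idx <- nodes[[i]]$idx[if (side == "l") go_l else !go_l]
      nd <- list(idx = idx, feature = 0L, threshold = NA_real_,
                 left = 0L, right = 0L,
                 value = sum(targets[idx]) / (sum(weights[idx]) + eps))
      nodes[[length(nodes) + 1L]] <- nd
      cand[length(nodes)] <- list(best_split(x, targets, idx))
      if (side == "l") nodes[[i]]$left <- length(nodes)
      else nodes[[i]]$right <- length(nodes)
    }
    nodes[[i]]$feature <- sp$feature
    nodes[[i]]$threshold <- sp$threshold
    nodes[[i]]$value <- NA_real_
  }
  structure(data.frame(
    feature = vapply(nodes, `[[`, integer(1L), "feature"),
    threshold = vapply(nodes, `[[`, numeric(1L), "threshold"),
    left = vapply(nodes, `[[`, integer(1L), "left"),
    right = vapply(nodes, `[[`, integer(1L), "right"),
    value = vapply(nodes, `[[`, numeric(1L), "value")),
    class = c("pr_tree", "data.frame"))
}

# Best single split of `idx` by squared-error reduction of the targets.
# Returns NULL when no split improves; thresholds are midpoints between
# consecutive distinct feature values.
best_split <- function(x, targets, idx) {
  n <- length(idx)
  if (n < 2L) return(NULL)
  t <- targets[idx]
  s_all <- sum(t)
  base <- s_all^2 / n
  best <- NULL
  for (f in seq_len(ncol(x))) {
    v <- x[idx, f]
    o <- order(v)
    vs <- v[o]
    cs <- cumsum(t[o])
    nl <- seq_len(n - 1L)
    ok <- vs[nl] != vs[nl + 1L]
    if (!any(ok)) next
    gain <- cs[nl]^2 / nl + (s_all - cs[nl])^2 / (n - nl) - base
    gain[!ok] <- -Inf
    b <- which.max(gain)
    if (gain[[b]] > 0 && (is.null(best) || gain[[b]] > best$gain))
      best <- list(feature = f, threshold = (vs[[b]] + vs[[b + 1L]]) / 2,
                   gain = gain[[b]])
  }
  best
}

predict_tree <- function(tree, x) {
  node <- rep(1L, nrow(x))
  repeat {
    at_split <- tree$feature[node] != 0L
    if (!any(at_split)) break
    i <- which(at_split)
    nd <- node[i]
    go_l <- x[cbind(i, tree$feature[nd])] <= tree$threshold[nd]
    node[i] <- ifelse(go_l, tree$left[nd], tree$right[nd])
  }
  tree$value[node]
}

#' Fit a LambdaMART listwise ranker
#'
#' Gradient-boosted regression trees trained on lambda gradients: each round
#' computes, within every query group, pairwise gradients weighted by the
#' NDCG@k swap change ([compute_lambdas()]), fits one variance-reduction tree
#' on the pooled samples ([fit_tree()]) and adds it with shrinkage. Groups
#' without a positive label (undefined ideal DCG) are excluded from training
#' but remain rankable at prediction time. Training is deterministic for a
#' given configuration.
#'
#' @param x Feature matrix, one row per (query, candidate) sample — here the
#'   stacked component scores (columns CF, LR, RF, SVM).
#' @param y Binary relevance labels.
#' @param group Query identifier per row (the grouping factor of the
#'   listwise loss).
#' @param config A [ranker_config()].
#' @return An object of class `lambdamart`: list with `base_score`, `trees`
#'   (list of `pr_tree`), `shrinkage`, `feature_names`, `config`.
#' @seealso [predict.lambdamart()], [feature_usage()], [write_lambdamart()]
#' @export
lambdamart <- function(x, y, group, config = ranker_config()) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(group) == length(y))
  groups <- split(seq_along(y), factor(group, levels = unique(group)))
  trainable <- Filter(function(ix) {
    any(y[ix] == 1L) && any(y[ix] == 0L)
  }, groups)
  if (!length(trainable)) stop("no trainable query group (need a group with ",
                               "both a positive and a negative label)")
  model <- structure(list(base_score = 0, trees = list(),
                          shrinkage = config$shrinkage,
                          feature_names = colnames(x) %||%
                            paste0("f", seq_len(ncol(x))),
                          config = config),
                     class = "lambdamart")
  if (config$n_trees == 0L) return(model)
  train_idx <- unlist(trainable, use.names = FALSE)
  xt <- x[train_idx, , drop = FALSE]
  # group offsets into the pooled training block
  off <- cumsum(c(0L, lengths(trainable)))
  scores <- rep(model$base_score, length(train_idx))
  with_seed(config$seed, for (round in seq_len(config$n_trees)) {
    lam <- numeric(length(train_idx)); hes <- numeric(length(train_idx))
    for (g in seq_along(trainable)) {
      sl <- (off[[g]] + 1L):off[[g + 1L]]
      lh <- compute_lambdas(scores[sl], y[train_idx[sl]],
                            config$truncation_k, config$sigma)
      lam[sl] <- lh$lambda; hes[sl] <- lh$hessian
    }
    tree <- fit_tree(xt, lam, hes, config$n_leaves)
    model$trees[[round]] <- tree
    scores <- scores + config$shrinkage * predict_tree(tree, xt)
  })
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict with a LambdaMART model
#'
#' Scores are `base_score + shrinkage * sum(tree outputs)`. With `group`
#' given, candidates are ranked within each query group by descending score,
#' ties keeping input order.
#'
#' @param object A `lambdamart` model.
#' @param x Feature matrix of candidates to score.
#' @param group Optional query identifier per row.
#' @param candidates Optional candidate (disease) ids per row, used to label
#'   the ranked lists; defaults to row numbers within each group.
#' @param ... Unused.
#' @return Without `group`: numeric score vector. With `group`: a named list
#'   of per-query data frames (`pirna`, `disease`, `score`, `rank`).
#' @export
predict.lambdamart <- function(object, x, group = NULL, candidates = NULL,
                               ...) {
  x <- as.matrix(x)
  s <- rep(object$base_score, nrow(x))
  for (tree in object$trees) s <- s + object$shrinkage * predict_tree(tree, x)
  if (is.null(group)) return(s)
  idx <- split(seq_along(s), factor(group, levels = unique(group)))
  lapply(idx, function(ix) {
    cand <- if (is.null(candidates)) as.character(seq_along(ix)) else
      candidates[ix]
    ranked_list(as.character(group[ix[[1L]]]), cand, s[ix])
  })
}

#' Assemble a ranked candidate list
#'
#' @param query Query (piRNA) id.
#' @param diseases Candidate ids, in input order.
#' @param scores Scores aligned with `diseases`.
#' @return Data frame with columns `pirna`, `disease`, `score`, `rank`
#'   (rank 1 = highest score; ties keep input order).
#' @export
ranked_list <- function(query, diseases, scores) {
  o <- order(-scores)   # stable
  data.frame(pirna = query, disease = diseases[o], score = scores[o],
             rank = seq_along(o), row.names = NULL)
}

#' Split usage counts of the component features
#'
#' Counts how often each stacking feature is used as an internal split across
#' all trees of the ensemble — a direct readout of how much the ranker relies
#' on each component scorer.
#'
#' @param model A `lambdamart` model.
#' @return Named integer vector, one count per feature; sums to the total
#'   number of internal nodes.
#' @export
feature_usage <- function(model) {
  counts <- integer(length(model$feature_names))
  names(counts) <- model$feature_names
  for (tree in model$trees) {
    f <- tree$feature[tree$feature != 0L]
    if (length(f)) counts <- counts + tabulate(f, length(counts))
  }
  counts
}

#' @export
print.lambdamart <- function(x, ...) {
  cat("LambdaMART ranker: ", length(x$trees), " trees (k = ",
      x$config$truncation_k, ", shrinkage = ", x$shrinkage, ", leaves <= ",
      x$config$n_leaves, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.lambdamart <- function(object, ...) {
  u <- feature_usage(object)
  cat("LambdaMART ranker\n")
  cat("  trees:        ", length(object$trees), "\n")
  cat("  truncation k: ", object$config$truncation_k, "\n")
  cat("  shrinkage:    ", object$shrinkage, "\n")
  cat("  max leaves:   ", object$config$n_leaves, "\n")
  cat("  split usage:  ",
      paste(names(u), u, sep = "=", collapse = "  "), "\n")
  invisible(u)
}

#' @export
#' @param y Unused (graphics argument).
#' @rdname feature_usage
plot.lambdamart <- function(x, y, ...) {
  u <- feature_usage(x)
  graphics::barplot(u, ylab = "internal splits",
                    xlab = "component feature",
                    main = "Component usage in the ranker", ...)
  invisible(u)
}
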