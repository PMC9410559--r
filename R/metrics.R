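#' NDCG at a truncation level
#'
#' Discounted cumulative gain of the top `k` ranks with binary gains
#' `2^rel - 1` and discount `log2(position + 1)`, normalized by the ideal
#' ordering's value. Returns 0 when the list has no positive (ideal DCG 0).
#'
#' @param labels Binary relevance labels in ranked order (rank 1 first).
#' @param k Truncation level (>= 1).
#' @return Value in `[0, 1]`.
#' @export
ndcg_at_k <- function(labels, k) {
  stopifnot(k >= 1)
  npos <- sum(labels == 1L)
  if (npos == 0L) return(0)
  top <- seq_len(min(k, length(labels)))
  dcg <- sum(labels[top] / log2(top + 1))
  idcg <- sum(1 / log2(seq_len(min(npos, k)) + 1))
  dcg / idcg
}

#' Average precision of a ranked binary list
#'
#' Non-interpolated AP: the mean, over the positions of the positives, of
#' the precision at each such position.
#'
#' @param labels Binary relevance labels in ranked order.
#' @return Value in `(0, 1]`, or `NA` when the list has no positive (the
#'   query cannot be evaluated and should be skipped).
#' @export
average_precision <- function(labels) {
  pos <- which(labels == 1L)
  if (!length(pos)) return(NA_real_)
  mean(seq_along(pos) / pos)
}

#' Truncated ROC score (ROC-k)
#'
#' The retrieval-quality score standard in ranked homolog search: walk the
#' ranked list past the first `k` false positives, counting the true
#' positives seen before each; `ROC_k = sum(t_i) / (k * T)` where `t_i` is
#' the number of positives ranked above the i-th negative and `T` the total
#' number of positives. With fewer than `k` negatives available the sum
#' truncates there and renormalizes; with no negatives the retrieval is
#' perfect and 1 is returned.
#'
#' @param labels Binary relevance labels in ranked order.
#' @param k Number of false positives to integrate over.
#' @return Value in `[0, 1]`, or `NA` when the list has no positive.
#' @export
roc_k <- function(labels, k) {
  stopifnot(k >= 1)
  total_pos <- sum(labels == 1L)
  if (total_pos == 0L) return(NA_real_)
  neg_pos <- which(labels == 0L)
  if (!length(neg_pos)) return(1)
  use <- utils::head(neg_pos, k)
  t_i <- vapply(use, function(p) sum(labels[seq_len(p)] == 1L), numeric(1L))
  sum(t_i) / (length(use) * total_pos)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (positive, negative) score pairs
#' ranked concordantly, with half credit for ties.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels aligned with `scores`.
#' @return Value in `[0, 1]`, or `NA` unless both classes are present.
#' @export
auc_score <- function(scores, labels) {
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)   # average ranks implement the 0.5 tie credit
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Computed as non-interpolated average precision over the score-sorted
#' items (stable ties, descending score) — the step-curve area.
#'
#' @inheritParams auc_score
#' @return Value in `(0, 1]`, or `NA` when there is no positive.
#' @export
aupr <- function(scores, labels) {
  if (sum(labels == 1L) == 0L) return(NA_real_)
  average_precision(labels[order(-scores)])
}

#' Evaluate ranked predictions per query and macro-average
#'
#' Computes AUC, AUPR, NDCG@k (for each k in `k_list`), MAP and ROC-k (for
#' each k in `roc_k_list`) per query piRNA over that query's evaluation
#' pairs only, then arithmetic-means across queries. Queries without a
#' positive are skipped (and counted); AUC additionally requires a negative.
#'
#' @param predictions List of per-query ranked data frames (columns `pirna`,
#'   `disease`, `score`, `rank`), as produced by [predict.pirank()] or
#'   [predict.lambdamart()].
#' @param labels Binary association matrix giving the true labels; only the
#'   (query, candidate) pairs present in `predictions` are consulted.
#' @param k_list NDCG truncation levels to report.
#' @param roc_k_list ROC-k truncation levels to report.
#' @param pooled Also report `pooled_auc` and `pooled_aupr` computed over
#'   all evaluation pairs at once, ignoring query grouping.
#' @return An `evaluation_report`: list with `per_query` (data frame),
#'   `macro` (named numeric), `n_queries_evaluated`, `n_queries_skipped`.
#' @export
evaluate <- function(predictions, labels, k_list = c(5L, 10L),
                     roc_k_list = c(1L, 3L, 5L, 10L), pooled = FALSE) {
  if (!length(predictions)) stop("empty prediction set")
  rows <- lapply(predictions, function(df) {
    df <- df[order(df$rank), ]
    y <- labels[cbind(df$pirna, df$disease)]
    out <- c(auc = auc_score(df$score, y), aupr = aupr(df$score, y),
             stats::setNames(vapply(k_list, ndcg_at_k, numeric(1L),
                                    labels = y),
                             paste0("ndcg@", k_list)),
             map = average_precision(y),
             stats::setNames(vapply(roc_k_list, roc_k, numeric(1L),
                                    labels = y),
                             paste0("roc@", roc_k_list)))
    c(n_pos = sum(y == 1L), n_candidates = length(y), out)
  })
  per_query <- data.frame(pirna = vapply(predictions, function(d)
    d$pirna[[1L]], character(1L)), do.call(rbind, rows),
    check.names = FALSE, row.names = NULL)
  has_pos <- per_query$n_pos > 0L
  metric_cols <- setdiff(names(per_query), c("pirna", "n_pos", "n_candidates"))
  macro <- vapply(metric_cols, function(m)
    mean(per_query[[m]][has_pos], na.rm = TRUE), numeric(1L))
  if (pooled) {
    all_s <- unlist(lapply(predictions, `[[`, "score"))
    all_y <- unlist(lapply(predictions, function(df)
      labels[cbind(df$pirna, df$disease)]))
    macro <- c(macro, pooled_auc = auc_score(all_s, all_y),
               pooled_aupr = aupr(all_s, all_y))
  }
  structure(list(per_query = per_query, macro = macro,
                 n_queries_evaluated = sum(has_pos),
                 n_queries_skipped = sum(!has_pos)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", x$n_queries_evaluated, "queries evaluated,",
      x$n_queries_skipped, "skipped (no positive)\n")
  print(round(x$macro, 4))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Per-query rows followed by a `macro` summary row.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  df <- report$per_query
  summary_row <- df[1L, ]
  summary_row$pirna <- "macro"
  summary_row$n_pos <- NA; summary_row$n_candidates <- NA
  for (m in intersect(names(report$macro), names(df)))
    summary_row[[m]] <- report$macro[[m]]
  utils::write.table(rbind(df, summary_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
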