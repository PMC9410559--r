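#' Semantic contributions of a disease term's ancestry
#'
#' Wang-style semantic values over the ontology DAG: the term itself
#' contributes 1, and each ancestor `i` contributes the maximum of
#' `decay * S(j)` over its children `j` that lie on a path to the target term.
#' Contributions therefore decay geometrically with distance from the target.
#'
#' @param dag An `ontology_dag` (see [read_ontology()]).
#' @param n A term id present in the DAG.
#' @param decay Semantic decay factor per edge (default 0.5).
#' @return Named numeric vector over `T_n` (the term and its ancestors),
#'   values in `(0, 1]`, with `S[n] == 1`.
#' @export
semantic_contributions <- function(dag, n, decay = 0.5) {
  if (!(n %in% dag$nodes)) stop("term not in ontology: ", n)
  s <- structure(1, names = n)
  frontier <- n
  # breadth-first up the parent links; a node may be reached along several
  # paths, so keep the maximum and repropagate when it improves
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (p in dag$parents[[v]]) {
        cand <- decay * s[[v]]
        if (is.na(s[p]) || cand > s[[p]]) {
          s[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Semantic similarity between two disease terms
#'
#' The shared-ancestor sum of Wang semantic values:
#' `sum over i in T_m intersect T_n of (S_m(i) + S_n(i))`, normalized by the
#' total semantic value `sum(S_m) + sum(S_n)`. Equal terms score exactly 1;
#' terms with disjoint ancestries (possible in a multi-root ontology) score 0.
#'
#' @inheritParams semantic_contributions
#' @param m,n Term ids present in the DAG.
#' @return Similarity in `[0, 1]`.
#' @examples
#' dag <- ontology_dag(cbind(c("r", "r"), c("a", "b")))
#' semantic_similarity(dag, "a", "b")  # siblings under one root: 1/3
#' @export
semantic_similarity <- function(dag, m, n, decay = 0.5) {
  sm <- semantic_contributions(dag, m, decay)
  sn <- semantic_contributions(dag, n, decay)
  shared <- intersect(names(sm), names(sn))
  if (!length(shared)) return(0)
  (sum(sm[shared]) + sum(sn[shared])) / (sum(sm) + sum(sn))
}

#' Disease semantic similarity matrix
#'
#' Pairwise Wang semantic similarities for an ordered list of disease terms;
#' semantic contributions are computed once per term and reused. The result
#' is symmetric with unit diagonal.
#'
#' @inheritParams semantic_contributions
#' @param diseases Ordered character vector of term ids.
#' @return Square numeric matrix with `diseases` as dimnames.
#' @export
disease_similarity_matrix <- function(dag, diseases, decay = 0.5) {
  missing <- setdiff(diseases, dag$nodes)
  if (length(missing))
    stop("disease term(s) not in ontology: ", paste(missing, collapse = ", "))
  contrib <- lapply(diseases, semantic_contributions, dag = dag, decay = decay)
  totals <- vapply(contrib, sum, numeric(1L))
  d <- length(diseases)
  sim <- diag(1, d)
  if (d > 1L) for (i in 1:(d - 1L)) for (j in (i + 1L):d) {
    shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
    v <- if (length(shared))
      (sum(contrib[[i]][shared]) + sum(contrib[[j]][shared])) /
        (totals[[i]] + totals[[j]]) else 0
    sim[i, j] <- sim[j, i] <- v
  }
  dimnames(sim) <- list(diseases, diseases)
  sim
}
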