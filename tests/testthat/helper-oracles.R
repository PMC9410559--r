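# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# Exhaustive global alignment score between two (short) strings: recursively
# enumerates every monotone alignment path, no memoization.
enum_global_score <- function(a, b, match, mismatch, gap) {
  if (!length(a)) return(gap * length(b))
  if (!length(b)) return(gap * length(a))
  s <- if (a[[1L]] == b[[1L]]) match else mismatch
  max(s + enum_global_score(a[-1L], b[-1L], match, mismatch, gap),
      gap + enum_global_score(a[-1L], b, match, mismatch, gap),
      gap + enum_global_score(a, b[-1L], match, mismatch, gap))
}

# Brute-force local alignment: best global score over all substring pairs,
# floored at 0 (the empty local alignment).
brute_sw <- function(a, b, match = 2, mismatch = -1, gap = -1) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      s <- enum_global_score(av[i1:i2], bv[j1:j2], match, mismatch, gap)
      if (s > best) best <- s
    }
  best
}

# AUC by explicit pair counting with half credit for ties.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (if (p > n) 1 else if (p == n) 0.5 else 0)
  total / (length(pos) * length(neg))
}

random_rna <- function(n, min_len = 24, max_len = 31) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), sample(min_len:max_len, 1L),
                 replace = TRUE), collapse = ""), character(1L))
}

# Random DAG: node i > 1 attaches to 1-2 earlier nodes (guaranteed acyclic).
random_dag <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  edges <- NULL
  for (i in 2:n_nodes) {
    k <- sample(1:min(2L, i - 1L), 1L)
    for (p in sample(nodes[seq_len(i - 1L)], k))
      edges <- rbind(edges, c(p, nodes[[i]]))
  }
  ontology_dag(edges)
}
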