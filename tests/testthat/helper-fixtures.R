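# Shared fixtures, built in code at test time.

# Small planted benchmark: 8 families x 4 members, 8 leaf diseases in 4
# clusters — large enough for the full stack to learn, small enough for
# fast unit tests.
tiny_config <- function(seed = 1L, ...) {
  synthetic_config(n_families = 8L, members_per_family = 4L,
                   dag_depth = 2L, dag_branching = c(4L, 2L),
                   n_disease_clusters = 4L, seed = seed, ...)
}

tiny_dataset <- function(seed = 1L, ...) {
  cfg <- tiny_config(seed, ...)
  seqs <- generate_sequences(cfg)
  dag <- generate_ontology(cfg)
  list(cfg = cfg, seqs = seqs, dag = dag,
       assoc = generate_associations(seqs, dag, cfg))
}

# Linearly separable pair-feature toy: positives live in [0.6, 1]^p,
# negatives in [0, 0.4]^p.
separable_features <- function(n_pos = 30L, n_neg = 30L, p = 5L, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(runif(n_pos * p, 0.6, 1), n_pos),
             matrix(runif(n_neg * p, 0, 0.4), n_neg))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, label = rep(c(1L, 0L), c(n_pos, n_neg)),
       pirna = paste0("p", seq_len(n_pos + n_neg)),
       disease = rep("d1", n_pos + n_neg))
}

# Separable listwise toy: groups whose positive candidates have uniformly
# higher component scores than their negatives.
separable_groups <- function(n_groups = 10L, n_cand = 10L, n_pos = 3L,
                             seed = 1L) {
  set.seed(seed)
  y <- integer(0); g <- character(0); x <- NULL
  for (i in seq_len(n_groups)) {
    lab <- rep(c(1L, 0L), c(n_pos, n_cand - n_pos))
    scores <- cbind(cf = ifelse(lab == 1, runif(n_cand, 0.6, 1),
                                runif(n_cand, 0, 0.4)),
                    lr = ifelse(lab == 1, runif(n_cand, 0.6, 1),
                                runif(n_cand, 0, 0.4)),
                    rf = ifelse(lab == 1, runif(n_cand, 0.6, 1),
                                runif(n_cand, 0, 0.4)),
                    svm = ifelse(lab == 1, runif(n_cand, 0.6, 1),
                                 runif(n_cand, 0, 0.4)))
    x <- rbind(x, scores)
    y <- c(y, lab)
    g <- c(g, rep(paste0("q", i), n_cand))
  }
  list(x = x, y = y, group = g)
}

mean_train_ndcg <- function(model, x, y, group, k = 5L) {
  s <- predict(model, x)
  mean(vapply(split(seq_along(y), factor(group, levels = unique(group))),
              function(ix) ndcg_at_k(y[ix][order(-s[ix])], k),
              numeric(1L)))
}
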