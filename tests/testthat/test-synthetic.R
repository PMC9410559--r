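test_that("sequence families honour length range, mutation rate and seed", {
  cfg0 <- tiny_config(seed = 2, mutation_rate = 0)
  s0 <- generate_sequences(cfg0)
  expect_length(s0, 32)
  fams <- split(s0, sub("_m\\d+$", "", names(s0)))
  for (f in fams) expect_identical(length(unique(f)), 1L)
  cfg <- tiny_config(seed = 2)
  s <- generate_sequences(cfg)
  expect_true(all(nchar(s) >= 24 & nchar(s) <= 31))
  expect_true(all(grepl("^[ACGU]+$", s)))
  expect_identical(generate_sequences(cfg), s)
})

test_that("generated ontologies have the configured shape", {
  cfg1 <- synthetic_config(dag_depth = 1, dag_branching = 3,
                           n_disease_clusters = 3)
  dag1 <- generate_ontology(cfg1)
  expect_length(dag1$nodes, 4)                 # root + 3 leaves
  expect_length(ontology_leaves(dag1), 3)
  # uniform branching b over depth d: sum of b^l nodes
  cfg2 <- synthetic_config(dag_depth = 2, dag_branching = 3,
                           n_disease_clusters = 3)
  expect_length(generate_ontology(cfg2)$nodes, 1 + 3 + 9)
  # same-subtree leaves are semantically closer than cross-subtree leaves
  dag <- generate_ontology(tiny_config())
  cl <- attr(dag, "clusters")
  leaves <- names(cl)
  m <- disease_similarity_matrix(dag, leaves)
  same <- m[outer(cl, cl, "==") & upper.tri(m)]
  cross <- m[outer(cl, cl, "!=") & upper.tri(m)]
  expect_gt(min(same), max(cross))
})

test_that("planted associations follow the block probabilities", {
  d <- tiny_dataset(seed = 3, p_in = 1, p_out = 0)
  cl <- attr(d$dag, "clusters")
  fam <- as.integer(sub("^f(\\d+)_.*$", "\\1", rownames(d$assoc)))
  expected <- outer(((fam - 1L) %% 4L) + 1L, cl[colnames(d$assoc)], "==") + 0L
  expect_identical(unname(d$assoc), unname(expected))
  # p_in = p_out: association rate independent of the block structure
  dn <- tiny_dataset(seed = 3, p_in = 0.3, p_out = 0.3)
  in_block <- expected == 1L
  rate_in <- mean(dn$assoc[in_block]); rate_out <- mean(dn$assoc[!in_block])
  expect_lt(abs(rate_in - rate_out), 0.1)
})

test_that("positive counts stay within binomial bounds across seeds", {
  cfg <- tiny_config()
  n_in <- 32 * 2          # each piRNA sees 2 in-cluster diseases
  n_out <- 32 * 6
  expected <- n_in * cfg$p_in + n_out * cfg$p_out
  variance <- n_in * cfg$p_in * (1 - cfg$p_in) +
    n_out * cfg$p_out * (1 - cfg$p_out)
  total <- 0
  for (seed in 1:20) {
    d <- tiny_dataset(seed = seed)
    total <- total + sum(d$assoc)
  }
  expect_lt(abs(total - 20 * expected), 3 * sqrt(20 * variance))
})

test_that("family members are more alike than cross-family pairs", {
  d <- tiny_dataset(seed = 5)   # default mutation rate 0.08
  set.seed(5)
  fam <- sub("_m\\d+$", "", names(d$seqs))
  hits <- 0
  for (i in 1:100) {
    f <- sample(unique(fam), 1)
    pair <- sample(names(d$seqs)[fam == f], 2)
    other <- sample(names(d$seqs)[fam != f], 1)
    s_in <- normalized_similarity(d$seqs[[pair[1]]], d$seqs[[pair[2]]])
    s_out <- normalized_similarity(d$seqs[[pair[1]]], d$seqs[[other]])
    hits <- hits + (s_in > s_out)
  }
  expect_gte(hits, 95)
})

test_that("benchmark files round-trip through the readers bit-identically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- tiny_config(seed = 9)
  t0 <- Sys.time()
  p1 <- generate_benchmark(cfg, dir1)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 5)
  p2 <- generate_benchmark(cfg, dir2)
  for (f in c("fasta", "ontology", "associations", "manifest"))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  seqs <- read_fasta(p1$fasta)
  expect_identical(seqs, generate_sequences(cfg))
  dag <- read_ontology(p1$ontology)
  expect_setequal(dag$nodes, generate_ontology(cfg)$nodes)
  assoc <- read_associations(p1$associations, seqs,
                             diseases = ontology_leaves(dag))
  ref <- generate_associations(seqs, generate_ontology(cfg), cfg)
  expect_identical(assoc[rownames(ref), colnames(ref)], ref)
  expect_true(any(grepl("^seed=9$", readLines(p1$manifest))))
})
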