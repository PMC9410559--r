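test_that("FASTA reading normalizes case and T/U and keeps record order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1 some description", "acgt", ">p2", "GGU", "ACU"), fa)
  s <- read_fasta(fa)
  expect_identical(names(s), c("p1", "p2"))
  expect_identical(unname(s), c("ACGU", "GGUACU"))
})

test_that("FASTA reader rejects duplicates, empties and bad characters", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU", ">a", "GGGG"), fa)
  expect_error(read_fasta(fa), "duplicate.*a")
  writeLines(c(">a", "ACGU", ">b"), fa)
  expect_error(read_fasta(fa), "empty sequence.*b")
  writeLines(c(">a", "ACXGU"), fa)
  expect_error(read_fasta(fa), "position 3")
})

test_that("a written sequence set reads back identically", {
  set.seed(4)
  seqs <- setNames(random_rna(50), paste0("p", 1:50))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
})

test_that("edge-tsv ontology parsing builds the DAG and detects cycles", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r\ta", "r\tb"), tsv)
  dag <- read_ontology(tsv)
  expect_setequal(dag$nodes, c("r", "a", "b"))
  expect_identical(dag$roots, "r")
  expect_setequal(dag$children[["r"]], c("a", "b"))
  writeLines(c("a\tb", "b\ta"), tsv)
  expect_error(read_ontology(tsv), "cycle")
  writeLines("a\ta", tsv)
  expect_error(ontology_dag(cbind("a", "a")), "self-edge")
})

test_that("OBO parsing keeps is_a edges and drops obsolete terms", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: DOID:1", "name: root", "",
               "[Term]", "id: DOID:2", "name: kid",
               "is_a: DOID:1 ! root", "",
               "[Term]", "id: DOID:3", "name: gone",
               "is_a: DOID:1", "is_obsolete: true", "",
               "[Typedef]", "id: part_of"), obo)
  dag <- read_ontology(obo, dialect = "obo")
  expect_setequal(dag$nodes, c("DOID:1", "DOID:2"))
  expect_identical(dag$parents[["DOID:2"]], "DOID:1")
})

test_that("association reading fills, de-duplicates and validates the matrix", {
  seqs <- c(p1 = "ACGU", p2 = "GGUU")
  dag <- ontology_dag(cbind("r", c("d1", "d2")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\td1", "p1\td2", "p2\td1"), tsv)
  m <- read_associations(tsv, seqs, dag, diseases = c("d1", "d2"))
  expect_identical(sum(m), 3L)
  expect_identical(m["p2", "d2"], 0L)
  writeLines(c("p1\td1", "p1\td1"), tsv)
  expect_identical(sum(read_associations(tsv, seqs, diseases = c("d1", "d2"))),
                   1L)
  writeLines("p9\td1", tsv)
  expect_error(read_associations(tsv, seqs, dag, diseases = c("d1", "d2")),
               "p9")
})

test_that("association-wise split reproduces paper-scale counts exactly", {
  # mock at deposited-benchmark scale: 5002 positives over 4350 x 21
  set.seed(99)
  assoc <- matrix(0L, 4350, 21,
                  dimnames = list(paste0("p", 1:4350), paste0("d", 1:21)))
  assoc[sample(length(assoc), 5002)] <- 1L
  sp <- split_associations(assoc, 0.2, seed = 3)
  expect_identical(nrow(sp$bench_pairs) + nrow(sp$ind_pairs), length(assoc))
  expect_identical(sum(assoc[sp$ind_pairs]), 1000L)
  expect_identical(sum(assoc[sp$bench_pairs]), 4002L)
  expect_identical(sum(assoc[sp$ind_pairs] == 0L), 17269L)
  expect_identical(sum(assoc[sp$bench_pairs] == 0L), 69079L)

  pw <- split_pirnas(assoc, 0.2, seed = 3)
  expect_identical(length(unique(pw$ind_pairs[, "pirna"])), 870L)
  expect_identical(length(unique(pw$bench_pairs[, "pirna"])), 3480L)
  expect_length(intersect(pw$ind_pairs[, "pirna"], pw$bench_pairs[, "pirna"]),
                0L)
  # every piRNA contributes all its pairs to one side
  expect_true(all(table(pw$ind_pairs[, "pirna"]) == 21L))
  expect_true(all(table(pw$bench_pairs[, "pirna"]) == 21L))
})

test_that("splits are deterministic in the seed and conserve positives", {
  set.seed(7)
  assoc <- matrix(rbinom(200, 1, 0.2), 20, 10,
                  dimnames = list(paste0("p", 1:20), paste0("d", 1:10)))
  for (fn in list(split_associations, split_pirnas)) {
    s1 <- fn(assoc, 0.25, seed = 11)
    s2 <- fn(assoc, 0.25, seed = 11)
    s3 <- fn(assoc, 0.25, seed = 12)
    expect_identical(s1[c("bench_pairs", "ind_pairs")],
                     s2[c("bench_pairs", "ind_pairs")])
    expect_false(identical(s1$ind_pairs, s3$ind_pairs))
    expect_identical(nrow(s3$ind_pairs), nrow(s1$ind_pairs))
    expect_identical(sum(assoc[s1$bench_pairs]) + sum(assoc[s1$ind_pairs]),
                     sum(assoc))
  }
  s0 <- split_associations(assoc, 0, seed = 1)
  expect_identical(nrow(s0$ind_pairs), 0L)
  expect_identical(nrow(s0$bench_pairs), length(assoc))
  expect_error(split_pirnas(assoc, 0.01, seed = 1), "zero")
})

test_that("prediction files round-trip with rank order preserved", {
  ranked <- list(q1 = ranked_list("q1", c("d1", "d2", "d3"), c(0.2, 0.9, 0.5)))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(out, ranked)
  back <- read_predictions(out)
  expect_identical(back$q1$disease, c("d2", "d3", "d1"))
  expect_identical(back$q1$rank, 1:3)
  write_predictions(out, list())
  expect_identical(readLines(out), "pirna\tdisease\tscore\trank")
})
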