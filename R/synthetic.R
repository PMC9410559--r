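#' Synthetic benchmark configuration
#'
#' Parameters of the self-contained synthetic benchmark: piRNA-length
#' sequences organized in mutation-derived families, a rooted disease
#' ontology whose leaves form clusters of related diseases, and a sparse
#' binary association matrix with a planted family-to-cluster block
#' structure. Defaults give 30 families x 10 members (300 sequences of
#' 24-31 nt), a depth-2 ontology with 5 clusters x 4 leaf diseases
#' (20 candidate diseases), per-position substitution rate 0.08, and block
#' association probabilities `p_in = 0.7` (a family's own disease cluster)
#' versus `p_out = 0.02` (elsewhere).
#'
#' @param n_families Number of sequence families.
#' @param members_per_family Sequences per family.
#' @param length_range Sequence length range (inclusive), default 24-31 nt.
#' @param mutation_rate Per-position substitution probability applied to each
#'   family member relative to the family seed sequence.
#' @param indel_rate Per-position probability of a single-base insertion or
#'   deletion (0 by default: substitutions only).
#' @param dag_depth Ontology tree depth (root = depth 0).
#' @param dag_branching Branching factor: a scalar (uniform tree) or one
#'   value per level. The default `c(5, 4)` gives 5 root subtrees of 4
#'   leaves each.
#' @param n_disease_clusters Number of disease clusters; must equal the
#'   number of root subtrees of the generated ontology.
#' @param p_in,p_out Association probability for in-block / out-of-block
#'   (piRNA, disease) pairs; `p_in >= p_out`.
#' @param seed Integer seed; every generated artifact is a pure function of
#'   the configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 30L, members_per_family = 10L,
                             length_range = c(24L, 31L),
                             mutation_rate = 0.08, indel_rate = 0,
                             dag_depth = 2L, dag_branching = c(5L, 4L),
                             n_disease_clusters = 5L,
                             p_in = 0.7, p_out = 0.02, seed = 1L) {
  if (length(dag_branching) == 1L)
    dag_branching <- rep(as.integer(dag_branching), dag_depth)
  stopifnot(n_families > 0, members_per_family > 0,
            length(length_range) == 2L, length_range[[1L]] >= 1,
            mutation_rate >= 0, mutation_rate < 1, indel_rate >= 0,
            dag_depth >= 1, length(dag_branching) == dag_depth,
            all(dag_branching >= 1), n_disease_clusters >= 1,
            p_in >= p_out, p_in <= 1, p_out >= 0)
  if (n_disease_clusters != dag_branching[[1L]])
    stop("n_disease_clusters must equal the number of root subtrees (",
         dag_branching[[1L]], ")")
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 length_range = as.integer(length_range),
                 mutation_rate = mutation_rate, indel_rate = indel_rate,
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 n_disease_clusters = as.integer(n_disease_clusters),
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "synthetic_config")
}

rna_bases <- c("A", "C", "G", "U")

#' Generate family-structured synthetic piRNA sequences
#'
#' Each family draws one random seed sequence of uniform random length in
#' `length_range`; members are independent per-position mutants of it at
#' `mutation_rate` (substitutions to a different base; optional indels at
#' `indel_rate`). Ids encode family membership as `f<family>_m<member>`.
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of RNA sequences.
#' @export
generate_sequences <- function(config) {
  with_seed(config$seed, {
    out <- character(0)
    for (f in seq_len(config$n_families)) {
      len <- sample(config$length_range[[1L]]:config$length_range[[2L]], 1L)
      seed_seq <- sample(rna_bases, len, replace = TRUE)
      for (m in seq_len(config$members_per_family)) {
        s <- seed_seq
        mut <- which(stats::runif(len) < config$mutation_rate)
        for (i in mut)
          s[[i]] <- sample(setdiff(rna_bases, s[[i]]), 1L)
        if (config$indel_rate > 0) {
          i <- 1L
          while (i <= length(s)) {
            if (stats::runif(1L) < config$indel_rate) {
              if (stats::runif(1L) < 0.5 && length(s) > 1L) s <- s[-i]
              else {
                s <- append(s, sample(rna_bases, 1L), after = i)
                i <- i + 1L
              }
            }
            i <- i + 1L
          }
        }
        out[[sprintf("f%02d_m%02d", f, m)]] <- paste(s, collapse = "")
      }
    }
    out
  })
}

#' Generate a rooted disease-ontology tree
#'
#' Builds a rooted tree with the configured depth and per-level branching;
#' the leaves are the candidate diseases and are grouped into clusters by
#' the root subtree they belong to.
#'
#' @param config A [synthetic_config()].
#' @return An `ontology_dag` whose leaves carry a `"clusters"` attribute
#'   (named integer vector: leaf id -> cluster index).
#' @export
generate_ontology <- function(config) {
  edges <- NULL
  level_nodes <- "DOID:root"
  for (d in seq_len(config$dag_depth)) {
    nxt <- character(0)
    for (p in level_nodes) {
      ch <- paste0(sub("^DOID:", "", p), ".", seq_len(config$dag_branching[[d]]))
      ch <- paste0("DOID:", sub("^root\\.", "", ch))
      edges <- rbind(edges, cbind(p, ch))
      nxt <- c(nxt, ch)
    }
    level_nodes <- nxt
  }
  dag <- ontology_dag(edges)
  leaves <- ontology_leaves(dag)
  cluster <- as.integer(factor(sub("\\..*$", "", sub("^DOID:", "", leaves)),
                               levels = as.character(seq_len(config$dag_branching[[1L]]))))
  attr(dag, "clusters") <- stats::setNames(cluster, leaves)
  dag
}

#' Generate a planted block association matrix
#'
#' Each sequence family is assigned one disease cluster round-robin; a pair
#' (piRNA, disease) is labelled 1 with probability `p_in` when the disease
#' lies in the family's cluster and `p_out` otherwise.
#'
#' @param seqs Sequences from [generate_sequences()] (family encoded in ids).
#' @param dag Ontology from [generate_ontology()] (clusters attribute).
#' @param config A [synthetic_config()].
#' @return Binary association matrix (piRNAs x leaf diseases).
#' @export
generate_associations <- function(seqs, dag, config) {
  leaves <- names(attr(dag, "clusters"))
  cluster <- attr(dag, "clusters")
  fam <- as.integer(sub("^f(\\d+)_.*$", "\\1", names(seqs)))
  fam_cluster <- ((fam - 1L) %% config$n_disease_clusters) + 1L
  p <- outer(fam_cluster, cluster[leaves],
             function(fc, dc) ifelse(fc == dc, config$p_in, config$p_out))
  lab <- with_seed(config$seed + 1L,
                   matrix(as.integer(stats::runif(length(p)) < p),
                          nrow(p), ncol(p)))
  dimnames(lab) <- list(names(seqs), leaves)
  lab
}

#' Write a complete synthetic benchmark to disk
#'
#' Emits the FASTA, ontology edge TSV and association TSV read back by the
#' data-io layer, plus a plain key=value manifest echoing the configuration.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Writable output directory (created if absent).
#' @return Invisibly, a named list of the written file paths.
#' @export
generate_benchmark <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- generate_sequences(config)
  dag <- generate_ontology(config)
  assoc <- generate_associations(seqs, dag, config)
  paths <- list(fasta = file.path(out_dir, "pirnas.fasta"),
                ontology = file.path(out_dir, "ontology.tsv"),
                associations = file.path(out_dir, "associations.tsv"),
                manifest = file.path(out_dir, "manifest.txt"))
  write_fasta(seqs, paths$fasta)
  edges <- do.call(rbind, lapply(dag$nodes, function(p) {
    ch <- dag$children[[p]]
    if (length(ch)) cbind(p, ch) else NULL
  }))
  utils::write.table(edges, paths$ontology, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pos <- which(assoc == 1L, arr.ind = TRUE)
  utils::write.table(data.frame(rownames(assoc)[pos[, 1L]],
                                colnames(assoc)[pos[, 2L]]),
                     paths$associations, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(paste0("generator=pirnarank synthetic benchmark"),
               vapply(names(unclass(config)), function(k)
                 paste0(k, "=", paste(config[[k]], collapse = ",")),
                 character(1L))),
             paths$manifest)
  invisible(paths)
}
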