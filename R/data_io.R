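#' Read piRNA sequences from a FASTA file
#'
#' Reads a FASTA file of small-RNA sequences and normalizes them to the RNA
#' alphabet: lowercase is raised to uppercase and `T` is mapped to `U`, so
#' DNA-alphabet exports of piRNA databases load transparently.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector: names are record identifiers (the first
#'   whitespace-delimited token of each header), values are RNA sequences over
#'   `A`, `C`, `G`, `U`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "acgt", ">p2", "GGGUU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[[1L]], ">"))
    stop("not a FASTA file (no leading '>' header): ", path)
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste0,
                 character(1L), collapse = "")
  # records with no sequence line never appear in split(); detect them
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    full <- rep("", length(ids))
    full[as.integer(names(seqs))] <- seqs
    bad <- ids[!nzchar(full)]
    stop("empty sequence for record(s): ", paste(bad, collapse = ", "))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- normalize_rna(unname(seqs), ids)
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (as from [read_fasta()]).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

# Uppercase, map T->U, and reject anything outside {A,C,G,U}, reporting the
# offending record and 1-based position.
normalize_rna <- function(seqs, ids) {
  seqs <- chartr("acgtuT", "ACGUUU", seqs)
  bad <- regexpr("[^ACGU]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[[1L]]
    stop("invalid character '", substr(seqs[[i]], bad[[i]], bad[[i]]),
         "' in sequence '", ids[[i]], "' at position ", bad[[i]])
  }
  seqs
}

#' Read a disease ontology as a directed acyclic graph
#'
#' Parses an ontology of disease terms connected by `is_a` (parent -> child)
#' edges, either from a minimal OBO 1.2 file (only `[Term]` stanzas with
#' `id:`, `is_a:` and `is_obsolete:` tags are interpreted; obsolete terms and
#' their edges are dropped) or from a two-column `parent<TAB>child` edge file.
#'
#' @param path Path to the ontology file.
#' @param dialect `"edge-tsv"` (default) or `"obo"`.
#' @return An object of class `ontology_dag`: a list with `nodes` (character),
#'   `parents` and `children` (named lists of character vectors), and `roots`.
#' @export
read_ontology <- function(path, dialect = c("edge-tsv", "obo")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("ontology file not found: ", path)
  if (dialect == "edge-tsv") {
    tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                             comment.char = "#", blank.lines.skip = TRUE)
    if (ncol(tab) < 2L) stop("edge-tsv needs two tab-separated columns")
    edges <- cbind(parent = trimws(tab[[1L]]), child = trimws(tab[[2L]]))
  } else {
    edges <- parse_obo_edges(readLines(path, warn = FALSE))
  }
  ontology_dag(edges)
}

# Minimal OBO 1.2 subset: [Term] stanzas; keeps is_a edges among
# non-obsolete terms. Returns a parent/child character matrix; isolated
# non-obsolete terms are kept via an attribute.
parse_obo_edges <- function(lines) {
  lines <- trimws(lines)
  term_starts <- which(lines == "[Term]")
  stanza_starts <- which(grepl("^\\[.*\\]$", lines))
  ids <- character(0); parents <- list(); obsolete <- character(0)
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    body <- lines[seq(s + 1L, e)]
    id <- sub("^id:\\s*", "", grep("^id:", body, value = TRUE))
    if (length(id) != 1L) next
    id <- sub("\\s*!.*$", "", id[[1L]])
    isa <- sub("^is_a:\\s*", "", grep("^is_a:", body, value = TRUE))
    isa <- trimws(sub("\\s*!.*$", "", isa))
    if (any(grepl("^is_obsolete:\\s*true", body))) {
      obsolete <- c(obsolete, id)
    } else {
      ids <- c(ids, id)
      parents[[id]] <- isa
    }
  }
  keep <- setdiff(ids, obsolete)
  edges <- do.call(rbind, lapply(keep, function(id) {
    pa <- setdiff(parents[[id]], obsolete)
    if (length(pa)) cbind(parent = pa, child = id) else NULL
  }))
  if (is.null(edges)) edges <- cbind(parent = character(0), child = character(0))
  attr(edges, "isolated") <- setdiff(keep, c(edges[, 1L], edges[, 2L]))
  edges
}

#' Construct an ontology DAG from an edge list
#'
#' @param edges Two-column matrix or data frame of `parent`, `child` term ids.
#' @param nodes Optional extra (isolated) node ids to include.
#' @return An `ontology_dag` object. Errors if the edge set contains a cycle
#'   (one witness cycle is reported) or a self-edge.
#' @export
ontology_dag <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edges must have two columns (parent, child)")
  edges <- edges[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-edge on node: ", edges[edges[, 1L] == edges[, 2L], 1L][[1L]])
  edges <- unique(edges)
  nodes <- unique(c(edges[, 1L], edges[, 2L], nodes, attr(edges, "isolated")))
  parents <- split(edges[, 1L], factor(edges[, 2L], levels = nodes))
  children <- split(edges[, 2L], factor(edges[, 1L], levels = nodes))
  # Kahn topological sort; leftovers witness a cycle
  indeg <- lengths(parents)
  queue <- nodes[indeg == 0L]
  seen <- 0L
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(nodes)) {
    rem <- names(indeg_work)[indeg_work > 0L]
    stop("ontology contains a cycle: ", paste(find_cycle(rem, parents),
                                              collapse = " -> "))
  }
  structure(list(nodes = nodes,
                 parents = lapply(parents, unique),
                 children = lapply(children, unique),
                 roots = nodes[indeg == 0L]),
            class = "ontology_dag")
}

# Walk parent links inside the cyclic subgraph until a node repeats.
find_cycle <- function(rem, parents) {
  v <- rem[[1L]]; path <- character(0)
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(parents[[v]], rem)[[1L]]
  }
  cyc <- path[seq(match(v, path), length(path))]
  c(rev(cyc), v)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$nodes), "terms,",
      sum(lengths(x$children)), "is_a edges,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' @rdname read_ontology
#' @param dag An `ontology_dag`.
#' @export
ontology_leaves <- function(dag) {
  dag$nodes[lengths(dag$children[dag$nodes]) == 0L]
}

#' Read a piRNA-disease association table
#'
#' Reads a TSV of known associations (columns: piRNA id, disease id; extra
#' columns are ignored) and returns the full binary association matrix over
#' the supplied piRNA and disease universes: 1 marks a known association,
#' 0 an unknown pair. Duplicate lines collapse to a single association.
#'
#' @param path Path to the TSV (a header line is auto-detected: a first line
#'   whose ids do not resolve is treated as a header).
#' @param seqs Named character vector of piRNA sequences (defines piRNA order).
#' @param dag Optional `ontology_dag`; disease ids must be terms of it. When
#'   `NULL`, `diseases` must be given.
#' @param diseases Optional explicit disease universe (character). Defaults to
#'   the terms of `dag`.
#' @return Integer matrix (piRNAs x diseases) with dimnames, entries in {0,1}.
#' @export
read_associations <- function(path, seqs, dag = NULL, diseases = NULL) {
  if (!file.exists(path)) stop("association file not found: ", path)
  if (is.null(diseases)) {
    if (is.null(dag)) stop("supply either `dag` or `diseases`")
    diseases <- dag$nodes
  }
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop("association TSV needs at least two columns")
  pir <- trimws(tab[[1L]]); dis <- trimws(tab[[2L]])
  if (nrow(tab) && (!(pir[[1L]] %in% names(seqs)) && !(dis[[1L]] %in% diseases))
      && (nrow(tab) == 1L || pir[[2L]] %in% names(seqs))) {
    pir <- pir[-1L]; dis <- dis[-1L]  # header line
  }
  bad_p <- setdiff(pir, names(seqs))
  if (length(bad_p)) stop("unknown piRNA id(s): ",
                          paste(utils::head(bad_p, 5L), collapse = ", "))
  bad_d <- setdiff(dis, diseases)
  if (length(bad_d)) stop("unknown disease id(s): ",
                          paste(utils::head(bad_d, 5L), collapse = ", "))
  association_matrix(names(seqs), diseases, cbind(pir, dis))
}

#' Build a binary association matrix
#'
#' @param pirna_ids Ordered piRNA identifiers.
#' @param disease_ids Ordered disease identifiers.
#' @param positives Two-column matrix/data.frame of (piRNA id, disease id)
#'   known associations; duplicates are collapsed.
#' @return Integer matrix with `dimnames = list(pirna_ids, disease_ids)`.
#' @export
association_matrix <- function(pirna_ids, disease_ids, positives) {
  m <- matrix(0L, length(pirna_ids), length(disease_ids),
              dimnames = list(pirna_ids, disease_ids))
  if (NROW(positives)) {
    positives <- as.matrix(positives)
    m[cbind(match(positives[, 1L], pirna_ids),
            match(positives[, 2L], disease_ids))] <- 1L
  }
  m
}

#' Split associations into benchmark and independent sets
#'
#' Association-wise split (missing-association scenario): a fixed fraction of
#' the known associations and, independently, of the unknown pairs is drawn
#' uniformly without replacement into the independent set; everything else is
#' the benchmark. Sizes use the floor convention,
#' `floor(ind_fraction * N)` for each class.
#'
#' @param assoc Binary association matrix (piRNAs x diseases).
#' @param ind_fraction Fraction of each class assigned to the independent set.
#' @param seed Integer seed; the split is a pure function of
#'   `(assoc, ind_fraction, seed)`.
#' @return A `benchmark_split` object: list with `scenario`
#'   (`"association-wise"`), `bench_pairs` and `ind_pairs` (two-column integer
#'   index matrices into `assoc`), and `seed`.
#' @export
split_associations <- function(assoc, ind_fraction, seed) {
  stopifnot(ind_fraction >= 0, ind_fraction <= 1)
  pos <- which(assoc == 1L); neg <- which(assoc == 0L)
  ind <- with_seed(seed, {
    c(sample(pos, floor(ind_fraction * length(pos))),
      sample(neg, floor(ind_fraction * length(neg))))
  })
  all_idx <- seq_len(length(assoc))
  new_split("association-wise", assoc,
            bench = setdiff(all_idx, ind), ind = ind, seed = seed)
}

#' Split piRNAs into known and newly-detected sets
#'
#' piRNA-wise split (cold-start scenario): `floor(ind_fraction * n_piRNAs)`
#' piRNAs are drawn uniformly into the independent ("newly detected") set; all
#' pairs of an independent piRNA go to the independent side, all other pairs
#' to the benchmark.
#'
#' @inheritParams split_associations
#' @return A `benchmark_split` with `scenario = "pirna-wise"`.
#' @export
split_pirnas <- function(assoc, ind_fraction, seed) {
  stopifnot(ind_fraction > 0, ind_fraction < 1)
  n <- nrow(assoc)
  k <- floor(ind_fraction * n)
  if (k < 1L) stop("ind_fraction yields zero independent piRNAs")
  ind_p <- with_seed(seed, sample.int(n, k))
  idx <- arrayInd(seq_len(length(assoc)), dim(assoc))
  ind <- which(idx[, 1L] %in% ind_p)
  new_split("pirna-wise", assoc,
            bench = which(!(idx[, 1L] %in% ind_p)), ind = ind, seed = seed)
}

new_split <- function(scenario, assoc, bench, ind, seed) {
  structure(list(scenario = scenario,
                 bench_pairs = pair_index(bench, assoc),
                 ind_pairs = pair_index(ind, assoc),
                 n_pirnas = nrow(assoc), n_diseases = ncol(assoc),
                 seed = as.integer(seed)),
            class = "benchmark_split")
}

pair_index <- function(linear, assoc) {
  m <- arrayInd(sort(linear), dim(assoc))
  colnames(m) <- c("pirna", "disease")
  m
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat("benchmark_split (", x$scenario, "): ",
      nrow(x$bench_pairs), " benchmark pairs, ",
      nrow(x$ind_pairs), " independent pairs, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Write ranked predictions to a TSV
#'
#' @param path Output path.
#' @param ranked A list of per-query data frames as returned by
#'   [predict.pirank()]/[ranked_list()]: columns `pirna`, `disease`, `score`,
#'   `rank`.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(path, ranked) {
  df <- if (length(ranked)) do.call(rbind, ranked) else
    data.frame(pirna = character(0), disease = character(0),
               score = numeric(0), rank = integer(0))
  df <- df[order(match(df$pirna, unique(df$pirna)), df$rank), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "character",
                                               "numeric", "integer"))
  split(df, factor(df$pirna, levels = unique(df$pirna)))
}
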