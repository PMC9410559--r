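#' Alignment scoring scheme
#'
#' Scoring parameters for Smith-Waterman local alignment: a positive match
#' reward, a mismatch score, and a linear (per-symbol) gap penalty. The
#' defaults (+2 / -1 / -1) are a deliberately simple scheme with positive
#' self-scores; all three are configurable.
#'
#' @param match Match reward, must be > 0.
#' @param mismatch Mismatch score.
#' @param gap Linear gap penalty per symbol, must be < 0.
#' @return An object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -1, gap = -1) {
  stopifnot(match > 0, gap < 0)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_scoring")
}

encode_rna <- function(seqs) {
  lapply(strsplit(chartr("acgtuT", "ACGUUU", seqs), ""), function(ch) {
    code <- match(ch, c("A", "C", "G", "U")) - 1L
    if (anyNA(code)) stop("non-ACGU character in sequence")
    code
  })
}

#' Smith-Waterman local alignment score
#'
#' Exact dynamic-programming local alignment: the score is the maximum entry
#' of the matrix `H` with `H(i,j) = max(0, H(i-1,j-1)+s(a_i,b_j),
#' H(i-1,j)+gap, H(i,j-1)+gap)` and zero borders.
#'
#' @param a,b RNA sequences (single strings; `T` is accepted and read as `U`).
#' @param scoring An [alignment_scoring()] scheme.
#' @return The raw alignment score (non-negative scalar).
#' @examples
#' smith_waterman("ACGU", "AGU")  # 5 with the default +2/-1/-1 scheme
#' @export
smith_waterman <- function(a, b, scoring = alignment_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  e <- encode_rna(c(a, b))
  .sw_score_cpp(e[[1L]], e[[2L]], scoring$match, scoring$mismatch, scoring$gap)
}

#' Normalized Smith-Waterman similarity
#'
#' `SW(a,b) / sqrt(SW(a,a) * SW(b,b))`, which lies in `[0,1]` for any scheme
#' with a uniform positive match reward, equals 1 for identical sequences and
#' 0 when no positive-scoring local alignment exists.
#'
#' @inheritParams smith_waterman
#' @return Similarity in `[0,1]`.
#' @export
normalized_similarity <- function(a, b, scoring = alignment_scoring()) {
  s <- smith_waterman(a, b, scoring)
  if (s == 0) return(0)
  s / sqrt(smith_waterman(a, a, scoring) * smith_waterman(b, b, scoring))
}

#' All-against-all normalized sequence similarity matrix
#'
#' Computes the symmetric matrix of normalized Smith-Waterman similarities for
#' a sequence set. Only the upper triangle is computed and mirrored; the
#' diagonal is exactly 1.
#'
#' @param seqs Named character vector of sequences.
#' @param scoring An [alignment_scoring()] scheme.
#' @return Square numeric matrix with the sequence names as dimnames.
#' @export
similarity_matrix <- function(seqs, scoring = alignment_scoring()) {
  stopifnot(length(seqs) >= 1L)
  enc <- encode_rna(seqs)
  raw <- .sw_matrix_cpp(enc, enc, scoring$match, scoring$mismatch,
                        scoring$gap, TRUE)
  self <- diag(raw)
  sim <- raw / sqrt(outer(self, self))
  sim[raw == 0] <- 0
  diag(sim) <- 1
  dimnames(sim) <- list(names(seqs), names(seqs))
  sim
}

#' Query-against-reference similarity matrix
#'
#' Rectangular normalized Smith-Waterman similarities, rows = query sequences
#' (e.g. newly detected piRNAs), columns = reference sequences. A query
#' identical to a reference sequence scores exactly 1 against it.
#'
#' @param query,reference Named character vectors of sequences.
#' @inheritParams similarity_matrix
#' @return `length(query) x length(reference)` numeric matrix.
#' @export
cross_similarity <- function(query, reference, scoring = alignment_scoring()) {
  stopifnot(length(query) >= 1L, length(reference) >= 1L)
  eq <- encode_rna(query); er <- encode_rna(reference)
  raw <- .sw_matrix_cpp(eq, er, scoring$match, scoring$mismatch,
                        scoring$gap, FALSE)
  self_q <- vapply(seq_along(eq), function(i)
    .sw_score_cpp(eq[[i]], eq[[i]], scoring$match, scoring$mismatch,
                  scoring$gap), numeric(1L))
  self_r <- vapply(seq_along(er), function(j)
    .sw_score_cpp(er[[j]], er[[j]], scoring$match, scoring$mismatch,
                  scoring$gap), numeric(1L))
  sim <- raw / sqrt(outer(self_q, self_r))
  sim[raw == 0] <- 0
  dimnames(sim) <- list(names(query), names(reference))
  sim
}

#' Export a similarity matrix as TSV
#'
#' Writes the matrix with a leading id column and id header row.
#'
#' @param sim Numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity <- function(sim, path) {
  utils::write.table(data.frame(id = rownames(sim), sim,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
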