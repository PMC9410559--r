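#' Save / load a LambdaMART model as text
#'
#' The model is persisted in a small human-readable, versioned format so it
#' can be inspected and ported across languages:
#' ```
#' pirnarank-lambdamart 1
#' config n_trees=... truncation_k=... shrinkage=... n_leaves=... sigma=... seed=... scenario=...
#' features cf lr rf svm
#' base_score 0
#' trees 2
#' tree 1 nodes 3
#' 1 split <feature> <threshold> <left> <right>
#' 2 leaf <value>
#' 3 leaf <value>
#' ...
#' end
#' ```
#' Node lines are `<id> split <feature-index> <threshold> <left-id>
#' <right-id>` or `<id> leaf <value>`; numbers are written with full
#' precision, so a write/read round trip reproduces the model exactly.
#'
#' @param model A `lambdamart` model.
#' @param path File path.
#' @return `write_lambdamart()`: invisibly, `path`. `read_lambdamart()`: the
#'   reconstructed `lambdamart` object.
#' @export
write_lambdamart <- function(model, path) {
  num <- function(x) format(x, digits = 17L, scientific = FALSE, trim = TRUE)
  cfg <- model$config
  out <- c(
    "pirnarank-lambdamart 1",
    paste0("config n_trees=", cfg$n_trees, " truncation_k=", cfg$truncation_k,
           " shrinkage=", num(cfg$shrinkage), " n_leaves=", cfg$n_leaves,
           " sigma=", num(cfg$sigma), " seed=", cfg$seed,
           " scenario=", cfg$scenario),
    paste("features", paste(model$feature_names, collapse = " ")),
    paste("base_score", num(model$base_score)),
    paste("trees", length(model$trees)))
  for (i in seq_along(model$trees)) {
    tr <- model$trees[[i]]
    out <- c(out, paste("tree", i, "nodes", nrow(tr)),
             vapply(seq_len(nrow(tr)), function(n) {
               if (tr$feature[[n]] == 0L)
                 paste(n, "leaf", num(tr$value[[n]]))
               else
                 paste(n, "split", tr$feature[[n]], num(tr$threshold[[n]]),
                       tr$left[[n]], tr$right[[n]])
             }, character(1L)))
  }
  writeLines(c(out, "end"), path)
  invisible(path)
}

#' @rdname write_lambdamart
#' @export
read_lambdamart <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(lines[[1L]], "pirnarank-lambdamart 1"))
    stop("not a pirnarank-lambdamart v1 model file: ", path)
  kv <- strsplit(sub("^config ", "", lines[[2L]]), " ")[[1L]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  cfgv <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  config <- ranker_config(n_trees = as.integer(cfgv[["n_trees"]]),
                          truncation_k = as.integer(cfgv[["truncation_k"]]),
                          shrinkage = as.numeric(cfgv[["shrinkage"]]),
                          n_leaves = as.integer(cfgv[["n_leaves"]]),
                          sigma = as.numeric(cfgv[["sigma"]]),
                          seed = as.integer(cfgv[["seed"]]),
                          scenario = cfgv[["scenario"]])
  feats <- strsplit(sub("^features ", "", lines[[3L]]), " ")[[1L]]
  base <- as.numeric(sub("^base_score ", "", lines[[4L]]))
  n_trees <- as.integer(sub("^trees ", "", lines[[5L]]))
  trees <- vector("list", n_trees)
  at <- 6L
  for (i in seq_len(n_trees)) {
    hd <- strsplit(lines[[at]], " ")[[1L]]
    stopifnot(hd[[1L]] == "tree")
    nn <- as.integer(hd[[4L]])
    tr <- data.frame(feature = integer(nn), threshold = NA_real_,
                     left = integer(nn), right = integer(nn),
                     value = NA_real_)
    for (n in seq_len(nn)) {
      tok <- strsplit(lines[[at + n]], " ")[[1L]]
      id <- as.integer(tok[[1L]])
      if (tok[[2L]] == "leaf") {
        tr$value[[id]] <- as.numeric(tok[[3L]])
      } else {
        tr$feature[[id]] <- as.integer(tok[[3L]])
        tr$threshold[[id]] <- as.numeric(tok[[4L]])
        tr$left[[id]] <- as.integer(tok[[5L]])
        tr$right[[id]] <- as.integer(tok[[6L]])
      }
    }
    trees[[i]] <- structure(tr, class = c("pr_tree", "data.frame"))
    at <- at + nn + 1L
  }
  structure(list(base_score = base, trees = trees,
                 shrinkage = config$shrinkage, feature_names = feats,
                 config = config),
            class = "lambdamart")
}
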