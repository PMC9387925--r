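#' Run the block-pair discovery stage of the pipeline
#'
#' Indexes spaced words, samples score-filtered reference quartet blocks,
#' pairs each with a second downstream block and keeps the informative
#' pairs. The result feeds both tree-building routes.
#'
#' @param seqs sequence set (named character vector, `DNAStringSet` or
#'   FASTA path) with at least four taxa.
#' @param pattern reference-block pattern (default [default_pattern()]).
#' @param pattern2 second-block pattern (default `"1111111"`).
#' @param score_matrix substitution score matrix.
#' @param L second-block search window in nucleotides (default 500).
#' @param max_blocks cap on sampled reference blocks (default one million).
#' @param quartets_per_word quartets sampled per eligible spaced word.
#' @param seed integer seed; fixes block sampling (and hence everything
#'   downstream) exactly.
#' @return List with `blocks`, `pairs`, `counts`, `taxa` and the call
#'   parameters.
#' @export
gapquartet_run <- function(seqs, pattern = default_pattern(),
                           pattern2 = spam_pattern("1111111"),
                           score_matrix = default_score_matrix(),
                           L = 500L, max_blocks = 1e6,
                           quartets_per_word = 1L, seed = NULL) {
  seqs <- as_sequence_set(seqs)
  pattern <- spam_pattern(pattern)
  pattern2 <- spam_pattern(pattern2)
  idx <- index_spaced_words(seqs, pattern)
  blocks <- sample_quartet_blocks(idx, seqs, pattern, score_matrix,
                                  max_blocks = max_blocks,
                                  quartets_per_word = quartets_per_word,
                                  seed = seed)
  pairs <- collect_block_pairs(blocks, seqs, pattern2, L)
  list(blocks = blocks, pairs = pairs, counts = attr(pairs, "counts"),
       taxa = names(seqs), pattern = pattern, pattern2 = pattern2,
       L = L, seed = seed)
}

#' Infer a tree from indel signal between quartet blocks
#'
#' One-shot driver: runs [gapquartet_run()] (unless given a prepared run)
#' and builds a tree from the informative block pairs, either by quartet
#' amalgamation ([quartet_supertree()]) or by maximum parsimony on the
#' encoded character matrix ([search_parsimony_tree()]).
#'
#' @param x a sequence set, or the result of [gapquartet_run()].
#' @param method `"maxcut"` (quartet amalgamation) or `"parsimony"`.
#' @param strong_only use only strongly supporting pairs.
#' @param parsimony_mode passed to [search_parsimony_tree()].
#' @param seed integer seed (used for block sampling when `x` is a
#'   sequence set, and for the heuristic searches).
#' @param ... further arguments passed to [gapquartet_run()].
#' @return An unrooted `phylo` tree with attribute `run` (the pipeline
#'   run object).
#' @export
infer_tree <- function(x, method = c("maxcut", "parsimony"),
                       strong_only = FALSE, parsimony_mode = "auto",
                       seed = NULL, ...) {
  method <- match.arg(method)
  run <- if (is.list(x) && !is.null(x$pairs)) x
         else gapquartet_run(x, seed = seed, ...)
  pairs <- run$pairs
  if (strong_only) pairs <- pairs[pairs$class == "strong", , drop = FALSE]
  if (!nrow(pairs))
    stop("no informative block pairs; cannot infer a tree")
  tree <- if (method == "maxcut") {
    quartet_supertree(quartet_calls(pairs), seed = seed)
  } else {
    m <- build_character_matrix(pairs, run$taxa)
    search_parsimony_tree(m, mode = parsimony_mode, seed = seed)
  }
  missing_taxa <- setdiff(run$taxa, tree$tip.label)
  if (length(missing_taxa))
    warning("taxa without informative signal left out of the tree: ",
            paste(missing_taxa, collapse = ", "))
  attr(tree, "run") <- run
  tree
}
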