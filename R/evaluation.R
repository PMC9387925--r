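#' Quartet topology induced by a tree on four taxa
#'
#' Restricts the tree to the four taxa and reads off the topology of the
#' restriction: the cherry structure around the single internal edge, or
#' `"unresolved"` when the restriction is a star (possible for non-binary
#' reference trees).
#'
#' @param tree a `phylo` tree.
#' @param taxa four taxon ids, all tips of `tree`.
#' @return Canonical topology string, or `"unresolved"`.
#' @export
induced_quartet <- function(tree, taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) != 4L || anyDuplicated(taxa))
    stop("need exactly four distinct taxa")
  if (!all(taxa %in% tree$tip.label))
    stop("unknown taxa: ", paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  kt <- ape::unroot(ape::keep.tip(tree, taxa))
  if (kt$Nnode < 2L) return("unresolved")
  ntip <- length(kt$tip.label)
  # the non-root internal node subtends one cherry
  E <- kt$edge
  root <- setdiff(E[, 1L], E[, 2L])
  inner <- setdiff(unique(E[, 1L]), root)
  cherry_tips <- E[E[, 1L] == inner & E[, 2L] <= ntip, 2L]
  if (length(cherry_tips) != 2L) return("unresolved")
  c1 <- kt$tip.label[cherry_tips]
  quartet_topology(c1, setdiff(taxa, c1))
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees; `normalized_rf()` divides by `2N - 6`, the maximum
#' possible distance between two binary trees on `N` shared leaves.
#'
#' @param t1,t2 `phylo` trees on the same leaf set (`N >= 4`).
#' @return `rf_distance`: even non-negative integer; `normalized_rf`: value
#'   in `[0, 1]` for binary trees.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  if (length(t1$tip.label) < 4L) stop("need at least 4 leaves")
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               normalize = FALSE, check.labels = TRUE))
}

#' @rdname rf_distance
#' @export
normalized_rf <- function(t1, t2) {
  n <- length(t1$tip.label)
  rf_distance(t1, t2) / (2L * n - 6L)
}

#' Quartet accuracy and coverage against a reference tree
#'
#' A call is *correct* when its topology equals the quartet induced from the
#' reference tree on the same four taxa. By default every informative call
#' (i.e. every retained block pair) counts once; with
#' `per_quartet_majority = TRUE` each 4-taxon set instead contributes a
#' single majority-vote call. *Coverage* is the percentage of all
#' `choose(N, 4)` 4-taxon sets with at least one informative call. Calls
#' whose reference restriction is unresolved (non-binary reference) are
#' counted as incorrect but reported separately.
#'
#' @param calls data frame with a `topology` column (e.g. the pair table
#'   from [collect_block_pairs()] or calls from [quartet_calls()]; an `n`
#'   multiplicity column is honoured when present).
#' @param reference a `phylo` reference tree containing all involved taxa.
#' @param taxa the full taxon set (default: the reference tree's tips),
#'   used for the coverage denominator.
#' @param per_quartet_majority use one majority call per 4-taxon set.
#' @return List with `pct_correct`, `pct_coverage`, `n_calls`,
#'   `n_unresolved_ref` (`pct_correct` is `NaN` when there are no calls).
#' @export
quartet_accuracy <- function(calls, reference, taxa = reference$tip.label,
                             per_quartet_majority = FALSE) {
  n_sets <- choose(length(taxa), 4L)
  if (!nrow(calls))
    return(list(pct_correct = NaN, pct_coverage = 0, n_calls = 0L,
                n_unresolved_ref = 0L))
  w <- if ("n" %in% names(calls)) as.numeric(calls$n) else rep(1, nrow(calls))
  parsed <- lapply(calls$topology, parse_topology)
  setkey <- vapply(parsed, function(p) paste(sort(p$taxa), collapse = ","), "")
  if (per_quartet_majority) {
    keep <- integer(0)
    for (k in unique(setkey)) {
      i <- which(setkey == k)
      votes <- rowsum(w[i], calls$topology[i])
      top <- rownames(votes)[which.max(votes[, 1L])]
      j <- i[match(top, calls$topology[i])]
      keep <- c(keep, j)
    }
    calls <- calls[keep, , drop = FALSE]
    parsed <- parsed[keep]
    setkey <- setkey[keep]
    w <- rep(1, length(keep))
  }
  ref_top <- vapply(parsed, function(p) induced_quartet(reference, p$taxa), "")
  unresolved <- ref_top == "unresolved"
  correct <- !unresolved & calls$topology == ref_top
  list(pct_correct = 100 * sum(w * correct) / sum(w),
       pct_coverage = 100 * length(unique(setkey)) / n_sets,
       n_calls = sum(w),
       n_unresolved_ref = sum(w * unresolved))
}

#' Evaluation report for an inferred tree and its quartet calls
#'
#' Bundles the quartet-level metrics ([quartet_accuracy()]) with the
#' tree-level Robinson-Foulds comparison into one record, mirroring the
#' usual benchmark-table structure.
#'
#' @param calls quartet calls (see [quartet_accuracy()]).
#' @param tree inferred `phylo` tree (may be `NULL` to skip RF).
#' @param reference reference `phylo` tree.
#' @return A one-row data frame with columns `n_informative_pairs`,
#'   `pct_correct`, `pct_coverage`, `rf`, `nrf`.
#' @export
evaluation_report <- function(calls, tree, reference) {
  qa <- quartet_accuracy(calls, reference)
  rf <- if (is.null(tree)) NA_integer_ else rf_distance(tree, reference)
  nrf <- if (is.null(tree)) NA_real_ else normalized_rf(tree, reference)
  data.frame(n_informative_pairs = qa$n_calls,
             pct_correct = qa$pct_correct,
             pct_coverage = qa$pct_coverage,
             rf = rf, nrf = nrf)
}
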