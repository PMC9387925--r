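#' Parsimony score of a tree for an indel character matrix
#'
#' Fitch small parsimony over the symbols '0', '1', '2' with '-' treated as
#' missing information (the full state set, imposing no constraint). The
#' score is the minimal total number of character-state changes — i.e. the
#' minimal number of indel events the tree requires to explain the observed
#' inter-block distances.
#'
#' @param tree an unrooted `phylo` tree whose tip labels contain all matrix
#'   taxa; tips absent from the matrix are treated as all-missing.
#' @param x character matrix from [build_character_matrix()].
#' @param site_weights optional per-column multiplicities.
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, x, site_weights = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  taxa <- rownames(x)
  if (is.null(taxa)) stop("matrix must have taxa as rownames")
  if (!all(taxa %in% tree$tip.label))
    stop("matrix taxa missing from tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  enc <- .encode_columns(x, tree$tip.label, site_weights)
  .fitch_cost(tree, enc$codes, enc$w)
}

# bitmask encoding: '0'->1, '1'->2, '2'->4, '-'->7; rows = tree tip order.
# duplicate columns are compressed with summed weights.
.encode_columns <- function(x, tip_order, site_weights = NULL) {
  if (is.null(site_weights)) site_weights <- rep(1, ncol(x))
  if (ncol(x) == 0L)
    return(list(codes = matrix(7L, length(tip_order), 0L,
                               dimnames = list(tip_order, NULL)),
                w = numeric()))
  map <- c("0" = 1L, "1" = 2L, "2" = 4L, "-" = 7L)
  if (any(!x %in% names(map))) stop("matrix symbols must be 0/1/2/-")
  full <- matrix("-", length(tip_order), ncol(x),
                 dimnames = list(tip_order, NULL))
  keep <- intersect(tip_order, rownames(x))
  full[keep, ] <- x[keep, , drop = FALSE]
  codes <- matrix(map[full], nrow(full), ncol(full),
                  dimnames = list(tip_order, NULL))
  key <- apply(codes, 2L, paste, collapse = ",")
  grp <- match(key, unique(key))
  w <- as.vector(tapply(site_weights, grp, sum))
  codes <- codes[, !duplicated(grp), drop = FALSE]
  list(codes = codes, w = w)
}

# Fitch pass over a (possibly unrooted) tree; codes: tips x columns bitmasks
.fitch_cost <- function(tree, codes, w) {
  if (!ncol(codes)) return(0L)
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  state <- matrix(0L, ntip + nnode, ncol(codes))
  state[seq_len(ntip), ] <- codes
  filled <- logical(ntip + nnode)
  filled[seq_len(ntip)] <- TRUE
  cost <- 0
  E <- tree$edge
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]
    if (!filled[p]) {
      state[p, ] <- state[ch, ]
      filled[p] <- TRUE
    } else {
      inter <- bitwAnd(state[p, ], state[ch, ])
      z <- inter == 0L
      if (any(z)) {
        cost <- cost + sum(w[z])
        inter[z] <- bitwOr(state[p, ], state[ch, ])[z]
      }
      state[p, ] <- inter
    }
  }
  as.integer(cost)
}

#' Search for a maximum-parsimony tree
#'
#' Finds an unrooted tree minimising [parsimony_score()] for the given
#' character matrix. In `"exhaustive"` mode every unrooted topology is
#' scored (feasible up to 8 taxa: 10395 topologies); in `"heuristic"` mode
#' seeded random-order stepwise addition is followed by
#' nearest-neighbour-interchange hill climbing, restarted `nstart` times.
#' `"auto"` picks exhaustive for 7 or fewer taxa. Ties between equally
#' parsimonious trees are broken deterministically by the canonical Newick
#' string ([canonical_newick()]), the analogue of "take the first reported
#' tree".
#'
#' @param x character matrix (rownames are the taxa, at least 4).
#' @param mode `"auto"`, `"exhaustive"` or `"heuristic"`.
#' @param nstart random restarts in heuristic mode.
#' @param seed integer seed for the heuristic's randomised addition order.
#' @param site_weights optional per-column multiplicities.
#' @return An unrooted `phylo` tree with attribute `score`.
#' @export
search_parsimony_tree <- function(x, mode = c("auto", "exhaustive", "heuristic"),
                                  nstart = 10L, seed = NULL,
                                  site_weights = NULL) {
  mode <- match.arg(mode)
  taxa <- rownames(x)
  n <- length(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  if (mode == "auto") mode <- if (n <= 7L) "exhaustive" else "heuristic"
  if (mode == "exhaustive" && n > 8L)
    stop("exhaustive search is limited to 8 taxa; use mode = 'heuristic'")
  enc <- .encode_columns(x, taxa, site_weights)
  run <- function() {
    if (mode == "exhaustive") .search_exhaustive(taxa, enc)
    else .search_heuristic(taxa, enc, nstart)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

.search_exhaustive <- function(taxa, enc) {
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  best <- NULL; best_score <- Inf; best_key <- ""
  for (i in seq_along(trees)) {
    tr <- trees[[i]]   # [[.multiPhylo restores the compressed tip labels
    s <- .fitch_cost(tr, enc$codes[tr$tip.label, , drop = FALSE], enc$w)
    if (s < best_score) {
      best <- tr; best_score <- s; best_key <- canonical_newick(tr)
    } else if (s == best_score) {
      k <- canonical_newick(tr)
      if (k < best_key) { best <- tr; best_key <- k }
    }
  }
  attr(best, "score") <- best_score
  best
}

.search_heuristic <- function(taxa, enc, nstart) {
  best <- NULL; best_score <- Inf; best_key <- ""
  score_tree <- function(tr)
    .fitch_cost(tr, enc$codes[tr$tip.label, , drop = FALSE], enc$w)
  for (rep in seq_len(max(1L, nstart))) {
    ord <- sample(taxa)
    tr <- .star3(ord[1:3])
    for (tx in ord[-(1:3)]) {
      cands <- lapply(seq_len(nrow(tr$edge)), function(e) .add_leaf(tr, tx, e))
      sc <- vapply(cands, score_tree, numeric(1L))
      tr <- cands[[which.min(sc)]]
    }
    cur <- score_tree(tr)
    repeat {   # NNI hill climbing to a local optimum
      nbs <- phangorn::nni(tr)
      sc <- vapply(nbs, score_tree, numeric(1L))
      if (min(sc) >= cur) break
      tr <- nbs[[which.min(sc)]]
      cur <- min(sc)
    }
    if (cur < best_score) {
      best <- tr; best_score <- cur; best_key <- canonical_newick(tr)
    } else if (cur == best_score) {
      k <- canonical_newick(tr)
      if (k < best_key) { best <- tr; best_key <- k }
    }
  }
  best <- ape::unroot(best)
  attr(best, "score") <- as.integer(best_score)
  best
}

# unrooted star on three taxa
.star3 <- function(labels) {
  structure(list(edge = matrix(c(4L, 4L, 4L, 1L, 2L, 3L), 3L, 2L),
                 tip.label = as.character(labels), Nnode = 1L),
            class = "phylo")
}

# attach a new tip in the middle of edge `edge_row` of an unrooted tree
.add_leaf <- function(tree, label, edge_row) {
  t <- length(tree$tip.label)
  E <- tree$edge
  E[E > t] <- E[E > t] + 1L      # make room for the new tip number
  newtip <- t + 1L
  v <- t + 1L + tree$Nnode + 1L  # new internal node
  p <- E[edge_row, 1L]; ch <- E[edge_row, 2L]
  E <- rbind(E[-edge_row, , drop = FALSE],
             c(p, v), c(v, ch), c(v, newtip))
  structure(list(edge = E, tip.label = c(tree$tip.label, label),
                 Nnode = tree$Nnode + 1L), class = "phylo")
}

#' Canonical Newick string of an unrooted tree topology
#'
#' A deterministic string representation: the tree is rooted at the
#' lexicographically smallest tip and children are sorted recursively, so
#' two trees have the same canonical string iff they share the same
#' unrooted topology. Used for deterministic tie-breaking.
#'
#' @param tree a `phylo` tree.
#' @return A single Newick string (no branch lengths).
#' @export
canonical_newick <- function(tree) {
  tree <- ape::unroot(tree)
  E <- tree$edge
  adj <- split(c(E[, 2L], E[, 1L]), c(E[, 1L], E[, 2L]))
  labs <- tree$tip.label
  start_tip <- which(labs == sort(labs)[1L])
  rec <- function(node, parent) {
    nb <- setdiff(adj[[as.character(node)]], parent)
    if (!length(nb)) return(labs[node])
    paste0("(", paste(sort(vapply(nb, rec, "", parent = node)),
                      collapse = ","), ")")
  }
  attach_node <- adj[[as.character(start_tip)]][1L]
  paste0("(", labs[start_tip], ",", rec(attach_node, start_tip), ");")
}
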