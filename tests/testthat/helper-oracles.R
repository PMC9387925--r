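# Independent oracles used across the test suite. These deliberately use the
# slowest, most transparent formulation available (character-by-character
# scans, exhaustive enumeration of internal states, path-length four-point
# checks) so they stay independent of the package's optimised code paths.

# naive character-by-character spaced-word extraction
oracle_spaced_word <- function(seq, pos, pattern_str) {
  sym <- strsplit(pattern_str, "")[[1]]
  ch <- strsplit(seq, "")[[1]]
  if (pos < 1 || pos + length(sym) - 1 > length(ch)) return(NA_character_)
  out <- character(0)
  for (j in seq_along(sym)) {
    c_j <- ch[pos + j - 1]
    if (!c_j %in% c("A", "C", "G", "T")) return(NA_character_)
    if (sym[j] == "1") out <- c(out, c_j)
  }
  paste(out, collapse = "")
}

# minimal changes on a quartet tree by enumerating both internal states
oracle_quartet_cost <- function(D, topology, states = 0:9) {
  top <- parse_topology(topology)
  best <- Inf
  for (u in states) for (v in states) {
    cost <- sum(D[top$cherry1] != u) + sum(D[top$cherry2] != v) + (u != v)
    best <- min(best, cost)
  }
  best
}

# brute-force small parsimony: enumerate states of internal nodes and of
# missing leaves over the 0/1/2 alphabet, count edge changes, take the min
oracle_parsimony <- function(tree, m) {
  tree <- ape::unroot(tree)
  E <- tree$edge
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  total <- 0
  for (j in seq_len(ncol(m))) {
    col <- rep("-", ntip)
    names(col) <- tree$tip.label
    hit <- intersect(tree$tip.label, rownames(m))
    col[hit] <- m[hit, j]
    state <- character(ntip + nn)
    state[seq_len(ntip)] <- col
    vars <- c(which(state == "-"), ntip + seq_len(nn))
    grid <- expand.grid(rep(list(c("0", "1", "2")), length(vars)),
                        stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      state[vars] <- unlist(grid[r, ])
      best <- min(best, sum(state[E[, 1]] != state[E[, 2]]))
    }
    total <- total + best
  }
  total
}

# four-point condition on path lengths with unit branch lengths
oracle_induced_quartet <- function(tree, q) {
  tr <- tree
  tr$edge.length <- rep(1, nrow(tr$edge))
  d <- ape::cophenetic.phylo(tr)[q, q]
  s <- c(d[q[1], q[2]] + d[q[3], q[4]],
         d[q[1], q[3]] + d[q[2], q[4]],
         d[q[1], q[4]] + d[q[2], q[3]])
  if (sum(s == min(s)) > 1) return("unresolved")
  k <- which.min(s)
  if (k == 1) quartet_topology(q[c(1, 2)], q[c(3, 4)])
  else if (k == 2) quartet_topology(q[c(1, 3)], q[c(2, 4)])
  else quartet_topology(q[c(1, 4)], q[c(2, 3)])
}

# non-trivial bipartitions of an unrooted tree as canonical strings
oracle_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  E <- tree$edge
  ntip <- length(tree$tip.label)
  desc <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(E[E[, 1] == node, 2], desc))
  }
  keys <- character(0)
  for (e in seq_len(nrow(E))) {
    if (E[e, 2] <= ntip) next                 # trivial split
    side <- sort(tree$tip.label[desc(E[e, 2])])
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    other <- sort(setdiff(tree$tip.label, side))
    keys <- c(keys, paste(min(paste(side, collapse = ","),
                              paste(other, collapse = ",")),
                          max(paste(side, collapse = ","),
                              paste(other, collapse = ",")), sep = " / "))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  b1 <- oracle_bipartitions(t1)
  b2 <- oracle_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# random nucleotide sequence
random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# random informative pair table on a taxon set (for matrix/parsimony tests)
random_pair_table <- function(taxa, ncols) {
  rows <- list()
  while (length(rows) < ncols) {
    tx <- sort(sample(taxa, 4))
    D <- sample(0:3, 4, TRUE)
    cl <- classify_support(stats::setNames(D, tx))
    if (cl$class == "uninformative") next
    rows[[length(rows) + 1]] <- data.frame(
      t1 = tx[1], t2 = tx[2], t3 = tx[3], t4 = tx[4],
      D1 = D[1], D2 = D[2], D3 = D[3], D4 = D[4],
      class = cl$class, topology = cl$topology, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# the balanced 8-taxon tree used by the simulation-recovery experiments
balanced8 <- function(branch = 0.02) {
  tr <- ape::stree(8, "balanced")
  tr$edge.length <- rep(branch, nrow(tr$edge))
  tr$tip.label <- paste0("S", 1:8)
  tr
}
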