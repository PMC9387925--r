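#' Quartet topologies
#'
#' An unrooted, fully resolved tree on four taxa is determined by how the
#' taxa split into two cherries, written `a,b|c,d`. The canonical form sorts
#' taxa within each cherry and then sorts the two cherries, so identical
#' topologies always compare equal as strings.
#'
#' @param cherry1,cherry2 character vectors of two taxon ids each.
#' @return Canonical topology string `"a,b|c,d"`.
#' @export
quartet_topology <- function(cherry1, cherry2) {
  if (length(cherry1) != 2L || length(cherry2) != 2L)
    stop("each cherry must contain exactly two taxa")
  taxa <- c(cherry1, cherry2)
  if (anyDuplicated(taxa)) stop("taxa must be pairwise distinct")
  c1 <- sort(as.character(cherry1)); c2 <- sort(as.character(cherry2))
  if (c2[1L] < c1[1L]) { tmp <- c1; c1 <- c2; c2 <- tmp }
  paste0(c1[1L], ",", c1[2L], "|", c2[1L], ",", c2[2L])
}

#' @rdname quartet_topology
#' @param x a canonical topology string.
#' @return `parse_topology` returns a list with elements `cherry1`,
#'   `cherry2` and `taxa`.
#' @export
parse_topology <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed topology string: ", x)
  c1 <- strsplit(parts[1L], ",", fixed = TRUE)[[1L]]
  c2 <- strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
  if (length(c1) != 2L || length(c2) != 2L)
    stop("malformed topology string: ", x)
  list(cherry1 = c1, cherry2 = c2, taxa = c(c1, c2))
}

#' Enumerate the three quartet topologies on four taxa
#'
#' @param taxa four distinct taxon ids.
#' @return Character vector of the three canonical topology strings.
#' @export
enumerate_topologies <- function(taxa) {
  taxa <- as.character(taxa)
  if (length(taxa) != 4L || anyDuplicated(taxa))
    stop("need exactly four distinct taxon ids")
  t <- sort(taxa)
  c(quartet_topology(t[c(1, 2)], t[c(3, 4)]),
    quartet_topology(t[c(1, 3)], t[c(2, 4)]),
    quartet_topology(t[c(1, 4)], t[c(2, 3)]))
}

#' Classify the support of a 4-distance vector
#'
#' Let `D` hold the inter-block distances of a block pair in its four taxa.
#' If two distances are equal and the other two are equal to each other but
#' different (`a,a,b,b`), the pair *strongly* supports the topology pairing
#' the equal-distance taxa: that topology explains the data with a single
#' indel event while both alternatives need two. If exactly one pair of
#' distances is equal and the remaining two differ from it and from each
#' other (`a,a,b,c`), all three topologies need two indels, but the topology
#' pairing the equal taxa is *weakly* preferred. Any other configuration is
#' uninformative.
#'
#' @param D named numeric vector of length 4 (names are taxon ids).
#' @return A list with elements `class` (`"strong"`, `"weak"` or
#'   `"uninformative"`) and `topology` (canonical string, `NA` when
#'   uninformative).
#' @export
classify_support <- function(D) {
  if (length(D) != 4L) stop("D must have exactly 4 entries")
  if (is.null(names(D)) || anyDuplicated(names(D)))
    stop("D must be named by four distinct taxa")
  u <- unique(D)
  cnt <- tabulate(match(D, u))
  if (length(u) == 2L && all(cnt == 2L)) {
    pair1 <- names(D)[D == u[1L]]
    pair2 <- names(D)[D == u[2L]]
    list(class = "strong", topology = quartet_topology(pair1, pair2))
  } else if (length(u) == 3L) {
    dup <- u[cnt == 2L]
    pair <- names(D)[D == dup]
    rest <- names(D)[D != dup]
    list(class = "weak", topology = quartet_topology(pair, rest))
  } else {
    list(class = "uninformative", topology = NA_character_)
  }
}

#' Minimal number of indel events for a quartet topology
#'
#' Treats the inter-block distance as a character and the four distances as
#' leaf states of the given quartet tree, and computes small parsimony over
#' an unbounded integer alphabet (Fitch on the single internal edge).
#'
#' @param D named numeric vector of length 4.
#' @param topology canonical topology string over the same four taxa.
#' @return Integer: minimal number of state changes (0, 1 or 2).
#' @export
min_indel_events <- function(D, topology) {
  if (length(D) != 4L || is.null(names(D)))
    stop("D must be a named vector of 4 distances")
  top <- parse_topology(topology)
  if (!setequal(top$taxa, names(D)))
    stop("topology taxa do not match names(D)")
  d1 <- unname(D[top$cherry1]); d2 <- unname(D[top$cherry2])
  cost <- 0L
  s1 <- unique(d1); if (length(s1) > 1L) cost <- cost + 1L
  s2 <- unique(d2); if (length(s2) > 1L) cost <- cost + 1L
  if (!length(intersect(s1, s2))) cost <- cost + 1L
  # a change is only needed on the internal edge when the cherry state sets
  # are disjoint; Fitch keeps the union after a forced change, which for a
  # quartet can never force a further change
  cost
}
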