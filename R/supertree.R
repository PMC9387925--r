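#' Amalgamate quartet topologies into a supertree
#'
#' Builds an unrooted tree on all taxa appearing in the quartet calls by
#' recursive weighted max-cut-style bipartitioning. Every quartet `a,b|c,d`
#' votes on candidate bipartitions: the four cross-cherry taxon pairs
#' (a,c), (a,d), (b,c), (b,d) are "good" edges (cutting them is what the
#' quartet asks for), the within-cherry pairs (a,b) and (c,d) are "bad"
#' edges (cutting them violates the quartet). At each step the bipartition
#' maximising the weighted good/bad ratio is chosen (a violation-free cut
#' with positive support ranks above every violated one); each side is then
#' resolved recursively, with the other side contracted into a placeholder
#' leaf so that rooted (triplet) information is preserved. On a
#' conflict-free, fully covering quartet set the returned tree displays
#' every input quartet; under conflict, weighted majority wins.
#'
#' For up to `exact_cut_max` taxa all bipartitions are enumerated; above
#' that a seeded randomised single-move hill climb over cuts is used.
#'
#' @param calls data frame with columns `topology` (canonical quartet
#'   strings, see [quartet_topology()]) and `n` (multiplicities); a bare
#'   character vector of topology strings is also accepted.
#' @param seed integer seed for the (large-set) randomised cut search.
#' @param exact_cut_max largest taxon set for which cuts are enumerated
#'   exhaustively.
#' @return An unrooted `phylo` tree on all taxa in `calls`.
#' @export
quartet_supertree <- function(calls, seed = NULL, exact_cut_max = 14L) {
  if (is.character(calls))
    calls <- data.frame(topology = calls, n = 1L, stringsAsFactors = FALSE)
  if (!nrow(calls)) stop("need at least one quartet call")
  parsed <- lapply(calls$topology, parse_topology)
  qt <- data.frame(
    a = vapply(parsed, function(p) p$cherry1[1L], ""),
    b = vapply(parsed, function(p) p$cherry1[2L], ""),
    c = vapply(parsed, function(p) p$cherry2[1L], ""),
    d = vapply(parsed, function(p) p$cherry2[2L], ""),
    w = as.numeric(calls$n), stringsAsFactors = FALSE)
  taxa <- sort(unique(unlist(qt[, c("a", "b", "c", "d")])))
  if (length(taxa) < 4L) stop("quartet calls must cover at least 4 taxa")
  run <- function() {
    split0 <- .best_cut(taxa, qt, out_present = FALSE, exact_cut_max)
    A <- split0$A; B <- setdiff(taxa, A)
    nwk <- paste0("(", .build_subtree(A, .reduce_quartets(qt, A), exact_cut_max),
                  ",", .build_subtree(B, .reduce_quartets(qt, B), exact_cut_max),
                  ");")
    ape::unroot(ape::read.tree(text = nwk))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

.OUT <- ".__out__"

# Newick string for the subtree on `taxa`, hung from its parent edge.
# `qt` contains quartets over taxa plus the placeholder .OUT standing for
# everything outside the subtree.
.build_subtree <- function(taxa, qt, exact_cut_max) {
  if (length(taxa) == 1L) return(taxa)
  if (length(taxa) == 2L)
    return(paste0("(", taxa[1L], ",", taxa[2L], ")"))
  if (!nrow(qt))   # no signal left: leave unresolved
    return(paste0("(", paste(sort(taxa), collapse = ","), ")"))
  cut <- .best_cut(taxa, qt, out_present = TRUE, exact_cut_max)
  A <- cut$A; B <- setdiff(taxa, A)
  paste0("(", .build_subtree(A, .reduce_quartets(qt, A), exact_cut_max),
         ",", .build_subtree(B, .reduce_quartets(qt, B), exact_cut_max), ")")
}

# restrict quartets to side `A`: members outside A (including .OUT) are
# replaced by the placeholder; quartets with fewer than 3 members in A are
# dropped, and identical reduced quartets are aggregated.
.reduce_quartets <- function(qt, A) {
  m <- as.matrix(qt[, c("a", "b", "c", "d")])
  inA <- matrix(m %in% A, nrow(qt), 4L)
  k <- rowSums(inA)
  keep4 <- k == 4L
  keep3 <- k == 3L
  rows <- vector("list", 2L)
  if (any(keep4))
    rows[[1L]] <- data.frame(m[keep4, , drop = FALSE],
                             w = qt$w[keep4], stringsAsFactors = FALSE)
  if (any(keep3)) {
    m3 <- m[keep3, , drop = FALSE]
    m3[!inA[keep3, , drop = FALSE]] <- .OUT
    rows[[2L]] <- data.frame(m3, w = qt$w[keep3], stringsAsFactors = FALSE)
  }
  red <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(red) || !nrow(red))
    return(data.frame(a = character(), b = character(), c = character(),
                      d = character(), w = numeric(), stringsAsFactors = FALSE))
  names(red) <- c("a", "b", "c", "d", "w")
  # canonicalise cherries so identical reduced quartets aggregate
  key <- vapply(seq_len(nrow(red)), function(i) {
    c1 <- sort(c(red$a[i], red$b[i])); c2 <- sort(c(red$c[i], red$d[i]))
    if (c2[1L] < c1[1L]) { tmp <- c1; c1 <- c2; c2 <- tmp }
    paste(c(c1, c2), collapse = "\r")
  }, "")
  agg <- rowsum(red$w, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(a = vapply(parts, `[[`, "", 1L),
             b = vapply(parts, `[[`, "", 2L),
             c = vapply(parts, `[[`, "", 3L),
             d = vapply(parts, `[[`, "", 4L),
             w = as.numeric(agg[, 1L]), stringsAsFactors = FALSE)
}

# choose the best bipartition A | (taxa \ A)  [+ .OUT on the complement
# side when out_present]. Returns list(A = character vector).
.best_cut <- function(taxa, qt, out_present, exact_cut_max) {
  n <- length(taxa)
  idx <- stats::setNames(seq_len(n), taxa)
  # quartet member -> taxon index, 0 for the placeholder (never in A)
  gi <- function(v) { r <- idx[v]; r[is.na(r)] <- 0L; unname(r) }
  qa <- gi(qt$a); qb <- gi(qt$b); qc <- gi(qt$c); qd <- gi(qt$d)
  w <- qt$w

  score_mask <- function(inA) {      # inA: logical over taxa indices
    mem <- function(q) q > 0L & inA[pmax(q, 1L)]
    xa <- mem(qa); xb <- mem(qb); xc <- mem(qc); xd <- mem(qd)
    good <- (xa != xc) + (xa != xd) + (xb != xc) + (xb != xd)
    bad <- (xa != xb) + (xc != xd)
    c(good = sum(w * good), bad = sum(w * bad))
  }

  rank_of <- function(s) {           # higher is better
    if (s[["bad"]] == 0 && s[["good"]] > 0) Inf
    else if (s[["bad"]] == 0) 0
    else s[["good"]] / s[["bad"]]
  }

  best <- NULL; best_rank <- -Inf; best_good <- -Inf; best_key <- ""
  consider <- function(inA) {
    s <- score_mask(inA)
    r <- rank_of(s)
    key <- paste(taxa[inA], collapse = ",")
    better <- r > best_rank ||
      (r == best_rank && (s[["good"]] > best_good ||
                          (s[["good"]] == best_good && key < best_key)))
    if (better) {
      best <<- inA; best_rank <<- r; best_good <<- s[["good"]]
      best_key <<- key
    }
  }

  if (n <= exact_cut_max) {
    for (maskval in seq_len(2L^n - 2L)) {
      inA <- bitwAnd(maskval, 2L^(seq_len(n) - 1L)) > 0L
      if (!out_present && !inA[1L]) next   # fix taxa[1] in A to kill symmetry
      consider(inA)
    }
  } else {
    for (start in 1:8) {               # randomised single-move hill climb
      inA <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(inA)) inA[sample.int(n, 1L)] <- FALSE
      if (!any(inA)) inA[sample.int(n, 1L)] <- TRUE
      repeat {
        cur <- score_mask(inA); curr <- rank_of(cur)
        improved <- FALSE
        for (i in sample.int(n)) {
          cand <- inA; cand[i] <- !cand[i]
          if (all(cand) || !any(cand)) next
          s <- rank_of(score_mask(cand))
          if (s > curr) { inA <- cand; improved <- TRUE; break }
        }
        if (!improved) break
      }
      consider(inA)
    }
  }
  list(A = taxa[best])
}
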