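#' Find the second block of a block pair
#'
#' Given a reference quartet block, searches a window of `L` nucleotides to
#' the right of the block in each of the four sequences for a second quartet
#' block with respect to `pattern2`. A candidate spaced word qualifies only
#' if it occurs *exactly once* in each of the four windows (so the pairing
#' is unambiguous); the first such word is used, where candidates are
#' ordered by their start position in the reference block's anchor taxon,
#' ties broken by lexicographic word order. No score filter is applied to
#' the second block: the probability of finding a common word in such small
#' windows by chance is already small.
#'
#' @param block one row of the block table from [sample_quartet_blocks()]
#'   (data frame row or equivalent list).
#' @param seqs the sequence set.
#' @param pattern2 pattern for the second block (default contiguous
#'   `"1111111"`, i.e. exact 7-mer matches).
#' @param L window length in nucleotides (default 500).
#' @return A list with elements `word`, `taxa`, `pos` (named positions of
#'   the second block) and `len2`, or `NULL` when no second block exists.
#' @export
find_second_block <- function(block, seqs, pattern2 = spam_pattern("1111111"),
                              L = 500L) {
  seqs <- as_sequence_set(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  .find_second_block_impl(block, chars, spam_pattern(pattern2), L)
}

# core second-block search over pre-split character vectors
.find_second_block_impl <- function(block, chars, pattern2, L) {
  taxa <- .block_taxa(block)
  pos1 <- .block_pos(block)
  len1 <- as.integer(block[["len1"]])
  l2 <- pattern2$length

  words <- vector("list", 4L)
  wpos <- vector("list", 4L)
  for (i in 1:4) {
    ch <- chars[[taxa[i]]]
    win_start <- pos1[i] + len1
    win_end <- min(win_start + L - 1L, length(ch))
    last_start <- win_end - l2 + 1L
    if (last_start < win_start) return(NULL)
    win <- ch[win_start:win_end]                # scan only the window slice
    st <- win_start - 1L + .valid_starts(win, l2)
    if (!length(st)) return(NULL)
    w <- .project_words(ch, st, pattern2$match_off)
    uniq <- !(duplicated(w) | duplicated(w, fromLast = TRUE))
    words[[i]] <- w[uniq]
    wpos[[i]] <- st[uniq]
    if (!length(words[[i]])) return(NULL)
  }
  cand <- Reduce(intersect, words)
  if (!length(cand)) return(NULL)
  anchor_i <- match(as.character(block[["anchor"]]), taxa)
  ap <- wpos[[anchor_i]][match(cand, words[[anchor_i]])]
  cand <- cand[order(ap, cand)]
  w <- cand[1L]
  pos2 <- vapply(1:4, function(i) wpos[[i]][match(w, words[[i]])], integer(1L))
  names(pos2) <- taxa
  list(word = w, taxa = taxa, pos = pos2, len2 = l2)
}

#' Inter-block distances of a block pair
#'
#' The distance in taxon `i` is the length of the segment between the two
#' blocks: `D_i = start2_i - start1_i - l1`, where `l1` is the length of the
#' reference-block pattern. All distances are non-negative for a valid pair
#' (the reference block lies strictly left of the second block).
#'
#' @param pair a block pair: one row of the table from
#'   [collect_block_pairs()], or any list with named elements `t1..t4`,
#'   `p1..p4`, `len1` and `q1..q4` (second-block positions).
#' @return Named integer vector of four distances, ascending taxon order.
#' @export
block_distances <- function(pair) {
  taxa <- .block_taxa(pair)
  p1 <- .block_pos(pair)
  p2 <- as.integer(unlist(pair[c("q1", "q2", "q3", "q4")]))
  D <- p2 - p1 - as.integer(pair[["len1"]])
  if (any(D < 0)) stop("negative inter-block distance: blocks overlap")
  names(D) <- taxa
  D[order(taxa)]
}

#' Pair reference blocks with second blocks and keep informative pairs
#'
#' For each reference block, searches for a second block (see
#' [find_second_block()]), computes the four inter-block distances and
#' classifies their support ([classify_support()]). Pairs without a second
#' block, and pairs whose distances are uninformative, are discarded;
#' counts per reason are returned as attribute `counts`.
#'
#' @inheritParams find_second_block
#' @param blocks block table from [sample_quartet_blocks()].
#' @return Data frame with one row per retained (informative) pair: taxa
#'   `t1..t4`, reference positions `p1..p4`, second-block positions
#'   `q1..q4`, distances `D1..D4` (ascending taxon order), `len1`, words of
#'   both blocks, `class` (`strong`/`weak`) and `topology`. Attribute
#'   `counts` is a named vector (`blocks`, `no_second`, `uninformative`,
#'   `strong`, `weak`).
#' @export
collect_block_pairs <- function(blocks, seqs, pattern2 = spam_pattern("1111111"),
                                L = 500L) {
  seqs <- as_sequence_set(seqs)
  pattern2 <- spam_pattern(pattern2)
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  out <- vector("list", nrow(blocks))
  n_no2 <- 0L; n_unin <- 0L; nb <- 0L
  for (r in seq_len(nrow(blocks))) {
    b <- blocks[r, ]
    second <- .find_second_block_impl(b, chars, pattern2, L)
    if (is.null(second)) { n_no2 <- n_no2 + 1L; next }
    taxa <- .block_taxa(b)
    D <- second$pos - .block_pos(b) - as.integer(b[["len1"]])
    names(D) <- taxa
    o <- order(taxa)
    D <- D[o]
    cl <- classify_support(D)
    if (cl$class == "uninformative") { n_unin <- n_unin + 1L; next }
    nb <- nb + 1L
    out[[nb]] <- data.frame(
      t1 = taxa[o][1], t2 = taxa[o][2], t3 = taxa[o][3], t4 = taxa[o][4],
      p1 = .block_pos(b)[o][1], p2 = .block_pos(b)[o][2],
      p3 = .block_pos(b)[o][3], p4 = .block_pos(b)[o][4],
      q1 = unname(second$pos[o][1]), q2 = unname(second$pos[o][2]),
      q3 = unname(second$pos[o][3]), q4 = unname(second$pos[o][4]),
      D1 = unname(D[1]), D2 = unname(D[2]), D3 = unname(D[3]),
      D4 = unname(D[4]),
      len1 = as.integer(b[["len1"]]), word1 = as.character(b[["word"]]),
      word2 = second$word, class = cl$class, topology = cl$topology,
      stringsAsFactors = FALSE)
  }
  res <- if (nb) do.call(rbind, out[seq_len(nb)]) else
    data.frame(t1 = character(), t2 = character(), t3 = character(),
               t4 = character(), p1 = integer(), p2 = integer(),
               p3 = integer(), p4 = integer(), q1 = integer(),
               q2 = integer(), q3 = integer(), q4 = integer(),
               D1 = integer(), D2 = integer(), D3 = integer(),
               D4 = integer(), len1 = integer(), word1 = character(),
               word2 = character(), class = character(),
               topology = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  counts <- c(blocks = nrow(blocks), no_second = n_no2,
              uninformative = n_unin,
              strong = sum(res$class == "strong"),
              weak = sum(res$class == "weak"))
  attr(res, "counts") <- counts
  res
}

#' Aggregate quartet calls from informative block pairs
#'
#' @param pairs pair table from [collect_block_pairs()].
#' @param strong_only keep only strongly supporting pairs (parsimony-
#'   informative signal), dropping weak ones.
#' @return Data frame with columns `topology` (canonical string) and `n`
#'   (multiplicity), sorted by topology.
#' @export
quartet_calls <- function(pairs, strong_only = FALSE) {
  if (strong_only) pairs <- pairs[pairs$class == "strong", , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(topology = character(), n = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(pairs$topology)
  data.frame(topology = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
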