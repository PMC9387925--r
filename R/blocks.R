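#' Index all spaced-word occurrences in a sequence set
#'
#' Enumerates every window of pattern length whose characters are all in
#' \{A,C,G,T\} and projects it onto the match positions. Occurrences are
#' grouped by spaced word and sorted by (word, taxon id, position).
#'
#' @param seqs sequence set (named character vector, `DNAStringSet`, or
#'   FASTA path); see [as_sequence_set()].
#' @param pattern a `spam_pattern` (default: [default_pattern()]).
#' @return A `data.table` with columns `word`, `seq_id`, `pos` (1-based),
#'   carrying the pattern as attribute `pattern`.
#' @export
index_spaced_words <- function(seqs, pattern = default_pattern()) {
  seqs <- as_sequence_set(seqs, min_n = 1L)
  pattern <- spam_pattern(pattern)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    st <- .valid_starts(ch, pattern$length)
    if (!length(st)) next
    out[[i]] <- data.table::data.table(
      word = .project_words(ch, st, pattern$match_off),
      seq_id = names(seqs)[i],
      pos = st)
  }
  idx <- data.table::rbindlist(out)
  if (nrow(idx) == 0L)
    idx <- data.table::data.table(word = character(), seq_id = character(),
                                  pos = integer())
  data.table::setorder(idx, word, seq_id, pos)
  data.table::setattr(idx, "pattern", pattern)
  idx[]
}

# starts of windows of length l containing only A/C/G/T
.valid_starts <- function(ch, l) {
  n <- length(ch)
  if (n < l) return(integer())
  bad <- cumsum(!(ch %in% .BASES))
  st <- seq_len(n - l + 1L)
  st[(bad[st + l - 1L] - c(0L, bad)[st]) == 0L]
}

# project windows at `starts` onto match offsets, returning word strings
.project_words <- function(ch, starts, match_off) {
  cols <- lapply(match_off, function(o) ch[starts + o - 1L])
  do.call(paste0, cols)
}

#' Sample quartet blocks
#'
#' A quartet block is one spaced word occurring in four *different*
#' sequences: a local, gap-free four-way alignment. To exclude random
#' matches, one occurrence serves as the *anchor* and the other three must
#' each have a strictly positive don't-care score against it.
#'
#' Sampling scheme: spaced words with occurrences in at least four distinct
#' sequences are visited in seeded random order; for each word up to
#' `quartets_per_word` quartets are drawn (random anchor occurrence, then one
#' random occurrence from each of three other randomly chosen sequences),
#' retrying up to `retries` times when the positive-score filter fails.
#' Sampling stops once `max_blocks` blocks have been collected.
#'
#' @param index spaced-word index from [index_spaced_words()].
#' @param seqs the sequence set the index was built from.
#' @param pattern the pattern used to build the index.
#' @param score_matrix substitution score matrix.
#' @param max_blocks cap on the number of blocks (default one million).
#' @param quartets_per_word quartets drawn per eligible word (default 1).
#' @param retries bounded retries when the score filter fails (default 5).
#' @param min_score blocks require anchor scores strictly greater than this
#'   (default 0, i.e. "positive score").
#' @param seed integer seed; fixing it fixes the output exactly.
#' @return A data frame with one row per block: `word`, taxon ids
#'   `t1..t4` (ascending), positions `p1..p4`, `anchor` (taxon id of the
#'   anchor occurrence), scores `s1..s4` against the anchor (`NA` for the
#'   anchor itself) and `len1` (pattern length). Attribute `pattern` holds
#'   the pattern.
#' @export
sample_quartet_blocks <- function(index, seqs, pattern = attr(index, "pattern"),
                                  score_matrix = default_score_matrix(),
                                  max_blocks = 1e6, quartets_per_word = 1L,
                                  retries = 5L, min_score = 0, seed = NULL) {
  if (is.null(pattern)) stop("pattern must be supplied (or carried by the index)")
  run <- function() .sample_blocks_impl(index, seqs, spam_pattern(pattern),
                                        score_matrix, max_blocks,
                                        quartets_per_word, retries, min_score)
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

.sample_blocks_impl <- function(index, seqs, pattern, score_matrix, max_blocks,
                                quartets_per_word, retries, min_score) {
  seqs <- as_sequence_set(seqs)
  check_score_matrix(score_matrix)
  empty <- data.frame(word = character(),
                      t1 = character(), t2 = character(), t3 = character(),
                      t4 = character(), p1 = integer(), p2 = integer(),
                      p3 = integer(), p4 = integer(), anchor = character(),
                      s1 = numeric(), s2 = numeric(), s3 = numeric(),
                      s4 = numeric(), len1 = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(index) == 0L) return(.with_pattern(empty, pattern))

  seq_id <- word <- NULL  # data.table NSE
  counts <- index[, list(nseq = data.table::uniqueN(seq_id)), by = word]
  words <- counts[counts$nseq >= 4L, ][["word"]]
  if (!length(words)) return(.with_pattern(empty, pattern))
  words <- sample(words)

  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  dt <- data.table::as.data.table(index)
  data.table::setkey(dt, word)

  blocks <- vector("list", min(length(words) * quartets_per_word, max_blocks))
  nb <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())

  for (w in words) {
    if (nb >= max_blocks) break
    occ <- dt[list(w)]
    sids <- unique(occ$seq_id)
    for (rep in seq_len(quartets_per_word)) {
      if (nb >= max_blocks) break
      for (try in seq_len(max(1L, retries))) {
        ai <- sample.int(nrow(occ), 1L)
        a_sid <- occ$seq_id[ai]; a_pos <- occ$pos[ai]
        others <- setdiff(sids, a_sid)
        if (length(others) < 3L) break
        pick_sids <- sample(others, 3L)
        pick_pos <- integer(3L)
        for (j in 1:3) {
          p <- occ$pos[occ$seq_id == pick_sids[j]]
          pick_pos[j] <- if (length(p) == 1L) p else sample(p, 1L)
        }
        sc <- vapply(1:3, function(j)
          .dc_score(chars[[a_sid]], a_pos, chars[[pick_sids[j]]], pick_pos[j],
                    pattern$dontcare_off, score_matrix), numeric(1L))
        if (all(sc > min_score)) {
          tx <- c(a_sid, pick_sids); ps <- c(a_pos, pick_pos)
          o <- order(tx)
          key <- paste(w, paste(tx[o], ps[o], collapse = ";"), sep = "|")
          if (!is.null(seen[[key]])) break
          seen[[key]] <- TRUE
          svec <- c(NA_real_, sc)[o]
          nb <- nb + 1L
          blocks[[nb]] <- data.frame(
            word = w, t1 = tx[o][1], t2 = tx[o][2], t3 = tx[o][3],
            t4 = tx[o][4], p1 = ps[o][1], p2 = ps[o][2], p3 = ps[o][3],
            p4 = ps[o][4], anchor = a_sid,
            s1 = svec[1], s2 = svec[2], s3 = svec[3], s4 = svec[4],
            len1 = pattern$length, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  res <- if (nb) do.call(rbind, blocks[seq_len(nb)]) else empty
  rownames(res) <- NULL
  .with_pattern(res, pattern)
}

.with_pattern <- function(df, pattern) {
  attr(df, "pattern") <- pattern
  df
}

# accessors for the four (taxon, position) slots of a block row
.block_taxa <- function(block) as.character(unlist(block[c("t1", "t2", "t3", "t4")]))
.block_pos  <- function(block) as.integer(unlist(block[c("p1", "p2", "p3", "p4")]))
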