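# helper: build four sequences sharing a reference block ("AGTC", pattern
# 1101) and a second block ("CAGTA", pattern 10111) separated by the given
# gap lengths, and run the pair stage on them
pair_from_gaps <- function(gaps, taxa = paste0("S", seq_along(gaps)),
                           L = 500L) {
  fills <- c("TTGT", "TGTT", "GTTG", "GGTT", "TTGG", "GTGT")
  seqs <- setNames(vapply(seq_along(gaps), function(i)
    paste0("CC", "AGTC", substr(fills[i], 1, gaps[i]), "CAGTA", "GG"), ""),
    taxa)
  idx <- index_spaced_words(seqs, "1101")
  blocks <- sample_quartet_blocks(idx, seqs, "1101", max_blocks = 500,
                                  seed = 4)
  pairs <- collect_block_pairs(blocks, seqs, "10111", L)
  list(seqs = seqs, blocks = blocks, pairs = pairs)
}

test_that("a shared downstream word yields a second block with equal D", {
  # four identical sequences: the unique downstream block is found and all
  # four distances agree (hence uninformative)
  res <- pair_from_gaps(c(2, 2, 2, 2))
  expect_gt(nrow(res$blocks), 0)
  b <- res$blocks[res$blocks$word == "AGC", ][1, ]
  sec <- find_second_block(b, res$seqs, "10111", L = 500)
  expect_false(is.null(sec))
  D <- sec$pos - as.integer(unlist(b[c("p1", "p2", "p3", "p4")])) - b$len1
  expect_true(all(D == D[1]))
  expect_equal(nrow(res$pairs), 0L)  # everything equal -> discarded
  cnt <- attr(res$pairs, "counts")
  expect_gt(cnt[["uninformative"]], 0)
})

test_that("the toy strong geometry gives the expected distances and call", {
  tb <- toy_block_pair("strong")
  expect_equal(unname(tb$D[c("S2", "S4", "S5", "S8")]), c(2L, 3L, 2L, 3L))
  expect_equal(tb$class, "strong")
  expect_equal(tb$topology, "S2,S5|S4,S8")
  res <- pair_from_gaps(c(2, 3, 2, 3), taxa = c("S2", "S4", "S5", "S8"))
  expect_gt(nrow(res$pairs), 0)
  expect_true(all(res$pairs$class == "strong"))
  expect_true(all(res$pairs$topology == "S2,S5|S4,S8"))
  # distances re-derived by slicing the sequences between the two blocks
  for (r in seq_len(nrow(res$pairs))) {
    pr <- res$pairs[r, ]
    taxa <- as.character(unlist(pr[c("t1", "t2", "t3", "t4")]))
    for (i in 1:4) {
      seg <- substr(res$seqs[[taxa[i]]],
                    pr[[paste0("p", i)]] + pr$len1,
                    pr[[paste0("q", i)]] - 1)
      expect_equal(nchar(seg), pr[[paste0("D", i)]])
    }
  }
})

test_that("the toy weak geometry weakly supports pairing the equal taxa", {
  tb <- toy_block_pair("weak")
  expect_equal(unname(tb$D[c("S1", "S4", "S5", "S6")]), c(2L, 2L, 3L, 4L))
  expect_equal(tb$class, "weak")
  expect_equal(tb$topology, "S1,S4|S5,S6")
  res <- pair_from_gaps(c(2, 2, 3, 4), taxa = c("S1", "S4", "S5", "S6"))
  expect_gt(nrow(res$pairs), 0)
  expect_true(all(res$pairs$class == "weak"))
  expect_true(all(res$pairs$topology == "S1,S4|S5,S6"))
})

test_that("words repeated inside a window are rejected as ambiguous", {
  mk <- function(first) paste0("ACGT", "CCCCCCC", first, "GGGGGGG", "TT")
  # S1 carries the candidate 7-mer CCCCCCC twice in its window; the other
  # three carry it once. It is therefore not unique in S1 and the next
  # candidate (GGGGGGG) must be chosen instead.
  seqs <- c(S1 = mk("ACCCCCCCA"), S2 = mk("TTTTATTTT"),
            S3 = mk("TTTTATTTT"), S4 = mk("TTTTATTTT"))
  block <- data.frame(word = "ACGT", t1 = "S1", t2 = "S2", t3 = "S3",
                      t4 = "S4", p1 = 1L, p2 = 1L, p3 = 1L, p4 = 1L,
                      anchor = "S1", len1 = 4L)
  sec <- find_second_block(block, seqs, "1111111", L = 100L)
  expect_equal(sec$word, "GGGGGGG")
  # without the duplication the all-C word is the leftmost unique candidate
  seqs2 <- c(S1 = mk("TTTTATTTT"), S2 = mk("TTTTATTTT"),
             S3 = mk("TTTTATTTT"), S4 = mk("TTTTATTTT"))
  sec2 <- find_second_block(block, seqs2, "1111111", L = 100L)
  expect_equal(sec2$word, "CCCCCCC")
})

test_that("windows sharing no common word give no second block", {
  seqs <- c(S1 = paste0("ACGT", strrep("A", 60)),
            S2 = paste0("ACGT", strrep("C", 60)),
            S3 = paste0("ACGT", strrep("G", 60)),
            S4 = paste0("ACGT", strrep("T", 60)))
  block <- data.frame(word = "ACGT", t1 = "S1", t2 = "S2", t3 = "S3",
                      t4 = "S4", p1 = 1L, p2 = 1L, p3 = 1L, p4 = 1L,
                      anchor = "S1", len1 = 4L)
  expect_null(find_second_block(block, seqs, "1111111", L = 50L))
})

test_that("block_distances matches slicing and rejects overlap", {
  pr <- list(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
             p1 = 10L, p2 = 20L, p3 = 30L, p4 = 40L,
             q1 = 17L, q2 = 27L, q3 = 40L, q4 = 47L, len1 = 7L)
  expect_equal(block_distances(pr), c(a = 0L, b = 0L, c = 3L, d = 0L))
  bad <- pr; bad$q1 <- 12L
  expect_error(block_distances(bad), "overlap")
  # random geometries: D equals the sliced segment length
  withr::with_seed(8, {
    for (i in 1:25) {
      gaps <- sample(0:4, 4, TRUE)
      res <- pair_from_gaps(gaps)
      for (r in seq_len(nrow(res$pairs))) {
        p <- res$pairs[r, ]
        D <- block_distances(p)
        taxa <- as.character(unlist(p[c("t1", "t2", "t3", "t4")]))
        for (i2 in 1:4) {
          tx <- taxa[i2]
          seg <- substr(res$seqs[[tx]], p[[paste0("p", i2)]] + p$len1,
                        p[[paste0("q", i2)]] - 1)
          expect_equal(unname(D[tx]), nchar(seg))
        }
      }
    }
  })
})

test_that("enlarging the window never loses pairable reference blocks", {
  withr::with_seed(31, {
    tr <- balanced8()
    sim <- simulate_sequences(tr, root_length = 4000, indel_rate = 0.1,
                              seed = 55)
  })
  p <- default_pattern()
  idx <- index_spaced_words(sim$sequences, p)
  blocks <- sample_quartet_blocks(idx, sim$sequences, p, max_blocks = 60,
                                  seed = 55)
  n_with_second <- function(L) {
    sum(vapply(seq_len(nrow(blocks)), function(r)
      !is.null(find_second_block(blocks[r, ], sim$sequences, "1111111", L)),
      logical(1)))
  }
  counts <- vapply(c(100L, 250L, 500L), n_with_second, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("collect_block_pairs retains only informative pairs and logs counts", {
  res <- pair_from_gaps(c(2, 3, 2, 3))
  cnt <- attr(res$pairs, "counts")
  expect_equal(unname(cnt[["strong"]] + cnt[["weak"]]), nrow(res$pairs))
  expect_equal(unname(cnt[["blocks"]]), nrow(res$blocks))
  expect_true(all(res$pairs$class %in% c("strong", "weak")))
  # empty block list -> empty pair table
  empty <- res$blocks[0, ]
  out <- collect_block_pairs(empty, res$seqs)
  expect_equal(nrow(out), 0L)
})
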