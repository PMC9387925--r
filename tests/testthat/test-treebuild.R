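test_that("character-matrix columns encode equal distances by equal symbols", {
  taxa <- paste0("S", 1:8)
  pairs <- data.frame(
    t1 = c("S2", "S1"), t2 = c("S4", "S4"), t3 = c("S5", "S5"),
    t4 = c("S8", "S6"),
    D1 = c(2, 2), D2 = c(3, 2), D3 = c(2, 3), D4 = c(3, 4),
    class = c("strong", "weak"),
    topology = c("S2,S5|S4,S8", "S1,S4|S5,S6"), stringsAsFactors = FALSE)
  m <- build_character_matrix(pairs, taxa)
  expect_equal(dim(m), c(8L, 2L))
  expect_equal(unname(m[c("S2", "S4", "S5", "S8"), 1]),
               c("0", "1", "0", "1"))
  expect_equal(unname(m[c("S1", "S4", "S5", "S6"), 2]),
               c("0", "0", "1", "2"))
  expect_equal(sum(m[, 1] == "-"), 4L)
  # strong columns use two symbols, weak columns three
  expect_length(setdiff(unique(m[, 1]), "-"), 2L)
  expect_length(setdiff(unique(m[, 2]), "-"), 3L)
  # empty input and uninformative input
  expect_equal(ncol(build_character_matrix(pairs[0, ], taxa)), 0L)
  bad <- pairs; bad$class[1] <- "uninformative"
  expect_error(build_character_matrix(bad, taxa), "informative")
})

test_that("parsimony scoring matches both oracles on random matrices", {
  withr::with_seed(42, {
    for (i in 1:15) {
      n <- sample(4:7, 1)
      taxa <- paste0("t", 1:n)
      pairs <- random_pair_table(taxa, sample(2:5, 1))
      m <- build_character_matrix(pairs, taxa)
      tr <- ape::rtopology(n, tip.label = taxa)
      s <- parsimony_score(tr, m)
      # independent brute force over all internal (and missing-leaf) states
      expect_equal(s, oracle_parsimony(tr, m))
      # independent library implementation of Fitch parsimony
      pd <- phangorn::phyDat(m, type = "USER", levels = c("0", "1", "2"),
                             ambiguity = "-")
      expect_equal(s, as.integer(phangorn::fitch(tr, pd)))
    }
  })
})

test_that("a strong column costs 1 on its topology and 2 on alternatives", {
  taxa <- c("a", "b", "c", "d")
  pairs <- data.frame(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                      D1 = 5, D2 = 5, D3 = 9, D4 = 9, class = "strong",
                      topology = "a,b|c,d", stringsAsFactors = FALSE)
  m <- build_character_matrix(pairs, taxa)
  good <- ape::read.tree(text = "((a,b),(c,d));")
  alt <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(parsimony_score(good, m), 1L)
  expect_equal(parsimony_score(alt, m), 2L)
  # all-missing column costs nothing
  m2 <- matrix("-", 4, 1, dimnames = list(taxa, NULL))
  expect_equal(parsimony_score(good, m2), 0L)
  # per-column score equals the quartet cost induced by the tree
  withr::with_seed(6, {
    for (i in 1:10) {
      taxa6 <- paste0("s", 1:6)
      pairs6 <- random_pair_table(taxa6, 4)
      pairs6 <- pairs6[pairs6$class == "strong", , drop = FALSE]
      if (!nrow(pairs6)) next
      m6 <- build_character_matrix(pairs6, taxa6)
      tr6 <- ape::rtopology(6, tip.label = taxa6)
      expected <- 0L
      for (j in seq_len(nrow(pairs6))) {
        tx <- as.character(unlist(pairs6[j, c("t1", "t2", "t3", "t4")]))
        D <- setNames(as.numeric(unlist(pairs6[j, c("D1", "D2", "D3", "D4")])),
                      tx)
        ind <- induced_quartet(tr6, tx)
        expected <- expected + min_indel_events(D, ind)
      }
      expect_equal(parsimony_score(tr6, m6), expected)
    }
  })
})

test_that("weak columns add 2 to every tree and never change the optimum", {
  withr::with_seed(19, {
    for (i in 1:10) {
      taxa <- paste0("t", 1:6)
      strong <- random_pair_table(taxa, 3)
      strong <- strong[strong$class == "strong", , drop = FALSE]
      weak <- random_pair_table(taxa, 8)
      weak <- weak[weak$class == "weak", , drop = FALSE][1, , drop = FALSE]
      if (!nrow(strong) || !nrow(weak)) next
      ms <- build_character_matrix(strong, taxa)
      mw <- build_character_matrix(rbind(strong, weak), taxa)
      for (k in 1:4) {
        tr <- ape::rtopology(6, tip.label = taxa)
        expect_equal(parsimony_score(tr, mw), parsimony_score(tr, ms) + 2L)
      }
    }
  })
})

test_that("exhaustive search attains the global optimum on the toy matrix", {
  tcm <- toy_character_matrix()
  expect_equal(dim(tcm$matrix), c(6L, 4L))
  best <- search_parsimony_tree(tcm$matrix, mode = "exhaustive")
  trees <- phangorn::allTrees(6, rooted = FALSE,
                              tip.label = rownames(tcm$matrix))
  oracle_scores <- vapply(seq_along(trees), function(i)
    oracle_parsimony(trees[[i]], tcm$matrix), numeric(1))
  expect_equal(attr(best, "score"), as.integer(min(oracle_scores)))
  expect_equal(oracle_parsimony(best, tcm$matrix), min(oracle_scores))
})

test_that("a single strong column on four taxa returns its own topology", {
  pairs <- data.frame(t1 = "a", t2 = "b", t3 = "c", t4 = "d",
                      D1 = 1, D2 = 7, D3 = 1, D4 = 7, class = "strong",
                      topology = "a,c|b,d", stringsAsFactors = FALSE)
  m <- build_character_matrix(pairs, c("a", "b", "c", "d"))
  tr <- search_parsimony_tree(m, mode = "exhaustive")
  expect_equal(induced_quartet(tr, c("a", "b", "c", "d")), "a,c|b,d")
})

test_that("heuristic search matches the exhaustive optimum", {
  withr::with_seed(23, {
    for (i in 1:12) {
      n <- sample(5:8, 1)
      taxa <- paste0("t", 1:n)
      pairs <- random_pair_table(taxa, sample(3:6, 1))
      m <- build_character_matrix(pairs, taxa)
      e <- search_parsimony_tree(m, mode = "exhaustive")
      h <- search_parsimony_tree(m, mode = "heuristic", seed = 100 + i)
      expect_equal(attr(h, "score"), attr(e, "score"))
    }
  })
})

test_that("supertree reproduces the generating tree from its quartets", {
  withr::with_seed(29, {
    for (i in 1:5) {
      tt <- ape::rtopology(6, tip.label = paste0("x", 1:6))
      quartets <- combn(tt$tip.label, 4)
      calls <- data.frame(
        topology = apply(quartets, 2, function(q) induced_quartet(tt, q)),
        n = 1)
      st <- quartet_supertree(calls, seed = i)
      expect_equal(rf_distance(st, tt), 0L)
    }
  })
})

test_that("supertree base cases and majority resolution", {
  one <- quartet_supertree(data.frame(topology = "t1,t2|t3,t4", n = 1))
  expect_equal(induced_quartet(one, paste0("t", 1:4)), "t1,t2|t3,t4")
  conf <- data.frame(topology = c("a,b|c,d", "a,c|b,d"), n = c(10, 1))
  expect_equal(induced_quartet(quartet_supertree(conf), c("a", "b", "c", "d")),
               "a,b|c,d")
  expect_error(quartet_supertree(conf[0, ]), "at least one")
})

test_that("supertree is equivariant under taxon relabeling", {
  withr::with_seed(37, {
    tt <- ape::rtopology(6, tip.label = paste0("x", 1:6))
    quartets <- combn(tt$tip.label, 4)
    calls <- data.frame(
      topology = apply(quartets, 2, function(q) induced_quartet(tt, q)),
      n = 1)
    st <- quartet_supertree(calls, seed = 2)
    perm <- setNames(paste0("y", sample(1:6)), tt$tip.label)
    relabel <- function(top) {
      p <- parse_topology(top)
      quartet_topology(unname(perm[p$cherry1]), unname(perm[p$cherry2]))
    }
    calls2 <- data.frame(topology = vapply(calls$topology, relabel, ""), n = 1)
    st2 <- quartet_supertree(calls2, seed = 2)
    st_relab <- st
    st_relab$tip.label <- unname(perm[st$tip.label])
    expect_equal(rf_distance(st2, st_relab), 0L)
  })
})

test_that("matrix and quartet exports round-trip losslessly", {
  tcm <- toy_character_matrix()
  m <- tcm$matrix
  # relaxed PHYLIP
  txt <- write_phylip_matrix(m)
  expect_equal(txt[1], "6 4")
  back <- read_phylip_matrix(txt)
  expect_equal(unname(back), unname(m))
  expect_equal(rownames(back), rownames(m))
  # NEXUS structure
  nx <- write_nexus_matrix(m)
  expect_equal(nx[1], "#NEXUS")
  expect_true(any(grepl("NTAX=6 NCHAR=4", nx)))
  expect_true(any(grepl("MISSING=-", nx)))
  # quartet list with multiplicities
  calls <- data.frame(topology = c("S1,S2|S3,S6", "S3,S6|S4,S5"), n = c(3L, 1L))
  lines <- export_quartets(calls)
  expect_length(lines, 4)
  expect_equal(parse_quartets(lines), calls)
  f <- withr::local_tempfile()
  export_quartets(calls, f)
  expect_equal(parse_quartets(f), calls)
})
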