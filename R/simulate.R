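#' Simulate sequence evolution with substitutions and indels
#'
#' Evolves a random root sequence along a tree with branch lengths in
#' expected substitutions per site. Substitutions follow the Jukes-Cantor
#' model (each site changes with the exact JC probability for the branch
#' length and picks one of the three other bases uniformly). Indel events
#' occur as a Poisson process with `indel_rate` expected events per site
#' per unit branch length, insertion and deletion equiprobable, positions
#' uniform, lengths geometric with mean `mean_indel_length`. Every indel is
#' recorded in an event log so tests can relate planted events to the
#' signal the pipeline extracts.
#'
#' @param tree `phylo` tree with branch lengths; tip labels become taxon
#'   ids. Internal nodes are identified in the event log by their ape node
#'   number.
#' @param root_length length of the root sequence in nucleotides.
#' @param sub_scale multiplier on branch lengths for the substitution
#'   process (0 switches substitutions off).
#' @param indel_rate expected indel events per site per unit branch length
#'   (0 switches indels off). The default 0.1 makes indels about a tenth as
#'   frequent as substitutions, a typical ratio for nuclear DNA.
#' @param mean_indel_length mean of the geometric indel length
#'   distribution (default 5).
#' @param seed integer seed; the same seed reproduces the output exactly.
#' @return List with `sequences` (named character vector, one per tip),
#'   `events` (data frame: `branch_to` node number, `branch_label`, `type`,
#'   `pos` in the pre-event sequence, `length`) and `tree`.
#' @export
simulate_sequences <- function(tree, root_length = 50000L, sub_scale = 1,
                               indel_rate = 0.1, mean_indel_length = 5,
                               seed = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (root_length < 1L) stop("root_length must be >= 1")
  if (sub_scale < 0 || indel_rate < 0) stop("rates must be >= 0")
  if (mean_indel_length < 1) stop("mean_indel_length must be >= 1")
  run <- function() .simulate_impl(tree, as.integer(root_length), sub_scale,
                                   indel_rate, mean_indel_length)
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

.simulate_impl <- function(tree, root_length, sub_scale, indel_rate,
                           mean_len) {
  q <- 1 / mean_len
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- sample(.BASES, root_length, replace = TRUE)
  events <- list()
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  E <- tree$edge

  label_of <- function(node)
    if (node <= ntip) tree$tip.label[node] else paste0("node", node)

  for (e in seq_len(nrow(E))) {
    p <- E[e, 1L]; ch <- E[e, 2L]; t <- tree$edge.length[e]
    s <- node_seq[[p]]
    # substitutions (exact JC transition probability)
    ts <- t * sub_scale
    if (ts > 0) {
      psub <- 0.75 * (1 - exp(-4 * ts / 3))
      hit <- which(stats::runif(length(s)) < psub)
      if (length(hit)) {
        repl <- .BASES[
          (match(s[hit], .BASES) - 1L + sample.int(3L, length(hit),
                                                   replace = TRUE)) %% 4L + 1L]
        s[hit] <- repl
      }
    }
    # indels
    nev <- stats::rpois(1L, indel_rate * t * length(s))
    for (k in seq_len(nev)) {
      len <- stats::rgeom(1L, q) + 1L
      type <- if (stats::runif(1L) < 0.5) "insertion" else "deletion"
      if (type == "deletion") {
        if (length(s) <= len + 1L) next   # never delete the whole sequence
        pos <- sample.int(length(s) - len + 1L, 1L)
        s <- s[-(pos:(pos + len - 1L))]
      } else {
        pos <- sample.int(length(s) + 1L, 1L)   # insert before `pos`
        s <- append(s, sample(.BASES, len, replace = TRUE), after = pos - 1L)
      }
      events[[length(events) + 1L]] <- data.frame(
        branch_to = ch, branch_label = label_of(ch), type = type,
        pos = pos, length = len, stringsAsFactors = FALSE)
    }
    node_seq[[ch]] <- s
  }
  seqs <- vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""),
                 "")
  names(seqs) <- tree$tip.label
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(branch_to = integer(), branch_label = character(),
               type = character(), pos = integer(), length = integer(),
               stringsAsFactors = FALSE)
  list(sequences = seqs, events = ev, tree = tree)
}

#' Toy block-pair geometries
#'
#' Small hand-built four-sequence sets in which a reference block (pattern
#' `"1101"`) and a second block (pattern `"10111"`) occur at known
#' positions, with inter-block segment lengths 2,3,2,3 (`"strong"`; the
#' distances strongly support pairing the two distance-2 taxa against the
#' two distance-3 taxa) or 2,2,3,4 (`"weak"`). Useful as worked examples
#' and as fixtures exercising the whole block-pair machinery.
#'
#' @param which `"strong"` or `"weak"`.
#' @return List with `seqs` (four named sequences), `pattern1`, `pattern2`,
#'   `D` (the expected distance vector, ascending taxon order), `class` and
#'   `topology` (the expected call).
#' @export
toy_block_pair <- function(which = c("strong", "weak")) {
  which <- match.arg(which)
  pattern1 <- spam_pattern("1101")
  pattern2 <- spam_pattern("10111")
  block1 <- "AGTC"                       # spaced word A,G,*,C
  block2 <- "CAGTA"                      # spaced word C,*,G,T,A
  gaps <- if (which == "strong") c(2L, 3L, 2L, 3L) else c(2L, 2L, 3L, 4L)
  taxa <- if (which == "strong") c("S2", "S4", "S5", "S8")
          else c("S1", "S4", "S5", "S6")
  fill <- c("TTGT", "TGTT", "GTTG", "GGTT")  # distinct fillers, no stray matches
  seqs <- vapply(seq_along(taxa), function(i)
    paste0("CC", block1, substr(fill[i], 1L, gaps[i]), block2, "GG"), "")
  names(seqs) <- taxa
  D <- stats::setNames(gaps, taxa)[order(taxa)]
  cl <- classify_support(D)
  list(seqs = seqs, pattern1 = pattern1, pattern2 = pattern2, D = D,
       class = cl$class, topology = cl$topology)
}

#' Toy six-taxon character matrix
#'
#' A 6-taxon, 4-column character matrix built from four strongly supporting
#' block pairs with quartets `S1,S2|S3,S6`, `S3,S6|S4,S5`, `S1,S6|S4,S5`
#' and `S1,S4|S2,S5`; each column has two missing cells for the two
#' uninvolved taxa. The standard worked example for the maximum-parsimony
#' route.
#'
#' @return List with `matrix` (6x4 character matrix) and `pairs` (the
#'   synthetic pair table it encodes).
#' @export
toy_character_matrix <- function() {
  tops <- c("S1,S2|S3,S6", "S3,S6|S4,S5", "S1,S6|S4,S5", "S1,S4|S2,S5")
  taxa <- paste0("S", 1:6)
  rows <- lapply(tops, function(tp) {
    p <- parse_topology(tp)
    tx <- sort(p$taxa)
    # distances: cherry membership decides equality; values are arbitrary
    D <- ifelse(tx %in% p$cherry1, 2L, 5L)
    data.frame(t1 = tx[1], t2 = tx[2], t3 = tx[3], t4 = tx[4],
               D1 = D[1], D2 = D[2], D3 = D[3], D4 = D[4],
               class = "strong", topology = tp, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  list(matrix = build_character_matrix(pairs, taxa), pairs = pairs)
}
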