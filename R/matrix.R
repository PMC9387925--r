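#' Build a parsimony character matrix from informative block pairs
#'
#' Rows are taxa, one column per informative block pair. Within a column the
#' four involved taxa get symbols '0', '1', '2' such that equal inter-block
#' distances get the same symbol (first-seen distance in ascending taxon
#' order is '0', the next new distance '1', then '2'); the symbols themselves
#' are arbitrary, only equality matters. Taxa not involved in a pair get
#' '-' for missing information.
#'
#' @param pairs informative pair table from [collect_block_pairs()], or any
#'   data frame with columns `t1..t4`, `D1..D4` and `class`.
#' @param taxa character vector of all taxa (row order of the matrix).
#' @return Character matrix with rownames `taxa`; `"-"` marks missing cells.
#' @export
build_character_matrix <- function(pairs, taxa) {
  taxa <- as.character(taxa)
  m <- matrix("-", nrow = length(taxa), ncol = nrow(pairs),
              dimnames = list(taxa, NULL))
  if (!nrow(pairs)) return(m)
  if (any(!pairs$class %in% c("strong", "weak")))
    stop("all pairs must be informative (strong or weak)")
  syms <- c("0", "1", "2")
  for (j in seq_len(nrow(pairs))) {
    tx <- as.character(unlist(pairs[j, c("t1", "t2", "t3", "t4")]))
    D <- as.numeric(unlist(pairs[j, c("D1", "D2", "D3", "D4")]))
    o <- order(tx)           # ascending taxon order defines first-seen
    tx <- tx[o]; D <- D[o]
    if (!all(tx %in% taxa)) stop("pair involves unknown taxa")
    codes <- syms[match(D, unique(D))]
    m[tx, j] <- codes
  }
  m
}

#' Export quartet calls as a quartet-list text
#'
#' One `a,b|c,d` record per call, repeated by multiplicity, in the format
#' accepted by quartet amalgamation tools. [parse_quartets()] reads the
#' format back, aggregating repeats.
#'
#' @param calls data frame with columns `topology` and `n` (see
#'   [quartet_calls()]).
#' @param path optional output file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to `path`).
#' @export
export_quartets <- function(calls, path = NULL) {
  lines <- rep(calls$topology, calls$n)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname export_quartets
#' @export
parse_quartets <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  canon <- vapply(lines, function(x) {
    p <- parse_topology(x)
    quartet_topology(p$cherry1, p$cherry2)
  }, "", USE.NAMES = FALSE)
  tab <- table(canon)
  data.frame(topology = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Character-matrix writers and readers
#'
#' Relaxed-PHYLIP and NEXUS writers for the 0/1/2 character matrix with '-'
#' as the missing symbol; the PHYLIP reader allows lossless round-trips.
#'
#' @param x character matrix from [build_character_matrix()].
#' @param path optional output file.
#' @return The text (character vector of lines); invisibly when written.
#' @export
write_phylip_matrix <- function(x, path = NULL) {
  nm <- rownames(x)
  pad <- formatC(nm, width = max(nchar(nm)) + 2L, flag = "-")
  lines <- c(paste(nrow(x), ncol(x)),
             paste0(pad, apply(x, 1L, paste, collapse = "")))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  if (length(body) != hdr[1L]) stop("malformed relaxed-PHYLIP matrix")
  parts <- strsplit(trimws(body), "\\s+")
  nm <- vapply(parts, `[[`, "", 1L)
  rows <- vapply(parts, `[[`, "", 2L)
  if (any(nchar(rows) != hdr[2L])) stop("row length disagrees with header")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- nm
  m
}

#' @rdname write_phylip_matrix
#' @export
write_nexus_matrix <- function(x, path = NULL) {
  nm <- rownames(x)
  pad <- formatC(nm, width = max(nchar(nm)) + 2L, flag = "-")
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    paste0("  DIMENSIONS NTAX=", nrow(x), " NCHAR=", ncol(x), ";"),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=-;",
    "  MATRIX",
    paste0("    ", pad, apply(x, 1L, paste, collapse = "")),
    "  ;",
    "END;")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
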