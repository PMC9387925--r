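#' Binary spaced-word patterns
#'
#' A pattern is a string over \{0,1\} where `1` marks a *match position* (the
#' nucleotide is part of the spaced word) and `0` a *don't-care position*
#' (any nucleotide is allowed; these positions carry the similarity score).
#' A pattern must start with a match position, so every spaced word begins on
#' a defined residue.
#'
#' @param x a character scalar of '0'/'1' symbols, or an existing
#'   `spam_pattern` object (returned unchanged).
#' @return An object of class `spam_pattern`: a list with elements `mask`
#'   (integer 0/1 vector), `length`, `weight` (number of match positions),
#'   `match_off` and `dontcare_off` (1-based offsets within the window).
#' @examples
#' p <- spam_pattern("110101")
#' p$length  # 6
#' p$weight  # 4
#' @seealso [default_pattern()] for the default length-110, weight-10 pattern.
#' @export
spam_pattern <- function(x) {
  if (inherits(x, "spam_pattern")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("pattern must be a single character string of '0'/'1'")
  if (!nzchar(x)) stop("pattern string must be non-empty")
  sym <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (!all(sym %in% c("0", "1")))
    stop("pattern may contain only '0' and '1' characters")
  if (sym[1L] != "1")
    stop("pattern must start with a match position ('1')")
  mask <- as.integer(sym == "1")
  structure(
    list(mask = mask,
         length = length(mask),
         weight = sum(mask),
         match_off = which(mask == 1L),
         dontcare_off = which(mask == 0L)),
    class = "spam_pattern")
}

#' @export
print.spam_pattern <- function(x, ...) {
  cat("spaced-word pattern: ", as.character(x),
      "\n  length ", x$length, ", weight ", x$weight,
      " (", x$length - x$weight, " don't-care positions)\n", sep = "")
  invisible(x)
}

#' @export
as.character.spam_pattern <- function(x, ...) paste(x$mask, collapse = "")

#' Default reference-block pattern
#'
#' The default pattern has length 110 with 10 match positions and 100
#' don't-care positions. The mask layout (match positions spread every 12
#' positions, starting at the first) is a deterministic choice; only length
#' and weight matter for the method, and both are user-overridable.
#'
#' @return A `spam_pattern` with length 110 and weight 10.
#' @export
default_pattern <- function() {
  mask <- integer(110L)
  mask[seq(1L, 109L, by = 12L)] <- 1L
  spam_pattern(paste(mask, collapse = ""))
}

#' Read patterns from a plain-text file
#'
#' One '0'/'1' string per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return A list of `spam_pattern` objects.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no patterns found in ", path)
  lapply(lines, spam_pattern)
}

#' Nucleotide substitution score matrix
#'
#' Symmetric 4x4 integer score table over A, C, G, T, used to score the
#' nucleotides aligned at the don't-care positions of a spaced-word match.
#' The default values are the ones used by the filtered spaced-word-match
#' family of programs; positive on the diagonal, negative off it, so that
#' homologous matches score positively and background matches negatively.
#'
#' @return A 4x4 numeric matrix with dimnames A, C, G, T.
#' @export
default_score_matrix <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(c(
      91, -114,  -31, -123,
    -114,  100, -125,  -31,
     -31, -125,  100, -114,
    -123,  -31, -114,   91), 4L, 4L, byrow = TRUE,
    dimnames = list(b, b))
  m
}

#' @rdname default_score_matrix
#' @param path file with 4 whitespace-separated rows labelled A C G T.
#' @export
read_score_matrix <- function(path) {
  x <- utils::read.table(path, header = FALSE, row.names = 1L,
                         stringsAsFactors = FALSE)
  m <- as.matrix(x)
  rn <- toupper(rownames(m))
  if (!setequal(rn, c("A", "C", "G", "T")) || ncol(m) != 4L)
    stop("score matrix file must have 4 rows labelled A C G T with 4 values each")
  rownames(m) <- rn
  colnames(m) <- rn
  m <- m[c("A", "C", "G", "T"), c("A", "C", "G", "T")]
  check_score_matrix(m)
  m
}

check_score_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)))
    stop("score matrix must be 4x4")
  if (!isTRUE(all.equal(m, t(m)))) stop("score matrix must be symmetric")
  if (any(diag(m) <= 0)) stop("diagonal scores must be strictly positive")
  off <- m[row(m) != col(m)]
  if (any(off >= 0)) stop("off-diagonal scores must be strictly negative")
  invisible(m)
}

.BASES <- c("A", "C", "G", "T")

#' Extract the spaced word at a position
#'
#' Projects the length-`l` window starting at `pos` onto the match positions
#' of `pattern`. Returns `NA` when the window overruns the sequence end or
#' contains any non-ACGT symbol (ambiguity codes make the don't-care score
#' undefined, so such windows produce no occurrence).
#'
#' @param sequence a nucleotide string (or a character vector of single
#'   characters, as produced by `strsplit`).
#' @param pos 1-based start coordinate of the window.
#' @param pattern a `spam_pattern` or pattern string.
#' @return The spaced word (a string of length `weight`) or `NA_character_`.
#' @export
spaced_word_at <- function(sequence, pos, pattern) {
  pattern <- spam_pattern(pattern)
  if (!is.numeric(pos) || length(pos) != 1L || pos < 1L)
    stop("pos must be a single coordinate >= 1")
  ch <- if (length(sequence) > 1L) sequence
        else strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  if (pos + pattern$length - 1L > length(ch)) return(NA_character_)
  win <- ch[pos:(pos + pattern$length - 1L)]
  if (!all(win %in% .BASES)) return(NA_character_)
  paste(win[pattern$match_off], collapse = "")
}

#' Score a spaced-word match at the don't-care positions
#'
#' The score of a spaced-word match is the sum of substitution scores of the
#' nucleotide pairs aligned at the don't-care positions of the pattern. For
#' an all-match pattern the sum is empty and the score is 0. Both occurrences
#' must carry the same spaced word; otherwise they do not form a match.
#'
#' @param occ1,occ2 occurrences: lists (or one-row data frames) with elements
#'   `seq_id` and `pos` (1-based window start).
#' @param seqs named character vector of sequences (see [read_fasta()]).
#' @param pattern a `spam_pattern`.
#' @param score_matrix symmetric 4x4 score matrix, see
#'   [default_score_matrix()].
#' @return Integer score.
#' @export
spam_score <- function(occ1, occ2, seqs, pattern,
                       score_matrix = default_score_matrix()) {
  pattern <- spam_pattern(pattern)
  seqs <- as_sequence_set(seqs, min_n = 1L)
  ch1 <- strsplit(seqs[[occ1$seq_id]], "", fixed = TRUE)[[1L]]
  ch2 <- strsplit(seqs[[occ2$seq_id]], "", fixed = TRUE)[[1L]]
  w1 <- spaced_word_at(ch1, occ1$pos, pattern)
  w2 <- spaced_word_at(ch2, occ2$pos, pattern)
  if (is.na(w1) || is.na(w2)) stop("occurrence window is not a valid spaced word")
  if (w1 != w2) stop("occurrences carry different spaced words: ", w1, " vs ", w2)
  .dc_score(ch1, occ1$pos, ch2, occ2$pos, pattern$dontcare_off, score_matrix)
}

# don't-care score between two windows; assumes windows are valid ACGT
.dc_score <- function(ch1, pos1, ch2, pos2, dc_off, score_matrix) {
  if (!length(dc_off)) return(0L)
  a <- ch1[pos1 + dc_off - 1L]
  b <- ch2[pos2 + dc_off - 1L]
  sum(score_matrix[cbind(a, b)])
}
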