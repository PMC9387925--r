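#' Read a multi-FASTA file into a sequence set
#'
#' Sequences are returned as a named character vector, uppercased; the taxon
#' id is the first whitespace-delimited token of each header. Duplicate ids
#' are rejected.
#'
#' @param path path to a FASTA file.
#' @param min_n minimal number of records required (the quartet machinery
#'   needs at least 4 taxa; readers used for other purposes may pass 1).
#' @return Named character vector of nucleotide sequences.
#' @export
read_fasta <- function(path, min_n = 4L) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
  seqs <- toupper(as.character(x))
  names(seqs) <- ids
  as_sequence_set(seqs, min_n = min_n)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_set(seqs, min_n = 1L)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Validate / coerce a sequence set
#'
#' @param x a named character vector, a `Biostrings::DNAStringSet`, or a
#'   path to a FASTA file.
#' @param min_n minimal number of taxa.
#' @return Named character vector (uppercase).
#' @export
as_sequence_set <- function(x, min_n = 4L) {
  if (inherits(x, "DNAStringSet")) {
    ids <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
    x <- stats::setNames(toupper(as.character(x)), ids)
  } else if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
             file.exists(x)) {
    return(read_fasta(x, min_n = min_n))
  }
  if (!is.character(x) || is.null(names(x)))
    stop("sequence set must be a named character vector of nucleotide sequences")
  if (anyDuplicated(names(x)))
    stop("duplicate taxon ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (length(x) < min_n)
    stop("need at least ", min_n, " sequences, got ", length(x))
  toupper(x)
}

#' Write a data frame as a TSV report
#'
#' Plain tab-separated writer used for block, pair and evaluation reports; a
#' `# key: value` comment header records run metadata (for example the seed).
#'
#' @param x data frame.
#' @param path output path.
#' @param header named character vector written as `# name: value` lines.
#' @export
write_tsv_report <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header) && length(header))
    writeLines(paste0("# ", names(header), ": ", unname(header)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
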