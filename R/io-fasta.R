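#' Read a genome FASTA into a named sequence vector
#'
#' @param path Path to a FASTA file (an accompanying `.fai` index is not
#'   required).
#' @return Named character vector of uppercase sequences, one per
#'   scaffold; names are truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(s))
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Fetch a subsequence by 1-based inclusive coordinates
#'
#' @param genome Named character vector from [read_fasta()] (or built in
#'   code).
#' @param scaffold Scaffold name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return Uppercase sequence string of length `end - start + 1`.
#' @export
fetch_seq <- function(genome, scaffold, start, end) {
  if (!scaffold %in% names(genome)) stop("unknown scaffold: ", scaffold)
  len <- nchar(genome[[scaffold]])
  if (start > end) stop("fetch with start > end (", start, " > ", end, ")")
  if (start < 1 || end > len) {
    stop("fetch out of range for ", scaffold, " (length ", len, ")")
  }
  substr(genome[[scaffold]], start, end)
}

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA sequences.
#' @return Reverse complement of each element.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scaffold index ordered longest to shortest
#'
#' @param x Either a genome vector from [read_fasta()] or a data frame
#'   with columns `scaffold` and `length`.
#' @return Tibble with columns `scaffold`, `length`, sorted by
#'   decreasing length (the plotting and reporting order).
#' @export
scaffold_index <- function(x) {
  if (is.character(x)) {
    out <- tibble(scaffold = names(x), length = unname(nchar(x)))
  } else {
    out <- as_tibble(x)[, c("scaffold", "length")]
  }
  if (any(out$length <= 0)) stop("scaffold lengths must be > 0")
  arrange(out, desc(.data$length), .data$scaffold)
}
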