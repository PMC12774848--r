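#' Read a protein multiple-sequence alignment
#'
#' Supports aligned FASTA and Clustal formats.
#'
#' @param path Path to the alignment.
#' @param format `"fasta"`, `"clustal"`, or `"auto"` (by extension, with
#'   `.aln`/`.clustal` read as Clustal).
#' @return Named character vector of uppercase aligned sequences.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(aln|clustal|clw)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  if (format == "fasta") {
    s <- Biostrings::readAAStringSet(path)
    out <- toupper(as.character(s))
    names(out) <- sub("\\s.*$", "", names(s))
    return(out)
  }
  # Clustal: header line, then blocks of "name  segment" rows; the
  # conservation rows (leading whitespace) and blank lines are skipped
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("not a Clustal alignment: missing CLUSTAL header")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !grepl("^\\s", body)]
  m <- regmatches(body, regexec("^(\\S+)\\s+([A-Za-z.*-]+)\\s*\\d*$", body))
  ok <- lengths(m) == 3
  pieces <- do.call(rbind, m[ok])
  segs <- split(pieces[, 3], pieces[, 2])
  out <- toupper(vapply(segs, paste, character(1), collapse = ""))
  out[unique(pieces[, 2])]
}

# Clustal "strong" similarity groups
.strong_groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                    "MILV", "MILF", "HY", "FYW")

#' Classify alignment columns as conserved, conservative, or variable
#'
#' Reproduces the Clustal column symbols: `"*"` for a fully conserved
#' column (all non-gap residues identical), `":"` for a conservative
#' column where every residue belongs to one strong similarity group
#' (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW), and `" "`
#' otherwise. A column containing only gaps is variable.
#'
#' @param alignment Named character vector of equal-length aligned
#'   protein sequences (see [read_alignment()]).
#' @param columns Integer vector of 1-based column indices; default all.
#' @return Tibble with columns `column`, `call` (`"*"`, `":"`, `" "`)
#'   and `residues` (the column's residues, gaps included, one character
#'   per sequence).
#' @export
classify_conservation <- function(alignment, columns = NULL) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequences have lengths ",
         paste(unique(lens), collapse = ", "))
  }
  width <- lens[1]
  if (is.null(columns)) columns <- seq_len(width)
  if (any(columns < 1 | columns > width)) stop("column index out of range")
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  calls <- vapply(columns, function(j) {
    col <- mat[, j]
    res <- col[!col %in% c("-", ".")]
    if (length(res) == 0) return(" ")
    if (length(unique(res)) == 1) return("*")
    in_group <- vapply(.strong_groups, function(grp) {
      all(res %in% strsplit(grp, "")[[1]])
    }, logical(1))
    if (any(in_group)) ":" else " "
  }, character(1))
  tibble(
    column = as.integer(columns),
    call = calls,
    residues = vapply(columns, function(j) paste(mat[, j], collapse = ""),
                      character(1))
  )
}
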