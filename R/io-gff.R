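#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features and keeps one canonical transcript
#' per gene: the one with the longest total CDS, ties broken by the
#' lexicographically smallest transcript ID. Exons are numbered in
#' transcription order (for a minus-strand gene, exon 1 is the
#' highest-coordinate exon), so consequence reports can read
#' "exon 6 of 8". CDS features without a resolvable parent gene are
#' excluded with a warning. Models whose CDS length is not a multiple of
#' three are flagged (`cds_complete = FALSE`), not rejected.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble: one row per gene with columns `gene_id`,
#'   `gene_name`, `scaffold`, `strand`, `start`, `end`, `transcript_id`,
#'   `n_exons`, `cds_len`, `cds_complete`, and list-columns `exons` and
#'   `cds` (tibbles of 1-based inclusive intervals in transcription
#'   order).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent1 <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  types <- tolower(as.character(df$type))

  genes <- df[types == "gene", , drop = FALSE]
  mrnas <- df[types %in% c("mrna", "transcript"), , drop = FALSE]
  cdss  <- df[types == "cds", , drop = FALSE]
  exons <- df[types == "exon", , drop = FALSE]

  orphan_tx <- !mrnas$Parent1 %in% genes$ID
  if (any(orphan_tx)) {
    warning(sum(orphan_tx), " transcript(s) without a parent gene excluded")
    mrnas <- mrnas[!orphan_tx, , drop = FALSE]
  }
  orphan_cds <- !cdss$Parent1 %in% mrnas$ID
  if (any(orphan_cds)) {
    warning(sum(orphan_cds), " CDS feature(s) without a parent transcript excluded")
    cdss <- cdss[!orphan_cds, , drop = FALSE]
  }

  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    tx <- mrnas[mrnas$Parent1 == g$ID, , drop = FALSE]
    if (nrow(tx) == 0) return(NULL)
    cds_len_by_tx <- vapply(tx$ID, function(tid) {
      sum(cdss$width[cdss$Parent1 == tid])
    }, numeric(1))
    keep <- which(cds_len_by_tx == max(cds_len_by_tx))
    keep <- keep[order(tx$ID[keep])][1]
    tid <- tx$ID[keep]
    gene_model(
      gene_id = as.character(g$ID),
      gene_name = if (!is.null(g$Name) && !is.na(g$Name)) as.character(g$Name)
                  else as.character(g$ID),
      scaffold = as.character(g$seqnames),
      strand = as.character(g$strand),
      exons = tibble(start = exons$start[exons$Parent1 == tid],
                     end = exons$end[exons$Parent1 == tid]),
      cds = tibble(start = cdss$start[cdss$Parent1 == tid],
                   end = cdss$end[cdss$Parent1 == tid]),
      transcript_id = as.character(tid)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) > 0 && any(!out$cds_complete)) {
    warning(sum(!out$cds_complete),
            " gene model(s) have CDS length not divisible by 3 (flagged)")
  }
  out
}

#' Construct a single gene model row
#'
#' Builds the same one-row tibble [read_gff3()] produces, from interval
#' tables given in any order; intervals are sorted into transcription
#' order according to `strand`.
#'
#' @param gene_id,gene_name,scaffold,strand Scalars describing the gene;
#'   `strand` is `"+"` or `"-"`.
#' @param exons,cds Data frames with columns `start`, `end` (1-based
#'   inclusive genomic coordinates).
#' @param transcript_id Optional transcript identifier.
#' @return A one-row gene-model tibble.
#' @export
gene_model <- function(gene_id, gene_name = gene_id, scaffold, strand,
                       exons, cds = exons, transcript_id = paste0(gene_id, ".t1")) {
  stopifnot(strand %in% c("+", "-"))
  ord <- function(x) {
    x <- as_tibble(x)[, c("start", "end")]
    x <- x[order(x$start, decreasing = (strand == "-")), , drop = FALSE]
    x
  }
  exons <- ord(exons)
  exons$ordinal <- seq_len(nrow(exons))
  cds <- ord(cds)
  cds_len <- sum(cds$end - cds$start + 1)
  tibble(
    gene_id = gene_id, gene_name = gene_name, scaffold = scaffold,
    strand = strand,
    start = min(exons$start), end = max(exons$end),
    transcript_id = transcript_id,
    n_exons = nrow(exons),
    cds_len = cds_len,
    cds_complete = cds_len %% 3 == 0,
    exons = list(exons), cds = list(cds)
  )
}
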