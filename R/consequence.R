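#' Translate a DNA codon with the standard genetic code
#'
#' @param codon Character vector of 3-base DNA codons (T, not U).
#' @return Single-letter amino acids, `"*"` for the three stop codons.
#' @export
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  unname(aa)
}

# genomic positions of the CDS in transcription order (5'->3' of the mRNA)
cds_positions <- function(gene_row) {
  cds <- gene_row$cds[[1]]
  unlist(lapply(seq_len(nrow(cds)), function(i) {
    if (gene_row$strand == "+") seq(cds$start[i], cds$end[i])
    else seq(cds$end[i], cds$start[i])
  }), use.names = FALSE)
}

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# base as read on the coding strand
coding_base <- function(base, strand) {
  if (strand == "+") base else unname(.comp[base])
}

#' Annotate SNV/MNP variants with codon-level consequences
#'
#' For each variant overlapping a gene, extracts the affected codon(s)
#' of the canonical transcript strand-awarely, translates reference and
#' alternate codons under the standard genetic code, and classifies the
#' effect: `synonymous`, `missense`, `stop_gained`, `stop_lost`,
#' `start_lost`, `splice_site_proximal` (within 2 bp of an exon boundary
#' inside an intron, or a substitution spanning an exon/intron
#' boundary), or `non_coding`. Indels inside a CDS are reported as
#' `indel_in_CDS` without protein-level detail. An MNP touching several
#' codons is decomposed codon-wise and reports the most severe class.
#' Codon changes are reported in the RNA alphabet (e.g. `UGG>UAG`), as
#' in standard nonsense-mutation reporting.
#'
#' The variant's reference allele is checked against the genome sequence
#' and a mismatch is a hard error, since it indicates a coordinate-system
#' fault.
#'
#' @param variants A variant tibble (only SNP/MNP rows receive codon
#'   calls).
#' @param genes A gene-model tibble from [read_gff3()] or [gene_model()].
#' @param genome Named sequence vector from [read_fasta()].
#' @return A tibble with one row per (variant, overlapping gene):
#'   `scaffold`, `pos`, `ref`, `alt`, `gene_id`, `gene_name`,
#'   `transcript_id`, `strand`, `exon_ordinal`, `exon_total`,
#'   `cds_codon_index` (= 1-based protein position), `codon_change`,
#'   `aa_change`, `effect_class`.
#' @export
annotate_variants <- function(variants, genes, genome) {
  variants <- as_variants(variants)
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    g_hit <- genes[genes$scaffold == v$scaffold &
                     genes$end >= v$pos &
                     genes$start <= v$pos + nchar(v$ref) - 1, , drop = FALSE]
    if (nrow(g_hit) == 0) next
    for (j in seq_len(nrow(g_hit))) {
      rows[[length(rows) + 1]] <- annotate_one(v, g_hit[j, ], genome)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(scaffold = character(), pos = numeric(), ref = character(),
                  alt = character(), gene_id = character(),
                  gene_name = character(), transcript_id = character(),
                  strand = character(), exon_ordinal = integer(),
                  exon_total = integer(), cds_codon_index = integer(),
                  codon_change = character(), aa_change = character(),
                  effect_class = character())
  }
  out
}

annotate_one <- function(v, g, genome) {
  p <- seq(v$pos, v$pos + nchar(v$ref) - 1)
  base <- tibble(
    scaffold = v$scaffold, pos = v$pos, ref = v$ref, alt = v$alt,
    gene_id = g$gene_id, gene_name = g$gene_name,
    transcript_id = g$transcript_id, strand = g$strand,
    exon_ordinal = exon_ordinal_at(g, v$pos), exon_total = g$n_exons,
    cds_codon_index = NA_integer_, codon_change = NA_character_,
    aa_change = NA_character_
  )
  cmap <- cds_positions(g)
  idx <- match(p, cmap)
  if (v$vclass == "INDEL") {
    base$effect_class <- if (any(!is.na(idx))) "indel_in_CDS" else
      intron_effect(g, p)
    return(base)
  }
  obs <- fetch_seq(genome, v$scaffold, v$pos, v$pos + nchar(v$ref) - 1)
  if (obs != toupper(v$ref)) {
    stop("reference mismatch at ", v$scaffold, ":", v$pos,
         " (VCF ", v$ref, ", genome ", obs, "); coordinate-system fault")
  }
  if (all(is.na(idx))) {
    base$effect_class <- intron_effect(g, p)
    return(base)
  }
  if (any(is.na(idx))) {
    # substitution spanning an exon/intron boundary: no codon change
    base$effect_class <- "splice_site_proximal"
    return(base)
  }
  alt_chars <- strsplit(toupper(v$alt), "")[[1]]
  codons <- unique((idx - 1) %/% 3 + 1)
  calls <- lapply(codons, function(k) {
    gpos <- cmap[(3 * k - 2):(3 * k)]
    if (any(is.na(gpos))) return(NULL)  # incomplete terminal codon
    ref_cod <- vapply(gpos, function(q) {
      coding_base(fetch_seq(genome, v$scaffold, q, q), g$strand)
    }, character(1))
    alt_cod <- ref_cod
    hit <- which(gpos %in% p)
    alt_cod[hit] <- vapply(gpos[hit], function(q) {
      coding_base(alt_chars[match(q, p)], g$strand)
    }, character(1))
    ref_aa <- translate_codon(paste(ref_cod, collapse = ""))
    alt_aa <- translate_codon(paste(alt_cod, collapse = ""))
    eff <- classify_codon_effect(ref_aa, alt_aa, k)
    tibble(k = k,
           codon_change = paste0(chartr("T", "U", paste(ref_cod, collapse = "")),
                                 ">",
                                 chartr("T", "U", paste(alt_cod, collapse = ""))),
           aa_change = paste0(ref_aa, k, alt_aa),
           effect_class = eff)
  })
  calls <- bind_rows(calls)
  if (nrow(calls) == 0) {
    base$effect_class <- "non_coding"
    return(base)
  }
  best <- calls[which.min(match(calls$effect_class, .effect_levels)), ]
  base$cds_codon_index <- as.integer(best$k)
  base$codon_change <- best$codon_change
  base$aa_change <- best$aa_change
  base$effect_class <- best$effect_class
  base
}

classify_codon_effect <- function(ref_aa, alt_aa, codon_index) {
  if (ref_aa == alt_aa) return("synonymous")
  if (alt_aa == "*") return("stop_gained")
  if (ref_aa == "*") return("stop_lost")
  if (codon_index == 1 && ref_aa == "M") return("start_lost")
  "missense"
}

# effect of positions lying entirely outside the CDS
intron_effect <- function(g, p) {
  ex <- g$exons[[1]]
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1)) {
      istart <- ex$end[i] + 1
      iend <- ex$start[i + 1] - 1
      if (iend < istart) next
      inside <- p >= istart & p <= iend
      near <- p <= istart + 1 | p >= iend - 1
      if (any(inside & near)) return("splice_site_proximal")
    }
  }
  "non_coding"
}

# transcription-order ordinal of the exon containing pos, NA if intronic
exon_ordinal_at <- function(g, pos) {
  ex <- g$exons[[1]]
  hit <- which(ex$start <= pos & ex$end >= pos)
  if (length(hit) == 0) NA_integer_ else as.integer(ex$ordinal[hit[1]])
}

#' Genes overlapping a candidate interval
#'
#' @param genes A gene-model tibble.
#' @param interval One-row data frame (or list) with `scaffold`,
#'   `start`, `end`. Any overlap counts, even a single base pair.
#' @return The overlapping gene rows, sorted by start.
#' @export
genes_in_interval <- function(genes, interval) {
  genes[genes$scaffold == interval$scaffold &
          genes$end >= interval$start &
          genes$start <= interval$end, , drop = FALSE] |>
    arrange(.data$start)
}

#' Rank annotated variants into a candidate report
#'
#' Deterministic triage of consequence calls within a candidate
#' interval: protein-truncating and splice-affecting variants
#' (stop_gained, stop_lost, start_lost, splice_site_proximal,
#' indel_in_CDS) first, then missense, then synonymous/non-coding; ties
#' broken by genomic position. An externally produced
#' differential-expression table (columns `gene_id` or `gene_name` plus
#' e.g. `log2fc`, `padj`) can be joined onto the report.
#'
#' @param consequences Output of [annotate_variants()].
#' @param expression Optional data frame joined by `gene_id` (or
#'   `gene_name` if `gene_id` is absent).
#' @return The consequence rows with `priority` (1 = high impact),
#'   `rank`, and a human-readable `report_line`, ordered by rank.
#' @export
summarize_candidates <- function(consequences, expression = NULL) {
  x <- as_tibble(consequences)
  if (nrow(x) == 0) return(mutate(x, priority = integer(0), rank = integer(0),
                                  report_line = character(0)))
  high <- c("stop_gained", "stop_lost", "start_lost",
            "splice_site_proximal", "indel_in_CDS")
  x <- x |>
    mutate(priority = dplyr::case_when(
      .data$effect_class %in% high ~ 1L,
      .data$effect_class == "missense" ~ 2L,
      TRUE ~ 3L
    )) |>
    arrange(.data$priority,
            match(.data$effect_class, .effect_levels),
            .data$scaffold, .data$pos) |>
    mutate(
      rank = dplyr::row_number(),
      report_line = sprintf(
        "%s - %s - %s - exon %s of %s",
        .data$gene_name, .data$effect_class,
        dplyr::coalesce(.data$codon_change, "."),
        dplyr::coalesce(as.character(.data$exon_ordinal), "."),
        .data$exon_total
      )
    )
  if (!is.null(expression)) {
    key <- if ("gene_id" %in% names(expression)) "gene_id" else "gene_name"
    x <- left_join(x, as_tibble(expression), by = key)
  }
  x
}
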