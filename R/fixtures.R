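#' Write gene models as GFF3
#'
#' @param genes A gene-model tibble ([gene_model()] / [read_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tid <- g$transcript_id
    lines <- c(lines, sprintf(
      "%s\tcosegmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      g$scaffold, g$start, g$end, g$strand, g$gene_id, g$gene_name
    ), sprintf(
      "%s\tcosegmap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      g$scaffold, g$start, g$end, g$strand, tid, g$gene_id
    ))
    ex <- g$exons[[1]][order(g$exons[[1]]$start), , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tcosegmap\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      g$scaffold, ex$start, ex$end, g$strand, tid
    ))
    cds <- g$cds[[1]]  # transcription order
    lens <- cds$end - cds$start + 1
    phase <- (3 - (cumsum(dplyr::lag(lens, default = 0)) %% 3)) %% 3
    lines <- c(lines, sprintf(
      "%s\tcosegmap\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
      g$scaffold, cds$start, cds$end, g$strand, phase, tid
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

# a random protein-coding DNA sequence: ATG + non-stop codons + TAA
random_coding_seq <- function(n_codons) {
  stopifnot(n_codons >= 3)
  bases <- c("A", "C", "G", "T")
  codons <- character(n_codons - 2)
  i <- 1
  while (i <= length(codons)) {
    cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    if (translate_codon(cod) != "*") {
      codons[i] <- cod
      i <- i + 1
    }
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# place the three synthetic genes around the causal position so that the
# causal base is the middle position (codon offset 2) of a coding UGG
# codon in the minus-strand gene g1
fixture_genes <- function(cfg) {
  cpos <- cfg$causal_pos
  make_g1 <- function(shift) {
    gene_model(
      gene_id = "gene_causal", gene_name = "PIGM1",
      scaffold = cfg$causal_scaffold, strand = "-",
      exons = tibble(start = cpos + c(-900, -200, 600) + shift,
                     end = cpos + c(-700, 249, 800) + shift)
    )
  }
  g1 <- make_g1(0)
  for (shift in 0:2) {
    g1 <- make_g1(shift)
    idx <- match(cpos, cds_positions(g1))
    if (!is.na(idx) && (idx - 1) %% 3 == 1) break
  }
  g2 <- gene_model(
    gene_id = "gene_plus", gene_name = "PIGM2",
    scaffold = cfg$causal_scaffold, strand = "+",
    exons = tibble(start = cpos + c(5000, 5800), end = cpos + c(5449, 6348))
  )
  g3 <- gene_model(
    gene_id = "gene_far", gene_name = "PIGM3",
    scaffold = cfg$causal_scaffold, strand = "-",
    exons = tibble(start = cpos - 6400, end = cpos - 5501)
  )
  bind_rows(g1, g2, g3)
}

#' Emit a complete on-disk fixture suite for the pipeline
#'
#' Simulates a cross with [simulate_cross()] and writes the standard
#' files the pipeline consumes: a genome FASTA whose bases agree with
#' every variant's reference allele, a four-sample VCF, a BED repeat
#' mask, a GFF3 with three synthetic genes straddling the causal locus
#' (the causal gene is minus-strand and carries the causal C-to-T
#' substitution inside its CDS, turning a UGG codon into the UAG stop;
#' a plus-strand gene is included for strand tests), and a ground-truth
#' JSON. Non-causal markers falling inside a synthetic gene's CDS are
#' dropped so the planted stop codon is the only protein-truncating
#' variant. Output is byte-identical across runs with the same seed.
#'
#' @param cfg A [cross_config()]. `mask_fraction >= 1` produces a mask
#'   covering the whole genome (degenerate-mask testing).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the simulation (`sim`), the gene
#'   models (`genes`), the genome (`genome`) and the file `paths`.
#' @export
make_fixture_suite <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_cross(cfg)
  variants <- sim$variants
  genes <- fixture_genes(cfg)

  # drop non-causal markers inside a synthetic CDS (+/- 2 bp)
  in_cds <- rep(FALSE, nrow(variants))
  for (i in seq_len(nrow(genes))) {
    cds <- genes$cds[[i]]
    for (j in seq_len(nrow(cds))) {
      lo <- min(cds$start[j], cds$end[j]) - 2
      hi <- max(cds$start[j], cds$end[j]) + 2
      in_cds <- in_cds | (variants$scaffold == genes$scaffold[i] &
                            variants$pos + nchar(variants$ref) - 1 >= lo &
                            variants$pos <= hi)
    }
  }
  causal <- variants$scaffold == cfg$causal_scaffold &
    variants$pos == cfg$causal_pos
  variants <- variants[!in_cds | causal, , drop = FALSE]

  # genome: random bases, then variant reference alleles, then gene CDS
  set.seed(cfg$seed + 1L)
  genome <- vapply(names(cfg$scaffold_lengths), function(s) {
    len <- cfg$scaffold_lengths[[s]]
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    v <- variants[variants$scaffold == s, , drop = FALSE]
    for (i in seq_len(nrow(v))) {
      b[v$pos[i]:(v$pos[i] + nchar(v$ref[i]) - 1)] <- strsplit(v$ref[i], "")[[1]]
    }
    paste(b, collapse = "")
  }, character(1))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cmap <- cds_positions(g)
    coding <- random_coding_seq(length(cmap) / 3)
    if (g$gene_id == "gene_causal") {
      k <- (match(cfg$causal_pos, cmap) - 1) %/% 3 + 1
      substr(coding, 3 * k - 2, 3 * k) <- "TGG"
    }
    cvec <- strsplit(coding, "")[[1]]
    if (g$strand == "-") cvec <- unname(.comp[cvec])
    s <- g$scaffold
    gb <- strsplit(genome[[s]], "")[[1]]
    gb[cmap] <- cvec
    genome[[s]] <- paste(gb, collapse = "")
  }

  # BED mask avoiding the causal neighbourhood (unless degenerate)
  set.seed(cfg$seed + 2L)
  mask_rows <- lapply(names(cfg$scaffold_lengths), function(s) {
    len <- cfg$scaffold_lengths[[s]]
    if (cfg$mask_fraction >= 1) {
      return(tibble(scaffold = s, start = 0, end = len))
    }
    if (cfg$mask_fraction <= 0) return(NULL)
    n_iv <- max(1, round(cfg$mask_fraction * len / 5000))
    start <- sort(sample.int(len - 5000, n_iv))
    iv <- tibble(scaffold = s, start = start - 1, end = start - 1 + 5000)
    if (s == cfg$causal_scaffold) {
      iv <- iv[!(iv$end > cfg$causal_pos - 20000 &
                   iv$start < cfg$causal_pos + 20000), , drop = FALSE]
    }
    iv
  })
  mask <- bind_rows(mask_rows)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    vcf = file.path(dir, "variants.vcf"),
    bed = file.path(dir, "mask.bed"),
    gff = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.json")
  )
  dna <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dna, paths$fasta, width = 80)
  write_vcf(variants, paths$vcf, contigs = sim$scaffolds)
  writeLines(sprintf("%s\t%d\t%d", mask$scaffold,
                     as.integer(mask$start), as.integer(mask$end)), paths$bed)
  write_gff3(genes, paths$gff)
  jsonlite::write_json(
    list(causal = sim$truth$causal,
         offspring = sim$truth$offspring,
         founders = sim$truth$founders,
         seed = cfg$seed),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(list(sim = sim, genes = genes, genome = genome, paths = paths,
                 variants = variants))
}
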