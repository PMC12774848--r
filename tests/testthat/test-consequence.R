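# builds a single-exon gene whose coding sequence is given explicitly,
# embedded at `gstart` in a random genome; minus-strand genes are written
# reverse-complemented so the coding sequence reads as specified
planted_gene <- function(coding, strand = "+", gstart = 101, flank = 100,
                         scaffold = "s1") {
  cvec <- strsplit(coding, "")[[1]]
  if (strand == "-") cvec <- rev(c(A = "T", C = "G", G = "C", T = "A")[cvec])
  set.seed(nchar(coding))
  bases <- sample(c("A", "C", "G", "T"), gstart + nchar(coding) + flank,
                  replace = TRUE)
  bases[gstart:(gstart + nchar(coding) - 1)] <- cvec
  genome <- setNames(paste(bases, collapse = ""), scaffold)
  gene <- gene_model("g1", "GENE1", scaffold, strand,
                     exons = tibble::tibble(start = gstart,
                                            end = gstart + nchar(coding) - 1))
  list(gene = gene, genome = genome,
       cds_range = c(gstart, gstart + nchar(coding) - 1))
}

test_that("a genomic C-to-T on the minus strand turns a UGG codon into the UAG stop", {
  # coding: ATG GCA TGG TTA -> codon 3 is UGG (Trp)
  pg <- planted_gene("ATGGCATGGTTA", strand = "-")
  # coding codon 3 middle base G sits at genomic position cds_end - 7,
  # where the genome carries the complement C
  gpos <- pg$cds_range[2] - 7
  expect_equal(fetch_seq(pg$genome, "s1", gpos, gpos), "C")
  ann <- annotate_variants(snv("s1", gpos, "C", "T"), pg$gene, pg$genome)
  expect_equal(ann$effect_class, "stop_gained")
  expect_equal(ann$codon_change, "UGG>UAG")
  expect_equal(ann$aa_change, "W3*")
  expect_equal(ann$cds_codon_index, 3L)
})

test_that("a genomic G-to-A on the minus strand turns a CGA codon into the UGA stop", {
  # coding: ATG CGA AAA TTA -> codon 2 is CGA (Arg)
  pg <- planted_gene("ATGCGAAAATTA", strand = "-")
  # coding codon 2 first base C is at genomic position cds_end - 3 (G on +)
  gpos <- pg$cds_range[2] - 3
  expect_equal(fetch_seq(pg$genome, "s1", gpos, gpos), "G")
  ann <- annotate_variants(snv("s1", gpos, "G", "A"), pg$gene, pg$genome)
  expect_equal(ann$effect_class, "stop_gained")
  expect_equal(ann$codon_change, "CGA>UGA")
  expect_equal(ann$aa_change, "R2*")
})

test_that("a missense in codon 392 reports protein position 392", {
  set.seed(392)
  coding <- cosegmap:::random_coding_seq(400)
  substr(coding, 392 * 3 - 2, 392 * 3) <- "GAT"  # Asp at position 392
  pg <- planted_gene(coding, strand = "+")
  gpos <- pg$cds_range[1] + (392 * 3 - 2) - 1    # codon 392, base 1 (G)
  ann <- annotate_variants(snv("s1", gpos, "G", "C"), pg$gene, pg$genome)
  expect_equal(ann$effect_class, "missense")     # GAT (D) -> CAT (H)
  expect_equal(ann$cds_codon_index, 392L)
  expect_equal(ann$aa_change, "D392H")
})

test_that("synonymous, start-lost and stop-lost substitutions classify correctly", {
  # ATG CTG TAA: Leu codon CTG -> CTA is synonymous
  pg <- planted_gene("ATGCTGTAA", strand = "+")
  g0 <- pg$cds_range[1]
  syn <- annotate_variants(snv("s1", g0 + 5, "G", "A"), pg$gene, pg$genome)
  expect_equal(syn$effect_class, "synonymous")
  sl <- annotate_variants(snv("s1", g0, "A", "C"), pg$gene, pg$genome)
  expect_equal(sl$effect_class, "start_lost")
  stl <- annotate_variants(snv("s1", g0 + 7, "A", "C"), pg$gene, pg$genome)
  expect_equal(stl$effect_class, "stop_lost")   # TAA -> TCA (Ser)
})

test_that("intronic variants near exon boundaries are splice-proximal", {
  set.seed(9)
  bases <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  genome <- setNames(paste(bases, collapse = ""), "s1")
  gene <- gene_model("g1", scaffold = "s1", strand = "+",
                     exons = tibble::tibble(start = c(101, 201),
                                            end = c(160, 260)))
  ref_at <- function(p) fetch_seq(genome, "s1", p, p)
  alt_of <- function(r) setdiff(c("A", "C", "G", "T"), r)[1]
  eff <- function(p) {
    r <- ref_at(p)
    annotate_variants(snv("s1", p, r, alt_of(r)), gene, genome)$effect_class
  }
  expect_equal(eff(161), "splice_site_proximal")  # intron base 1
  expect_equal(eff(162), "splice_site_proximal")  # intron base 2
  expect_equal(eff(180), "non_coding")            # deep intron
  expect_equal(eff(199), "splice_site_proximal")  # 2 bp before exon 2
})

test_that("an MNP spanning an exon/intron boundary gets no codon change", {
  set.seed(10)
  bases <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
  genome <- setNames(paste(bases, collapse = ""), "s1")
  gene <- gene_model("g1", scaffold = "s1", strand = "+",
                     exons = tibble::tibble(start = c(101, 201),
                                            end = c(160, 260)))
  ref <- fetch_seq(genome, "s1", 160, 161)
  ann <- annotate_variants(snv("s1", 160, ref, chartr("ACGT", "TGCA", ref)),
                           gene, genome)
  expect_equal(ann$effect_class, "splice_site_proximal")
  expect_true(is.na(ann$codon_change))
})

test_that("a reference mismatch with the genome is a hard error", {
  pg <- planted_gene("ATGCTGTAA")
  g0 <- pg$cds_range[1]
  wrong <- setdiff(c("A", "C", "G", "T"),
                   fetch_seq(pg$genome, "s1", g0 + 4, g0 + 4))[1]
  expect_error(
    annotate_variants(snv("s1", g0 + 4, wrong, "A"), pg$gene, pg$genome),
    "mismatch"
  )
})

test_that("all 64 codons translate and the stops are exactly UAA, UAG, UGA", {
  codons <- apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                              c("T","C","A","G")), 1, paste, collapse = "")
  aa <- translate_codon(codons)
  expect_false(any(is.na(aa)))
  expect_setequal(codons[aa == "*"], c("TAA", "TAG", "TGA"))
})

test_that("effect classes match a full-CDS rebuild-and-translate oracle", {
  set.seed(64)
  n_match <- 0
  for (i in 1:200) {
    cs <- random_gene_case()
    ann <- annotate_variants(snv("s1", cs$pos, cs$ref, cs$alt),
                             cs$gene, cs$genome)
    expect_equal(nrow(ann), 1)
    expected <- oracle_effect(cs$gene, cs$genome, cs$pos, cs$alt)
    expect_equal(ann$effect_class, expected,
                 info = sprintf("case %d: %s:%d %s>%s strand %s", i, "s1",
                                cs$pos, cs$ref, cs$alt, cs$gene$strand))
    n_match <- n_match + (ann$effect_class == expected)
  }
  expect_equal(n_match, 200)
})

test_that("strand-mirrored constructions give identical codon calls", {
  set.seed(77)
  for (i in 1:25) {
    n_codons <- sample(5:20, 1)
    coding <- cosegmap:::random_coding_seq(n_codons)
    off <- sample(0:(3 * n_codons - 1), 1)
    pg_p <- planted_gene(coding, strand = "+")
    pg_m <- planted_gene(coding, strand = "-")
    pos_p <- pg_p$cds_range[1] + off
    pos_m <- pg_m$cds_range[2] - off
    ref_p <- fetch_seq(pg_p$genome, "s1", pos_p, pos_p)
    alt_p <- sample(setdiff(c("A", "C", "G", "T"), ref_p), 1)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ann_p <- annotate_variants(snv("s1", pos_p, ref_p, alt_p),
                               pg_p$gene, pg_p$genome)
    ann_m <- annotate_variants(snv("s1", pos_m, unname(comp[ref_p]),
                                   unname(comp[alt_p])),
                               pg_m$gene, pg_m$genome)
    expect_equal(ann_m$codon_change, ann_p$codon_change)
    expect_equal(ann_m$effect_class, ann_p$effect_class)
    expect_equal(ann_m$aa_change, ann_p$aa_change)
  }
})

test_that("genes are selected by any overlap with an interval", {
  genes <- dplyr::bind_rows(
    gene_model("in", scaffold = "s1", strand = "+",
               exons = tibble::tibble(start = 500, end = 800)),
    gene_model("edge", scaffold = "s1", strand = "+",
               exons = tibble::tibble(start = 950, end = 1200)),
    gene_model("out", scaffold = "s1", strand = "+",
               exons = tibble::tibble(start = 1500, end = 1600)),
    gene_model("other", scaffold = "s2", strand = "+",
               exons = tibble::tibble(start = 500, end = 800))
  )
  hit <- genes_in_interval(genes, list(scaffold = "s1", start = 100, end = 950))
  expect_equal(hit$gene_id, c("in", "edge"))   # 1 bp overlap counts
})

test_that("candidate reports rank truncating variants first, ties by position", {
  cons <- tibble::tibble(
    scaffold = "s1", pos = c(500, 300, 100, 200),
    ref = "C", alt = "T", gene_id = paste0("g", 1:4),
    gene_name = c("GENE_MIS", "GENE_STOP2", "GENE_SYN", "GENE_STOP1"),
    transcript_id = paste0("t", 1:4), strand = "+",
    exon_ordinal = 1L, exon_total = c(8L, 23L, 2L, 8L),
    cds_codon_index = 5L,
    codon_change = c("GAU>CAU", "CGA>UGA", "CUG>CUA", "UGG>UAG"),
    aa_change = c("D5H", "R5*", "L5L", "W5*"),
    effect_class = c("missense", "stop_gained", "synonymous", "stop_gained")
  )
  rep <- summarize_candidates(cons)
  expect_equal(rep$gene_name[1:2], c("GENE_STOP1", "GENE_STOP2"))  # by position
  expect_equal(rep$gene_name[3], "GENE_MIS")
  expect_equal(rep$rank, 1:4)
  expect_match(rep$report_line[1], "GENE_STOP1 - stop_gained - UGG>UAG - exon 1 of 8")
  empty <- summarize_candidates(cons[0, ])
  expect_equal(nrow(empty), 0)
  withx <- summarize_candidates(cons, tibble::tibble(gene_id = "g2", log2fc = -2))
  expect_equal(withx$log2fc[withx$gene_id == "g2"], -2)
})

test_that("conservation columns are classified by the Clustal symbols", {
  aln <- c(sp1 = "WIV-W", sp2 = "WLVGW", sp3 = "WVV-R")
  cc <- classify_conservation(aln)
  # column 4 has a single non-gap residue, hence conserved by convention
  expect_equal(cc$call, c("*", ":", "*", "*", " "))
  # column 2 is {I,L,V}: all in the MILV strong group
  expect_equal(cc$residues[2], "ILV")
  gapcol <- classify_conservation(c(a = "-A", b = "-A"))
  expect_equal(gapcol$call, c(" ", "*"))
  expect_error(classify_conservation(c(a = "AB", b = "A")), "ragged")
  one <- classify_conservation(aln, columns = 5)
  expect_equal(one$call, " ")
  expect_error(classify_conservation(aln, columns = 9), "out of range")
})

test_that("alignments read from FASTA and Clustal agree", {
  fa <- file.path(tempdir(), "aln.fa")
  writeLines(c(">sp1", "MKV-W", ">sp2", "MKVGW"), fa)
  a1 <- read_alignment(fa)
  expect_equal(unname(a1), c("MKV-W", "MKVGW"))
  cl <- file.path(tempdir(), "aln.aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "sp1             MKV-W", "sp2             MKVGW", ""), cl)
  a2 <- read_alignment(cl)
  expect_equal(toupper(unname(a2)), unname(a1))
})
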