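# shared fixtures and independent oracles, all built in code

# a small variant table with explicit genotypes
toy_variants <- function(scaffold = "s1", pos, coseg = TRUE,
                         informative = TRUE, pass = TRUE,
                         ref = "A", alt = "G") {
  n <- length(pos)
  rec <- function(x) rep_len(x, n)
  tibble::tibble(
    scaffold = rec(scaffold), pos = pos,
    ref = rec(ref), alt = rec(alt),
    pass_filter = rec(pass),
    gt_hom_parent = ifelse(rec(informative), 2L, 1L),
    gt_het_parent = 1L,
    gt_hom_pool = ifelse(rec(coseg), 2L, 1L),
    gt_het_pool = 1L
  )
}

# random variant table for property tests (sorted, biallelic)
random_variants <- function(n, scaffolds, max_pos) {
  s <- sort(sample(scaffolds, n, replace = TRUE))
  v <- tibble::tibble(
    scaffold = s,
    pos = unlist(lapply(split(seq_len(n), s), function(i) {
      sort(sample.int(max_pos, length(i), replace = TRUE))
    }), use.names = FALSE),
    ref = sample(c("A", "C", "G", "T", "AT"), n, replace = TRUE),
    pass_filter = runif(n) > 0.1,
    gt_hom_parent = sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(.15, .15, .6, .1)),
    gt_het_parent = sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(.1, .7, .1, .1)),
    gt_hom_pool = sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(.1, .2, .6, .1)),
    gt_het_pool = sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(.1, .6, .2, .1))
  )
  v$alt <- ifelse(v$ref == "AT", sample(c("GC", "A"), n, TRUE), "G")
  v$alt[v$ref == "G"] <- "T"
  dplyr::arrange(v, match(scaffold, scaffolds), pos)
}

# brute-force window recount: the oracle for window_scan
brute_force_windows <- function(variants, scaffolds, mask = NULL,
                                cfg = scan_config()) {
  v <- variants
  v$informative <- is_informative(v, mask, cfg, "genome")
  v$coseg <- v$informative & is_cosegregating(v, cfg)
  scaffolds <- scaffold_index(scaffolds)
  scaffolds <- scaffolds[scaffolds$length > cfg$min_scaffold_bp, ]
  out <- list()
  for (i in seq_len(nrow(scaffolds))) {
    s <- scaffolds$scaffold[i]; len <- scaffolds$length[i]
    for (start0 in seq(0, max(len - 1, 0), by = cfg$step_bp)) {
      ws <- start0 + 1; we <- min(start0 + cfg$window_bp, len)
      in_w <- v$scaffold == s & v$pos >= ws & v$pos <= we
      out[[length(out) + 1]] <- tibble::tibble(
        scaffold = s, start = ws, end = we,
        n_informative = sum(v$informative & in_w),
        n_coseg = sum(v$coseg & in_w)
      )
    }
  }
  dplyr::bind_rows(out)
}

# full-CDS rebuild-and-translate oracle for single-SNV effect classes
oracle_effect <- function(gene, genome, pos, alt) {
  cds_pos <- cosegmap:::cds_positions(gene)
  get_cds <- function(g) {
    chars <- strsplit(g[[gene$scaffold]], "")[[1]][cds_pos]
    if (gene$strand == "-") chars <- c(A = "T", C = "G", G = "C", T = "A")[chars]
    paste(chars, collapse = "")
  }
  ref_cds <- get_cds(genome)
  g2 <- genome
  substr(g2[[gene$scaffold]], pos, pos) <- alt
  alt_cds <- get_cds(g2)
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), if.fuzzy.codon = "X", no.init.codon = TRUE))
  p_ref <- tr(ref_cds); p_alt <- tr(alt_cds)
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
  aa_ref <- substr(p_ref, d, d); aa_alt <- substr(p_alt, d, d)
  if (aa_alt == "*") return("stop_gained")
  if (aa_ref == "*") return("stop_lost")
  if (d == 1 && aa_ref == "M") return("start_lost")
  "missense"
}

# random single-exon gene + genome for the consequence oracle test
random_gene_case <- function() {
  n_codons <- sample(10:40, 1)
  strand <- sample(c("+", "-"), 1)
  cds_len <- 3 * n_codons
  gstart <- sample(50:100, 1)
  coding <- cosegmap:::random_coding_seq(n_codons)
  glen <- gstart + cds_len + 50
  bases <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  cvec <- strsplit(coding, "")[[1]]
  if (strand == "-") cvec <- rev(c(A = "T", C = "G", G = "C", T = "A")[cvec])
  bases[gstart:(gstart + cds_len - 1)] <- cvec
  genome <- setNames(paste(bases, collapse = ""), "s1")
  gene <- gene_model("g1", scaffold = "s1", strand = strand,
                     exons = tibble::tibble(start = gstart,
                                            end = gstart + cds_len - 1))
  pos <- sample(gstart:(gstart + cds_len - 1), 1)
  ref <- substr(genome, pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  list(gene = gene, genome = genome, pos = pos, ref = ref, alt = alt)
}

# a one-SNV variant table for annotation tests
snv <- function(scaffold, pos, ref, alt) {
  tibble::tibble(scaffold = scaffold, pos = pos, ref = ref, alt = alt,
                 pass_filter = TRUE, gt_hom_parent = 2L, gt_het_parent = 1L,
                 gt_hom_pool = 2L, gt_het_pool = 1L)
}

# small, fast cross + scan configuration for end-to-end fixture tests
small_cross_cfg <- function(seed = 11, ...) {
  cross_config(scaffold_lengths = c(scf_1 = 5e5, scf_2 = 5e5, scf_3 = 5e5),
               causal_scaffold = "scf_1", causal_pos = 2.5e5,
               seed = seed, ...)
}

small_scan_cfg <- function(...) {
  scan_config(window_bp = 1e5, step_bp = 2e4, min_scaffold_bp = 2e5,
              fine_window_bp = 2e4, fine_step_bp = 5e3,
              min_interval_coseg = 20, ...)
}

# independent Monte-Carlo oracle: probability that an unlinked marker
# co-segregates, modelling Mendelian segregation and binomial read
# sampling directly (no cosegmap code)
mc_unlinked_coseg <- function(n_reps, n_pool, depth, error, f_het, f_hom) {
  call1 <- function(f_true) {
    dp <- rpois(1, depth)
    if (dp == 0) return(NA_integer_)
    p <- f_true * (1 - error) + (1 - f_true) * error
    af <- rbinom(1, dp, p) / dp
    if (af >= f_hom) return(2L)
    if (af <= 1 - f_hom) return(0L)
    if (min(af, 1 - af) >= f_het) return(1L)
    NA_integer_
  }
  hits <- vapply(seq_len(n_reps), function(i) {
    # unlinked informative marker: het parent transmits alt w.p. 1/2,
    # hom parent always transmits alt
    hom_alt <- n_pool + rbinom(1, n_pool, 0.5)
    het_alt <- n_pool + rbinom(1, n_pool, 0.5)
    c_hom <- call1(hom_alt / (2 * n_pool))
    c_het <- call1(het_alt / (2 * n_pool))
    isTRUE(c_hom == 2L) && isTRUE(c_het == 1L)
  }, logical(1))
  mean(hits)
}
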