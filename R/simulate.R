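#' Parameterize a synthetic mapping-by-sequencing cross
#'
#' Describes a family design for a monogenic recessive trait: a mutant
#' lineage segregating a causal allele, two parents (homozygous mutant x
#' heterozygous carrier by default), and two phenotype-sorted offspring
#' pools sequenced as single libraries. Markers are placed with Poisson
#' density along the scaffolds; linkage to the causal locus decays with
#' recombination distance under an interference-free (Poisson) crossover
#' model; pooled genotype calls carry depth- and error-driven noise via
#' binomial read sampling and a threshold caller.
#'
#' @param scaffold_lengths Numeric vector of scaffold lengths in bp
#'   (named, or auto-named `scf_1`, ...).
#' @param marker_density Mean markers per Mb (Poisson).
#' @param causal_scaffold,causal_pos Location of the causal locus;
#'   defaults to the middle of the first scaffold.
#' @param design `"hom_x_het"` (homozygous mutant x carrier; offspring
#'   split ~1:1 into the pools) or `"het_x_het"` (carrier x carrier;
#'   homozygous wild-type offspring are discarded).
#' @param n_offspring Offspring per pool.
#' @param recomb_rate_cm_mb Recombination rate in cM/Mb; crossovers per
#'   gamete per scaffold are Poisson with mean `rate * length_Mb / 100`.
#' @param depth Mean pooled read depth per site (Poisson).
#' @param error_rate Per-base, symmetric sequencing error rate.
#' @param f_het,f_hom Pooled-call thresholds: a site is called
#'   heterozygous when the minor-allele read fraction is at least
#'   `f_het`, homozygous when the major fraction is at least `f_hom`;
#'   fractions in between are missing calls. Requires
#'   `0 < f_het <= 0.5 < f_hom <= 1`.
#' @param informative_fraction Fraction of markers with the
#'   founder-informative pattern (fixed alternate on the mutant lineage).
#' @param ref_bias_fraction Fraction of informative markers whose
#'   alleles are flipped so the reference genome carries the mutant
#'   allele (the reference-individual-bias scenario).
#' @param mnp_fraction,indel_fraction Fractions of markers emitted as
#'   MNPs and indels rather than SNPs.
#' @param lowqual_fraction Fraction of markers written with a failing
#'   FILTER.
#' @param mask_fraction Fraction of each scaffold covered by the
#'   synthetic repeat mask in [make_fixture_suite()].
#' @param marker_positions Optional named list scaffold -> integer
#'   positions, overriding Poisson placement (the causal position is
#'   always added).
#' @param null_model If `TRUE`, offspring are assigned to the pools at
#'   random instead of by causal genotype — a no-linkage null in which
#'   phenotype and genotype are unrelated, used as the baseline for the
#'   scan's signal.
#' @param seed Integer RNG seed; the simulation is deterministic given
#'   the seed.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(scaffold_lengths = c(1e7, 1e7, 1e7),
                         marker_density = 200,
                         causal_scaffold = NULL, causal_pos = NULL,
                         design = c("hom_x_het", "het_x_het"),
                         n_offspring = 10,
                         recomb_rate_cm_mb = 1,
                         depth = 30,
                         error_rate = 0.005,
                         f_het = 0.25, f_hom = 0.9,
                         informative_fraction = 0.7,
                         ref_bias_fraction = 0,
                         mnp_fraction = 0.03, indel_fraction = 0.03,
                         lowqual_fraction = 0.02,
                         mask_fraction = 0.05,
                         marker_positions = NULL,
                         null_model = FALSE,
                         seed = 1L) {
  design <- match.arg(design)
  if (is.null(names(scaffold_lengths))) {
    names(scaffold_lengths) <- paste0("scf_", seq_along(scaffold_lengths))
  }
  if (is.null(causal_scaffold)) causal_scaffold <- names(scaffold_lengths)[1]
  if (!causal_scaffold %in% names(scaffold_lengths)) {
    stop("causal_scaffold '", causal_scaffold, "' is not a scaffold name")
  }
  if (is.null(causal_pos)) {
    causal_pos <- floor(scaffold_lengths[[causal_scaffold]] / 2)
  }
  stopifnot(
    f_het > 0, f_het <= 0.5, f_hom > 0.5, f_hom <= 1,
    marker_density >= 0, recomb_rate_cm_mb >= 0, depth >= 0,
    error_rate >= 0, error_rate < 0.5,
    causal_scaffold %in% names(scaffold_lengths),
    causal_pos >= 1, causal_pos <= scaffold_lengths[[causal_scaffold]]
  )
  structure(
    list(scaffold_lengths = scaffold_lengths, marker_density = marker_density,
         causal_scaffold = causal_scaffold, causal_pos = causal_pos,
         design = design, n_offspring = n_offspring,
         recomb_rate_cm_mb = recomb_rate_cm_mb, depth = depth,
         error_rate = error_rate, f_het = f_het, f_hom = f_hom,
         informative_fraction = informative_fraction,
         ref_bias_fraction = ref_bias_fraction,
         mnp_fraction = mnp_fraction, indel_fraction = indel_fraction,
         lowqual_fraction = lowqual_fraction, mask_fraction = mask_fraction,
         marker_positions = marker_positions, null_model = null_model,
         seed = as.integer(seed)),
    class = "cross_config"
  )
}

# transmitted haplotype (1 or 2) at each sorted marker position of one
# scaffold, under Poisson crossovers at uniform positions
gamete_haplotype <- function(pos, scaffold_len, rate_cm_mb) {
  start <- sample(c(1L, 2L), 1)
  n_x <- rpois(1, rate_cm_mb * scaffold_len / 1e8)
  if (n_x == 0) return(rep(start, length(pos)))
  xpos <- sort(runif(n_x, 0, scaffold_len))
  1L + (start - 1L + findInterval(pos, xpos)) %% 2L
}

# pooled threshold caller: alt reads / depth -> dosage call
call_pooled <- function(alt_reads, dp, f_het, f_hom) {
  out <- rep(NA_integer_, length(dp))
  af <- ifelse(dp > 0, alt_reads / dp, NA_real_)
  out[!is.na(af) & af >= f_hom] <- 2L
  out[!is.na(af) & af <= 1 - f_hom] <- 0L
  het <- !is.na(af) & pmin(af, 1 - af) >= f_het & af < f_hom & af > 1 - f_hom
  out[het] <- 1L
  out
}

#' Simulate a family cross and its pooled sequencing libraries
#'
#' Implements the generative model the co-segregation scan assumes:
#' (1) founder haplotypes with the causal allele and linked alternate
#' alleles on the mutant lineage; (2) gametes with interference-free
#' Poisson crossovers at uniform positions; (3) offspring sorted into
#' the homozygous pool iff homozygous for the causal allele (recessive)
#' and into the heterozygous pool iff carrier (`het_x_het` discards
#' homozygous wild-type offspring); (4) per-marker pooled reads drawn
#' binomially from the true pooled allele fraction with symmetric
#' per-base error and called by the `f_het`/`f_hom` threshold rule;
#' (5) parents genotyped error-free. Deterministic under `cfg$seed`.
#'
#' @param cfg A [cross_config()].
#' @return A list of class `coseg_cross` with elements `variants` (a
#'   variant tibble ready for [window_scan()]), `truth` (causal locus,
#'   founder phases, per-offspring causal genotypes and pool
#'   assignments, true pool allele counts, and the het-parent
#'   transmission matrix), `scaffolds` (a [scaffold_index()] tibble) and
#'   `config`.
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  set.seed(cfg$seed)
  sl <- cfg$scaffold_lengths

  # --- marker placement ---------------------------------------------------
  marker_list <- lapply(names(sl), function(s) {
    if (!is.null(cfg$marker_positions)) {
      pos <- sort(unique(as.integer(cfg$marker_positions[[s]])))
    } else {
      n <- rpois(1, cfg$marker_density * sl[[s]] / 1e6)
      pos <- sort(sample.int(sl[[s]], min(n, sl[[s]])))
    }
    if (s == cfg$causal_scaffold) pos <- sort(unique(c(pos, cfg$causal_pos)))
    tibble(scaffold = s, pos = pos)
  })
  markers <- bind_rows(marker_list)
  M <- nrow(markers)
  causal_idx <- which(markers$scaffold == cfg$causal_scaffold &
                        markers$pos == cfg$causal_pos)

  # --- founder haplotypes: columns p1_a, p1_b, p2_m, p2_w -----------------
  info_pattern <- if (cfg$design == "hom_x_het") c(1L, 1L, 1L, 0L)
                  else c(1L, 0L, 1L, 0L)
  all_patterns <- as.matrix(expand.grid(rep(list(0:1), 4)))
  keep_pat <- !(apply(all_patterns, 1, function(p) all(p == info_pattern)) |
                  rowSums(all_patterns) == 0)
  noninfo_patterns <- all_patterns[keep_pat, , drop = FALSE]

  informative <- runif(M) < cfg$informative_fraction
  informative[causal_idx] <- TRUE
  founders <- matrix(0L, nrow = M, ncol = 4,
                     dimnames = list(NULL, c("p1_a", "p1_b", "p2_m", "p2_w")))
  founders[informative, ] <- matrix(info_pattern, nrow = sum(informative),
                                    ncol = 4, byrow = TRUE)
  n_non <- sum(!informative)
  if (n_non > 0) {
    founders[!informative, ] <-
      noninfo_patterns[sample.int(nrow(noninfo_patterns), n_non, replace = TRUE), ,
                       drop = FALSE]
  }
  orientation <- if_else(informative, "alt", NA_character_)
  if (cfg$ref_bias_fraction > 0) {
    flip <- informative & runif(M) < cfg$ref_bias_fraction
    flip[causal_idx] <- FALSE
    founders[flip, ] <- 1L - founders[flip, ]
    orientation[flip] <- "ref"
  }

  # --- offspring generation ----------------------------------------------
  scaffold_of <- markers$scaffold
  idx_by_scaffold <- split(seq_len(M), factor(scaffold_of, levels = names(sl)))
  draw_gamete <- function(col_a, col_b) {
    hap <- integer(M)
    for (s in names(sl)) {
      i <- idx_by_scaffold[[s]]
      if (length(i) == 0) next
      hap[i] <- gamete_haplotype(markers$pos[i], sl[[s]], cfg$recomb_rate_cm_mb)
    }
    list(allele = if_else(hap == 1L, founders[, col_a], founders[, col_b]),
         hap = hap)
  }

  n_per_pool <- cfg$n_offspring
  max_draws <- max(1000L, 100L * n_per_pool)
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    n_draws <- 0L
    n_hom <- n_het <- 0L
    dosage_hom <- dosage_het <- list()
    p2hap_hom <- p2hap_het <- list()
    draw_cd <- integer(0)
    draw_pool <- character(0)
    while ((n_hom < n_per_pool || n_het < n_per_pool) && n_draws < max_draws) {
      n_draws <- n_draws + 1L
      g1 <- draw_gamete("p1_a", "p1_b")
      g2 <- draw_gamete("p2_m", "p2_w")
      dos <- g1$allele + g2$allele
      cd <- dos[causal_idx]
      if (isTRUE(cfg$null_model)) {
        open <- c(if (n_hom < n_per_pool) "hom", if (n_het < n_per_pool) "het")
        pool <- open[sample.int(length(open), 1)]
      } else if (cd == 2L && n_hom < n_per_pool) {
        pool <- "hom"
      } else if (cd == 1L && n_het < n_per_pool) {
        pool <- "het"
      } else if (cd == 2L || cd == 1L) {
        pool <- "surplus"
      } else {
        pool <- "discarded"
      }
      draw_cd[n_draws] <- cd
      draw_pool[n_draws] <- pool
      if (pool == "hom") {
        n_hom <- n_hom + 1L
        dosage_hom[[n_hom]] <- dos
        p2hap_hom[[n_hom]] <- g2$hap == 1L
      } else if (pool == "het") {
        n_het <- n_het + 1L
        dosage_het[[n_het]] <- dos
        p2hap_het[[n_het]] <- g2$hap == 1L
      }
    }
    if (n_hom == n_per_pool && n_het == n_per_pool) break
    if (attempt >= 100L) stop("could not fill both offspring pools after 100 attempts")
    warning("a pool was left empty or unfilled; regenerating offspring draw")
  }
  draws <- tibble(id = seq_len(n_draws), causal_dosage = draw_cd,
                  pool = draw_pool)
  D_hom <- do.call(cbind, dosage_hom)
  D_het <- do.call(cbind, dosage_het)

  # --- pooled read sampling and threshold calls ---------------------------
  pool_call <- function(D) {
    alt_true <- rowSums(D)
    f_true <- alt_true / (2 * ncol(D))
    dp <- rpois(M, cfg$depth)
    p <- f_true * (1 - cfg$error_rate) + (1 - f_true) * cfg$error_rate
    alt_reads <- rbinom(M, dp, p)
    list(call = call_pooled(alt_reads, dp, cfg$f_het, cfg$f_hom),
         alt_true = alt_true)
  }
  hom_call <- pool_call(D_hom)
  het_call <- pool_call(D_het)

  # --- alleles, classes, filters ------------------------------------------
  bases <- c("A", "C", "G", "T")
  u <- runif(M)
  vclass <- dplyr::case_when(
    u < cfg$mnp_fraction ~ "MNP",
    u < cfg$mnp_fraction + cfg$indel_fraction ~ "INDEL",
    TRUE ~ "SNP"
  )
  vclass[causal_idx] <- "SNP"
  ref <- character(M)
  alt <- character(M)
  other <- function(b) vapply(b, function(x) sample(setdiff(bases, x), 1),
                              character(1))
  is_snp <- vclass == "SNP"
  ref[is_snp] <- sample(bases, sum(is_snp), replace = TRUE)
  alt[is_snp] <- other(ref[is_snp])
  is_mnp <- vclass == "MNP"
  if (any(is_mnp)) {
    r1 <- sample(bases, sum(is_mnp), TRUE); r2 <- sample(bases, sum(is_mnp), TRUE)
    ref[is_mnp] <- paste0(r1, r2)
    alt[is_mnp] <- paste0(other(r1), other(r2))
  }
  is_ind <- vclass == "INDEL"
  if (any(is_ind)) {
    b1 <- sample(bases, sum(is_ind), TRUE); b2 <- sample(bases, sum(is_ind), TRUE)
    ins <- runif(sum(is_ind)) < 0.5
    ref[is_ind] <- if_else(ins, b1, paste0(b1, b2))
    alt[is_ind] <- if_else(ins, paste0(b1, b2), b1)
  }
  ref[causal_idx] <- "C"
  alt[causal_idx] <- "T"
  pass <- runif(M) >= cfg$lowqual_fraction
  pass[causal_idx] <- TRUE

  variants <- as_variants(tibble(
    scaffold = markers$scaffold, pos = markers$pos, ref = ref, alt = alt,
    pass_filter = pass,
    gt_hom_parent = founders[, "p1_a"] + founders[, "p1_b"],
    gt_het_parent = founders[, "p2_m"] + founders[, "p2_w"],
    gt_hom_pool = hom_call$call,
    gt_het_pool = het_call$call
  ))

  truth <- list(
    causal = list(scaffold = cfg$causal_scaffold, pos = cfg$causal_pos),
    founders = markers |>
      mutate(p1_a = founders[, 1], p1_b = founders[, 2],
             p2_m = founders[, 3], p2_w = founders[, 4],
             informative = informative, orientation = orientation),
    offspring = draws,
    pool_counts = tibble(scaffold = markers$scaffold, pos = markers$pos,
                         hom_pool_alt = hom_call$alt_true,
                         het_pool_alt = het_call$alt_true,
                         n_chrom = 2 * n_per_pool),
    het_transmission = list(
      hom_pool = do.call(cbind, p2hap_hom),
      het_pool = do.call(cbind, p2hap_het)
    )
  )
  structure(
    list(variants = variants, truth = truth,
         scaffolds = scaffold_index(tibble(scaffold = names(sl),
                                           length = unname(sl))),
         config = cfg),
    class = "coseg_cross"
  )
}
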