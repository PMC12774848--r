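#' Configuration of the co-segregation scan
#'
#' Defaults follow the published mapping-by-sequencing setup: a 1-Mb
#' sliding window with a 100-kb step over scaffolds longer than 1 Mb for
#' the genome-wide scan (SNP/MNP only), and 200-kb windows with a 50-kb
#' step that additionally include indels for the fine scan.
#'
#' @param window_bp,step_bp Genome-wide window length and step (bp).
#' @param min_scaffold_bp Only scaffolds strictly longer than this are
#'   scanned genome-wide.
#' @param fine_window_bp,fine_step_bp Fine-scan window length and step.
#' @param genomewide_classes,fine_classes Variant classes counted in each
#'   tier.
#' @param min_interval_coseg Candidate intervals with fewer
#'   co-segregating variants than this are flagged `disregarded`
#'   (peak triage).
#' @param proportion_threshold Fixed peak-calling threshold in `[0, 1]`,
#'   or `NULL` (default) for the adaptive rule
#'   `max(0.5, midpoint of the median and the maximum of defined window
#'   proportions)`, which separates the unlinked background (the median,
#'   since most of the genome is unlinked) from the linked plateau (the
#'   maximum) at any genome size.
#' @param allele_orientation `"alt_is_mutant"` (reference genome carries
#'   the wild-type allele) or `"auto"`, which additionally accepts the
#'   mirrored genotype pattern (homozygous-reference in the homozygous
#'   libraries) arising when the reference individual carries the mutant
#'   allele.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_bp = 1e6, step_bp = 1e5, min_scaffold_bp = 1e6,
                        fine_window_bp = 2e5, fine_step_bp = 5e4,
                        genomewide_classes = c("SNP", "MNP"),
                        fine_classes = c("SNP", "MNP", "INDEL"),
                        min_interval_coseg = 100,
                        proportion_threshold = NULL,
                        allele_orientation = c("alt_is_mutant", "auto")) {
  allele_orientation <- match.arg(allele_orientation)
  stopifnot(step_bp <= window_bp, fine_step_bp <= fine_window_bp,
            min_interval_coseg >= 0,
            is.null(proportion_threshold) ||
              (proportion_threshold >= 0 && proportion_threshold <= 1))
  structure(
    list(window_bp = window_bp, step_bp = step_bp,
         min_scaffold_bp = min_scaffold_bp,
         fine_window_bp = fine_window_bp, fine_step_bp = fine_step_bp,
         genomewide_classes = genomewide_classes, fine_classes = fine_classes,
         min_interval_coseg = min_interval_coseg,
         proportion_threshold = proportion_threshold,
         allele_orientation = allele_orientation),
    class = "scan_config"
  )
}

# per-variant allele orientation: "alt" when the parental pattern is
# (hom parent HOM_ALT, het parent HET), "ref" for the mirrored pattern
# (only under auto), NA when the parents do not match either pattern
variant_orientation <- function(variants, cfg) {
  hp <- variants$gt_hom_parent
  tp <- variants$gt_het_parent
  out <- rep(NA_character_, nrow(variants))
  out[!is.na(hp) & !is.na(tp) & hp == 2L & tp == 1L] <- "alt"
  if (cfg$allele_orientation == "auto") {
    out[!is.na(hp) & !is.na(tp) & hp == 0L & tp == 1L] <- "ref"
  }
  out
}

#' Is a variant informative for the co-segregation scan?
#'
#' A variant is informative when it passes the quality filter, lies
#' outside the repeat mask, belongs to a variant class permitted for the
#' scan tier, and its parental genotypes already match the expected
#' pattern: homozygous in the homozygous parent and heterozygous in the
#' heterozygous parent. A missing parental genotype makes the site
#' uninformative. Informative variants form the denominator of the
#' windowed co-segregation proportion.
#'
#' @param variants A variant tibble.
#' @param mask A `repeat_mask` or `NULL`.
#' @param cfg A [scan_config()].
#' @param tier `"genome"` (SNP/MNP) or `"fine"` (SNP/MNP and indels).
#' @return Logical vector, one element per variant.
#' @export
is_informative <- function(variants, mask = NULL, cfg = scan_config(),
                           tier = c("genome", "fine")) {
  tier <- match.arg(tier)
  classes <- if (tier == "genome") cfg$genomewide_classes else cfg$fine_classes
  masked <- if (is.null(mask)) FALSE else
    mask_contains(mask, variants$scaffold, variants$pos)
  variants$pass_filter &
    variants$vclass %in% classes &
    !masked &
    !is.na(variant_orientation(variants, cfg))
}

#' Does a variant co-segregate with the phenotype?
#'
#' Among informative variants, a variant co-segregates when the offspring
#' pools show the transmitted pattern: the homozygous-phenotype pool is
#' homozygous for the mutant-lineage allele and the heterozygous pool is
#' heterozygous. A missing pool genotype never counts as co-segregating.
#' The result is only meaningful for variants where [is_informative()] is
#' `TRUE`; windowed statistics use the conjunction.
#'
#' @inheritParams is_informative
#' @return Logical vector, one element per variant.
#' @export
is_cosegregating <- function(variants, cfg = scan_config()) {
  orient <- variant_orientation(variants, cfg)
  hp <- variants$gt_hom_pool
  tp <- variants$gt_het_pool
  ok_alt <- !is.na(hp) & !is.na(tp) & hp == 2L & tp == 1L
  ok_ref <- !is.na(hp) & !is.na(tp) & hp == 0L & tp == 1L
  dplyr::case_when(
    is.na(orient) ~ FALSE,
    orient == "alt" ~ ok_alt,
    TRUE ~ ok_ref
  )
}

# variants + informative/coseg/orientation columns for one tier
flag_variants <- function(variants, mask, cfg, tier) {
  variants$orientation <- variant_orientation(variants, cfg)
  variants$informative <- is_informative(variants, mask, cfg, tier)
  variants$coseg <- variants$informative & is_cosegregating(variants, cfg)
  variants
}

# counts of sorted positions falling in [ws, we] per window
count_in_windows <- function(pos_sorted, ws, we) {
  findInterval(we, pos_sorted) - findInterval(ws - 1, pos_sorted)
}

# window stats for one scaffold given flagged, sorted variants
scaffold_windows <- function(flagged, scaffold, scaffold_len, window_bp, step_bp) {
  start0 <- seq(0, max(scaffold_len - 1, 0), by = step_bp)
  ws <- start0 + 1
  we <- pmin(start0 + window_bp, scaffold_len)
  pos_inf <- flagged$pos[flagged$informative]
  pos_cos <- flagged$pos[flagged$coseg]
  n_inf <- count_in_windows(pos_inf, ws, we)
  n_cos <- count_in_windows(pos_cos, ws, we)
  tibble(
    scaffold = scaffold, start = ws, end = we,
    n_informative = n_inf, n_coseg = n_cos,
    proportion = if_else(n_inf > 0, n_cos / n_inf, NA_real_),
    defined = n_inf > 0,
    truncated = (we - ws + 1) < window_bp
  )
}

#' Genome-wide sliding-window co-segregation scan
#'
#' For every scaffold longer than `cfg$min_scaffold_bp`, computes in
#' sliding windows (anchored at position 0, advancing by `cfg$step_bp`)
#' the number of informative variants, the number of those that
#' co-segregate with the phenotype, and their ratio — the co-segregation
#' proportion. The final partial windows at a scaffold end are retained
#' and flagged `truncated`. Windows with no informative variant are
#' `defined = FALSE` (0/0 is not evidence) and are excluded from peak
#' calling.
#'
#' @param variants A variant tibble sorted by (scaffold, pos).
#' @param scaffolds Tibble with columns `scaffold`, `length` (see
#'   [scaffold_index()]).
#' @param mask A `repeat_mask` or `NULL`.
#' @param cfg A [scan_config()].
#' @return A `coseg_windows` tibble: one row per (scaffold, window) with
#'   columns `scaffold`, `start`, `end` (1-based inclusive),
#'   `n_informative`, `n_coseg`, `proportion`, `defined`, `truncated`.
#'   Attributes `config`, `tier` and `scaffolds` carry the scan context.
#' @export
window_scan <- function(variants, scaffolds, mask = NULL, cfg = scan_config()) {
  variants <- as_variants(variants)
  check_sorted_variants(variants)
  scaffolds <- scaffold_index(scaffolds)
  scanned <- scaffolds[scaffolds$length > cfg$min_scaffold_bp, , drop = FALSE]
  flagged <- flag_variants(variants, mask, cfg, "genome")
  out <- purrr::map2(scanned$scaffold, scanned$length, function(s, len) {
    scaffold_windows(flagged[flagged$scaffold == s, , drop = FALSE],
                     s, len, cfg$window_bp, cfg$step_bp)
  }) |> bind_rows()
  new_coseg_windows(out, cfg, "genome", scaffolds)
}

#' Fine-scale co-segregation scan of a candidate region
#'
#' Recomputes the co-segregation proportion inside one region at fine
#' resolution (defaults: 200-kb windows, 50-kb step), with indels now
#' included among the counted variant classes. Windows stay anchored on
#' the scaffold's `fine_step_bp` grid so fine and genome-wide windows are
#' comparable; windows are clipped to the region.
#'
#' @param variants A variant tibble sorted by (scaffold, pos).
#' @param scaffold Scaffold name.
#' @param region Numeric length-2 vector: 1-based inclusive region bounds.
#' @param mask A `repeat_mask` or `NULL`.
#' @param cfg A [scan_config()].
#' @return A `coseg_windows` tibble (tier `"fine"`); empty for an empty
#'   region.
#' @export
fine_scan <- function(variants, scaffold, region, mask = NULL,
                      cfg = scan_config()) {
  variants <- as_variants(variants)
  check_sorted_variants(variants)
  if (length(region) != 2 || region[2] < region[1]) {
    return(new_coseg_windows(empty_windows(), cfg, "fine",
                             tibble(scaffold = character(), length = numeric())))
  }
  flagged <- flag_variants(variants[variants$scaffold == scaffold, , drop = FALSE],
                           mask, cfg, "fine")
  first0 <- floor((region[1] - 1) / cfg$fine_step_bp) * cfg$fine_step_bp
  start0 <- seq(first0, region[2] - 1, by = cfg$fine_step_bp)
  ws <- pmax(start0 + 1, region[1])
  we <- pmin(start0 + cfg$fine_window_bp, region[2])
  keep <- ws <= we
  ws <- ws[keep]; we <- we[keep]
  n_inf <- count_in_windows(flagged$pos[flagged$informative], ws, we)
  n_cos <- count_in_windows(flagged$pos[flagged$coseg], ws, we)
  out <- tibble(
    scaffold = scaffold, start = ws, end = we,
    n_informative = n_inf, n_coseg = n_cos,
    proportion = if_else(n_inf > 0, n_cos / n_inf, NA_real_),
    defined = n_inf > 0,
    truncated = (we - ws + 1) < cfg$fine_window_bp
  )
  new_coseg_windows(out, cfg, "fine",
                    tibble(scaffold = scaffold, length = max(region[2], 0)))
}

empty_windows <- function() {
  tibble(scaffold = character(), start = numeric(), end = numeric(),
         n_informative = integer(), n_coseg = integer(),
         proportion = numeric(), defined = logical(), truncated = logical())
}

new_coseg_windows <- function(x, cfg, tier, scaffolds) {
  class(x) <- c("coseg_windows", class(x))
  attr(x, "config") <- cfg
  attr(x, "tier") <- tier
  attr(x, "scaffolds") <- scaffolds
  x
}
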