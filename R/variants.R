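#' Classify a biallelic substitution or indel
#'
#' A variant is a `SNP` when reference and alternate alleles are both a
#' single base, an `MNP` (multi-nucleotide polymorphism) when they have
#' equal length greater than one, and an `INDEL` otherwise.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector with values `"SNP"`, `"MNP"` or `"INDEL"`.
#' @export
#' @examples
#' variant_class(c("A", "AT", "A"), c("G", "GC", "AT"))
variant_class <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  dplyr::case_when(
    nr == 1L & na == 1L ~ "SNP",
    nr == na ~ "MNP",
    TRUE ~ "INDEL"
  )
}

#' Coerce and validate a variant table
#'
#' The variant table is the package's central data structure: one row per
#' biallelic variant with the genotype of each of the four family
#' libraries stored as alt-allele dosage (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing call).
#'
#' @param x A data frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt`, `pass_filter`, and the four genotype columns
#'   `gt_hom_parent`, `gt_het_parent`, `gt_hom_pool`, `gt_het_pool`.
#'   A `vclass` column is recomputed if absent.
#' @return A tibble with a validated `vclass` column.
#' @export
as_variants <- function(x) {
  x <- as_tibble(x)
  need <- c("scaffold", "pos", "ref", "alt", "pass_filter", .gt_cols)
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(x$pos < 1)) stop("variant positions must be >= 1 (1-based)")
  if (any(grepl(",", x$alt, fixed = TRUE))) {
    stop("variant table must be biallelic: multi-allelic ALT found")
  }
  bad_gt <- vapply(
    x[.gt_cols],
    function(g) any(!is.na(g) & !g %in% 0:2),
    logical(1)
  )
  if (any(bad_gt)) stop("genotype dosages must be 0, 1, 2 or NA")
  x$vclass <- variant_class(x$ref, x$alt)
  dplyr::relocate(x, "scaffold", "pos", "ref", "alt", "vclass", "pass_filter")
}

# error unless variants are sorted by (scaffold block, pos)
check_sorted_variants <- function(x) {
  r <- rle(as.character(x$scaffold))
  if (anyDuplicated(r$values) > 0) {
    stop("variants are not sorted: scaffolds are interleaved; ",
         "sort the input by scaffold and position")
  }
  ok <- unlist(lapply(split(x$pos, factor(x$scaffold, levels = r$values)),
                      function(p) all(diff(p) >= 0)), use.names = FALSE)
  if (!all(ok)) {
    stop("variants are not sorted by position within scaffold; ",
         "sort the input by scaffold and position")
  }
  invisible(x)
}
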