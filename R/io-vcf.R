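#' Read a four-library multi-sample VCF into a variant table
#'
#' Reads a VCF v4.x file, keeps biallelic sites only (multi-allelic sites
#' are skipped and counted), and maps each library role onto a sample
#' column. Genotype strings (`0/0`, `0/1`, `1/1`, `./.`, phased or
#' unphased) become alt-allele dosages; phase is ignored. `pass_filter`
#' is `TRUE` iff the FILTER field is `PASS` or `.`. Records failing
#' FILTER are retained with `pass_filter = FALSE`; the scan decides
#' exclusion.
#'
#' @param path Path to a VCF file.
#' @param role_map Named character vector mapping the four roles
#'   (`hom_parent`, `het_parent`, `hom_pool`, `het_pool`) to sample names
#'   in the VCF header. Defaults to samples named after the roles.
#' @return A variant tibble (see [as_variants()]), sorted by
#'   (scaffold, pos) as required of the input, with attributes
#'   `n_multiallelic` (skipped multi-allelic sites) and `samples`.
#' @export
read_vcf <- function(path, role_map = setNames(.roles, .roles)) {
  miss_role <- setdiff(.roles, names(role_map))
  if (length(miss_role) > 0) {
    stop("role_map is missing role(s): ", paste(miss_role, collapse = ", "))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  absent <- role_map[!role_map %in% samples]
  if (length(absent) > 0) {
    stop("sample(s) not in VCF header: ",
         paste(sprintf("%s (role %s)", absent, names(absent)), collapse = ", "))
  }
  multi <- is.na(fix$ALT) | grepl(",", fix$ALT, fixed = TRUE) | fix$ALT == "."
  n_multi <- sum(multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(samples),
                                     dimnames = list(NULL, samples))
  out <- tibble(
    scaffold = fix$CHROM[!multi],
    pos = as.integer(fix$POS[!multi]),
    ref = fix$REF[!multi],
    alt = fix$ALT[!multi],
    pass_filter = fix$FILTER[!multi] %in% c("PASS", ".") | is.na(fix$FILTER[!multi])
  )
  for (role in .roles) {
    out[[paste0("gt_", role)]] <- gt_to_dosage(gt[!multi, role_map[[role]]])
  }
  out <- as_variants(out)
  check_sorted_variants(out)
  attr(out, "n_multiallelic") <- n_multi
  attr(out, "samples") <- role_map
  out
}

# "0/1", "0|1", "./." etc. -> alt dosage
gt_to_dosage <- function(g) {
  g <- gsub("|", "/", g, fixed = TRUE)
  d <- rep(NA_integer_, length(g))
  d[g == "0/0"] <- 0L
  d[g %in% c("0/1", "1/0")] <- 1L
  d[g == "1/1"] <- 2L
  d
}

#' Write a variant table as a minimal VCF v4.2 file
#'
#' Emits a four-sample VCF with GT-only genotypes. Records with
#' `pass_filter = FALSE` are written with FILTER `q_fail` so that the
#' flag survives a round trip through [read_vcf()].
#'
#' @param variants A variant tibble (see [as_variants()]).
#' @param path Output path.
#' @param sample_names Named character vector role -> sample name used as
#'   column headers; defaults to the role names.
#' @param contigs Optional tibble with columns `scaffold`, `length` used
#'   to emit `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path,
                      sample_names = setNames(.roles, .roles),
                      contigs = NULL) {
  variants <- as_variants(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cosegmap",
    "##FILTER=<ID=q_fail,Description=\"Failed quality filter\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          contigs$scaffold, as.integer(contigs$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT",
                        unname(sample_names[.roles])), collapse = "\t"))
  dosage_to_gt <- function(d) {
    g <- rep("./.", length(d))
    g[!is.na(d) & d == 0] <- "0/0"
    g[!is.na(d) & d == 1] <- "0/1"
    g[!is.na(d) & d == 2] <- "1/1"
    g
  }
  body <- paste(
    variants$scaffold, variants$pos, ".", variants$ref, variants$alt, ".",
    if_else(variants$pass_filter, "PASS", "q_fail"), ".", "GT",
    dosage_to_gt(variants$gt_hom_parent),
    dosage_to_gt(variants$gt_het_parent),
    dosage_to_gt(variants$gt_hom_pool),
    dosage_to_gt(variants$gt_het_pool),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}
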