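#' Run the full mapping-by-sequencing pipeline
#'
#' Orchestrates the published analysis flow on one set of inputs:
#' genome-wide window scan, peak calling and triage, fine scan of each
#' surviving candidate interval, consequence annotation of the
#' co-segregating variants inside those intervals, and a ranked
#' candidate report. Writes TSV artifacts (window stats, fine-scan
#' stats, candidate intervals, consequence report) plus a Markdown
#' summary in the narrative order genome-wide scan, fine scan, genes,
#' high-impact variants. Every TSV carries a provenance header (package
#' version, seed, configuration hash); timestamps are confined to
#' messages so reruns are byte-identical.
#'
#' @param vcf,mask,gff,fasta Input file paths (`mask`, `gff`, `fasta`
#'   may be `NULL`; annotation stages are skipped without `gff`+`fasta`).
#' @param role_map Named character vector role -> VCF sample name.
#' @param outdir Output directory (created if needed).
#' @param cfg A [scan_config()].
#' @param seed Integer recorded in output headers (the pipeline itself
#'   is deterministic).
#' @return Invisibly, a list with `windows`, `peaks`, `fine` (list per
#'   candidate), `consequences`, `report` (ranked candidate tibble) and
#'   `paths`.
#' @export
run_pipeline <- function(vcf, mask = NULL, gff = NULL, fasta = NULL,
                         role_map = setNames(.roles, .roles),
                         outdir, cfg = scan_config(), seed = 0L) {
  for (p in c(vcf, mask, gff, fasta)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  miss_role <- setdiff(.roles, names(role_map))
  if (length(miss_role) > 0) {
    stop("role_map is missing role(s): ", paste(miss_role, collapse = ", "))
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  message("[scan] reading inputs")
  variants <- read_vcf(vcf, role_map)
  mask_iv <- if (!is.null(mask)) read_bed_mask(mask) else NULL
  genome <- if (!is.null(fasta)) read_fasta(fasta) else NULL
  genes <- if (!is.null(gff)) read_gff3(gff) else NULL
  scaffolds <- if (!is.null(genome)) scaffold_index(genome) else
    variants |>
      group_by(.data$scaffold) |>
      summarise(length = max(.data$pos), .groups = "drop") |>
      scaffold_index()

  prov <- sprintf("# cosegmap %s | seed=%d | config=%s",
                  as.character(utils::packageVersion("cosegmap")),
                  as.integer(seed), rlang::hash(cfg))
  write_prov_tsv <- function(x, path) {
    writeLines(prov, path)
    suppressWarnings(readr::write_tsv(as_tibble(x), path, append = TRUE,
                                      col_names = TRUE))
  }

  message("[scan] genome-wide window scan")
  windows <- window_scan(variants, scaffolds, mask_iv, cfg)
  message("[peaks] calling candidate intervals")
  peaks <- call_peaks(windows, variants, mask_iv, cfg)
  surv <- peaks[!peaks$disregarded, , drop = FALSE]

  message("[fine] fine-scanning ", nrow(surv), " candidate interval(s)")
  fine <- lapply(seq_len(nrow(surv)), function(i) {
    fine_scan(variants, surv$scaffold[i], c(surv$start[i], surv$end[i]),
              mask_iv, cfg)
  })

  consequences <- NULL
  report <- NULL
  if (!is.null(genes) && !is.null(genome) && nrow(surv) > 0) {
    message("[annotate] consequence calls in candidate intervals")
    flagged <- flag_variants(variants, mask_iv, cfg, "fine")
    cons <- lapply(seq_len(nrow(surv)), function(i) {
      v <- flagged[flagged$scaffold == surv$scaffold[i] &
                     flagged$pos >= surv$start[i] &
                     flagged$pos <= surv$end[i] & flagged$coseg, , drop = FALSE]
      annotate_variants(v, genes, genome)
    })
    consequences <- bind_rows(cons)
    report <- summarize_candidates(consequences)
  }

  paths <- list(
    windows = file.path(outdir, "window_stats.tsv"),
    peaks = file.path(outdir, "candidate_intervals.tsv"),
    fine = file.path(outdir, "fine_scan.tsv"),
    consequences = file.path(outdir, "consequences.tsv"),
    report = file.path(outdir, "report.md")
  )
  write_prov_tsv(windows, paths$windows)
  write_prov_tsv(peaks, paths$peaks)
  write_prov_tsv(bind_rows(fine), paths$fine)
  if (!is.null(report)) write_prov_tsv(report, paths$consequences)

  md <- c(
    "# Mapping-by-sequencing report", "", prov, "",
    "## Genome-wide scan", "",
    sprintf("- %d windows over %d scaffolds; %d defined.",
            nrow(windows), length(unique(windows$scaffold)),
            sum(windows$defined)),
    sprintf("- Peak-calling threshold: %.3f (proportion of co-segregating variants).",
            attr(peaks, "threshold")),
    "",
    "## Candidate intervals", "",
    if (nrow(peaks) == 0) "- none" else sprintf(
      "- %s:%d-%d  max proportion %.3f, %d co-segregating variants (%d/Mb, %.1f Mb)%s",
      peaks$scaffold, as.integer(peaks$start), as.integer(peaks$end),
      peaks$max_proportion, peaks$n_coseg_total,
      as.integer(peaks$density_per_mb), peaks$width_mb,
      if_else(peaks$disregarded, " [disregarded: too few co-segregating variants]", "")
    ),
    ""
  )
  if (!is.null(report) && nrow(report) > 0) {
    md <- c(md, "## Candidate genes and high-impact variants", "",
            sprintf("%d. %s", report$rank, report$report_line), "")
  }
  writeLines(md, paths$report)
  message("[done] report at ", paths$report)
  invisible(list(windows = windows, peaks = peaks, fine = fine,
                 consequences = consequences, report = report, paths = paths))
}
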