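#' Call and triage candidate intervals from window statistics
#'
#' Windows with a defined co-segregation proportion at or above the
#' peak-calling threshold are merged when they overlap or are adjacent.
#' The threshold is `cfg$proportion_threshold` when set, otherwise the
#' adaptive rule `max(0.5, (median + max) / 2)` over defined window
#' proportions, which sits between the unlinked background level and the
#' linked plateau. Each merged interval's total number of co-segregating
#' variants is *recounted over its span* (overlapping windows are never
#' summed). Intervals supported by fewer than `cfg$min_interval_coseg`
#' co-segregating variants are retained but flagged `disregarded` —
#' the published triage that drops peaks backed by only a handful of
#' variants. Survivors are ranked by maximum window proportion, then by
#' total co-segregating variants, then by (scaffold order, start).
#'
#' @param windows A `coseg_windows` tibble from [window_scan()] or
#'   [fine_scan()].
#' @param variants The variant tibble the windows were computed from.
#' @param mask A `repeat_mask` or `NULL` (must match the scan call).
#' @param cfg A [scan_config()]; defaults to the one recorded on
#'   `windows`.
#' @return A `coseg_peaks` tibble: `scaffold`, `start`, `end`,
#'   `max_proportion`, `n_informative_total`, `n_coseg_total`,
#'   `width_mb`, `density_per_mb`, `disregarded`, `rank` (NA for
#'   disregarded intervals). Attribute `threshold` records the
#'   proportion cutoff used.
#' @export
call_peaks <- function(windows, variants, mask = NULL,
                       cfg = attr(windows, "config")) {
  if (is.null(cfg)) cfg <- scan_config()
  tier <- attr(windows, "tier") %||% "genome"
  thr <- cfg$proportion_threshold
  w <- as_tibble(windows)
  defined <- w[w$defined, , drop = FALSE]
  if (is.null(thr)) {
    thr <- if (nrow(defined) == 0) 0.5 else
      max(0.5, (stats::median(defined$proportion, na.rm = TRUE) +
                  max(defined$proportion, na.rm = TRUE)) / 2)
  }
  sel <- defined[defined$proportion >= thr, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(new_coseg_peaks(empty_peaks(), thr))
  }
  scaff_order <- attr(windows, "scaffolds")$scaffold %||% unique(w$scaffold)
  sel$scaffold <- factor(sel$scaffold, levels = scaff_order)
  sel <- arrange(sel, .data$scaffold, .data$start)
  merged <- sel |>
    group_by(.data$scaffold) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -Inf) + 1)) |>
    group_by(.data$scaffold, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              max_proportion = max(.data$proportion), .groups = "drop")

  flagged <- flag_variants(as_variants(variants), mask, cfg, tier)
  counts <- purrr::pmap(merged, function(scaffold, grp, start, end, ...) {
    v <- flagged[flagged$scaffold == as.character(scaffold) &
                   flagged$pos >= start & flagged$pos <= end, , drop = FALSE]
    tibble(n_informative_total = sum(v$informative), n_coseg_total = sum(v$coseg))
  }) |> bind_rows()
  m <- interval_metrics(merged$start, merged$end, counts$n_coseg_total,
                        union = FALSE)
  out <- tibble(
    scaffold = as.character(merged$scaffold),
    start = merged$start, end = merged$end,
    max_proportion = merged$max_proportion,
    n_informative_total = counts$n_informative_total,
    n_coseg_total = counts$n_coseg_total,
    width_mb = m$width_mb, density_per_mb = m$density_per_mb,
    disregarded = counts$n_coseg_total < cfg$min_interval_coseg
  )
  surv <- which(!out$disregarded)
  out$rank <- NA_integer_
  if (length(surv) > 0) {
    key <- order(-out$max_proportion[surv], -out$n_coseg_total[surv],
                 match(out$scaffold[surv], scaff_order), out$start[surv])
    out$rank[surv[key]] <- seq_along(surv)
  }
  out <- arrange(out, is.na(.data$rank), .data$rank,
                 match(.data$scaffold, scaff_order), .data$start)
  new_coseg_peaks(out, thr)
}

empty_peaks <- function() {
  tibble(scaffold = character(), start = numeric(), end = numeric(),
         max_proportion = numeric(), n_informative_total = integer(),
         n_coseg_total = integer(), width_mb = numeric(),
         density_per_mb = numeric(), disregarded = logical(),
         rank = integer())
}

new_coseg_peaks <- function(x, threshold) {
  class(x) <- c("coseg_peaks", class(x))
  attr(x, "threshold") <- threshold
  x
}

#' Width and co-segregating-variant density of a candidate interval
#'
#' Computes the two summary metrics printed for candidate intervals:
#' width in megabases (rounded to 0.1 Mb) and co-segregating variants
#' per megabase (rounded to the nearest integer, computed from the
#' unrounded width). An interval may consist of several disjoint parts
#' (`union = TRUE`): the width is then the summed span and the density
#' uses the total count, e.g. a 1.3 Mb + 1.1 Mb two-part interval with
#' 6,201 co-segregating variants has density 2,584/Mb.
#'
#' @param start,end Numeric vectors of part bounds (bp, 1-based
#'   inclusive).
#' @param n_coseg Total co-segregating variants: a scalar when
#'   `union = TRUE`, a vector parallel to `start` otherwise.
#' @param union If `TRUE` (default) the parts form one interval and a
#'   single row is returned; if `FALSE`, metrics are computed per part.
#' @return Tibble with columns `width_mb`, `density_per_mb`.
#' @export
#' @examples
#' interval_metrics(51.9e6, 56.7e6, 13906)       # 4.8 Mb, 2897/Mb
#' interval_metrics(c(26.7e6, 31.7e6), c(28e6, 32.8e6), 6201)  # 2584/Mb
interval_metrics <- function(start, end, n_coseg, union = TRUE) {
  if (any(end < start)) stop("zero- or negative-width interval")
  span <- end - start + 1
  if (union) {
    w <- sum(span) / 1e6
    tibble(width_mb = round(w, 1), density_per_mb = round(sum(n_coseg) / w))
  } else {
    w <- span / 1e6
    tibble(width_mb = round(w, 1), density_per_mb = round(n_coseg / w))
  }
}

#' Co-segregating SNPs nearest the edges of an interval
#'
#' Selects up to `k` co-segregating SNPs closest to each edge of a
#' candidate interval — fixed markers suitable for genotyping assays
#' that verify the interval boundaries in additional animals.
#'
#' @param variants A variant tibble.
#' @param interval One-row data frame (or list) with `scaffold`,
#'   `start`, `end`.
#' @param k Markers per edge.
#' @param mask,cfg Passed to [is_informative()].
#' @return Variant rows with extra columns `edge` (`"start"`/`"end"`)
#'   and `edge_distance_bp`, at most `k` per edge.
#' @export
diagnostic_markers <- function(variants, interval, k = 3, mask = NULL,
                               cfg = scan_config()) {
  flagged <- flag_variants(as_variants(variants), mask, cfg, "genome")
  v <- flagged[flagged$scaffold == interval$scaffold &
                 flagged$pos >= interval$start & flagged$pos <= interval$end &
                 flagged$coseg & flagged$vclass == "SNP", , drop = FALSE]
  if (nrow(v) == 0) return(mutate(v, edge = character(0), edge_distance_bp = numeric(0)))
  pick <- function(edge_pos, label) {
    d <- abs(v$pos - edge_pos)
    idx <- order(d)[seq_len(min(k, nrow(v)))]
    mutate(v[idx, , drop = FALSE], edge = label, edge_distance_bp = d[idx])
  }
  bind_rows(pick(interval$start, "start"), pick(interval$end, "end")) |>
    dplyr::distinct(.data$scaffold, .data$pos, .data$edge, .keep_all = TRUE)
}
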