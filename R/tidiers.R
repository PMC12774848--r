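#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy window statistics
#'
#' @param x A `coseg_windows` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-window statistics.
#' @export
tidy.coseg_windows <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  attr(out, "config") <- NULL
  attr(out, "tier") <- NULL
  attr(out, "scaffolds") <- NULL
  out
}

#' One-row summary of a co-segregation scan
#'
#' @param x A `coseg_windows` tibble.
#' @param ... Unused.
#' @return A one-row tibble: windows, defined windows, scaffolds
#'   scanned, and the maximum co-segregation proportion.
#' @export
glance.coseg_windows <- function(x, ...) {
  tibble(
    tier = attr(x, "tier") %||% NA_character_,
    n_windows = nrow(x),
    n_defined = sum(x$defined),
    n_scaffolds = length(unique(x$scaffold)),
    max_proportion = if (any(x$defined)) max(x$proportion, na.rm = TRUE) else NA_real_
  )
}

#' Tidy candidate intervals
#'
#' @param x A `coseg_peaks` tibble.
#' @param ... Unused.
#' @return A plain tibble of candidate intervals.
#' @export
tidy.coseg_peaks <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  attr(out, "threshold") <- NULL
  out
}

#' One-row summary of called candidate intervals
#'
#' @param x A `coseg_peaks` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the threshold used, interval counts,
#'   and the top-ranked interval's location.
#' @export
glance.coseg_peaks <- function(x, ...) {
  top <- x[!is.na(x$rank) & x$rank == 1, , drop = FALSE]
  tibble(
    threshold = attr(x, "threshold") %||% NA_real_,
    n_intervals = nrow(x),
    n_disregarded = sum(x$disregarded),
    top_scaffold = if (nrow(top)) top$scaffold else NA_character_,
    top_start = if (nrow(top)) top$start else NA_real_,
    top_end = if (nrow(top)) top$end else NA_real_
  )
}

#' Tidy a simulated cross into its variant table
#'
#' @param x A `coseg_cross` from [simulate_cross()].
#' @param ... Unused.
#' @return The simulated variant tibble.
#' @export
tidy.coseg_cross <- function(x, ...) x$variants

#' One-row summary of a simulated cross
#'
#' @param x A `coseg_cross` from [simulate_cross()].
#' @param ... Unused.
#' @return A one-row tibble: markers, informative markers, offspring
#'   drawn, and the causal locus.
#' @export
glance.coseg_cross <- function(x, ...) {
  tibble(
    n_markers = nrow(x$variants),
    n_informative_truth = sum(x$truth$founders$informative),
    n_offspring_drawn = nrow(x$truth$offspring),
    causal_scaffold = x$truth$causal$scaffold,
    causal_pos = x$truth$causal$pos
  )
}
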