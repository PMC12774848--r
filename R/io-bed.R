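#' Read a BED repeat mask
#'
#' Loads a 3+ column BED file (0-based, half-open) of repetitive regions
#' to be excluded from the co-segregation scan, merging overlapping and
#' bookended intervals per scaffold. Lines with `start >= end` are
#' rejected with a warning.
#'
#' @param path Path to a BED file.
#' @return A `repeat_mask` tibble with columns `scaffold`, `start`,
#'   `end` (0-based half-open, merged, non-overlapping).
#' @export
read_bed_mask <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(bed) < 3) stop("BED file must have at least 3 columns")
  x <- tibble(
    scaffold = bed[[1]],
    start = as.numeric(bed[[2]]),
    end = as.numeric(bed[[3]])
  )
  bad <- x$start >= x$end
  if (any(bad)) {
    warning(sum(bad), " BED line(s) with start >= end rejected")
    x <- x[!bad, , drop = FALSE]
  }
  new_repeat_mask(x)
}

# merge to non-overlapping intervals and tag the class
new_repeat_mask <- function(x) {
  x <- x |>
    arrange(.data$scaffold, .data$start, .data$end) |>
    group_by(.data$scaffold) |>
    mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end), default = -Inf))) |>
    group_by(.data$scaffold, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    select("scaffold", "start", "end")
  class(x) <- c("repeat_mask", class(x))
  x
}

#' Query a repeat mask at 1-based positions
#'
#' @param mask A `repeat_mask` from [read_bed_mask()].
#' @param scaffold,pos Vectors (recycled) of scaffold names and 1-based
#'   positions.
#' @return Logical vector: `TRUE` where the position falls inside a
#'   masked interval.
#' @export
mask_contains <- function(mask, scaffold, pos) {
  n <- max(length(scaffold), length(pos))
  scaffold <- rep_len(scaffold, n)
  pos0 <- rep_len(pos, n) - 1  # to 0-based
  out <- logical(n)
  if (is.null(mask) || nrow(mask) == 0) return(out)
  for (s in unique(scaffold)) {
    m <- mask[mask$scaffold == s, , drop = FALSE]
    if (nrow(m) == 0) next
    i <- scaffold == s
    idx <- findInterval(pos0[i], m$start)
    out[i] <- idx > 0 & pos0[i] < m$end[pmax(idx, 1L)]
  }
  out
}
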