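#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a co-segregation scan
#'
#' Draws the classic mapping-by-sequencing panel: co-segregation
#' proportion against cumulative genomic position, scaffolds ordered
#' longest to shortest and coloured alternately. Undefined windows
#' (no informative variant) appear as gaps.
#'
#' @param object A `coseg_windows` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coseg_windows <- function(object, ...) {
  scaffolds <- attr(object, "scaffolds")
  w <- as_tibble(object)
  if (is.null(scaffolds)) {
    scaffolds <- w |> group_by(.data$scaffold) |>
      summarise(length = max(.data$end), .groups = "drop") |>
      scaffold_index()
  }
  offs <- c(0, cumsum(as.numeric(scaffolds$length)))[seq_len(nrow(scaffolds))]
  names(offs) <- scaffolds$scaffold
  w <- w |>
    filter(.data$defined) |>
    mutate(
      gpos = offs[.data$scaffold] + (.data$start + .data$end) / 2,
      colour_band = factor(match(.data$scaffold, scaffolds$scaffold) %% 2)
    )
  ggplot2::ggplot(w, ggplot2::aes(x = .data$gpos / 1e6, y = .data$proportion,
                                  colour = .data$colour_band)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("black", "red3")) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Cumulative position (Mb)",
                  y = "Proportion of co-segregating variants") +
    ggplot2::theme_classic()
}

#' Plot candidate intervals along their scaffolds
#'
#' @param object A `coseg_peaks` tibble.
#' @param ... Unused.
#' @return A ggplot object with one horizontal segment per interval,
#'   disregarded intervals drawn in grey.
#' @export
autoplot.coseg_peaks <- function(object, ...) {
  p <- as_tibble(object)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                                  y = .data$max_proportion,
                                  yend = .data$max_proportion,
                                  colour = .data$disregarded)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "red3", `TRUE` = "grey60"),
                                 name = "disregarded") +
    ggplot2::facet_wrap(~ scaffold, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Max window proportion") +
    ggplot2::theme_classic()
}
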