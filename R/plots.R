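#' Plot a reinforcement scan along the contig
#'
#' Draws the divergence differences (`dd_fst`, `dd_dxy`), the Tajima's D
#' contrast `td_d` and the mean recipient-population ancestry per window
#' against window midpoints, highlighting candidate windows.
#'
#' @param object An `rcd_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rcd_scan <- function(object, ...) {
  w <- tidy(object)
  long <- w |>
    mutate(mid = (.data$start + .data$end) / 2) |>
    select("chrom", "mid", "candidate",
           "dd_fst", "dd_dxy", "td_d", "mean_para_fas_q") |>
    tidyr::pivot_longer(cols = c("dd_fst", "dd_dxy", "td_d",
                                 "mean_para_fas_q"),
                        names_to = "statistic", values_to = "value")
  long$statistic <- factor(
    long$statistic,
    levels = c("dd_fst", "dd_dxy", "td_d", "mean_para_fas_q"),
    labels = c("D[d]~(F[ST])", "D[d]~(D[XY])", "TD[d]",
               "bar(q)[para~fas]")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$candidate),
                        size = 0.8, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$statistic),
                        scales = "free_y",
                        labeller = ggplot2::label_parsed) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "candidate") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.rcd_scan
#' @param scan An `rcd_scan`.
#' @export
plot_scan <- function(scan) autoplot.rcd_scan(scan)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
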