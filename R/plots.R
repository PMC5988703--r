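# ggplot2 views of annotation results.

#' Plot the read-start landscape around a position
#'
#' Shows the per-position validated start counts in a window around a
#' (candidate or called) TSS, the visual counterpart of the Poisson peak
#' test.
#'
#' @param counts Start count map (`pos`, `strand`, `n`), e.g.
#'   `ann$start_counts`.
#' @param pos,strand Anchor site.
#' @param window Half-window in nt (50).
#' @return A ggplot.
#' @export
plot_start_profile <- function(counts, pos, strand, window = 50L) {
  df <- counts[counts$strand == strand &
                 abs(counts$pos - pos) <= window, , drop = FALSE]
  offs <- if (strand == "+") df$pos - pos else pos - df$pos
  dd <- tibble::tibble(offset = offs, n = df$n)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$offset, y = .data$n)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$offset, yend = 0)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = sprintf("offset from %s:%d (nt, 5'→3')", strand, pos),
                  y = "validated read starts") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for annotation results
#'
#' `type = "map"` draws the annotated transcripts along the genome
#' coloured by category; `type = "overlaps"` shows per-class overlap
#' counts and sizes; `type = "dispersion"` compares the start/end
#' dispersion statistics across kinetic classes and PAS types.
#'
#' @param object A `viranno_annotation`.
#' @param type One of `"map"`, `"overlaps"`, `"dispersion"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.viranno_annotation <- function(object, type = c("map", "overlaps",
                                                         "dispersion"), ...) {
  type <- match.arg(type)
  if (type == "map") {
    tx <- object$transcripts
    tx <- tx[order(tx$span_start), , drop = FALSE]
    tx$row <- seq_len(nrow(tx))
    ggplot2::ggplot(tx) +
      ggplot2::geom_segment(
        ggplot2::aes(x = .data$span_start, xend = .data$span_end,
                     y = .data$row, yend = .data$row,
                     colour = .data$category),
        linewidth = 2,
        arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))
      ) +
      ggplot2::labs(x = "genome position (bp)", y = NULL,
                    colour = "category") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  } else if (type == "overlaps") {
    ov <- object$overlaps
    ggplot2::ggplot(ov, ggplot2::aes(x = .data$cls, y = .data$length,
                                     fill = .data$predicted)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = "overlap class", y = "overlap length (bp)") +
      ggplot2::theme_minimal()
  } else {
    sd1 <- object$start_dispersion
    sd2 <- object$tes_dispersion
    df <- dplyr::bind_rows(
      if (!is.null(sd1)) dplyr::mutate(sd1, site = "TSS (kinetic class)"),
      if (!is.null(sd2)) dplyr::mutate(sd2, site = "TES (PAS)")
    )
    df <- df[!is.na(df$sd), , drop = FALSE]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$sd)) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~site, scales = "free_x") +
      ggplot2::labs(x = NULL, y = "off-peak frequency SD") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
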