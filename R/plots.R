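# ggplot2 displays for the main result types.

#' Volcano plot of a differential-abundance table
#'
#' @param object A `circmir_da` table.
#' @param fdr_threshold Highlighting threshold on the FDR.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot circmir_da
#' @export
autoplot.circmir_da <- function(object, fdr_threshold = 0.1, ...) {
  df <- as_tibble(unclass(object))
  df <- df[is.finite(df$log2_fold) & !is.na(df$fdr), , drop = FALSE]
  df$significant <- df$fdr < fdr_threshold
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fold,
                                   -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = paste0("FDR < ", fdr_threshold)) +
    ggplot2::labs(x = "log2 fold difference (group 1 vs group 2)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Ranked abundance plot
#'
#' Range-and-mean display of the most abundant circulating miRNAs: one
#' column per gene spanning its across-sample range, a point at its mean,
#' genes ordered by decreasing mean.
#'
#' @param counts Count or normalized tibble.
#' @param top_n Number of top genes to show.
#' @param highlight Gene ids to mark (e.g. the signature genes).
#' @return A ggplot.
#' @export
plot_abundance_ranks <- function(counts, top_n = 100L,
                                 highlight = c("hsa-miR-375",
                                               "hsa-miR-122")) {
  rk <- rank_by_abundance(counts, top_n)
  rk$gene <- factor(rk$gene, levels = rk$gene)
  rk$marked <- rk$gene %in% highlight
  ggplot2::ggplot(rk, ggplot2::aes(.data$gene)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$min,
                                         ymax = .data$max),
                            colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean,
                                     colour = .data$marked),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "normalized counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 5,
                                                       vjust = 0.5))
}

#' Small-RNA class composition plot
#'
#' @param composition Long composition tibble from [annotate_samples()]
#'   (`sample`, `class`, `fraction`).
#' @return A ggplot.
#' @export
plot_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(.data$sample, .data$fraction,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of assigned reads") +
    ggplot2::theme_minimal()
}
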