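#' Plot a ranked drug score table
#'
#' FAM score against rank for all ranked drugs, optionally highlighting a
#' drug set (e.g. the known effective drugs), whose clustering toward low
#' ranks is the visual analogue of the AUROC and percentile metrics.
#'
#' @param object A `drug_score_table`.
#' @param highlight Optional character vector of drug ids to highlight.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drug_score_table <- function(object, highlight = NULL, ...) {
  dat <- filter(object, !is.na(.data$rank))
  dat$highlighted <- if (is.null(highlight)) {
    FALSE
  } else {
    dat$drug_id %in% normalize_drug_ids(highlight)
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$fam)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlighted),
                        show.legend = !is.null(highlight)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 name = "in drug set") +
    ggplot2::labs(x = "rank (1 = best)", y = "FAM score") +
    ggplot2::theme_minimal()
  p
}

#' Plot the under-sampled AUROC distribution
#'
#' Histogram of the per-repetition AUROC values with the mean marked; the
#' spread shows the sampling variability induced by random under-sampling
#' of the negative class.
#'
#' @param object A `fam_auroc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fam_auroc <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$auroc)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_auroc, linetype = 2) +
    ggplot2::labs(x = "AUROC per repetition", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot leave-one-protein-out ranking stability
#'
#' Kendall tau of the recomputed versus original drug ranking for each
#' excluded top-associated gene; values near 1 mean no single protein
#' drives the predictions.
#'
#' @param object A `fam_stability` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fam_stability <- function(object, ...) {
  dat <- object$report |>
    mutate(gene_id = factor(.data$gene_id,
                            levels = rev(.data$gene_id)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tau, y = .data$gene_id)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$gene_id),
                          colour = "grey70") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "Kendall tau vs full ranking", y = "excluded gene") +
    ggplot2::theme_minimal()
}
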