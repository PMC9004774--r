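#' Plot the distribution of final signature scores
#'
#' @param object A `"signature_scores"` tibble from [score_cohort()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signature_scores
#' @export
autoplot.signature_scores <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$final_score)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "final score (z of μUP/μDW)", y = "samples",
                  title = attr(object, "signature") %||% "signature scores") +
    ggplot2::theme_minimal()
}

#' Signature scores by BMI class
#'
#' Box-and-jitter plot of final scores per BMI class, optionally
#' facetted by menopausal status — the tabular analogue of a
#' per-group score strip.
#'
#' @param scores A [score_cohort()] result.
#' @param assignment An [assign_groups()] result.
#' @param facet_menopause Facet by menopause stratum.
#' @return A ggplot object.
#' @export
plot_score_by_group <- function(scores, assignment, facet_menopause = FALSE) {
  score_col <- if ("final_score" %in% names(scores)) "final_score" else "score1"
  dat <- dplyr::inner_join(
    dplyr::select(scores, "sample_id", score = dplyr::all_of(score_col)),
    assignment, by = "sample_id")
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$bmi_class, y = .data$score,
                                         colour = .data$bmi_class)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "final signature score") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (facet_menopause) p <- p + ggplot2::facet_wrap(~menopause)
  p
}

#' Volcano plot of a differential-expression result
#'
#' Highlights the genes retained in a signature's up/down sets when
#' one is supplied.
#'
#' @param de A [differential_expression()] result.
#' @param signature Optional `"gene_signature"` to highlight.
#' @return A ggplot object.
#' @export
plot_de_volcano <- function(de, signature = NULL) {
  dat <- dplyr::mutate(de, set = dplyr::case_when(
    !is.null(signature) & .data$gene_id %in% (signature$up %||% character()) ~ "up",
    !is.null(signature) & .data$gene_id %in% (signature$down %||% character()) ~ "down",
    TRUE ~ "other"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(pmax(.data$p.value, 1e-300)),
                                    colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "navy",
                                            other = "grey70")) +
    ggplot2::labs(x = "log2 fold change (phospho-high vs low)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}
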