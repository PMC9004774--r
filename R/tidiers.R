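#' Tidy a gene signature into a long gene table
#'
#' @param x A `"gene_signature"`.
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `direction` (up/down).
#' @method tidy gene_signature
#' @export
tidy.gene_signature <- function(x, ...) {
  tibble(gene_id = c(x$up, x$down),
         direction = rep(c("up", "down"), c(length(x$up), length(x$down))))
}

#' One-row summary of a gene signature
#'
#' @param x A `"gene_signature"`.
#' @param ... Unused.
#' @return One-row tibble: set sizes, anchor, thresholds, discordant
#'   count.
#' @method glance gene_signature
#' @export
glance.gene_signature <- function(x, ...) {
  p <- x$provenance
  tibble(name = p$name, anchor = p$anchor %||% NA_character_,
         n_up = length(x$up), n_down = length(x$down),
         n_discordant = p$n_discordant, n_genes_tested = p$n_genes_tested,
         lfc_min = p$lfc_min, fdr_max = p$fdr_max, p_max = p$p_max)
}

#' One-row summary of cohort signature scores
#'
#' @param x A `"signature_scores"` tibble.
#' @param ... Unused.
#' @return One-row tibble: n, score spread, per-set coverage.
#' @method glance signature_scores
#' @export
glance.signature_scores <- function(x, ...) {
  tibble(n = nrow(x), mean_score1 = mean(x$score1), sd_score1 = sd(x$score1),
         coverage_up = attr(x, "coverage_up"),
         coverage_down = attr(x, "coverage_down"),
         signature = attr(x, "signature") %||% NA_character_)
}

#' Tidy a cohort report into its comparison table
#'
#' @param x A `"cohort_report"`.
#' @param ... Unused.
#' @return The pairwise comparison tibble.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) {
  as_tibble(x$comparisons)
}

#' One-row-per-group summary of a cohort report
#'
#' @param x A `"cohort_report"`.
#' @param ... Unused.
#' @return The per-group summary tibble.
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  as_tibble(x$summary)
}
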