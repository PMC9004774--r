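#' Collapse probe-level rows to genes by largest interquartile range
#'
#' For each gene with several probes, keeps exactly the probe whose
#' across-sample IQR (Q3 - Q1, linear-interpolation quantiles) is
#' largest; ties are broken by the lexicographically smallest probe id.
#' Probes absent from the annotation are dropped and their count
#' reported.
#'
#' @param matrix Probe-by-sample expression tibble (first column probe
#'   ids).
#' @param annotation Tibble with columns `probe_id` and `gene_id`; each
#'   probe maps to exactly one gene.
#' @return A gene-by-sample tibble (first column `gene_id`) with one row
#'   per distinct annotated gene; the value scale is inherited.
#' @export
#' @examples
#' m <- tibble::tibble(probe_id = c("pA", "pB"),
#'                     s1 = c(0, 5), s2 = c(10, 5), s3 = c(0, 5))
#' ann <- tibble::tibble(probe_id = c("pA", "pB"), gene_id = c("gX", "gX"))
#' collapse_probes(m, ann)  # keeps pA (IQR of pB is 0)
collapse_probes <- function(matrix, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    abort("probe annotation is empty", class = "phosphosig_error_input")
  }
  if (!all(c("probe_id", "gene_id") %in% names(annotation))) {
    abort("annotation must have columns `probe_id` and `gene_id`",
          class = "phosphosig_error_input")
  }
  if (anyDuplicated(annotation$probe_id)) {
    abort("annotation maps some probe to more than one gene",
          class = "phosphosig_error_input")
  }
  scale <- expr_scale(matrix)
  probe_col <- names(matrix)[1]
  n_in <- nrow(matrix)
  joined <- dplyr::inner_join(
    dplyr::rename(matrix, probe_id = !!probe_col), annotation, by = "probe_id")
  n_dropped <- n_in - nrow(joined)
  if (n_dropped > 0) {
    inform(sprintf("collapse_probes: %d unannotated probe(s) dropped", n_dropped))
  }
  value_cols <- setdiff(names(joined), c("probe_id", "gene_id"))
  iqr <- apply(as.matrix(joined[, value_cols, drop = FALSE]), 1L,
               function(v) unname(quantile(v, 0.75) - quantile(v, 0.25)))
  out <- joined |>
    dplyr::mutate(.iqr = iqr) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$.iqr), .data$probe_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select("gene_id", dplyr::all_of(value_cols))
  set_expr_scale(out, scale)
}

#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) to share one empirical distribution:
#' the means of the column-sorted matrix rows. Within-column ties
#' receive the mean of the corresponding sorted-row means. Row and
#' column labels are preserved, and the operation is idempotent.
#'
#' @param matrix Gene-by-sample expression tibble with at least two
#'   sample columns and no missing values.
#' @return A tibble of the same shape with normalized values.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
#'                     s1 = c(5, 2, 3), s2 = c(4, 1, 6))
#' quantile_normalize(m)
quantile_normalize <- function(matrix) {
  m <- tbl_to_matrix(matrix, "expression matrix")
  if (ncol(m) < 2L) {
    abort("quantile normalization needs at least 2 samples",
          class = "phosphosig_error_input")
  }
  if (any(!is.finite(m))) {
    abort("quantile normalization requires finite values",
          class = "phosphosig_error_input")
  }
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  set_expr_scale(matrix_to_tbl(qn, names(matrix)[1]), expr_scale(matrix))
}

#' Transform raw counts to log2 counts-per-million
#'
#' `value = log2(1e6 * x / L + 1)` with `L` the sample's total count.
#' The +1 pseudocount keeps all transformed values >= 0, which the
#' ratio-of-means signature score requires.
#'
#' @param matrix Counts-scale gene-by-sample tibble.
#' @return The transformed tibble with scale attribute `"log2"`.
#' @export
log_cpm <- function(matrix) {
  sc <- expr_scale(matrix)
  if (!is.null(sc) && sc != "counts") {
    abort(sprintf("log_cpm expects counts-scale input, got scale '%s'", sc),
          class = "phosphosig_error_input")
  }
  m <- tbl_to_matrix(matrix, "count matrix")
  if (any(m < 0)) {
    abort("log_cpm: negative counts", class = "phosphosig_error_input")
  }
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("log_cpm: zero library size in sample(s): %s",
                  paste(colnames(m)[lib == 0], collapse = ", ")),
          class = "phosphosig_error_input")
  }
  out <- log2(sweep(m, 2, lib, "/") * 1e6 + 1)
  set_expr_scale(matrix_to_tbl(out, names(matrix)[1]), "log2")
}
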