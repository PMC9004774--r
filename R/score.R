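#' Per-sample ratio-of-means signature scores
#'
#' For each sample, the mean expression of the signature's up genes
#' (`mu_up`) and down genes (`mu_down`) are computed independently and
#' `score1 = mu_up / mu_down`. Expression must be on a non-negative
#' scale (log2(x+1) or intensity); counts are log-CPM transformed
#' first. Signature genes absent from the matrix reduce the per-set
#' coverage, which must reach `min_coverage`.
#'
#' @param expr Gene-by-sample expression tibble.
#' @param signature A `"gene_signature"`.
#' @param min_coverage Minimum fraction of each set's genes that must
#'   be present (default 0.5; cross-platform application loses genes).
#' @param eps Denominator guard: `mu_down <= eps` is an error naming
#'   the sample (default 1e-8).
#' @return A tibble: `sample_id`, `mu_up`, `mu_down`, `score1`;
#'   attributes `coverage_up`, `coverage_down`, `signature`.
#' @export
score_samples <- function(expr, signature, min_coverage = 0.5, eps = 1e-8) {
  if (!inherits(signature, "gene_signature")) {
    abort("`signature` must be a gene_signature",
          class = "phosphosig_error_input")
  }
  expr <- ensure_log_scale(expr)
  m <- tbl_to_matrix(expr, "expression matrix")
  if (any(m < 0)) {
    abort("signature scoring requires a non-negative expression scale (log2(x+1) or intensity)",
          class = "phosphosig_error_input")
  }
  found <- lapply(list(up = signature$up, down = signature$down),
                  intersect, y = rownames(m))
  coverage <- vapply(c("up", "down"), function(s) {
    length(found[[s]]) / length(signature[[s]])
  }, numeric(1))
  for (s in c("up", "down")) {
    if (length(found[[s]]) == 0) {
      abort(sprintf("no %s-set gene found in the expression matrix", s),
            class = "phosphosig_error_coverage")
    }
    if (coverage[[s]] < min_coverage) {
      abort(sprintf("%s-set coverage %.2f below min_coverage %.2f", s,
                    coverage[[s]], min_coverage),
            class = "phosphosig_error_coverage")
    }
    n_missing <- length(signature[[s]]) - length(found[[s]])
    if (n_missing > 0) {
      inform(sprintf("score_samples: %d %s-set gene(s) missing from the matrix",
                     n_missing, s))
    }
  }
  mu_up <- colMeans(m[found$up, , drop = FALSE])
  mu_down <- colMeans(m[found$down, , drop = FALSE])
  bad <- mu_down <= eps
  if (any(bad)) {
    abort(sprintf("mu_down <= %g in sample(s): %s", eps,
                  paste(head(names(mu_down)[bad], 5), collapse = ", ")),
          class = "phosphosig_error_degenerate")
  }
  out <- tibble(sample_id = colnames(m), mu_up = unname(mu_up),
                mu_down = unname(mu_down),
                score1 = unname(mu_up / mu_down))
  attr(out, "coverage_up") <- unname(coverage[["up"]])
  attr(out, "coverage_down") <- unname(coverage[["down"]])
  attr(out, "signature") <- signature$provenance$name
  out
}

#' Z-scale a score vector within its cohort
#'
#' `z = (x - mean(x)) / sd_pop(x)` with the population (divide-by-n)
#' standard deviation, so the output has mean 0 and population SD 1.
#'
#' @param x Numeric vector, length >= 2, nonzero variance.
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' zscale(c(1, 2, 3))  # -1.2247, 0, 1.2247
zscale <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    abort("zscale needs a numeric vector of length >= 2",
          class = "phosphosig_error_input")
  }
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    abort("zscale: zero variance", class = "phosphosig_error_degenerate")
  }
  (x - mean(x)) / s
}

#' Score a cohort: ratio-of-means score1 plus cohort-wise z (final score)
#'
#' Runs [score_samples()] and z-scales `score1` across the cohort being
#' scored ([zscale()]), yielding the final score. A cohort whose
#' samples all score identically is degenerate and raises an error.
#'
#' @inheritParams score_samples
#' @return A tibble of class `"signature_scores"`: `sample_id`,
#'   `mu_up`, `mu_down`, `score1`, `final_score`; attributes
#'   `coverage_up`, `coverage_down`, `signature`.
#' @export
score_cohort <- function(expr, signature, min_coverage = 0.5, eps = 1e-8) {
  out <- score_samples(expr, signature, min_coverage = min_coverage, eps = eps)
  out$final_score <- zscale(out$score1)
  class(out) <- c("signature_scores", class(out))
  out
}
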